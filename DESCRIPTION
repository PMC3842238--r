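Package: paleofam
Title: Mapping Gene-Family Evolution onto a Ranked Taxonomy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers the evolutionary history of a gene family from per-species
    homologue counts mapped onto a ranked (phylum-to-species) taxonomy. A
    strict-majority parsimony walk assigns ancestral copy numbers, reports the
    family's origin, flags unexpected presences as horizontal gene transfer
    candidates, and lists gene gains and losses. Also provides an
    alignment-conservation scanner for nominating candidate catalytic residues
    against a reference numbering, and a seeded simulator of gene-family
    evolution (duplication, loss, transfer) with ground-truth event logs for
    measuring recovery. Ships a worked analysis of the archaeal thermopsin
    peptidase family (MEROPS A5).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
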