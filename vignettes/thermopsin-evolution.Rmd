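---
title: "Mapping gene-family evolution onto a ranked taxonomy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping gene-family evolution onto a ranked taxonomy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleofam)
```

## The problem

Thermopsin is a secreted peptidase of *Sulfolobus acidocaldarius*, active at
pH 2 and high temperature, and the type example of MEROPS family A5 — the
only peptidase family restricted to the Archaea. Its homologues are scattered
across distantly related archaeal lineages (Thermoplasmata in the
Euryarchaeota; Sulfolobales, Thermoproteales and others in the
Crenarchaeota), which raises two questions this package addresses:

1. **Where did the family originate, and which presences are best explained
   by horizontal gene transfer (HGT)?** Given only per-species homologue
   counts and the ranked NCBI-style classification, infer ancestral copy
   numbers, the family's birthplace, transfer candidates, and gains and
   losses.
2. **Which residues might form the active site?** No structure is known for
   any family member; candidate catalytic residues are nominated from column
   conservation in a multiple alignment numbered against the
   preprothermopsin precursor.

Both stages are backed by a seeded simulator with ground-truth event logs,
so every claim the package makes can be measured on data where the answer is
known.

## The parsimony model on a ranked taxonomy

The tree is the ranked taxonomy itself — phylum, class, order, family,
genus, species, exactly one node per rank on every root-to-tip path — not a
branch-length phylogeny. The method is therefore count- and rank-based only;
it assumes the classification mirrors the organismal phylogeny, and it
neither uses nor estimates divergence times.

**Observation model.** Each species tip carries an observed homologue count.
A subtree is *surveyed* if it contains at least one completely sequenced
genome: only surveyed children carry information, because a homologue can
not be found in a genome nobody has sequenced. Unsurveyed children are
excluded from both the numerator and the denominator of the majority rule —
absence of evidence in an unsequenced clade is not evidence of absence.

**Strict-majority rule.** Walking bottom-up rank by rank, a parent taxon is
credited with the family only if *strictly more than half* of its surveyed
children carry a (nonzero) count. The strictness matters: with two children
of which one bears, the parent is not credited, so a single transferred gene
never drags the family up the tree; this is what keeps transfer candidates
separated from the origin.

**Ancestral value.** When the majority passes, the assigned copy number is
the integer minimizing the sum of absolute differences to the nonzero child
counts — the integer L1 median, with ties broken toward the smaller integer.
Any other integer implies a strictly larger total of gains plus losses on
the child branches, so the L1 median is the arithmetically exact reading of
"maximally parsimonious" for copy numbers; the tie-break prefers the more
conservative (smaller) ancestral gene complement. The lower median
`sort(x)[ceiling(n/2)]` realizes this in closed form, and the test suite
checks it against a brute-force search at every use.

**Origin, HGT, gains, losses.** The *origin* is the highest-ranked maximal
credited taxon (a credited taxon none of whose ancestors is credited). Every
other maximal credited taxon is an *unexpected presence* — an HGT candidate.
Because species tips always carry their observed count, a lone bearer inside
an uncredited genus is itself maximal and is reported by its species name
(this is how a single stray species such as *Pyrobaculum* sp. 1860 appears),
while a bearer whose whole unary chain is credited is reported at the top of
that chain (how a one-species family such as Thermofilaceae appears). Gains
and losses compare each credited node with its credited parent: larger is a
gain, smaller-but-nonzero a paralogue reduction, and a species count of zero
under a credited parent a *complete loss*, reported separately because it
removes the family rather than thinning it.

**Tie-breaks.** The origin tie-break (rank, then number of bearing surveyed
species in the clade, then name) is this package's choice; on the thermopsin
data the winner is unique, so the tie-break is exercised only by simulated
data. Child ordering is lexicographic everywhere, making tree construction
and all reports independent of input row order.

## Design choices on the input side

* **Strain aggregation.** Sequence databases list strains; the analysis
  counts species. Multiple rows with one species name collapse to one tip
  carrying the maximum count across strains (`aggregate = "max"`, the
  default, treating strains as redundant samples of one proteome);
  `aggregate = "sum"` is available when strains are known to carry distinct
  loci.
* **Placeholder ranks.** Lineages missing intermediate ranks (common for
  *Candidatus* taxa) are bridged with placeholder nodes named
  `<nearest-named-child>_incertae_<rank>`, so the rank-by-rank walk always
  sees exactly one rank per step and never skips a level.
* **Unclassified taxa** (`classified = FALSE`) are dropped before the tree
  is built; their counts stay visible in the table for the phenotype
  tabulation but cannot be placed on the taxonomy.
* Blank phenotype cells are *unknown* (`NA`), never `FALSE`; the phenotype
  crosstab excludes unknowns from every margin.

## The packaged thermopsin table

`thermopsin_records()` ships the lineage table behind the worked analysis:
52 rows — every completely sequenced archaeal genome considered plus every
homologue-bearing species, 21 bearers in all. The published account of the
family is internally inconsistent in places (the *Sulfolobus islandicus*
count appears as both seven and one; several counts were never printed), so
disputed or reconstructed cells carry `disputed = TRUE` and a free-text
`note`. Consequences:

* the **qualitative** results — origin in the class Thermoplasmata, and the
  transfer-candidate set containing Sulfolobales, Thermofilaceae,
  *Caldivirga*, *Thermoproteus* and *Pyrobaculum* sp. 1860 — are stable
  under every resolution of the disputed cells we examined, and they are
  what the test suite asserts;
* the **specific ancestral integers** (e.g. four copies for the ancestor of
  Sulfolobaceae) depend on the disputed leaf counts and cannot be
  reproduced from the published text alone; the package computes and
  reports its own, but treats them as illustrative and does not test their
  values.

## The conservation scan

The alignment object maps 1-based reference positions to alignment columns
by skipping reference gaps (`pos2col`), so every claim is made in
preprothermopsin precursor numbering — counting from the initiator Met
through the signal peptide and propeptide, with the mature peptidase domain
at roughly residues 32–330. Counts are of explicit residues only: gaps and
ambiguity codes never match. The default residue classes encode the
conservative interchanges relevant to an aspartic peptidase: D, D/N
(asparagine can deamidate to aspartate), E, E/Q, and S/T (interchangeable
nucleophiles). The default reporting threshold of 0.6 is chosen so that all
five candidate aspartate positions — conserved in 28 to 70 of the 75
sequences, with D∪N at position 129 reaching 71 — are reportable under the
D/N class; the threshold is a plain argument and any value in (0, 1] can be
used.

**The synthetic reference alignment.** The original supplementary alignment
is distributed only as a rendered document without deposited accessions, so
the package ships a *synthetic* stand-in built by `simulate_alignment()`:
every documented position carries its residue in exactly the documented
number of sequences (28 D and 43 N at 129, 48 D at 144, 61 D at 228, 70 D at
257, 61 D at 302, 51 T and 22 S at 150, out of 75), motif-context positions
(QDV, DNVWN, YDKITI, DAELV, Asp-Thr-Gly) carry plausible synthetic counts,
and all unconstrained cells are uniform over the remaining amino acids — so
the engineered counts can never be inflated by chance and are independent of
the background seed. What this buys and what it does not: the scanner's
arithmetic (projection, counting, class sums, thresholding) is fully
exercised against known answers, but the stand-in has no gaps, no
phylogenetic correlation between columns, and no real sequence content —
conclusions about the real family rest on the documented counts themselves,
not on this alignment.

## The simulator and what passing tests mean

`simulate_family()` draws a taxonomy (by default 3 phyla, 2–3 children per
node at every lower rank — a size where majority decisions are non-trivial
but hundreds of runs stay cheap), seeds one gene copy at a uniformly chosen
taxon of the origin rank (class by default, matching the depth of the
thermopsin question), and walks down rank by rank. Per rank step each gene
copy is independently lost with `p_loss` and duplicated with `p_dup` (a
branching process — the simplest model consistent with repeated rounds of
duplication), and with probability `p_hgt` one copy is transferred into a
uniformly chosen taxon at the current rank with no bearing ancestor —
clade-to-clade transfer, mirroring the ancestral-lineage transfer inferred
for thermopsin rather than a tip-to-tip event. Defaults are `p_dup = 0.2`
(four rank steps at 0.2 give an expected 2.07 copies per bearing species —
a "few rounds of duplication" regime), `p_loss = 0.05`, `p_hgt = 0.05`.

A single seeded stream drives tree shape, then origin choice, then events in
canonical taxon order, so identical parameters and seed give byte-identical
output, and the ordered event log replayed from the origin reproduces the
final counts exactly — an invariant the suite checks on every run it
simulates.

The validation study (`analysis/03_simulation_study.R`, 100 runs per
condition) measures: origin recovery, transfer sensitivity and precision (a
candidate is a true positive if it names a logged transfer's destination
clade or a descendant), and event-level gain/loss F1. Two readings matter:

* With duplication only (`p_loss = p_hgt = 0`), origin recovery is 100% and
  no transfer is ever falsely flagged (both also asserted over 200 runs in
  the acceptance tests).
* With loss switched on, losses fragment clades and both origin recovery
  and transfer precision degrade — the metric is reported, not asserted
  against a threshold, because that degradation is a property of the method
  being measured, not a bug. Event-level loss F1 is low even at
  `p_loss = 0`: the inference reports events *relative to the L1-median
  baseline* among siblings, so a child that merely duplicated less than its
  siblings is reported as a reduction. The F1 therefore measures agreement
  between two legitimately different event definitions and is most useful
  as a trend, not an absolute.

What the simulator does not emulate: real taxonomies' wildly uneven
branching, correlated survey effort (sequenced genomes cluster in cultivable
clades), and any sequence-level evolution. Passing recovery tests show the
inference is correct *given the model's assumptions*; they cannot show the
assumptions hold for real archaea.

## Numerical and degenerate-input conventions

* Majority comparisons are done in integers (`2 * support > surveyed`), so
  no floating-point boundary can flip a decision.
* A family absent from every species yields a distinct "family absent"
  result, not an error; inference on a tree without species counts is an
  error.
* A degenerate simulated taxonomy with nowhere to transfer to skips the
  transfer step with a warning rather than failing the run.
* Transfer sensitivity is `NA` (undefined) when no transfer was simulated;
  precision is 1 when nothing was reported. Empty gain/loss sets on both
  sides score F1 = 1.
* Problem sizes in the shipped tests and scripts — 500 random trees for the
  parsimony properties, 200 runs for replay/recovery, 1000 for the
  branching-process calibration, 100 per grid cell in the validation study —
  were chosen once as the smallest sizes at which the binomial noise on the
  reported rates is a few percent or less.

## Known limitations

* The method sees presence only through surveyed genomes; a bearer known
  from protein databases but lacking a sequenced genome must be flagged
  `genome_sequenced = TRUE` to participate in majority decisions (the
  packaged table does so for all bearers).
* Rank-based parsimony cannot distinguish an ancient transfer into a clade's
  ancestor from independent origin in that clade, and it dates nothing.
* The canonical six ranks are a modelling choice; intermediate ranks
  (suborders etc.) must be collapsed onto them before input.
* The phenotype tabulation is descriptive (counts and violator lists); it
  deliberately fits no association model, since survey effort and phylogeny
  confound any naive test of the "only in thermoacidophiles" pattern.
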