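#' Thermopsin (family A5) species records
#'
#' The packaged lineage table for the thermopsin analysis: every archaeon
#' with a completely sequenced genome considered in the study plus every
#' species carrying a thermopsin homologue, with ranked lineage, survey and
#' phenotype flags and the per-species homologue count. The published
#' account of the family contains internal inconsistencies (e.g. the
#' \emph{Sulfolobus islandicus} count is given as both seven and one), so
#' cells that are contradictory or were never printed are best-effort values
#' flagged in the \code{disputed} column with a \code{note}; the table
#' supports qualitative reproduction (origin, transfer candidates), not
#' exact ancestral integers.
#'
#' @return Species records (see \code{\link{read_lineage_table}}) with extra
#'   \code{disputed} and \code{note} columns.
#' @export
thermopsin_records <- function() {
  path <- system.file("extdata", "thermopsin_lineages.tsv",
                      package = "paleofam", mustWork = TRUE)
  rec <- read_lineage_table(path)
  rec$disputed <- .parse_flag(rec$disputed, blank = FALSE)
  rec
}

#' Conservation profile of the family A5 reference alignment
#'
#' Per-position residue counts (out of 75 aligned peptidase-domain
#' homologues, in preprothermopsin numbering) used to parameterize the
#' synthetic reference alignment. The eight \code{candidate} rows are the
#' reported conservation counts behind the candidate catalytic residues of
#' the family: the five well-conserved aspartates (Asp129/144/228/257/302),
#' the Asn replacing Asp129, and the Thr150/Ser150 pair. The remaining rows
#' reconstruct the motif context (QDV, DNVWN, YDKITI, DAELV, Asp-Thr-Gly)
#' and other well-conserved positions with plausible synthetic counts.
#'
#' @return Data.frame with columns \code{position}, \code{residue},
#'   \code{count}, \code{fraction}, \code{candidate}.
#' @export
thermopsin_conservation_spec <- function() {
  n <- 75L
  spec <- data.frame(
    position = c(129L, 129L, 144L, 228L, 257L, 302L, 150L, 150L,
                 109L, 111L, 128L, 130L,
                 145L, 146L, 147L, 148L,
                 227L, 229L, 230L, 231L, 232L,
                 258L, 259L, 260L, 261L,
                 303L, 304L, 305L),
    residue = c("D", "N", "D", "D", "D", "D", "T", "S",
                "Q", "N", "Q", "V",
                "N", "V", "W", "N",
                "Y", "K", "I", "T", "I",
                "A", "E", "L", "V",
                "T", "G", "E"),
    count = c(28L, 43L, 48L, 61L, 70L, 61L, 51L, 22L,
              63L, 61L, 68L, 60L,
              55L, 58L, 62L, 60L,
              58L, 52L, 57L, 55L, 54L,
              63L, 60L, 62L, 59L,
              57L, 50L, 58L),
    candidate = c(rep(TRUE, 8L), rep(FALSE, 20L)),
    stringsAsFactors = FALSE)
  spec$fraction <- spec$count / n
  spec
}

#' Synthetic reference alignment for the thermopsin family
#'
#' A synthetic stand-in for the 75-sequence peptidase-domain alignment of
#' family A5, generated by \code{\link{simulate_alignment}} so that every
#' position in \code{\link{thermopsin_conservation_spec}} carries exactly
#' its specified residue counts (the engineered counts are deterministic;
#' only the unconstrained background cells depend on \code{seed}). The
#' first sequence is the ungapped preprothermopsin reference, so alignment
#' columns coincide with precursor numbering.
#'
#' @param seed Seed for the unconstrained background cells.
#' @return A \code{ref_alignment} of 75 sequences x 340 columns.
#' @export
thermopsin_reference_alignment <- function(seed = 2013L) {
  simulate_alignment(75L, 340L, thermopsin_conservation_spec(), seed = seed,
                     reference_id = "preprothermopsin")
}
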