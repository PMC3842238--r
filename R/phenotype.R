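#' Cross-tabulate homologue presence against growth phenotypes
#'
#' Tests the co-distribution of the gene family with hyperthermophily and
#' acidophily: presence/absence of a homologue is tabulated against each
#' phenotype flag, excluding species whose flag is unknown. Also returns the
#' two interesting violator lists: homologue-bearing species that are not
#' hyperthermophiles, and acidophilic hyperthermophiles that nevertheless
#' lack a homologue.
#'
#' @param records Species records (see \code{\link{read_lineage_table}}).
#'   Strains are collapsed per species (maximum count, flags OR-combined) so
#'   each species is tallied once.
#' @return A list: \code{hyperthermophile} and \code{acidophile} 2x2 tables
#'   (presence x flag), \code{bearers_not_hyperthermophilic} and
#'   \code{thermoacidophiles_without_homologue} (character vectors of species
#'   names), and \code{n_unknown} per phenotype.
#' @export
phenotype_crosstab <- function(records) {
  records <- as_species_records(records)
  split_rec <- split(records, records$species)
  sp <- data.frame(
    species = names(split_rec),
    present = vapply(split_rec, function(r) any(r$homologue_count > 0L),
                     logical(1)),
    hyper = vapply(split_rec, function(r) .combine_flag(r$hyperthermophile),
                   logical(1)),
    acid = vapply(split_rec, function(r) .combine_flag(r$acidophile),
                  logical(1)),
    stringsAsFactors = FALSE)

  tab <- function(flag) {
    keep <- !is.na(flag)
    table(presence = factor(sp$present[keep], levels = c(FALSE, TRUE),
                            labels = c("absent", "present")),
          phenotype = factor(flag[keep], levels = c(FALSE, TRUE),
                             labels = c("no", "yes")))
  }
  list(
    hyperthermophile = tab(sp$hyper),
    acidophile = tab(sp$acid),
    bearers_not_hyperthermophilic =
      sort(sp$species[sp$present & sp$hyper %in% FALSE]),
    thermoacidophiles_without_homologue =
      sort(sp$species[!sp$present & sp$hyper %in% TRUE & sp$acid %in% TRUE]),
    n_unknown = c(hyperthermophile = sum(is.na(sp$hyper)),
                  acidophile = sum(is.na(sp$acid))))
}
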