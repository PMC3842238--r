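#' Simulate an alignment with controlled column conservation
#'
#' Generates an ungapped alignment in which each specified column carries a
#' given residue in exactly \code{round(fraction * n)} sequences;
#' unconstrained cells are drawn uniformly from the remaining standard amino
#' acids, so the engineered counts can never be inflated by chance. Several
#' residues may be specified at one position (their carrier sets are
#' disjoint, filled in input order starting from sequence 1); the same
#' residue twice at one position, or carrier totals exceeding \code{n}, are
#' contradictory and rejected. The first sequence is the ungapped reference
#' and carries the first specified residue at every specified position.
#'
#' @param n_sequences Number of sequences.
#' @param length Alignment length (equals the reference length: no gaps).
#' @param conserved_spec Data.frame with columns \code{position},
#'   \code{residue} (single letters), \code{fraction} in [0, 1].
#' @param seed Optional integer seed (restores the RNG state on exit).
#' @param reference_id Identifier of the first sequence.
#' @return A \code{ref_alignment}.
#' @export
#' @examples
#' aln <- simulate_alignment(20, 30,
#'   data.frame(position = 10, residue = "D", fraction = 1.0), seed = 42)
#' count_residue_at(aln, 10, "D") # 20
simulate_alignment <- function(n_sequences, length, conserved_spec,
                               seed = NULL,
                               reference_id = "preprothermopsin") {
  n <- as.integer(n_sequences)
  L <- as.integer(length)
  stopifnot(n >= 2L, L >= 1L)
  spec <- as.data.frame(conserved_spec, stringsAsFactors = FALSE)
  stopifnot(all(c("position", "residue", "fraction") %in% names(spec)))
  spec$position <- as.integer(spec$position)
  spec$residue <- toupper(as.character(spec$residue))
  if (any(spec$position < 1L | spec$position > L))
    stop("conserved positions must lie in 1..", L)
  if (any(spec$fraction < 0 | spec$fraction > 1))
    stop("fractions must lie in [0, 1]")
  if (!all(spec$residue %in% .AA20))
    stop("residues must be single standard amino-acid letters")
  for (p in unique(spec$position)) {
    s <- spec[spec$position == p, ]
    if (anyDuplicated(s$residue))
      stop("contradictory spec: residue given twice at position ", p)
    if (sum(round(s$fraction * n)) > n)
      stop("contradictory spec: carrier counts exceed n at position ", p)
  }

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    })
    set.seed(seed)
  }

  mat <- matrix("", nrow = n, ncol = L)
  for (col in seq_len(L)) {
    s <- spec[spec$position == col, , drop = FALSE]
    if (nrow(s)) {
      filled <- 0L
      for (k in seq_len(nrow(s))) {
        m <- as.integer(round(s$fraction[k] * n))
        if (m > 0L) mat[filled + seq_len(m), col] <- s$residue[k]
        filled <- filled + m
      }
      if (filled < n) {
        pool <- setdiff(.AA20, s$residue)
        mat[(filled + 1L):n, col] <- sample(pool, n - filled, replace = TRUE)
      }
    } else {
      mat[, col] <- sample(.AA20, n, replace = TRUE)
    }
  }
  ids <- c(reference_id, sprintf("homologue_%03d", seq_len(n - 1L) + 1L))
  strings <- stats::setNames(apply(mat, 1L, paste, collapse = ""), ids)
  new_ref_alignment(strings, reference_id)
}
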