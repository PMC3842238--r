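#' Read a multiple sequence alignment with a reference numbering
#'
#' Loads a FASTA or Clustal alignment and projects its columns onto the
#' residue numbering of one reference sequence (for thermopsin work, the
#' preprothermopsin precursor: signal peptide + propeptide + mature domain,
#' numbered from the initiator Met). Case is normalized to upper and
#' \code{'.'} gaps to \code{'-'}; ragged alignments are rejected naming the
#' offending sequence.
#'
#' @param path Alignment file.
#' @param reference_id Identifier of the reference sequence; must be present.
#' @param format \code{"fasta"} or \code{"clustal"}.
#' @return A \code{ref_alignment}: list with \code{ids}, character matrix
#'   \code{mat} (sequences x columns), \code{reference_id}, and
#'   \code{pos2col}, the strictly increasing map from 1-based reference
#'   positions to alignment columns.
#' @export
read_alignment <- function(path, reference_id,
                           format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    # readAAStringSet pads/errors oddly on ragged input, so check widths
    # ourselves from the raw records
    seqs <- Biostrings::readBStringSet(path, format = "fasta")
    ids <- sub("\\s.*$", "", names(seqs))
    widths <- Biostrings::width(seqs)
    if (length(unique(widths)) > 1L) {
      off <- ids[widths != widths[1L]][1L]
      stop("ragged alignment: sequence '", off,
           "' length differs from the first sequence")
    }
    strings <- as.character(seqs)
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    strings <- as.character(aln)
    ids <- names(strings)
  }
  new_ref_alignment(stats::setNames(strings, ids), reference_id)
}

#' Construct a reference-numbered alignment from aligned strings
#'
#' @param strings Named character vector of equal-length aligned sequences.
#' @param reference_id Name of the reference sequence.
#' @return A \code{ref_alignment} (see \code{\link{read_alignment}}).
#' @export
new_ref_alignment <- function(strings, reference_id) {
  if (length(strings) < 2L) stop("alignment needs at least 2 sequences")
  ids <- names(strings)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("all sequences must be named")
  if (anyDuplicated(ids)) stop("duplicated sequence ids in alignment")
  if (!reference_id %in% ids)
    stop("reference sequence '", reference_id, "' not found in alignment")
  strings <- toupper(strings)
  strings <- gsub(".", "-", strings, fixed = TRUE)
  lens <- nchar(strings)
  if (length(unique(lens)) > 1L) {
    stop("ragged alignment: sequence '", ids[lens != lens[1L]][1L],
         "' length differs from the first sequence")
  }
  mat <- do.call(rbind, strsplit(strings, ""))
  rownames(mat) <- ids
  ref <- mat[reference_id, ]
  pos2col <- which(ref != "-")
  structure(list(ids = ids, mat = mat, reference_id = reference_id,
                 pos2col = pos2col),
            class = "ref_alignment")
}

#' @export
print.ref_alignment <- function(x, ...) {
  cat("Reference-numbered alignment: ", length(x$ids), " sequences x ",
      ncol(x$mat), " columns; reference '", x$reference_id, "' (",
      length(x$pos2col), " residues)\n", sep = "")
  invisible(x)
}

#' Write a reference alignment to FASTA
#'
#' @param aln A \code{ref_alignment}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "ref_alignment"))
  strings <- apply(aln$mat, 1L, paste, collapse = "")
  out <- character(2L * length(strings))
  out[c(TRUE, FALSE)] <- paste0(">", aln$ids)
  out[c(FALSE, TRUE)] <- strings
  writeLines(out, path)
  invisible(path)
}

#' Count sequences carrying given residues at a reference position
#'
#' The number of aligned sequences whose character in the column mapped to
#' \code{ref_pos} belongs to \code{residues}. Gaps and ambiguity codes never
#' match: conservation counts are of explicit residues only.
#'
#' @param aln A \code{ref_alignment}.
#' @param ref_pos 1-based position on the reference sequence.
#' @param residues Residue set, e.g. \code{"D"}, \code{c("D", "N")} or
#'   \code{"DN"}.
#' @return Integer count.
#' @export
#' @examples
#' aln <- simulate_alignment(10, 20,
#'   data.frame(position = 5, residue = "D", fraction = 0.8), seed = 1)
#' count_residue_at(aln, 5, "D")
count_residue_at <- function(aln, ref_pos, residues) {
  stopifnot(inherits(aln, "ref_alignment"))
  ref_pos <- as.integer(ref_pos)
  if (length(ref_pos) != 1L || is.na(ref_pos) || ref_pos < 1L ||
      ref_pos > length(aln$pos2col)) {
    stop("ref_pos must be in 1..", length(aln$pos2col),
         " (ungapped reference length)")
  }
  residues <- .residue_set(residues)
  sum(aln$mat[, aln$pos2col[ref_pos]] %in% residues)
}

.residue_set <- function(residues) {
  residues <- toupper(unlist(strsplit(residues, "")))
  intersect(residues, .AA20)
}

#' Per-position residue conservation profile
#'
#' Tallies every residue (and the gap) at every reference position. At each
#' position the residue counts plus the gap count sum to the number of
#' sequences.
#'
#' @param aln A \code{ref_alignment}.
#' @return Data.frame with columns \code{position}, \code{residue} (gap as
#'   \code{"-"}), \code{count}, \code{fraction}.
#' @export
conservation_profile <- function(aln) {
  stopifnot(inherits(aln, "ref_alignment"))
  n <- length(aln$ids)
  out <- lapply(seq_along(aln$pos2col), function(p) {
    tab <- table(aln$mat[, aln$pos2col[p]])
    data.frame(position = p, residue = names(tab),
               count = as.integer(tab),
               fraction = as.integer(tab) / n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Scan for candidate conserved (possibly catalytic) positions
#'
#' Reports every reference position where the combined count of some residue
#' class reaches \code{min_fraction} of the sequences. The default classes
#' encode the chemically conservative interchanges used when nominating
#' catalytic residues of an aspartic peptidase: Asp alone, Asp/Asn
#' (deamidation can interconvert them), Glu, Glu/Gln, and Ser/Thr
#' (interchangeable nucleophiles).
#'
#' @param aln A \code{ref_alignment}.
#' @param residue_classes Named list of residue sets; names label the report.
#' @param min_fraction Reporting threshold in (0, 1].
#' @return Data.frame sorted by position: \code{position}, \code{class},
#'   \code{residues}, \code{count}, \code{fraction}.
#' @export
scan_candidate_sites <- function(aln,
                                 residue_classes = list(
                                   D = "D", DN = c("D", "N"), E = "E",
                                   EQ = c("E", "Q"), ST = c("S", "T")),
                                 min_fraction = 0.6) {
  stopifnot(inherits(aln, "ref_alignment"))
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must be in (0, 1]")
  if (is.null(names(residue_classes)))
    names(residue_classes) <- vapply(residue_classes, paste, character(1),
                                     collapse = "")
  n <- length(aln$ids)
  rows <- list()
  for (cl in names(residue_classes)) {
    set <- .residue_set(residue_classes[[cl]])
    counts <- vapply(seq_along(aln$pos2col), function(p) {
      sum(aln$mat[, aln$pos2col[p]] %in% set)
    }, integer(1))
    hit <- which(counts / n >= min_fraction)
    if (length(hit)) {
      rows[[cl]] <- data.frame(
        position = hit, class = cl,
        residues = paste(set, collapse = ""),
        count = counts[hit], fraction = counts[hit] / n,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(position = integer(0), class = character(0),
                      residues = character(0), count = integer(0),
                      fraction = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$position, out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract a sequence motif over a reference window
#'
#' Returns the characters of one aligned sequence at the columns mapped to
#' reference positions \code{ref_start..ref_end}; positions where the
#' sequence is gapped appear as \code{'-'}.
#'
#' @param aln A \code{ref_alignment}.
#' @param seq_id Sequence identifier.
#' @param ref_start,ref_end 1-based reference window (inclusive).
#' @return A character string of length \code{ref_end - ref_start + 1}.
#' @export
extract_motif <- function(aln, seq_id, ref_start, ref_end) {
  stopifnot(inherits(aln, "ref_alignment"))
  if (!seq_id %in% aln$ids) stop("unknown sequence id '", seq_id, "'")
  ref_start <- as.integer(ref_start); ref_end <- as.integer(ref_end)
  n_ref <- length(aln$pos2col)
  if (ref_start > ref_end || ref_start < 1L || ref_end > n_ref)
    stop("window must satisfy 1 <= ref_start <= ref_end <= ", n_ref)
  paste(aln$mat[seq_id, aln$pos2col[ref_start:ref_end]], collapse = "")
}
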