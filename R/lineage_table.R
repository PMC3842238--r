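#' Read a species lineage table
#'
#' Reads a tab-separated table with one row per species (or strain) carrying
#' its ranked lineage, survey and phenotype flags, and the observed homologue
#' count. Blank phenotype cells mean "unknown" (\code{NA}), not \code{FALSE};
#' a blank \code{genome_sequenced} cell means the genome is not completely
#' sequenced; a blank \code{classified} cell defaults to \code{TRUE}.
#'
#' @param path Path to a UTF-8 TSV file with one header row. Mandatory
#'   columns: \code{species}, \code{genus}, \code{family}, \code{order},
#'   \code{class}, \code{phylum}, \code{genome_sequenced},
#'   \code{hyperthermophile}, \code{acidophile}, \code{classified},
#'   \code{homologue_count}. Extra columns are kept as-is.
#' @return A \code{data.frame} of species records (class
#'   \code{"species_records"}): lineage columns as character (\code{NA} for
#'   blank cells), flags as logical, \code{homologue_count} as integer.
#' @export
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   paste("species", "genus", "family", "order", "class", "phylum",
#'         "genome_sequenced", "hyperthermophile", "acidophile",
#'         "classified", "homologue_count", sep = "\t"),
#'   paste("Sulfolobus acidocaldarius", "Sulfolobus", "Sulfolobaceae",
#'         "Sulfolobales", "Thermoprotei", "Crenarchaeota",
#'         "TRUE", "TRUE", "TRUE", "TRUE", "6", sep = "\t")), tsv)
#' read_lineage_table(tsv)
read_lineage_table <- function(path) {
  if (!file.exists(path)) stop("lineage table not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = NULL,
                           check.names = FALSE, quote = "",
                           fileEncoding = "UTF-8")
  mandatory <- c("species", "genus", "family", "order", "class", "phylum",
                 "genome_sequenced", "hyperthermophile", "acidophile",
                 "classified", "homologue_count")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop("lineage table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  as_species_records(raw)
}

#' Validate and normalize species records
#'
#' Coerces a raw data.frame into typed species records, enforcing the record
#' invariants: every row names a species; homologue counts are non-negative
#' integers. Non-integer counts are rejected with the offending row number.
#'
#' @param x A data.frame with the columns listed in
#'   \code{\link{read_lineage_table}}.
#' @return The normalized \code{data.frame}, class \code{"species_records"}.
#' @export
as_species_records <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in c("species", "genus", "family", "order", "class", "phylum")) {
    v <- trimws(as.character(x[[col]]))
    v[v == "" | toupper(v) == "NA"] <- NA_character_
    x[[col]] <- v
  }
  if (anyNA(x$species)) {
    stop("row(s) ", paste(which(is.na(x$species)), collapse = ", "),
         ": species name is mandatory")
  }
  x$genome_sequenced <- .parse_flag(x$genome_sequenced, blank = FALSE)
  x$hyperthermophile <- .parse_flag(x$hyperthermophile, blank = NA)
  x$acidophile <- .parse_flag(x$acidophile, blank = NA)
  x$classified <- .parse_flag(x$classified, blank = TRUE)
  cnt <- trimws(as.character(x$homologue_count))
  bad <- !grepl("^[0-9]+$", cnt)
  if (any(bad)) {
    stop("row(s) ", paste(which(bad), collapse = ", "),
         ": homologue_count must be a non-negative integer (got ",
         paste(unique(cnt[bad]), collapse = ", "), ")")
  }
  x$homologue_count <- as.integer(cnt)
  rownames(x) <- NULL
  class(x) <- c("species_records", "data.frame")
  x
}

# blank: value for empty/NA cells. Accepts TRUE/FALSE/T/F/1/0/yes/no.
.parse_flag <- function(v, blank) {
  if (is.logical(v)) return(v)
  v <- trimws(tolower(as.character(v)))
  out <- rep(blank, length(v))
  out[v %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[v %in% c("false", "f", "0", "no", "n")] <- FALSE
  unknown <- !(v %in% c("true", "t", "1", "yes", "y",
                        "false", "f", "0", "no", "n", "", "na"))
  if (any(unknown))
    stop("unrecognized flag value(s): ", paste(unique(v[unknown]), collapse = ", "))
  as.logical(out)
}
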