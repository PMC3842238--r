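#' Render the species presence/phenotype matrix
#'
#' One row per species tip in taxonomy (depth-first) order with the four
#' annotations of the classic presence figure: completely sequenced genome,
#' hyperthermophily, acidophily, and homologue count.
#'
#' @param history A \code{family_history} from
#'   \code{\link{infer_family_history}}.
#' @return Data.frame with columns \code{species}, \code{genome_sequenced},
#'   \code{hyperthermophile}, \code{acidophile}, \code{homologue_count}.
#' @export
render_presence_matrix <- function(history) {
  stopifnot(inherits(history, "family_history"))
  tips <- species_tips(history$tree)
  out <- data.frame(species = tips$name,
                    genome_sequenced = tips$surveyed,
                    hyperthermophile = tips$hyperthermophile,
                    acidophile = tips$acidophile,
                    homologue_count = tips$observed,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a family history report as JSON
#'
#' Machine-readable report with a provenance block (package version,
#' timestamp, configuration echo, and md5 checksums of any input files).
#' Apart from the timestamp, rerunning with identical inputs yields
#' identical output.
#'
#' @param history A \code{family_history}.
#' @param path Output file.
#' @param config Optional named list echoed into the provenance block.
#' @param input_paths Optional character vector of input files to checksum.
#' @return \code{path}, invisibly.
#' @export
write_history_json <- function(history, path, config = list(),
                               input_paths = character(0)) {
  stopifnot(inherits(history, "family_history"))
  payload <- list(
    provenance = list(
      package = "paleofam",
      version = as.character(utils::packageVersion("paleofam")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = config,
      input_checksums = as.list(tools::md5sum(input_paths))),
    origin = history$origin,
    origin_rank = history$origin_rank,
    family_absent = history$absent,
    hgt_candidates = history$hgt_candidates,
    gains = history$gains,
    losses = history$losses,
    complete_losses = history$complete_losses)
  jsonlite::write_json(payload, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a family history report as TSV
#'
#' Human-readable event table: one row per reported item (origin, each
#' transfer candidate, each gain/loss).
#'
#' @param history A \code{family_history}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_history_tsv <- function(history, path) {
  stopifnot(inherits(history, "family_history"))
  row <- function(type, taxon, rank, detail) {
    data.frame(type = type, taxon = taxon, rank = rank, detail = detail,
               stringsAsFactors = FALSE)
  }
  out <- row("origin", history$origin, history$origin_rank,
             if (history$absent) "family absent" else "inferred origin")
  if (nrow(history$hgt_candidates)) {
    out <- rbind(out, row("hgt_candidate", history$hgt_candidates$taxon,
                          history$hgt_candidates$rank,
                          history$hgt_candidates$kind))
  }
  for (ev in list(c("gain", "gains"), c("loss", "losses"))) {
    df <- history[[ev[2L]]]
    if (nrow(df)) {
      out <- rbind(out, row(ev[1L], df$taxon, df$rank,
                            paste0(df$child_count, " vs parent ",
                                   df$parent_count)))
    }
  }
  if (nrow(history$complete_losses)) {
    out <- rbind(out, row("complete_loss", history$complete_losses$taxon,
                          "species",
                          paste0("0 vs parent ",
                                 history$complete_losses$parent_count)))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check a history JSON report against the shipped schema
#'
#' Light structural validation (required fields, types) against the JSON
#' schema shipped in \code{inst/schema/family_history.json}.
#'
#' @param path Path to a JSON report written by
#'   \code{\link{write_history_json}}.
#' @return \code{TRUE} invisibly, or an error describing the first
#'   violation.
#' @export
validate_history_json <- function(path) {
  x <- jsonlite::read_json(path)
  schema <- jsonlite::read_json(system.file("schema", "family_history.json",
                                            package = "paleofam",
                                            mustWork = TRUE))
  required <- names(schema$properties)
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("report is missing required field(s): ",
         paste(missing, collapse = ", "))
  prov_required <- names(schema$properties$provenance$properties)
  miss_prov <- setdiff(prov_required, names(x$provenance))
  if (length(miss_prov))
    stop("provenance block is missing field(s): ",
         paste(miss_prov, collapse = ", "))
  for (fld in c("hgt_candidates", "gains", "losses", "complete_losses")) {
    if (!is.list(x[[fld]])) stop("field '", fld, "' must be an array")
  }
  invisible(TRUE)
}
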