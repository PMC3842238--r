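#' Write a taxonomy tree as annotated Newick
#'
#' Serializes a \code{taxon_tree} to Newick text in which every label carries
#' a square-bracket comment of \code{key=value} annotations (rank, surveyed
#' flag, observed and inferred counts, phenotype flags, majority-rule
#' bookkeeping). Labels containing characters outside
#' \code{[A-Za-z0-9_.-]} are single-quoted, so species names with spaces
#' survive a round trip through \code{\link{read_annotated_newick}}
#' unchanged. Stripping the \code{[...]} comments yields plain Newick
#' readable by standard parsers.
#'
#' @param tree A \code{taxon_tree}.
#' @param path Optional file path; when \code{NULL} the Newick string is
#'   returned invisibly only.
#' @return The Newick string, invisibly.
#' @export
write_annotated_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "taxon_tree"))
  df <- tree$nodes
  lab <- function(i) {
    ann <- paste0(
      "&rank=", df$rank[i],
      ",surveyed=", .ann_val(df$surveyed[i]),
      ",observed=", .ann_val(df$observed[i]),
      ",inferred=", .ann_val(df$inferred[i]),
      ",majority=", .ann_val(df$majority_passed[i]),
      ",support=", .ann_val(df$supporting_children[i]),
      ",surveyed_children=", .ann_val(df$surveyed_children[i]),
      ",hyperthermophile=", .ann_val(df$hyperthermophile[i]),
      ",acidophile=", .ann_val(df$acidophile[i]))
    paste0(.quote_label(df$name[i]), "[", ann, "]")
  }
  emit <- function(id) {
    i <- match(id, df$id)
    kids <- df$id[!is.na(df$parent) & df$parent == id]
    if (length(kids)) {
      paste0("(", paste(vapply(kids, emit, character(1)), collapse = ","),
             ")", lab(i))
    } else {
      lab(i)
    }
  }
  txt <- paste0(emit(df$id[1L]), ";")
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

.ann_val <- function(v) if (is.na(v)) "NA" else as.character(v)

.quote_label <- function(x) {
  if (grepl("^[A-Za-z0-9_.-]+$", x)) x
  else paste0("'", gsub("'", "''", x), "'")
}

#' Read an annotated Newick tree
#'
#' Parses Newick text written by \code{\link{write_annotated_newick}} back
#' into a \code{taxon_tree}; write-read-write is idempotent.
#'
#' @param x A file path, or a character string starting with \code{"("}.
#' @return A \code{taxon_tree}.
#' @export
read_annotated_newick <- function(x) {
  txt <- if (length(x) == 1L && !grepl("^\\s*\\(", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    paste(x, collapse = "")
  }
  txt <- trimws(txt)
  if (!nzchar(txt) || substr(txt, nchar(txt), nchar(txt)) != ";")
    stop("not a Newick string (missing terminal ';')")
  chars <- strsplit(substr(txt, 1L, nchar(txt) - 1L), "")[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(chars)) chars[pos] else ""
  advance <- function() { ch <- chars[pos]; pos <<- pos + 1L; ch }

  rows <- list()
  n_nodes <- 0L

  read_label <- function() {
    name <- ""
    if (peek() == "'") {
      advance()
      repeat {
        ch <- advance()
        if (ch == "'") {
          if (peek() == "'") { name <- paste0(name, "'"); advance() }
          else break
        } else name <- paste0(name, ch)
      }
    } else {
      while (peek() != "" && !peek() %in% c("(", ")", ",", "[", ";")) {
        name <- paste0(name, advance())
      }
    }
    ann <- character(0)
    if (peek() == "[") {
      advance()
      buf <- ""
      while (peek() != "]") buf <- paste0(buf, advance())
      advance()
      buf <- sub("^&", "", buf)
      ann <- strsplit(buf, ",", fixed = TRUE)[[1]]
    }
    list(name = name, ann = ann)
  }

  parse_node <- function(parent_id) {
    kids_first <- list()
    if (peek() == "(") {
      advance()
      repeat {
        kids_first[[length(kids_first) + 1L]] <- parse_node(NA)
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        stop("malformed Newick near position ", pos)
      }
    }
    lab <- read_label()
    n_nodes <<- n_nodes + 1L
    id <- n_nodes
    kv <- list()
    for (piece in lab$ann) {
      eq <- regexpr("=", piece, fixed = TRUE)
      kv[[substr(piece, 1L, eq - 1L)]] <- substr(piece, eq + 1L, nchar(piece))
    }
    num <- function(k) {
      v <- kv[[k]]
      if (is.null(v) || v == "NA") NA_integer_ else as.integer(v)
    }
    flag <- function(k) {
      v <- kv[[k]]
      if (is.null(v) || v == "NA") NA else as.logical(v)
    }
    rows[[id]] <<- data.frame(
      id = id, name = lab$name,
      rank = if (is.null(kv$rank)) NA_character_ else kv$rank,
      parent = NA_integer_, surveyed = flag("surveyed"),
      observed = num("observed"),
      hyperthermophile = flag("hyperthermophile"),
      acidophile = flag("acidophile"), inferred = num("inferred"),
      majority_passed = flag("majority"),
      supporting_children = num("support"),
      surveyed_children = num("surveyed_children"),
      stringsAsFactors = FALSE)
    for (k in kids_first) rows[[k]]$parent <<- id
    id
  }

  parse_node(NA)
  df <- do.call(rbind, rows)
  # renumber so the root is node 1 and ids follow the writer's depth-first
  # order (children keep file order, which is the canonical order)
  ord <- integer(0)
  walk <- function(id) {
    ord <<- c(ord, id)
    for (k in df$id[!is.na(df$parent) & df$parent == id]) walk(k)
  }
  walk(df$id[is.na(df$parent)])
  df <- df[match(ord, df$id), , drop = FALSE]
  remap <- stats::setNames(seq_along(ord), ord)
  df$id <- as.integer(remap[as.character(df$id)])
  df$parent <- ifelse(is.na(df$parent), NA_integer_,
                      as.integer(remap[as.character(df$parent)]))
  rownames(df) <- NULL
  structure(list(nodes = df), class = "taxon_tree")
}

#' Dump a taxonomy tree to JSON
#'
#' Writes the node table (one object per taxon, with parent links by id) for
#' consumption outside R.
#'
#' @param tree A \code{taxon_tree}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "taxon_tree"))
  jsonlite::write_json(tree$nodes, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
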