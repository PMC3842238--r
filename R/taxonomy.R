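#' Build a ranked taxonomy tree from species records
#'
#' Assembles the six-rank (phylum..species) tree that the parsimony walk
#' traverses. Records flagged \code{classified = FALSE} are dropped first.
#' Multiple strains of one species are collapsed to a single tip (see
#' \code{aggregate}). Missing intermediate ranks are bridged with placeholder
#' nodes named \code{"<child>_incertae_<rank>"} so that every root-to-tip path
#' carries exactly one node per rank. Children are ordered lexicographically,
#' making the build deterministic and input-order independent.
#'
#' @param records Species records (see \code{\link{read_lineage_table}}).
#' @param aggregate How to combine homologue counts across strains of one
#'   species: \code{"max"} (default; databases list strains but the analysis
#'   counts per species) or \code{"sum"}.
#' @param root_name Name of the synthetic super-root joining the phyla.
#' @return A \code{taxon_tree}: a list with element \code{nodes}, a
#'   data.frame with one row per taxon (\code{id}, \code{name}, \code{rank},
#'   \code{parent} id, \code{surveyed}, species-only \code{observed} count,
#'   phenotype flags, and \code{inferred}/majority columns filled by
#'   \code{\link{assign_ancestral_counts}}).
#' @export
build_taxonomy <- function(records, aggregate = c("max", "sum"),
                           root_name = "Archaea") {
  aggregate <- match.arg(aggregate)
  records <- as_species_records(records)
  records <- records[is.na(records$classified) | records$classified, ,
                     drop = FALSE]
  if (nrow(records) == 0L)
    stop("no classified species records to build a tree from")

  # collapse strains (identical species name) into one tip
  agg_fun <- if (aggregate == "max") max else sum
  split_rec <- split(records, records$species)
  tips <- lapply(split_rec, function(rs) {
    lin <- unique(rs[, c("phylum", "class", "order", "family", "genus")])
    if (nrow(lin) > 1L)
      stop("conflicting lineages for species '", rs$species[1L], "'")
    data.frame(
      species = rs$species[1L],
      phylum = lin$phylum, class = lin$class, order = lin$order,
      family = lin$family, genus = lin$genus,
      genome_sequenced = any(rs$genome_sequenced, na.rm = TRUE),
      hyperthermophile = .combine_flag(rs$hyperthermophile),
      acidophile = .combine_flag(rs$acidophile),
      homologue_count = agg_fun(rs$homologue_count),
      stringsAsFactors = FALSE)
  })
  tips <- do.call(rbind, tips)
  rownames(tips) <- NULL

  # bridge missing ranks with placeholders named after the nearest child
  lin_mat <- t(vapply(seq_len(nrow(tips)), function(i) {
    l <- c(tips$phylum[i], tips$class[i], tips$order[i], tips$family[i],
           tips$genus[i], tips$species[i])
    carry <- l[6L] # nearest named taxon below the gap
    for (j in rev(seq_len(5L))) {
      if (is.na(l[j])) l[j] <- paste0(carry, "_incertae_", .RANKS[j])
      else carry <- l[j]
    }
    l
  }, character(6L)))
  colnames(lin_mat) <- .RANKS

  # conflict check: a taxon name at one rank must have a single parent
  for (j in 2L:6L) {
    pairs <- unique(data.frame(taxon = lin_mat[, j], parent = lin_mat[, j - 1L],
                               stringsAsFactors = FALSE))
    dup <- pairs$taxon[duplicated(pairs$taxon)]
    if (length(dup))
      stop("conflicting lineages: ", .RANKS[j], " '", dup[1L],
           "' appears under more than one ", .RANKS[j - 1L])
  }

  # canonical depth-first build, children sorted by name
  acc <- new.env(parent = emptyenv())
  acc$name <- root_name; acc$rank <- "root"; acc$parent <- NA_integer_
  acc$tip <- NA_integer_; acc$n <- 1L
  tip_row <- match(lin_mat[, "species"], tips$species)

  add_children <- function(parent_id, rank_j, sel) {
    kids <- sort(unique(lin_mat[sel, rank_j]))
    for (kid in kids) {
      ksel <- sel & lin_mat[, rank_j] == kid
      id <- acc$n + 1L
      acc$n <- id
      acc$name[id] <- kid
      acc$rank[id] <- .RANKS[rank_j]
      acc$parent[id] <- parent_id
      acc$tip[id] <- if (rank_j == 6L) tip_row[which(ksel)[1L]] else
        NA_integer_
      if (rank_j < 6L) add_children(id, rank_j + 1L, ksel)
    }
  }
  add_children(1L, 1L, rep(TRUE, nrow(lin_mat)))

  df <- data.frame(
    id = seq_len(acc$n), name = acc$name, rank = acc$rank,
    parent = acc$parent,
    surveyed = ifelse(is.na(acc$tip), NA, tips$genome_sequenced[acc$tip]),
    observed = ifelse(is.na(acc$tip), NA_integer_,
                      tips$homologue_count[acc$tip]),
    hyperthermophile = ifelse(is.na(acc$tip), NA,
                              tips$hyperthermophile[acc$tip]),
    acidophile = ifelse(is.na(acc$tip), NA, tips$acidophile[acc$tip]),
    stringsAsFactors = FALSE)
  # surveyed = subtree contains >=1 genome-sequenced species (propagate up)
  for (i in rev(seq_len(nrow(df)))) {
    if (df$rank[i] != "species") {
      kid_ids <- df$id[!is.na(df$parent) & df$parent == df$id[i]]
      df$surveyed[i] <- any(df$surveyed[match(kid_ids, df$id)])
    }
  }
  df$inferred <- NA_integer_
  df$majority_passed <- NA
  df$supporting_children <- NA_integer_
  df$surveyed_children <- NA_integer_
  structure(list(nodes = df), class = "taxon_tree")
}

.combine_flag <- function(v) {
  if (any(v %in% TRUE)) TRUE else if (any(v %in% FALSE)) FALSE else NA
}

#' @export
print.taxon_tree <- function(x, ...) {
  df <- x$nodes
  n_sp <- sum(df$rank == "species")
  n_bear <- sum(df$rank == "species" & df$observed > 0L, na.rm = TRUE)
  cat("Ranked taxonomy tree: ", nrow(df), " taxa, ", n_sp, " species tips (",
      n_bear, " homologue-bearing), root '", df$name[1L], "'\n", sep = "")
  if (any(!is.na(df$inferred)))
    cat("Ancestral counts assigned at ",
        sum(!is.na(df$inferred) & df$rank != "species"),
        " internal taxa\n", sep = "")
  invisible(x)
}

# ---- internal tree helpers ------------------------------------------------

.children_of <- function(df, id) df[!is.na(df$parent) & df$parent == id, ,
                                    drop = FALSE]

# ids of the subtree rooted at id (including id), by repeated frontier growth
.subtree_ids <- function(df, id) {
  out <- id
  frontier <- id
  repeat {
    nxt <- df$id[!is.na(df$parent) & df$parent %in% frontier]
    if (!length(nxt)) break
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

# ids on the path from id up to the root (excluding id)
.ancestor_ids <- function(df, id) {
  out <- integer(0)
  p <- df$parent[match(id, df$id)]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- df$parent[match(p, df$id)]
  }
  out
}

#' Extract the species tips of a taxonomy tree
#'
#' @param tree A \code{taxon_tree}.
#' @return Data.frame of species-rank rows in canonical (depth-first) order.
#' @export
species_tips <- function(tree) {
  stopifnot(inherits(tree, "taxon_tree"))
  tree$nodes[tree$nodes$rank == "species", , drop = FALSE]
}
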