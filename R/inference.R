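#' Assign ancestral homologue counts by strict-majority parsimony
#'
#' Walks the tree bottom-up, rank by rank (species, genus, ..., phylum, then
#' the super-root), assigning each parent taxon a homologue count only if
#' strictly more than half of its surveyed children carry a (nonzero) count.
#' Children whose subtree contains no genome-sequenced species are ignored
#' entirely — absence of evidence in an unsurveyed clade is not evidence of
#' absence. The assigned value is the integer minimizing the total absolute
#' difference to the nonzero child counts (the L1 median), with ties broken
#' toward the smaller integer, so that the implied total gain-plus-loss
#' magnitude is minimal. Species tips take their observed count.
#'
#' @param tree A \code{taxon_tree} from \code{\link{build_taxonomy}} whose
#'   species tips carry observed counts.
#' @return The tree with columns \code{inferred}, \code{majority_passed},
#'   \code{supporting_children} and \code{surveyed_children} filled in.
#'   Unassigned taxa keep \code{inferred = NA}.
#' @export
assign_ancestral_counts <- function(tree) {
  stopifnot(inherits(tree, "taxon_tree"))
  df <- tree$nodes
  sp <- df$rank == "species"
  if (!any(sp) || all(is.na(df$observed[sp])))
    stop("tree has no species observed counts attached")

  df$inferred[sp] <- df$observed[sp]
  df$majority_passed[sp] <- TRUE
  df$supporting_children[sp] <- 0L
  df$surveyed_children[sp] <- 0L

  for (rank in c("genus", "family", "order", "class", "phylum", "root")) {
    for (i in which(df$rank == rank)) {
      kids <- .children_of(df, df$id[i])
      kids <- kids[kids$surveyed %in% TRUE, , drop = FALSE]
      support <- !is.na(kids$inferred) & kids$inferred > 0L
      df$surveyed_children[i] <- nrow(kids)
      df$supporting_children[i] <- sum(support)
      # strict majority, exact in integers: 2 * support > surveyed
      passed <- 2L * sum(support) > nrow(kids)
      df$majority_passed[i] <- passed
      df$inferred[i] <- if (passed) {
        l1_median_count(kids$inferred[support])
      } else NA_integer_
    }
  }
  tree$nodes <- df
  tree
}

#' Integer L1 median of a set of counts
#'
#' The smallest integer minimizing the sum of absolute differences to
#' \code{x} — the lower median. Realizes "maximally parsimonious" for
#' ancestral copy numbers: any other integer implies a larger total of gains
#' plus losses along the child branches.
#'
#' @param x Positive integer counts (nonzero child counts).
#' @return A single integer.
#' @export
#' @examples
#' l1_median_count(c(2, 5, 6)) # 5
#' l1_median_count(c(1, 3))    # 1, 2 and 3 tie; the smallest wins
l1_median_count <- function(x) {
  x <- as.integer(x)
  stopifnot(length(x) > 0L, all(x > 0L))
  sort(x)[ceiling(length(x) / 2)]
}

# assigned-and-bearing nodes: the family is credited to the taxon
.assigned_ids <- function(df) df$id[!is.na(df$inferred) & df$inferred > 0L]

# maximal assigned taxa: assigned nodes none of whose ancestors is assigned
.maximal_assigned <- function(df) {
  assigned <- .assigned_ids(df)
  keep <- vapply(assigned, function(id) {
    !any(.ancestor_ids(df, id) %in% assigned)
  }, logical(1))
  assigned[keep]
}

#' Locate the origin of the gene family
#'
#' The highest taxon credited with the family under the majority rule — the
#' family's inferred birthplace. Among maximal assigned taxa (credited taxa
#' with no credited ancestor) the one of highest rank wins; ties are broken
#' by the larger number of homologue-bearing surveyed species in the clade,
#' then alphabetically.
#'
#' @param tree A tree processed by \code{\link{assign_ancestral_counts}}.
#' @return A list with \code{taxon}, \code{rank}, \code{node_id},
#'   \code{absent} (\code{TRUE} when no taxon carries the family — returned,
#'   not thrown).
#' @export
find_origin <- function(tree) {
  stopifnot(inherits(tree, "taxon_tree"))
  df <- tree$nodes
  if (all(is.na(df$inferred)))
    stop("ancestral counts not assigned; run assign_ancestral_counts() first")
  maximal <- .maximal_assigned(df)
  if (!length(maximal)) {
    return(list(taxon = NA_character_, rank = NA_character_,
                node_id = NA_integer_, absent = TRUE))
  }
  cand <- df[match(maximal, df$id), , drop = FALSE]
  cand$rank_level <- match(cand$rank, .ALL_RANKS)
  cand$bearers <- vapply(cand$id, function(id) {
    sub <- df[match(.subtree_ids(df, id), df$id), , drop = FALSE]
    sum(sub$rank == "species" & sub$surveyed %in% TRUE &
          sub$observed > 0L, na.rm = TRUE)
  }, integer(1))
  cand <- cand[order(cand$rank_level, -cand$bearers, cand$name), ,
               drop = FALSE]
  list(taxon = cand$name[1L], rank = cand$rank[1L], node_id = cand$id[1L],
       absent = FALSE)
}

#' Detect unexpected presences (horizontal gene transfer candidates)
#'
#' Every maximal credited taxon other than the origin, plus every
#' homologue-bearing species lying outside all credited clades, is an
#' unexpected presence: under a single-origin reading of the taxonomy these
#' are best explained by horizontal gene transfer. Each entry names the
#' deepest taxon covering the presence.
#'
#' @param tree A tree processed by \code{\link{assign_ancestral_counts}}.
#' @param origin Result of \code{\link{find_origin}} on the same tree.
#' @return Data.frame with columns \code{taxon}, \code{rank}, \code{kind}
#'   (\code{"clade"} for a credited clade, \code{"species"} for a stray
#'   bearer). Empty when presence is confined to the origin clade.
#' @export
detect_hgt <- function(tree, origin) {
  stopifnot(inherits(tree, "taxon_tree"))
  df <- tree$nodes
  maximal <- .maximal_assigned(df)
  if (origin$absent || !length(maximal)) {
    return(data.frame(taxon = character(0), rank = character(0),
                      kind = character(0), stringsAsFactors = FALSE))
  }
  # a stray bearer species outside every credited clade is itself a maximal
  # credited taxon (species tips always carry their observed count), so the
  # maximal set covers clades and lone species alike
  clade_ids <- setdiff(maximal, origin$node_id)
  ranks <- df$rank[match(clade_ids, df$id)]
  out <- data.frame(taxon = df$name[match(clade_ids, df$id)],
                    rank = ranks,
                    kind = ifelse(ranks == "species", "species", "clade"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Detect gene gains and losses between credited taxa
#'
#' Compares each credited taxon (and every species tip) against its credited
#' parent: a larger count is a gain, a smaller-but-nonzero count a loss
#' (paralogue reduction), and a species count of zero under a credited parent
#' a complete loss, reported separately.
#'
#' @param tree A tree processed by \code{\link{assign_ancestral_counts}}.
#' @return A list with data.frames \code{gains} and \code{losses} (columns
#'   \code{taxon}, \code{rank}, \code{child_count}, \code{parent_count},
#'   \code{delta}) and \code{complete_losses} (\code{taxon},
#'   \code{parent_count}).
#' @export
detect_gains_losses <- function(tree) {
  stopifnot(inherits(tree, "taxon_tree"))
  df <- tree$nodes
  assigned <- .assigned_ids(df)
  ev <- function() data.frame(taxon = character(0), rank = character(0),
                              child_count = integer(0),
                              parent_count = integer(0), delta = integer(0),
                              stringsAsFactors = FALSE)
  gains <- ev(); losses <- ev()
  complete <- data.frame(taxon = character(0), parent_count = integer(0),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    p <- df$parent[i]
    if (is.na(p) || !(p %in% assigned)) next
    child <- df$inferred[i]
    if (is.na(child)) next # unassigned internal node: no count to compare
    parent <- df$inferred[match(p, df$id)]
    row <- data.frame(taxon = df$name[i], rank = df$rank[i],
                      child_count = child, parent_count = parent,
                      delta = child - parent, stringsAsFactors = FALSE)
    if (child > parent) {
      gains <- rbind(gains, row)
    } else if (child == 0L) {
      complete <- rbind(complete,
                        data.frame(taxon = df$name[i], parent_count = parent,
                                   stringsAsFactors = FALSE))
    } else if (child < parent) {
      losses <- rbind(losses, row)
    }
  }
  rownames(gains) <- rownames(losses) <- rownames(complete) <- NULL
  list(gains = gains, losses = losses, complete_losses = complete)
}

#' Infer the full evolutionary history of a gene family
#'
#' One-call wrapper: builds the taxonomy from species records, assigns
#' ancestral counts under the strict-majority parsimony rule, and reports the
#' family origin, horizontal-transfer candidates, gains and losses.
#'
#' @inheritParams build_taxonomy
#' @return A \code{family_history} list: \code{origin}, \code{origin_rank},
#'   \code{absent}, \code{hgt_candidates} (data.frame),
#'   \code{gains}/\code{losses}/\code{complete_losses}, and the annotated
#'   \code{tree}.
#' @export
infer_family_history <- function(records, aggregate = c("max", "sum"),
                                 root_name = "Archaea") {
  tree <- build_taxonomy(records, aggregate = aggregate,
                         root_name = root_name)
  tree <- assign_ancestral_counts(tree)
  origin <- find_origin(tree)
  hgt <- detect_hgt(tree, origin)
  events <- detect_gains_losses(tree)
  structure(list(
    origin = origin$taxon, origin_rank = origin$rank,
    absent = origin$absent, hgt_candidates = hgt,
    gains = events$gains, losses = events$losses,
    complete_losses = events$complete_losses, tree = tree),
    class = "family_history")
}

#' @export
print.family_history <- function(x, ...) {
  if (x$absent) {
    cat("Family absent: no taxon carries a homologue\n")
    return(invisible(x))
  }
  cat("Inferred family origin: ", x$origin_rank, " ", x$origin, "\n", sep = "")
  cat("Horizontal transfer candidates (unexpected presences): ",
      if (nrow(x$hgt_candidates)) paste(x$hgt_candidates$taxon,
                                        collapse = ", ") else "none",
      "\n", sep = "")
  cat("Gene gains: ", nrow(x$gains), "; losses (paralogue reduction): ",
      nrow(x$losses), "; complete losses: ", nrow(x$complete_losses),
      "\n", sep = "")
  invisible(x)
}
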