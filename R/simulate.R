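#' Parameters for simulating gene-family evolution on a ranked taxonomy
#'
#' Defines the taxonomy shape and the per-rank-step event model: each gene
#' copy is independently lost with \code{p_loss} and duplicated with
#' \code{p_dup} on each parent-to-child rank step (a branching process, the
#' simplest model consistent with repeated rounds of gene duplication), and
#' with probability \code{p_hgt} per rank step one gene copy is transferred
#' into a uniformly chosen clade outside the currently bearing clades
#' (clade-to-clade transfer, mirroring an ancestral-lineage transfer rather
#' than a tip-to-tip one).
#'
#' @param n_phyla Number of phyla under the root.
#' @param branching Integer range \code{c(min, max)} of children per taxon at
#'   every rank below phylum.
#' @param p_dup,p_loss Per-gene, per-rank-step duplication / loss
#'   probabilities.
#' @param p_hgt Per-rank-step probability of one cross-clade transfer.
#' @param origin_rank Rank at which the family is born.
#' @param origin_rule \code{"uniform"} (a uniformly drawn taxon at
#'   \code{origin_rank}) or \code{"first"} (the canonically first one).
#' @param seed Integer seed; fixes the full output byte-for-byte.
#' @return A \code{simulation_params} list.
#' @export
simulation_params <- function(n_phyla = 3L, branching = c(2L, 3L),
                              p_dup = 0.2, p_loss = 0.05, p_hgt = 0.05,
                              origin_rank = "class",
                              origin_rule = c("uniform", "first"),
                              seed = 1L) {
  origin_rule <- match.arg(origin_rule)
  stopifnot(n_phyla >= 1L, length(branching) == 2L,
            branching[1L] >= 1L, branching[2L] >= branching[1L],
            origin_rank %in% .RANKS)
  for (p in c(p_dup, p_loss, p_hgt)) {
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("probabilities must lie in [0, 1]")
  }
  structure(list(n_phyla = as.integer(n_phyla),
                 branching = as.integer(branching),
                 p_dup = p_dup, p_loss = p_loss, p_hgt = p_hgt,
                 origin_rank = origin_rank, origin_rule = origin_rule,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Simulate a gene family evolving over a ranked taxonomy
#'
#' Draws a taxonomy, seeds one gene copy at the origin taxon, and walks down
#' rank by rank applying per-gene loss and duplication and per-step
#' horizontal transfer (see \code{\link{simulation_params}}). A single
#' seeded random stream drives, in order: tree shape, origin choice, then
#' events step by step in canonical taxon order, so identical parameters and
#' seed give byte-identical output.
#'
#' @param params A \code{\link{simulation_params}} object.
#' @return A list with \code{records} (a lineage table consumable by
#'   \code{\link{build_taxonomy}}; all species genome-sequenced and
#'   classified, phenotypes unknown) and \code{truth}, a
#'   \code{simulation_truth} list: \code{origin}, \code{origin_rank},
#'   ordered \code{events} data.frame (\code{event} in duplication / loss /
#'   transfer, \code{source}, \code{destination}, \code{rank_step}),
#'   \code{species_counts} named vector, and the node table \code{taxa}.
#' @export
simulate_family <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(params$seed)

  # -- draw the taxonomy, breadth-first so sibling counts are drawn in
  #    canonical order
  taxa <- data.frame(id = 1L, name = "root", rank = "root",
                     parent = NA_integer_, stringsAsFactors = FALSE)
  rank_letter <- c(phylum = "P", class = "C", order = "O", family = "F",
                   genus = "G", species = "S")
  for (d in seq_along(.RANKS)) {
    rank <- .RANKS[d]
    parents <- taxa[taxa$rank == (if (d == 1L) "root" else .RANKS[d - 1L]), ]
    for (i in seq_len(nrow(parents))) {
      k <- if (d == 1L) params$n_phyla else {
        params$branching[1L] +
          sample.int(params$branching[2L] - params$branching[1L] + 1L, 1L) - 1L
      }
      base <- if (d == 1L) "" else parents$name[i]
      kids <- data.frame(
        id = nrow(taxa) + seq_len(k),
        name = paste0(base, rank_letter[rank], seq_len(k)),
        rank = rank, parent = parents$id[i], stringsAsFactors = FALSE)
      taxa <- rbind(taxa, kids)
    }
  }

  # -- origin
  origin_pool <- taxa[taxa$rank == params$origin_rank, ]
  origin_i <- if (params$origin_rule == "uniform")
    sample.int(nrow(origin_pool), 1L) else 1L
  origin <- origin_pool$name[origin_i]

  counts <- stats::setNames(integer(nrow(taxa)), taxa$name)
  counts[origin] <- 1L
  events <- list()
  add_event <- function(event, source, destination, rank_step, n) {
    if (n > 0L) {
      events[[length(events) + 1L]] <<- data.frame(
        event = rep(event, n), source = rep(source, n),
        destination = rep(destination, n), rank_step = rep(rank_step, n),
        stringsAsFactors = FALSE)
    }
  }

  # -- walk down rank by rank from the origin rank
  origin_d <- match(params$origin_rank, .RANKS)
  for (d in origin_d:(length(.RANKS) - 1L)) {
    parent_rank <- .RANKS[d]; child_rank <- .RANKS[d + 1L]
    bearing <- taxa[taxa$rank == parent_rank & counts[taxa$name] > 0L, ]
    for (i in seq_len(nrow(bearing))) {
      k <- counts[bearing$name[i]]
      kids <- taxa[!is.na(taxa$parent) & taxa$parent == bearing$id[i], ]
      for (j in seq_len(nrow(kids))) {
        survivors <- stats::rbinom(1L, k, 1 - params$p_loss)
        dups <- stats::rbinom(1L, survivors, params$p_dup)
        counts[kids$name[j]] <- survivors + dups
        add_event("loss", bearing$name[i], kids$name[j], child_rank,
                  k - survivors)
        add_event("duplication", bearing$name[i], kids$name[j], child_rank,
                  dups)
      }
    }
    if (stats::runif(1L) < params$p_hgt) {
      at_rank <- taxa[taxa$rank == child_rank, ]
      parent_cnt <- counts[taxa$name[match(at_rank$parent, taxa$id)]]
      eligible <- at_rank$name[counts[at_rank$name] == 0L & parent_cnt == 0L]
      sources <- at_rank$name[counts[at_rank$name] > 0L]
      if (!length(eligible) || !length(sources)) {
        warning("transfer step at rank '", child_rank,
                "' skipped: no taxon outside the bearing clade")
      } else {
        dest <- eligible[sample.int(length(eligible), 1L)]
        src <- sources[sample.int(length(sources), 1L)]
        counts[dest] <- counts[dest] + 1L
        add_event("transfer", src, dest, child_rank, 1L)
      }
    }
  }

  events <- if (length(events)) do.call(rbind, events) else
    data.frame(event = character(0), source = character(0),
               destination = character(0), rank_step = character(0),
               stringsAsFactors = FALSE)
  rownames(events) <- NULL

  # -- emit the lineage table
  sp <- taxa[taxa$rank == "species", ]
  lineage_of <- function(id) {
    out <- character(6L); names(out) <- .RANKS
    i <- match(id, taxa$id)
    while (!is.na(taxa$parent[i])) {
      out[taxa$rank[i]] <- taxa$name[i]
      i <- match(taxa$parent[i], taxa$id)
    }
    out
  }
  lin <- t(vapply(sp$id, lineage_of, character(6L)))
  records <- data.frame(
    species = lin[, "species"], genus = lin[, "genus"],
    family = lin[, "family"], order = lin[, "order"],
    class = lin[, "class"], phylum = lin[, "phylum"],
    genome_sequenced = TRUE, hyperthermophile = NA, acidophile = NA,
    classified = TRUE, homologue_count = as.integer(counts[sp$name]),
    stringsAsFactors = FALSE)
  records <- as_species_records(records)

  truth <- structure(list(
    origin = origin, origin_rank = params$origin_rank, events = events,
    species_counts = counts[sp$name], taxa = taxa, params = params),
    class = "simulation_truth")
  list(records = records, truth = truth)
}

#' Replay a simulation event log from the origin
#'
#' Recomputes every species count by applying the logged loss, duplication
#' and transfer events rank step by rank step, starting from a single gene
#' copy at the origin taxon. By the simulator's contract the replayed counts
#' equal the recorded final counts exactly; this function is the independent
#' check of that invariant.
#'
#' @param truth A \code{simulation_truth} from \code{\link{simulate_family}}.
#' @return Named integer vector of species counts.
#' @export
replay_truth <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  taxa <- truth$taxa
  ev <- truth$events
  counts <- stats::setNames(integer(nrow(taxa)), taxa$name)
  counts[truth$origin] <- 1L
  origin_d <- match(truth$origin_rank, .RANKS)
  n_ev <- function(type, dest, rank) {
    sum(ev$event == type & ev$destination == dest & ev$rank_step == rank)
  }
  for (d in origin_d:(length(.RANKS) - 1L)) {
    child_rank <- .RANKS[d + 1L]
    kids <- taxa[taxa$rank == child_rank, ]
    parent_counts <- counts[taxa$name[match(kids$parent, taxa$id)]]
    for (j in seq_len(nrow(kids))) {
      if (parent_counts[j] > 0L) {
        counts[kids$name[j]] <- parent_counts[j] -
          n_ev("loss", kids$name[j], child_rank) +
          n_ev("duplication", kids$name[j], child_rank)
      }
    }
    transfers <- ev[ev$event == "transfer" & ev$rank_step == child_rank, ]
    for (dest in transfers$destination) counts[dest] <- counts[dest] + 1L
  }
  counts[taxa$name[taxa$rank == "species"]]
}

#' Score an inferred history against simulation ground truth
#'
#' Compares an inferred \code{family_history} with the event log that
#' generated the data. A reported transfer candidate is a true positive if
#' it names a logged transfer's destination clade or a descendant of it.
#' Gain and loss recovery is scored as an F1 over the sets of taxa where
#' events were inferred versus logged.
#'
#' @param truth A \code{simulation_truth}.
#' @param history A \code{family_history} inferred from the matching
#'   \code{records}.
#' @param records The simulated lineage table both were computed from.
#' @return A list: \code{origin_correct}, \code{hgt_sensitivity} (NA when no
#'   transfer was simulated), \code{hgt_precision} (1 when nothing was
#'   reported), \code{gain_f1}, \code{loss_f1}, \code{n_candidates},
#'   \code{n_transfers}.
#' @export
evaluate_recovery <- function(truth, history, records) {
  stopifnot(inherits(truth, "simulation_truth"),
            inherits(history, "family_history"))
  records <- as_species_records(records)
  truth_species <- sort(names(truth$species_counts))
  if (!identical(sort(unique(records$species)), truth_species))
    stop("species sets of truth and records do not match")

  taxa <- truth$taxa
  desc_names <- function(name) {
    id <- taxa$id[match(name, taxa$name)]
    ids <- id
    frontier <- id
    repeat {
      nxt <- taxa$id[!is.na(taxa$parent) & taxa$parent %in% frontier]
      if (!length(nxt)) break
      ids <- c(ids, nxt); frontier <- nxt
    }
    taxa$name[match(ids, taxa$id)]
  }

  transfers <- unique(ev_dest(truth, "transfer"))
  candidates <- history$hgt_candidates$taxon
  tp <- vapply(candidates, function(cand) {
    any(vapply(transfers, function(dst) cand %in% desc_names(dst),
               logical(1)))
  }, logical(1))
  covered <- vapply(transfers, function(dst) {
    any(candidates %in% desc_names(dst))
  }, logical(1))

  f1 <- function(pred, true) {
    if (!length(pred) && !length(true)) return(1)
    tp_n <- length(intersect(pred, true))
    denom <- 2 * tp_n + length(setdiff(pred, true)) +
      length(setdiff(true, pred))
    if (denom == 0) 1 else 2 * tp_n / denom
  }
  pred_gain <- unique(history$gains$taxon)
  true_gain <- unique(ev_dest(truth, "duplication"))
  pred_loss <- unique(c(history$losses$taxon, history$complete_losses$taxon))
  true_loss <- unique(ev_dest(truth, "loss"))

  list(origin_correct = identical(history$origin, truth$origin),
       hgt_sensitivity = if (length(transfers)) mean(covered) else NA_real_,
       hgt_precision = if (length(candidates)) mean(tp) else 1,
       gain_f1 = f1(pred_gain, true_gain),
       loss_f1 = f1(pred_loss, true_loss),
       n_candidates = length(candidates),
       n_transfers = length(transfers))
}

ev_dest <- function(truth, type) {
  truth$events$destination[truth$events$event == type]
}
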