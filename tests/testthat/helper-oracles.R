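# Independent oracles and small fixture builders shared across tests.

# Brute-force L1 median over 0..max(x): smallest integer minimizing the sum
# of absolute differences. Kept deliberately naive.
bf_l1_median <- function(x) {
  cand <- 0:max(x)
  cost <- vapply(cand, function(v) sum(abs(v - x)), numeric(1))
  cand[which.min(cost)] # which.min returns the first (smallest) minimizer
}

# Compact record builder: lineage strings "phylum/class/order/family/genus/
# species" with count and flags.
rec_rows <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    lin <- strsplit(r$lineage, "/", fixed = TRUE)[[1]]
    data.frame(species = lin[6], genus = lin[5], family = lin[4],
               order = lin[3], class = lin[2], phylum = lin[1],
               genome_sequenced = if (is.null(r$sequenced)) TRUE else
                 r$sequenced,
               hyperthermophile = if (is.null(r$hyper)) NA else r$hyper,
               acidophile = if (is.null(r$acid)) NA else r$acid,
               classified = if (is.null(r$classified)) TRUE else
                 r$classified,
               homologue_count = r$count, stringsAsFactors = FALSE)
  }))
}

sp <- function(lineage, count, ...) {
  c(list(lineage = lineage, count = count), list(...))
}

# Random species records over a small taxonomy: package generator supplies
# the tree shape only; counts and survey flags are overwritten here so the
# assignment oracle sees arbitrary presence patterns.
random_records <- function(seed, p_zero = 0.45) {
  sim <- simulate_family(simulation_params(
    n_phyla = 1L, branching = c(1L, 2L), p_dup = 0, p_loss = 0, p_hgt = 0,
    origin_rank = "phylum", origin_rule = "first", seed = seed))
  rec <- sim$records
  set.seed(seed + 10000L)
  n <- nrow(rec)
  rec$homologue_count <- ifelse(stats::runif(n) < p_zero, 0L,
                                sample(1:6, n, replace = TRUE))
  rec$genome_sequenced <- stats::runif(n) < 0.85
  # keep at least one surveyed species so the tree is not degenerate
  rec$genome_sequenced[1L] <- TRUE
  rec
}

# Independent strict-majority assignment oracle: recursive descent over the
# raw records (no tree object), one rank at a time. Returns a named list of
# inferred counts (NA when the majority rule fails) keyed by taxon name,
# plus species entries.
oracle_assign <- function(rec) {
  ranks <- c("phylum", "class", "order", "family", "genus", "species")
  out <- new.env(parent = emptyenv())
  recurse <- function(rows, level) {
    if (level == 6L) {
      # species leaf: observed count, surveyed iff genome sequenced
      val <- max(rows$homologue_count)
      assign(rows$species[1L], val, envir = out)
      return(list(value = val, surveyed = any(rows$genome_sequenced)))
    }
    kids <- split(rows, rows[[ranks[level + 1L]]])
    res <- lapply(kids, recurse, level = level + 1L)
    surveyed <- vapply(res, `[[`, logical(1), "surveyed")
    vals <- vapply(res, function(r) as.numeric(r$value), numeric(1))
    support <- surveyed & !is.na(vals) & vals > 0
    passed <- 2L * sum(support) > sum(surveyed)
    val <- if (passed) bf_l1_median(vals[support]) else NA_real_
    name <- rows[[ranks[level]]][1L]
    assign(name, val, envir = out)
    list(value = val, surveyed = any(surveyed))
  }
  top <- split(rec, rec$phylum)
  res <- lapply(top, recurse, level = 1L)
  surveyed <- vapply(res, `[[`, logical(1), "surveyed")
  vals <- vapply(res, function(r) as.numeric(r$value), numeric(1))
  support <- surveyed & !is.na(vals) & vals > 0
  root_val <- if (2L * sum(support) > sum(surveyed))
    bf_l1_median(vals[support]) else NA_real_
  assign(".root", root_val, envir = out)
  as.list(out, all.names = TRUE)
}

# Compare package assignments to the oracle for every named taxon.
expect_assignments_match_oracle <- function(rec) {
  tree <- assign_ancestral_counts(build_taxonomy(rec, root_name = ".root"))
  ora <- oracle_assign(rec)
  df <- tree$nodes
  for (i in seq_len(nrow(df))) {
    expected <- ora[[df$name[i]]]
    got <- df$inferred[i]
    if (is.na(expected)) {
      expect_true(is.na(got), label = paste0("taxon ", df$name[i],
                                             " unassigned"))
    } else {
      expect_identical(as.integer(got), as.integer(expected),
                       label = paste0("taxon ", df$name[i]))
    }
  }
  invisible(tree)
}
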