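test_that("parameters are validated and the output is seed-deterministic", {
  expect_error(simulation_params(p_dup = 1.2), "\\[0, 1\\]")
  expect_error(simulation_params(origin_rank = "kingdom"), "origin_rank")

  p <- simulation_params(seed = 42)
  a <- simulate_family(p)
  b <- simulate_family(p)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$events, b$truth$events)
  expect_identical(a$truth$species_counts, b$truth$species_counts)
  # a different seed changes the draw
  c_ <- simulate_family(simulation_params(seed = 43))
  expect_false(identical(a$truth$species_counts, c_$truth$species_counts))
  # the caller's RNG stream is left untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_family(p)); after <- runif(1)
  expect_identical(before, after)
})

test_that("with no events every origin descendant carries exactly one copy", {
  sim <- simulate_family(simulation_params(
    p_dup = 0, p_loss = 0, p_hgt = 0, seed = 5))
  rec <- sim$records
  origin_class <- sim$truth$origin
  inside <- rec$class == origin_class
  expect_true(all(rec$homologue_count[inside] == 1L))
  expect_true(all(rec$homologue_count[!inside] == 0L))
  expect_equal(nrow(sim$truth$events), 0L)
})

test_that("without loss or transfer the bearers form one monophyletic clade", {
  for (seed in 11:20) {
    sim <- simulate_family(simulation_params(
      p_dup = 0.3, p_loss = 0, p_hgt = 0, seed = seed))
    rec <- sim$records
    bearing <- rec[rec$homologue_count > 0L, ]
    expect_identical(unique(bearing$class), sim$truth$origin)
    # and every species of that clade bears at least one copy
    expect_true(all(rec$homologue_count[rec$class == sim$truth$origin] > 0L))
  }
})

test_that("replaying the event log reproduces the final counts exactly", {
  for (seed in 21:40) {
    sim <- simulate_family(simulation_params(
      p_dup = 0.25, p_loss = 0.1, p_hgt = 0.3, seed = seed))
    expect_identical(replay_truth(sim$truth), sim$truth$species_counts)
  }
})

test_that("a degenerate taxonomy skips transfer steps with a warning", {
  p <- simulation_params(n_phyla = 1L, branching = c(1L, 1L), p_hgt = 1,
                         p_dup = 0, p_loss = 0, origin_rank = "genus",
                         seed = 1)
  expect_warning(simulate_family(p), "skipped")
})

test_that("mean species count follows the branching-process expectation", {
  # depth 4 (class -> species) with duplication only: E[count] = 1.2^4
  means <- vapply(1:200, function(seed) {
    sim <- simulate_family(simulation_params(
      p_dup = 0.2, p_loss = 0, p_hgt = 0, origin_rank = "class",
      seed = seed))
    rec <- sim$records
    mean(rec$homologue_count[rec$class == sim$truth$origin])
  }, numeric(1))
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 1.2^4), 3 * se)
})

test_that("recovery metrics behave on engineered histories", {
  # no-event run: origin correct, empty candidate list scores precision 1
  sim <- simulate_family(simulation_params(
    p_dup = 0, p_loss = 0, p_hgt = 0, seed = 3))
  h <- infer_family_history(sim$records, root_name = "root")
  m <- evaluate_recovery(sim$truth, h, sim$records)
  expect_true(m$origin_correct)
  expect_identical(m$n_candidates, 0L)
  expect_identical(m$hgt_precision, 1)
  expect_identical(m$gain_f1, 1)
  expect_identical(m$loss_f1, 1)
  expect_true(is.na(m$hgt_sensitivity))

  # a run with at least one transfer and no loss: sensitivity 1
  found <- FALSE
  for (seed in 50:80) {
    sim <- simulate_family(simulation_params(
      p_dup = 0, p_loss = 0, p_hgt = 0.8, seed = seed))
    if (!any(sim$truth$events$event == "transfer")) next
    found <- TRUE
    h <- infer_family_history(sim$records, root_name = "root")
    m <- evaluate_recovery(sim$truth, h, sim$records)
    expect_identical(m$hgt_sensitivity, 1)
    expect_true(m$origin_correct)
    break
  }
  expect_true(found)

  # mismatched species sets are rejected
  sim <- simulate_family(simulation_params(seed = 4))
  h <- infer_family_history(sim$records, root_name = "root")
  expect_error(evaluate_recovery(sim$truth, h, sim$records[-1, ]),
               "species sets")

  # metrics are reproducible under identical seeds
  again <- simulate_family(simulation_params(seed = 4))
  h2 <- infer_family_history(again$records, root_name = "root")
  expect_identical(evaluate_recovery(again$truth, h2, again$records),
                   evaluate_recovery(sim$truth, h, sim$records))
})

test_that("engineered alignment columns carry exact counts", {
  spec <- data.frame(position = c(10, 10), residue = c("D", "N"),
                     fraction = c(1.0, 0.0))
  a <- simulate_alignment(20, 15, spec, seed = 2)
  expect_identical(count_residue_at(a, 10, "D"), 20L)

  # random specs verified by brute-force tally
  set.seed(6)
  for (i in 1:5) {
    pos <- sample(1:30, 3)
    res <- sample(c("A", "D", "K"), 3)
    frac <- round(stats::runif(3, 0.2, 0.9), 2)
    spec <- data.frame(position = pos, residue = res, fraction = frac)
    a <- simulate_alignment(40, 30, spec, seed = i)
    for (j in 1:3) {
      expect_identical(count_residue_at(a, pos[j], res[j]),
                       as.integer(round(frac[j] * 40)))
      expect_identical(sum(a$mat[, pos[j]] == res[j]),
                       as.integer(round(frac[j] * 40)))
    }
  }

  # byte-identical under the same seed
  s <- data.frame(position = 3, residue = "W", fraction = 0.5)
  expect_identical(simulate_alignment(10, 8, s, seed = 9)$mat,
                   simulate_alignment(10, 8, s, seed = 9)$mat)

  # contradictory specs are rejected
  expect_error(simulate_alignment(10, 8, data.frame(
    position = c(2, 2), residue = c("D", "D"), fraction = c(0.5, 0.4))),
    "contradictory")
  expect_error(simulate_alignment(10, 8, data.frame(
    position = c(2, 2), residue = c("D", "N"), fraction = c(0.8, 0.8))),
    "contradictory")
})

test_that("transfer destinations lie outside the bearing clade", {
  for (seed in 81:95) {
    sim <- simulate_family(simulation_params(
      p_dup = 0, p_loss = 0, p_hgt = 0.9, seed = seed))
    tr <- sim$truth$events[sim$truth$events$event == "transfer", ]
    if (!nrow(tr)) next
    taxa <- sim$truth$taxa
    origin_id <- taxa$id[taxa$name == sim$truth$origin]
    origin_clade <- sim$truth$taxa$name[
      match(paleofam:::.subtree_ids(
        data.frame(id = taxa$id, parent = taxa$parent), origin_id),
        taxa$id)]
    # the first transfer of a run cannot land inside the origin clade
    expect_false(tr$destination[1L] %in% origin_clade)
  }
})
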