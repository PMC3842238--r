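test_that("ancestral counts follow the strict-majority rule on forced cases", {
  # one child with a count: 1/1 is a strict majority, value propagates
  one <- rec_rows(sp("P/C/O/F/G/S1", 3))
  df1 <- assign_ancestral_counts(build_taxonomy(one))$nodes
  expect_identical(df1$inferred[df1$name == "G"], 3L)
  expect_identical(df1$inferred[df1$name == "P"], 3L)

  # 1 bearer of 3 surveyed children is not a strict majority
  minority <- rec_rows(sp("P/C/O/F/G/S1", 2), sp("P/C/O/F/G/S2", 0),
                       sp("P/C/O/F/G/S3", 0))
  df2 <- assign_ancestral_counts(build_taxonomy(minority))$nodes
  expect_true(is.na(df2$inferred[df2$name == "G"]))
  expect_false(df2$majority_passed[df2$name == "G"])
  expect_identical(df2$supporting_children[df2$name == "G"], 1L)
  expect_identical(df2$surveyed_children[df2$name == "G"], 3L)
})

test_that("assigned values are the L1 median with ties toward the smaller integer", {
  # expected values frozen from the brute-force oracle:
  # bf_l1_median(c(2,5,6)) == 5; bf_l1_median(c(1,3)) == 1
  expect_identical(bf_l1_median(c(2, 5, 6)), 5L)
  expect_identical(bf_l1_median(c(1, 3)), 1L)

  three <- rec_rows(sp("P/C/O/F/G/S1", 2), sp("P/C/O/F/G/S2", 5),
                    sp("P/C/O/F/G/S3", 6))
  df <- assign_ancestral_counts(build_taxonomy(three))$nodes
  expect_identical(df$inferred[df$name == "G"], 5L)

  tie <- rec_rows(sp("P/C/O/F/G/S1", 1), sp("P/C/O/F/G/S2", 3))
  df <- assign_ancestral_counts(build_taxonomy(tie))$nodes
  expect_identical(df$inferred[df$name == "G"], 1L)

  for (seed in 1:25) {
    set.seed(seed)
    x <- sample(1:9, sample(1:7, 1), replace = TRUE)
    expect_identical(l1_median_count(x), as.integer(bf_l1_median(x)))
  }
})

test_that("unsurveyed children are ignored by numerator and denominator", {
  rec <- rec_rows(sp("P/C/O/F/G/S1", 4),
                  sp("P/C/O/F/G/S2", 0, sequenced = FALSE),
                  sp("P/C/O/F/G/S3", 0, sequenced = FALSE))
  df <- assign_ancestral_counts(build_taxonomy(rec))$nodes
  g <- df$name == "G"
  expect_identical(df$surveyed_children[g], 1L)
  expect_identical(df$inferred[g], 4L) # 1/1 among surveyed children
})

test_that("assignments match the independent recursive oracle on random trees", {
  for (seed in 1:40) {
    expect_assignments_match_oracle(random_records(seed))
  }
})

test_that("majority-rule soundness holds exactly in integers", {
  for (seed in 41:60) {
    tree <- assign_ancestral_counts(
      build_taxonomy(random_records(seed), root_name = ".root"))
    df <- tree$nodes
    internal <- df$rank != "species"
    assigned <- internal & !is.na(df$inferred)
    expect_true(all(2L * df$supporting_children[assigned] >
                      df$surveyed_children[assigned]))
    unassigned <- internal & is.na(df$inferred)
    expect_true(all(2L * df$supporting_children[unassigned] <=
                      df$surveyed_children[unassigned]))
  }
})

test_that("a tree without species counts is rejected", {
  tree <- build_taxonomy(rec_rows(sp("P/C/O/F/G/S1", 1)))
  tree$nodes$observed[] <- NA_integer_
  expect_error(assign_ancestral_counts(tree), "counts")
})

test_that("the origin is the highest credited taxon, with a family-absent result", {
  # all homologues confined to one genus -> that genus
  rec <- rec_rows(sp("P/C/O/F/G1/S1", 2), sp("P/C/O/F/G1/S2", 2),
                  sp("P/C/O/F/G2/S3", 0), sp("P/C/O/F/G3/S4", 0))
  tree <- assign_ancestral_counts(build_taxonomy(rec))
  origin <- find_origin(tree)
  expect_identical(origin$taxon, "G1")
  expect_identical(origin$rank, "genus")

  # no homologues at all: a distinct absent result, not an exception
  none <- rec_rows(sp("P/C/O/F/G/S1", 0), sp("P/C/O/F/G/S2", 0))
  absent <- find_origin(assign_ancestral_counts(build_taxonomy(none)))
  expect_true(absent$absent)
  expect_identical(absent$taxon, NA_character_)
  expect_identical(detect_hgt(assign_ancestral_counts(build_taxonomy(none)),
                              absent)$taxon, character(0))
})

test_that("a simulated family seeded at a class is recovered at that class", {
  for (seed in 101:110) {
    sim <- simulate_family(simulation_params(
      p_dup = 0.2, p_loss = 0, p_hgt = 0, origin_rank = "class",
      seed = seed))
    h <- infer_family_history(sim$records, root_name = "root")
    expect_identical(h$origin, sim$truth$origin)
    expect_identical(h$origin_rank, "class")
  }
})

test_that("presence confined to one clade yields no transfer candidates", {
  rec <- rec_rows(sp("P/C/O/F/G/S1", 1), sp("P/C/O/F/G/S2", 1),
                  sp("P/C2/O2/F2/G2/S3", 0))
  h <- infer_family_history(rec, root_name = "root")
  expect_equal(nrow(h$hgt_candidates), 0L)
})

test_that("unexpected presences are the maximal credited taxa outside the origin", {
  # family born in class C1; a stray bearing genus, and a stray species
  # whose genus holds non-bearing members so the species itself is maximal
  rec <- rec_rows(
    sp("P/C1/O1/F1/G1/S1", 1), sp("P/C1/O2/F2/G2/S2", 1),
    sp("P/C2/O3/F3/G3/S3", 1), sp("P/C2/O3/F3/G3/S3b", 0),
    sp("P/C2/O3/F3/G3/S3c", 0),                     # lone bearer species
    sp("P/C2/O4/F4/G4/S4", 2), sp("P/C2/O4/F4/G4/S5", 2), # a bearing genus
    sp("P/C2/O4/F4/G5/S6", 0), sp("P/C2/O4/F5/G6/S7", 0),
    sp("P/C2/O5/F6/G7/S8", 0))
  h <- infer_family_history(rec, root_name = "root")
  expect_identical(h$origin, "C1")
  expect_setequal(h$hgt_candidates$taxon, c("S3", "G4"))
  expect_identical(sort(h$hgt_candidates$kind), c("clade", "species"))
})

test_that("every bearer species lies in exactly one reported clade", {
  for (seed in 61:75) {
    rec <- random_records(seed)
    tree <- assign_ancestral_counts(
      build_taxonomy(rec, root_name = ".root"))
    origin <- find_origin(tree)
    if (origin$absent) next
    hgt <- detect_hgt(tree, origin)
    df <- tree$nodes
    clade_ids <- df$id[df$name %in% c(origin$taxon, hgt$taxon)]
    bearer_ids <- df$id[df$rank == "species" & df$observed > 0L]
    coverage <- vapply(bearer_ids, function(b) {
      sum(vapply(clade_ids, function(cl) {
        b %in% paleofam:::.subtree_ids(df, cl)
      }, logical(1)))
    }, integer(1))
    expect_true(all(coverage == 1L))
  }
})

test_that("raising one species count never removes its clade from the credited set", {
  for (seed in 76:85) {
    rec <- random_records(seed)
    tree <- assign_ancestral_counts(
      build_taxonomy(rec, root_name = ".root"))
    df <- tree$nodes
    set.seed(seed)
    pick <- sample(which(rec$homologue_count >= 0L), 1L)
    assigned_before <- df$name[!is.na(df$inferred) & df$inferred > 0L]
    containing_before <- intersect(
      assigned_before,
      c(rec$species[pick],
        unlist(rec[pick, c("genus", "family", "order", "class", "phylum")])))
    rec2 <- rec
    rec2$homologue_count[pick] <- rec2$homologue_count[pick] + 3L
    df2 <- assign_ancestral_counts(
      build_taxonomy(rec2, root_name = ".root"))$nodes
    assigned_after <- df2$name[!is.na(df2$inferred) & df2$inferred > 0L]
    expect_true(all(containing_before %in% assigned_after))
  }
})

test_that("gains and losses match an exhaustive parent/child comparison", {
  # engineered case: Caldivirga-style expansion to 3 against a background of 1
  rec <- rec_rows(
    sp("P/C/O/F/G1/S1", 3), sp("P/C/O/F/G1/S2", 3),
    sp("P/C/O/F/G2/S3", 1), sp("P/C/O/F/G3/S4", 1),
    sp("P/C/O/F/G4/S5", 1))
  h <- infer_family_history(rec, root_name = "root")
  gain <- h$gains[h$gains$taxon == "G1", ]
  expect_equal(nrow(gain), 1L)
  expect_identical(gain$delta, 2L)
  expect_identical(gain$parent_count, 1L)

  # uniform counts: no events at all
  flat <- rec_rows(sp("P/C/O/F/G1/S1", 2), sp("P/C/O/F/G2/S2", 2))
  hf <- infer_family_history(flat, root_name = "root")
  expect_equal(nrow(hf$gains) + nrow(hf$losses) +
                 nrow(hf$complete_losses), 0L)

  # random trees against a brute-force scan of assigned parent/child pairs
  for (seed in 86:95) {
    tree <- assign_ancestral_counts(
      build_taxonomy(random_records(seed), root_name = ".root"))
    ev <- detect_gains_losses(tree)
    df <- tree$nodes
    expected_gain <- expected_loss <- character(0)
    expected_complete <- character(0)
    for (i in seq_len(nrow(df))) {
      p <- df$parent[i]
      if (is.na(p)) next
      pc <- df$inferred[match(p, df$id)]
      cc <- df$inferred[i]
      if (is.na(pc) || pc == 0L || is.na(cc)) next
      if (cc > pc) expected_gain <- c(expected_gain, df$name[i])
      else if (cc == 0L) expected_complete <- c(expected_complete, df$name[i])
      else if (cc < pc) expected_loss <- c(expected_loss, df$name[i])
    }
    expect_setequal(ev$gains$taxon, expected_gain)
    expect_setequal(ev$losses$taxon, expected_loss)
    expect_setequal(ev$complete_losses$taxon, expected_complete)
    expect_true(all(ev$gains$child_count > ev$gains$parent_count))
    expect_true(all(ev$losses$child_count > 0L &
                      ev$losses$child_count < ev$losses$parent_count))
  }
})

test_that("phenotype crosstab tallies flags and violators correctly", {
  rec <- rec_rows(
    sp("P/C/O/F/G/S1", 2, hyper = TRUE, acid = TRUE),
    sp("P/C/O/F/G/S2", 1, hyper = FALSE, acid = TRUE),
    sp("P/C/O/F/G/S3", 0, hyper = TRUE, acid = TRUE),
    sp("P/C/O/F/G/S4", 0, hyper = TRUE, acid = FALSE),
    sp("P/C/O/F/G/S5", 0, hyper = NA, acid = TRUE))
  ct <- phenotype_crosstab(rec)
  expect_identical(ct$bearers_not_hyperthermophilic, "S2")
  expect_identical(ct$thermoacidophiles_without_homologue, "S3")
  # hand tally: hyper known for S1..S4; bearers 2 (1 hyper), absent 2 hyper
  expect_equal(as.vector(ct$hyperthermophile),
               c(0L, 1L, 2L, 1L)) # absent/no, present/no, absent/yes, present/yes
  expect_equal(unname(ct$n_unknown["hyperthermophile"]), 1L)
  # all bearers thermoacidophilic -> empty violator list (a)
  all_ok <- rec_rows(sp("P/C/O/F/G/S1", 1, hyper = TRUE, acid = TRUE))
  expect_length(phenotype_crosstab(all_ok)$bearers_not_hyperthermophilic, 0L)
})
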