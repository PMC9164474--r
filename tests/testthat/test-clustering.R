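test_that("first-level partition applies the precedence rules", {
  expect_identical(as.character(first_level_partition("AAAAAASPAAAAA")), "I")
  expect_identical(as.character(first_level_partition("AAARAASAAAAAA")), "II")
  expect_identical(as.character(first_level_partition("AAASAATAAAAAA")), "III")
  expect_identical(as.character(first_level_partition("AAAAAGSAAAAAA")), "IV")
  expect_error(first_level_partition("NOTAWINDOW"), "malformed")
})

test_that("proline at +1 always wins and the partition is total", {
  set.seed(17)
  wins <- replicate(200, paste(
    c(sample(kinbayes:::AA_STANDARD, 6, TRUE), sample(c("S", "T", "Y"), 1),
      sample(kinbayes:::AA_STANDARD, 6, TRUE)), collapse = ""))
  grp <- first_level_partition(wins)
  expect_identical(sum(table(grp)), 200L)
  expect_false(anyNA(grp))
  forced <- vapply(wins, function(w) {
    substr(w, 8, 8) <- "P"
    w
  }, character(1), USE.NAMES = FALSE)
  expect_true(all(first_level_partition(forced) == "I"))
})

test_that("direction at 15 min follows the sign, with ties an explicit error", {
  expect_identical(direction_at_15(c(0, 0, 0, 0.4)), "increased")
  expect_identical(direction_at_15(c(0, 0, 0, -0.4)), "decreased")
  expect_error(direction_at_15(c(0.1, 0.2, 0.3, 0)), "tie")
})

test_that("half-max time scans the four points in order", {
  expect_identical(half_max_time(c(0.5, 0.6, 0.7, 0.8)),
                   list(time = 1L, speed = "fast"))
  expect_identical(half_max_time(c(0.1, 0.2, 0.4, 0.8)),
                   list(time = 5L, speed = "slow"))
  # half-max is 0.2 and is already reached at 1 min
  expect_identical(half_max_time(c(0.2, 0.1, 0.3, 0.4)),
                   list(time = 1L, speed = "fast"))
  expect_identical(half_max_time(c(0.05, 0.11, 0.15, 0.2))$speed, "intermediate")
  expect_error(half_max_time(c(0, 0, 0, 0)), "undefined")
})

test_that("pattern classes follow the sign sequence of successive differences", {
  expect_identical(pattern_class(c(-0.1, -0.2, -0.3, -0.35)), "monotonic")
  expect_identical(pattern_class(c(-0.2, -0.3, -0.1, 0.05)), "dip_then_rise_at_5")
  expect_identical(pattern_class(c(-0.2, -0.1, 0.0, 0.1)), "dip_then_rise_by_2")
  expect_identical(pattern_class(c(0.3, 0.1, 0.4, 0.5)), "rise_dip_rise")
  expect_identical(pattern_class(c(0.3, 0.4, 0.5, 0.6)), "other")
})

test_that("the leaf decision tree reproduces the named subclusters", {
  # Group I: increased is a leaf on its own
  a <- assign_leaf(make_window("1" = "P"), c(0.2, 0.3, 0.35, 0.4))
  expect_identical(a$leaf, "I.B")
  # I.A.1: basic at +5 and +6, decreased
  a <- assign_leaf(make_window("1" = "P", "5" = "R", "6" = "K"),
                   c(-0.2, -0.3, -0.35, -0.4))
  expect_identical(a$leaf, "I.A.1")
  # I.A.2.a/b/c by pattern
  w1 <- make_window("1" = "P")
  expect_identical(assign_leaf(w1, c(-0.2, -0.3, -0.35, -0.4))$leaf, "I.A.2.a")
  expect_identical(assign_leaf(w1, c(-0.2, -0.3, -0.1, -0.05))$leaf, "I.A.2.b")
  expect_identical(assign_leaf(w1, c(-0.3, -0.2, -0.1, -0.05))$leaf, "I.A.2.c")
  # II.A.1 by speed (slow -> a, fast -> b)
  w2 <- make_window("-3" = "R", "-2" = "K")
  expect_identical(assign_leaf(w2, c(0.05, 0.1, 0.3, 0.4))$leaf, "II.A.1.a")
  expect_identical(assign_leaf(w2, c(0.3, 0.35, 0.38, 0.4))$leaf, "II.A.1.b")
  expect_true(assign_leaf(w2, c(-0.3, -0.35, -0.38, -0.4))$unassigned)
  # II.B: increased -> II.B.2; decreased by pattern
  w3 <- make_window("-3" = "R", "-2" = "A")
  expect_identical(assign_leaf(w3, c(0.1, 0.2, 0.3, 0.4))$leaf, "II.B.2")
  expect_identical(assign_leaf(w3, c(0.2, 0.1, 0.3, -0.2))$leaf, "II.B.1.a")
  expect_identical(assign_leaf(w3, c(-0.3, -0.2, -0.1, -0.4))$leaf, "II.B.1.b")
  # III: increased -> III.A; decreased split on basic at -1
  w4 <- make_window("-2" = "T")
  expect_identical(assign_leaf(w4, c(0.1, 0.2, 0.3, 0.4))$leaf, "III.A")
  expect_identical(assign_leaf(make_window("-2" = "T", "-1" = "R"),
                               c(-0.1, -0.2, -0.3, -0.4))$leaf, "III.B.2")
  expect_identical(assign_leaf(w4, c(-0.1, -0.2, -0.3, -0.4))$leaf, "III.B.1")
  # IV by direction
  w5 <- make_window()
  expect_identical(assign_leaf(w5, c(0.1, 0.2, 0.3, 0.4))$leaf, "IV.A")
  expect_identical(assign_leaf(w5, c(-0.1, -0.2, -0.3, -0.4))$leaf, "IV.B")
  # 15-min tie is excluded from direction-based subclustering
  expect_true(assign_leaf(w5, c(0.1, 0.2, 0.3, 0))$unassigned)
  # every assignment carries a decision trail
  expect_gt(length(assign_leaf(w5, c(0.1, 0.2, 0.3, 0.4))$trail), 1)
})

test_that("cluster assignment is deterministic and order-independent", {
  set.seed(23)
  sim <- simulate_experiment(sim_config(seed = 23, n_sites = 120,
                                        n_regulated = 30))
  rep <- filter_regulated(sim$sites)
  cl1 <- cluster_sites(sim$sites, rep$regulated_ids)
  shuffled <- sim$sites[sample(nrow(sim$sites)), ]
  cl2 <- cluster_sites(shuffled, rep$regulated_ids)
  cl2 <- cl2[match(cl1$site_id, cl2$site_id), ]
  rownames(cl2) <- NULL
  expect_equal(as.data.frame(cl1), as.data.frame(cl2))
})

test_that("frequency matrices normalize per position and exclude padding", {
  fm <- frequency_matrix("AAAAAASPAAAAA")
  expect_identical(fm$n, 1L)
  expect_identical(unname(fm$mat["0", "S"]), 1)
  expect_identical(unname(fm$mat["1", "P"]), 1)
  expect_equal(unname(rowSums(fm$mat)), rep(1, 13), tolerance = 1e-9)

  fm2 <- frequency_matrix(c(make_window("1" = "P"), make_window("1" = "A")))
  expect_equal(unname(fm2$mat["1", c("P", "A")]), c(0.5, 0.5))

  fmJ <- frequency_matrix(c("JJJJJJSKJJJJJ", "AAAAAASPAAAAA"))
  # padded positions: only the unpadded window contributes
  expect_identical(unname(fmJ$mat["-6", "A"]), 1)
  expect_equal(unname(rowSums(fmJ$mat)), rep(1, 13), tolerance = 1e-9)

  expect_error(frequency_matrix(character()), "at least one")
})

test_that("uniform windows give near-uniform frequencies", {
  set.seed(31)
  wins <- replicate(1000, paste(
    c(sample(kinbayes:::AA_STANDARD, 6, TRUE), "S",
      sample(kinbayes:::AA_STANDARD, 6, TRUE)), collapse = ""))
  fm <- frequency_matrix(wins)
  se <- sqrt((1 / 20) * (19 / 20) / 1000)
  off_center <- fm$mat[rownames(fm$mat) != "0", ]
  expect_true(all(abs(off_center - 1 / 20) < 4 * se))
})

test_that("class frequencies collapse the residue alphabet", {
  fm <- frequency_matrix(make_window("-3" = "R", "1" = "P"))
  cf <- class_frequencies(fm)
  expect_identical(unname(cf["-3", "Psi"]), 1)
  expect_identical(unname(cf["0", "Delta"]), 1)
  expect_equal(unname(rowSums(cf)), rep(1, 13), tolerance = 1e-9)
})

test_that("the enrichment chi-square matches the reference implementation", {
  expect_equal(enrichment_chisq(5, 50, 100, 1000)$statistic, 0, tolerance = 1e-12)
  got <- enrichment_chisq(8, 21, 8, 100)
  oracle <- suppressWarnings(
    stats::chisq.test(matrix(c(8, 13, 8, 92), 2, byrow = TRUE),
                      correct = FALSE))
  expect_equal(got$statistic, unname(oracle$statistic), tolerance = 1e-9)
  expect_equal(got$p_value, oracle$p.value, tolerance = 1e-9)
  expect_identical(enrichment_chisq(0, 10, 0, 100)$statistic, 0)
  expect_true(enrichment_chisq(1, 2, 1, 3)$low_expected)
  # Yates-corrected variant agrees with the corrected reference
  gotc <- enrichment_chisq(8, 21, 8, 100, correct = TRUE)
  oc <- suppressWarnings(
    stats::chisq.test(matrix(c(8, 13, 8, 92), 2, byrow = TRUE), correct = TRUE))
  expect_equal(gotc$statistic, unname(oc$statistic), tolerance = 1e-9)
})
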