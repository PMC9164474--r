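test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_experiment(sim_config(seed = 11, n_sites = 80, n_regulated = 20,
                                      substrates_per_kinase = 40))
  b <- simulate_experiment(sim_config(seed = 11, n_sites = 80, n_regulated = 20,
                                      substrates_per_kinase = 40))
  expect_identical(a$sites, b$sites)
  expect_identical(a$truth, b$truth)
  expect_identical(a$bundle$substrates, b$bundle$substrates)
  expect_identical(a$bundle$transcript, b$bundle$transcript)
  c <- simulate_experiment(sim_config(seed = 12, n_sites = 80, n_regulated = 20,
                                      substrates_per_kinase = 40))
  expect_false(identical(a$sites$ratio_15, c$sites$ratio_15))
})

test_that("site means equal the replicate averages exactly", {
  sim <- simulate_experiment(sim_config(seed = 4, n_sites = 60, n_regulated = 10,
                                        substrates_per_kinase = 20))
  for (t in c(1, 2, 5, 15)) {
    reps <- as.matrix(sim$sites[, paste0("rep", 1:3, "_", t)])
    expect_equal(sim$sites[[paste0("ratio_", t)]], unname(rowMeans(reps)),
                 tolerance = 1e-9)
  }
})

test_that("null data reproduce the configured per-time noise SDs", {
  sites <- simulate_null_experiment(sim_config(seed = 21))
  sds <- per_timepoint_sd(sites)
  cfg_sds <- c(0.104, 0.104, 0.128, 0.148)
  for (t in 1:4) {
    se <- cfg_sds[t] / sqrt(2 * (nrow(sites) - 1))
    expect_lt(abs(sds[[t]] - cfg_sds[t]), 3 * se)
  }
})

test_that("planted windows land deterministically in their intended groups", {
  for (s in c(31, 32, 33)) {
    sim <- simulate_experiment(sim_config(seed = s))
    tr <- sim$truth
    planted <- !is.na(tr$kinase)
    grp <- as.character(
      first_level_partition(sim$sites$window[match(tr$site_id[planted],
                                                   sim$sites$site_id)]))
    intended <- sub("\\..*$", "", tr$group[planted])
    expect_identical(grp, intended)
  }
})

test_that("the noiseless temporal shapes classify exactly as named", {
  sh <- temporal_shapes()
  expect_identical(half_max_time(sh$fast_up)$speed, "fast")
  expect_identical(half_max_time(sh$slow_up)$speed, "slow")
  expect_identical(pattern_class(sh$monotonic_down), "monotonic")
  expect_identical(pattern_class(sh$dip_rise_2), "dip_then_rise_by_2")
  expect_identical(pattern_class(sh$dip_rise_5), "dip_then_rise_at_5")
  expect_identical(pattern_class(sh$rise_dip_rise), "rise_dip_rise")
  expect_identical(direction_at_15(sh$fast_up), "increased")
  expect_identical(direction_at_15(sh$monotonic_down), "decreased")
})

test_that("most surviving planted sites are assigned to their intended leaf", {
  tot <- 0; ok <- 0
  for (s in c(101, 102, 103)) {
    sim <- simulate_experiment(sim_config(seed = s))
    rep <- filter_regulated(sim$sites)
    cl <- cluster_sites(sim$sites, rep$regulated_ids)
    m <- merge(cl, sim$truth, by = "site_id")
    m <- m[!is.na(m$kinase), ]
    tot <- tot + nrow(m)
    ok <- ok + sum(!is.na(m$leaf.x) & m$leaf.x == m$leaf.y)
  }
  expect_gt(ok / tot, 0.8)
})

test_that("planted sites pass the filter far more often than background sites", {
  pass_p <- 0; pass_n <- 0; n_p <- 0; n_n <- 0
  for (s in c(111, 112, 113)) {
    sim <- simulate_experiment(sim_config(seed = s))
    rep <- filter_regulated(sim$sites)
    planted <- sim$truth$site_id[!is.na(sim$truth$kinase)]
    bg <- setdiff(sim$sites$site_id, planted)
    pass_p <- pass_p + sum(planted %in% rep$regulated_ids)
    pass_n <- pass_n + sum(bg %in% rep$regulated_ids)
    n_p <- n_p + length(planted); n_n <- n_n + length(bg)
  }
  expect_gt(pass_p / n_p, 0.5)      # planted power
  expect_lt(pass_n / n_n, 0.05)     # background false-positive rate
})

test_that("generated tables round-trip through the table readers", {
  sim <- simulate_experiment(sim_config(seed = 9, n_sites = 50, n_regulated = 10,
                                        substrates_per_kinase = 20))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_phosphosite_table(sim$sites, path)
  expect_equal(read_phosphosite_table(path), sim$sites, tolerance = 0)
})

test_that("an undetectable effect size triggers a warning, not an error", {
  expect_warning(sim_config(seed = 1, effect = 0.2), "half-width")
  expect_silent(sim_config(seed = 1))
})
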