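test_that("cmbf evaluates the minimum-Bayes-factor complement", {
  expect_identical(cmbf(0), 0)
  expect_equal(cmbf(1), 1 - exp(-0.5), tolerance = 1e-12)
  expect_equal(cmbf(2), 1 - exp(-2), tolerance = 1e-12)
  expect_identical(cmbf(-1.3), cmbf(1.3))  # sign-symmetric
  expect_error(cmbf(Inf), "finite")
})

test_that("likelihood flooring is an idempotent elementwise max", {
  expect_identical(floor_likelihood(c(0, 0.3, 0.9)), c(0.5, 0.5, 0.9))
  v <- c(0.5, 0.7, 1)
  expect_identical(floor_likelihood(v), v)
  expect_identical(floor_likelihood(floor_likelihood(c(0.1, 0.9))),
                   floor_likelihood(c(0.1, 0.9)))
})

test_that("bayes_update normalizes prior x likelihood", {
  u <- uniform_prior(c("a", "b", "c"))
  expect_equal(unname(bayes_update(u, c(a = 0.7, b = 0.7, c = 0.7))),
               rep(1 / 3, 3), tolerance = 1e-12)
  post <- bayes_update(c(a = 0.5, b = 0.5), c(a = 0.9, b = 0.1))
  expect_equal(unname(post), c(0.9, 0.1), tolerance = 1e-12)
  expect_error(bayes_update(c(a = 1, b = 0), c(a = 0, b = 1)), "zero")
})

test_that("sequential updates equal the single-pass product form", {
  u <- uniform_prior(c("a", "b", "c"))
  L1 <- c(a = 0.9, b = 0.5, c = 0.5)
  L2 <- c(a = 0.5, b = 0.9, c = 0.5)
  seq_post <- bayes_update(bayes_update(u, L1), L2)
  expect_equal(unname(seq_post), c(0.3913, 0.3913, 0.2174), tolerance = 1e-4)
  prod_post <- (u * L1 * L2) / sum(u * L1 * L2)
  expect_equal(seq_post, prod_post, tolerance = 1e-12)
  # probability ratios of the two-step toy
  expect_equal(unname(seq_post * 3), c(1.174, 1.174, 0.652), tolerance = 1e-3)
})

test_that("expression likelihoods floor absent and weak kinases at 0.5", {
  syms <- c("a", "b", "c")
  lk <- expression_likelihood(c(a = 0, b = 3), pivot = 1, symbols = syms)
  expect_identical(unname(lk["a"]), 0.5)          # zero value
  expect_identical(unname(lk["c"]), 0.5)          # absent from the table
  expect_equal(unname(lk["b"]), 0.9888910035, tolerance = 1e-9)
  # monotonicity: expressed never below unexpressed
  set.seed(2)
  vals <- stats::setNames(runif(3, 0.1, 10), syms)
  lk2 <- expression_likelihood(vals, pivot = 1, symbols = syms)
  expect_true(all(lk2 >= 0.5))
  expect_error(expression_likelihood(c(a = 1), pivot = 0, symbols = syms), "pivot")
  expect_error(expression_likelihood(c(a = -1), pivot = 1, symbols = syms),
               "non-negative")
})

test_that("S/T/Y preference scores by dot product with pivot 1/9", {
  m <- rbind(pureS = c(1, 0, 0), pureY = c(0, 0, 1), mixed = c(0.5, 0.5, 0))
  colnames(m) <- c("S", "T", "Y")
  lk <- sty_preference_likelihood(m, c(1, 0, 0))
  expect_equal(unname(lk["pureS"]), cmbf(9), tolerance = 1e-12)
  expect_gt(unname(lk["pureS"]), 0.9999)
  expect_identical(unname(sty_preference_likelihood(m, c(0.7, 0.3, 0))["pureY"]),
                   0.5)
  lk2 <- sty_preference_likelihood(m, c(0.6, 0.4, 0))
  expect_equal(unname(lk2["mixed"]), cmbf(0.5 * 9), tolerance = 1e-12)
  bad <- rbind(x = c(0.9, 0.9, 0.9)); colnames(bad) <- c("S", "T", "Y")
  expect_error(sty_preference_likelihood(bad, c(1, 0, 0)), "at most 1")
})

test_that("colocalization scores match an elementwise-product oracle", {
  profs <- rbind(k1 = c(1, 0, 0), k2 = c(0, 1, 0))
  colnames(profs) <- paste0("f", 1:3)
  lk <- colocalization_likelihood(profs, c(0, 0, 1), pivot = 1)
  expect_identical(as.numeric(lk), c(0.5, 0.5))  # orthogonal
  lk2 <- colocalization_likelihood(rbind(k1 = c(1, 0, 0)), c(1, 0, 0), pivot = 0.5)
  expect_equal(as.numeric(lk2), cmbf(2), tolerance = 1e-12)

  set.seed(12)
  P <- matrix(runif(30), nrow = 5,
              dimnames = list(paste0("k", 1:5), paste0("f", 1:6)))
  v <- runif(6)
  got <- colocalization_likelihood(P, v)
  oracle <- vapply(1:5, function(i) sum(P[i, ] * v), numeric(1))
  expect_equal(unname(attr(got, "pivot")), mean(oracle), tolerance = 1e-12)
  expect_equal(as.numeric(got),
               unname(pmax(cmbf(oracle / mean(oracle)), 0.5)), tolerance = 1e-12)
  expect_error(colocalization_likelihood(P, runif(4)), "fraction")
})

test_that("activity annotations map to the four discrete likelihoods", {
  act <- c(up = "increase", down = "decrease", reg = "regulated_unknown",
           none = "none")
  syms <- c("up", "down", "reg", "none", "absent")
  inc <- activity_likelihood(act, "increased", syms)
  expect_identical(unname(inc), c(0.9, 0.1, 0.7, 0.5, 0.5))
  dec <- activity_likelihood(act, "decreased", syms)
  expect_identical(unname(dec), c(0.1, 0.9, 0.7, 0.5, 0.5))
  expect_error(activity_likelihood(act, "sideways", syms), "direction")
})

test_that("information content follows P * log2(P / Pref)", {
  P <- matrix(c(0.25, 1, 0.5), nrow = 3,
              dimnames = list(c("-1", "0", "1"), "S"))
  bg <- c(S = 0.25)
  ic <- information_content(P, bg)
  expect_equal(unname(ic["-1", "S"]), 0, tolerance = 1e-12)
  expect_equal(unname(ic["0", "S"]), 2, tolerance = 1e-12)
  ic2 <- information_content(matrix(0.5, 1, 1, dimnames = list("0", "S")),
                             c(S = 0.05))
  expect_equal(unname(ic2[1, 1]), 1.6609640474, tolerance = 1e-9)
  # zero frequency contributes zero
  ic3 <- information_content(matrix(0, 1, 1, dimnames = list("0", "S")),
                             c(S = 0.25))
  expect_identical(unname(ic3[1, 1]), 0)
  expect_error(information_content(matrix(0.5, 1, 1, dimnames = list("0", "S")),
                                   c(S = 0)), "S")
})

test_that("motif matching scores IC dot products over selected positions", {
  mk_ic <- function(vals) {
    m <- matrix(0, nrow = 13, ncol = 20,
                dimnames = list(as.character(-6:6), kinbayes:::AA_STANDARD))
    for (nm in names(vals)) {
      p <- strsplit(nm, "_")[[1]]
      m[p[1], p[2]] <- vals[[nm]]
    }
    m
  }
  cluster <- mk_ic(c("1_P" = 2, "-3_R" = 1, "2_A" = -0.5))
  kin <- list(
    match = mk_ic(c("1_P" = 2, "-3_R" = 1)),
    anti = mk_ic(c("1_P" = -3, "2_A" = 4)),
    blank = mk_ic(c())
  )
  got <- motif_match_likelihood(kin, cluster, positions = c(-3, 1, 2), pivot = 1)
  # oracle: nested loop with clipping of negative elementwise products
  oracle <- vapply(kin, function(icm) {
    s <- 0
    for (p in c("-3", "1", "2")) for (a in kinbayes:::AA_STANDARD) {
      s <- s + max(0, icm[p, a] * cluster[p, a])
    }
    s
  }, numeric(1))
  expect_equal(unname(attr(got, "scores")), unname(oracle), tolerance = 1e-12)
  expect_equal(unname(got["match"]), cmbf(5), tolerance = 1e-12)
  expect_identical(unname(got["anti"]), 0.5)   # anti-motifs clipped, floored
  expect_identical(unname(got["blank"]), 0.5)
  # identical IC maximizes the score among these kinases
  expect_identical(names(which.max(oracle)), "match")
  # all-zero cluster IC floors everything
  z <- motif_match_likelihood(kin, mk_ic(c()), positions = 1)
  expect_true(all(z == 0.5))
  expect_error(motif_match_likelihood(kin, cluster, positions = integer()),
               "non-empty")
})

test_that("missing scores are interpolated from kinome-tree neighbors", {
  nb <- c(K3 = "K2", K2 = "K1", K1 = "K3")
  expect_identical(
    interpolate_missing(c(K1 = 0.8, K2 = 0.2, K3 = NA), nb)[["K3"]], 0.2)
  v <- c(K1 = 1, K2 = 2, K3 = 3)
  expect_identical(interpolate_missing(v, nb), v)
  # chain K3 -> K2 (missing) -> K1
  expect_identical(
    interpolate_missing(c(K1 = 0.6, K2 = NA, K3 = NA), nb)[["K3"]], 0.6)
  # full cycle of missing values resolves to 0
  expect_identical(unname(interpolate_missing(c(K1 = NA, K2 = NA, K3 = NA), nb)),
                   c(0, 0, 0))
  expect_warning(
    out <- interpolate_missing(c(K1 = 1, KX = NA), nb), "neighbor map")
  expect_identical(out[["KX"]], 0)
})

test_that("the Poisson pivot is the sample mean of the scores", {
  expect_identical(estimate_poisson_pivot(c(1, 2, 3))$value, 2)
  expect_identical(estimate_poisson_pivot(rep(4.2, 10))$rate_lambda, 4.2)
  set.seed(8)
  draws <- stats::rpois(1000, 4)
  expect_lt(abs(estimate_poisson_pivot(draws)$value - 4), 3 * sqrt(4 / 1000))
  expect_error(estimate_poisson_pivot(c(0, 0)), "all-zero")
  expect_error(estimate_poisson_pivot(c(-1, 2)), "non-negative")
})

test_that("the engine is order-invariant and never eliminates a kinase", {
  set.seed(55)
  syms <- paste0("k", 1:5)
  for (i in 1:20) {
    L <- matrix(runif(7 * 5, 0.1, 1), nrow = 7, dimnames = list(NULL, syms))
    u <- uniform_prior(syms)
    p1 <- Reduce(bayes_update, lapply(1:7, function(s) L[s, ]), accumulate = FALSE,
                 init = u)
    perm <- sample(7)
    p2 <- Reduce(bayes_update, lapply(perm, function(s) L[s, ]), init = u)
    expect_equal(p1, p2, tolerance = 1e-12)
    expect_true(all(p1 > 0))
    expect_equal(sum(p1), 1, tolerance = 1e-9)
  }
  # a kinase with zero raw evidence (all likelihoods floored to 0.5)
  # retains exactly the all-0.5 path's posterior
  Lf <- rbind(c(k1 = 0.9, k2 = 0.5), c(k1 = 0.9, k2 = 0.5))
  post <- Reduce(bayes_update, lapply(1:2, function(s) Lf[s, ]),
                 init = uniform_prior(c("k1", "k2")))
  expect_equal(post[["k2"]], 0.5 * 0.25 / (0.5 * 0.81 + 0.5 * 0.25),
               tolerance = 1e-12)
  expect_gt(post[["k2"]], 0)
})

test_that("raising one likelihood never lowers that kinase's rank", {
  set.seed(66)
  syms <- paste0("k", 1:6)
  L <- matrix(runif(7 * 6, 0.4, 1), nrow = 7, dimnames = list(NULL, syms))
  base <- Reduce(bayes_update, lapply(1:7, function(s) L[s, ]),
                 init = uniform_prior(syms))
  rank_of <- function(post, k) match(k, names(sort(post, decreasing = TRUE)))
  for (k in syms) {
    L2 <- L
    L2[3, k] <- min(1, L2[3, k] + 0.3)
    up <- Reduce(bayes_update, lapply(1:7, function(s) L2[s, ]),
                 init = uniform_prior(syms))
    expect_lte(rank_of(up, k), rank_of(base, k))
  }
})
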