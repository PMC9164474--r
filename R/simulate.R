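# Seeded synthetic-data generator. Produces a phosphosite table, a complete
# evidence bundle, and a ground-truth table with the statistical structure
# the analysis assumes, so every pipeline stage is testable offline.
#
# Noise model: the across-site SD of the per-time mean log2 ratio equals the
# configured SD_t. The variance is partitioned into a persistent per-site
# offset ~ N(0, sqrt(2/3) * SD_t) (site-to-site biological/technical
# variability of the ratio) plus replicate noise ~ N(0, SD_t); the mean of 3
# replicates then has across-site SD exactly SD_t.

#' Temporal response shapes
#'
#' Target mean log2 ratios at 1, 2, 5, 15 min, on a unit scale (multiplied by
#' the planted effect size). Shapes are chosen to satisfy the
#' [pattern_class()] and [half_max_time()] definitions exactly:
#' `fast_up` reaches half-maximum by 1 min, `slow_up` not until 5 min,
#' `monotonic_down` decreases through 5 min, `dip_rise_2` recovers after
#' 1 min, `dip_rise_5` after 2 min, and `rise_dip_rise` shows the
#' up-down-up pattern.
#'
#' @return Named list of length-4 numeric vectors.
#' @export
temporal_shapes <- function() {
  list(
    fast_up        = c(0.80, 0.90, 0.95, 1.00),
    slow_up        = c(0.20, 0.40, 0.80, 1.00),
    monotonic_down = c(-0.40, -0.70, -0.90, -1.00),
    dip_rise_2     = c(-1.00, -0.50, 0.20, 0.60),
    dip_rise_5     = c(-0.80, -1.00, -0.30, 0.20),
    rise_dip_rise  = c(0.60, 0.30, 0.80, 1.00)
  )
}

#' Default planted kinase -> cluster map
#'
#' Five planted kinases spanning the four top-level groups and five distinct
#' leaf clusters; their motif constraints place every planted window
#' deterministically in the intended group, and their temporal shapes place
#' surviving sites in the intended leaf.
#'
#' @return `data.frame` with columns `kinase`, `family`, `group`, `shape`,
#'   `leaf`.
#' @export
default_planted_map <- function() {
  data.frame(
    kinase = sprintf("KIN%02d", 1:5),
    family = c("CMGC", "AGC", "CAMK", "AGC", "STE"),
    group = c("I", "II.A", "II.B", "III", "IV"),
    shape = c("fast_up", "fast_up", "slow_up", "dip_rise_2", "monotonic_down"),
    leaf = c("I.B", "II.A.1.b", "II.B.2", "III.A", "IV.B"),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' @param seed Integer seed expanded internally into per-component streams.
#' @param n_sites Total quantified phosphosites (default 500).
#' @param n_regulated Planted regulated sites, split evenly over the planted
#'   kinases (default 40).
#' @param sds Per-time-point across-site SDs of the mean log2 ratio
#'   (default 0.104, 0.104, 0.128, 0.148).
#' @param n_kinases Registry size (default 20).
#' @param effect Planted effect size in log2 units scaling the temporal
#'   shapes (default 0.4).
#' @param planted Planted map (see [default_planted_map()]).
#' @param substrates_per_kinase Substrate records generated per kinase
#'   (default 200).
#' @param n_fractions Subcellular fractions in the profiles (default 6).
#' @param dropout Probability that a non-planted kinase is missing from an
#'   expression table (default 0.1).
#' @param sty_background S/T/Y probabilities for background phosphoacceptors
#'   (default 0.8, 0.15, 0.05, the typical phosphoproteome skew).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_sites = 500L, n_regulated = 40L,
                       sds = c(0.104, 0.104, 0.128, 0.148),
                       n_kinases = 20L, effect = 0.4,
                       planted = default_planted_map(),
                       substrates_per_kinase = 200L, n_fractions = 6L,
                       dropout = 0.1,
                       sty_background = c(S = 0.8, T = 0.15, Y = 0.05)) {
  stopifnot(n_regulated <= n_sites, all(sds > 0), n_kinases >= nrow(planted))
  cfg <- structure(list(
    seed = as.integer(seed), n_sites = as.integer(n_sites),
    n_regulated = as.integer(n_regulated), sds = sds,
    n_kinases = as.integer(n_kinases), effect = effect, planted = planted,
    substrates_per_kinase = as.integer(substrates_per_kinase),
    n_fractions = as.integer(n_fractions), dropout = dropout,
    sty_background = sty_background
  ), class = "sim_config")
  if (effect <= 2 * max(sds)) {
    warning(sprintf(
      "planted effect %.3g is at or below the expected confidence half-width %.3g; planted sites may be undetectable",
      effect, 2 * max(sds)), call. = FALSE)
  }
  cfg
}

PSI <- c("R", "K", "H")
DELTA <- c("S", "T", "Y")

# Draw one 13-mer flank + center honouring hard group constraints, so the
# first-level partition of planted windows is deterministic.
draw_window <- function(group, center_probs) {
  res <- sample(AA_STANDARD, 12L, replace = TRUE)
  # positions -6..-1 are res[1:6], +1..+6 are res[7:12]
  set_pos <- function(p, allowed) {
    i <- if (p < 0) p + 7L else p + 6L
    res[i] <<- if (length(allowed) == 1L) allowed else sample(allowed, 1L)
  }
  not_pos <- function(p, banned) {
    i <- if (p < 0) p + 7L else p + 6L
    if (res[i] %in% banned) {
      res[i] <<- sample(setdiff(AA_STANDARD, banned), 1L)
    }
  }
  if (group == "I") {
    set_pos(+1L, "P")
  } else if (group != "background") {
    not_pos(+1L, "P")
    if (group == "II.A") {
      set_pos(-3L, PSI); set_pos(-2L, PSI)
      if (stats::runif(1L) < 0.75) set_pos(-1L, "G")  # II.A.1.b flavour
    } else if (group == "II.B") {
      set_pos(-3L, PSI); not_pos(-2L, PSI)
    } else if (group == "III") {
      not_pos(-3L, c(PSI, DELTA)); set_pos(-2L, DELTA)
    } else if (group == "IV") {
      not_pos(-3L, c(PSI, DELTA)); not_pos(-2L, DELTA)
    }
  }
  center <- sample(names(center_probs), 1L, prob = center_probs)
  paste0(paste(res[1:6], collapse = ""), center, paste(res[7:12], collapse = ""))
}

random_profile <- function(n, concentration = 0.5) {
  x <- stats::rgamma(n, shape = concentration)
  if (sum(x) == 0) x <- rep(1, n)
  x / sum(x)
}

make_registry <- function(config) {
  symbols <- sprintf("KIN%02d", seq_len(config$n_kinases))
  fams <- c("AGC", "CAMK", "CMGC", "STE", "CK1", "TKL", "TK", "Other")
  family <- sample(fams, config$n_kinases, replace = TRUE)
  planted <- config$planted
  family[match(planted$kinase, symbols)] <- planted$family
  nb <- stats::setNames(symbols[c(seq_len(config$n_kinases)[-1L], 1L)], symbols)
  list(kinases = data.frame(symbol = symbols, family = family,
                            stringsAsFactors = FALSE),
       neighbor_map = nb)
}

simulate_sites <- function(config, null = FALSE) {
  shapes <- temporal_shapes()
  n <- config$n_sites
  planted <- config$planted
  n_reg <- if (null) 0L else config$n_regulated
  site_kinase <- rep(NA_character_, n)
  if (n_reg > 0L) {
    site_kinase[seq_len(n_reg)] <- rep_len(planted$kinase, n_reg)
  }
  planted_sty <- c(S = 0.85, T = 0.10, Y = 0.05)
  windows <- character(n)
  for (i in seq_len(n)) {
    if (is.na(site_kinase[i])) {
      windows[i] <- draw_window("background", config$sty_background)
    } else {
      grp <- planted$group[planted$kinase == site_kinase[i]]
      windows[i] <- draw_window(grp, planted_sty)
    }
  }
  tau <- config$sds * sqrt(2 / 3)
  reps <- array(0, dim = c(n, N_REPLICATES, length(TIMEPOINTS)))
  for (t in seq_along(TIMEPOINTS)) {
    mu <- rep(0, n)
    if (n_reg > 0L) {
      for (k in seq_len(nrow(planted))) {
        idx <- which(site_kinase == planted$kinase[k])
        mu[idx] <- shapes[[planted$shape[k]]][t] * config$effect
      }
    }
    offset <- stats::rnorm(n, 0, tau[t])
    reps[, , t] <- matrix(stats::rnorm(n * N_REPLICATES, 0, config$sds[t]),
                          n, N_REPLICATES) + mu + offset
  }
  sites <- data.frame(
    site_id = sprintf("site%04d", seq_len(n)),
    gene_symbol = sprintf("GENE%04d", seq_len(n)),
    residue = vapply(windows, window_residue, character(1L), pos = 0L,
                     USE.NAMES = FALSE),
    position = sample(10:800, n, replace = TRUE),
    window = windows,
    stringsAsFactors = FALSE
  )
  for (t in seq_along(TIMEPOINTS)) {
    sites[[ratio_cols()[t]]] <- rowMeans(reps[, , t])
  }
  for (t in seq_along(TIMEPOINTS)) {
    for (r in seq_len(N_REPLICATES)) {
      sites[[paste0("rep", r, "_", TIMEPOINTS[t])]] <- reps[, r, t]
    }
  }
  truth <- data.frame(
    site_id = sites$site_id,
    kinase = site_kinase,
    group = ifelse(is.na(site_kinase), NA_character_,
                   planted$group[match(site_kinase, planted$kinase)]),
    leaf = ifelse(is.na(site_kinase), NA_character_,
                  planted$leaf[match(site_kinase, planted$kinase)]),
    shape = ifelse(is.na(site_kinase), NA_character_,
                   planted$shape[match(site_kinase, planted$kinase)]),
    stringsAsFactors = FALSE
  )
  list(sites = sites, truth = truth)
}

simulate_bundle <- function(config, sites, truth, registry) {
  planted <- config$planted
  symbols <- registry$kinases$symbol
  is_planted <- symbols %in% planted$kinase

  # expression: planted kinases strongly expressed; others variable with
  # dropout (absent from the table entirely)
  expr_table <- function() {
    vals <- ifelse(is_planted,
                   exp(stats::rnorm(length(symbols), 3, 0.5)),
                   exp(stats::rnorm(length(symbols), 1, 1)))
    drop <- !is_planted & stats::runif(length(symbols)) < config$dropout
    stats::setNames(vals, symbols)[!drop]
  }
  transcript <- expr_table(); protein_a <- expr_table(); protein_b <- expr_table()

  # substrate records: planted kinases emit windows matching their group
  # motif; a quarter of the others are tyrosine-directed; the rest are
  # generic S/T kinases with a random positional preference
  planted_sty <- c(S = 0.85, T = 0.10, Y = 0.05)
  generic_sty <- c(S = 0.70, T = 0.25, Y = 0.05)
  y_sty <- c(S = 0.05, T = 0.05, Y = 0.90)
  y_directed <- !is_planted & (seq_along(symbols) %% 4L == 0L)
  subs <- list()
  for (j in seq_along(symbols)) {
    k <- symbols[j]
    m <- config$substrates_per_kinase
    if (is_planted[j]) {
      grp <- planted$group[planted$kinase == k]
      wins <- replicate(m, draw_window(grp, planted_sty))
    } else {
      sty <- if (y_directed[j]) y_sty else generic_sty
      pref_pos <- sample(setdiff(-6:6, 0L), 1L)
      pref_res <- sample(AA_STANDARD, 1L)
      wins <- replicate(m, {
        w <- draw_window("background", sty)
        if (stats::runif(1L) < 0.6) {
          flank <- 6L
          idx <- pref_pos + flank + 1L
          substr(w, idx, idx) <- pref_res
        }
        w
      })
    }
    loc <- ifelse(stats::runif(m) < 0.7, stats::runif(m, 0.751, 1),
                  stats::runif(m, 0, 0.75))
    subs[[k]] <- data.frame(
      kinase = k, window = wins,
      localization_probability = loc,
      has_site_determining_ions = stats::runif(m) < 0.9,
      stringsAsFactors = FALSE
    )
  }
  substrates <- do.call(rbind, c(subs, make.row.names = FALSE))

  # fractionation: substrate proteins of planted sites share their kinase's
  # profile (plus noise); everything else is random
  frac_names <- paste0("frac", seq_len(config$n_fractions))
  kinase_profiles <- t(vapply(symbols, function(k) random_profile(config$n_fractions),
                              numeric(config$n_fractions)))
  dimnames(kinase_profiles) <- list(symbols, frac_names)
  site_profiles <- t(vapply(sites$gene_symbol,
                            function(g) random_profile(config$n_fractions),
                            numeric(config$n_fractions)))
  dimnames(site_profiles) <- list(sites$gene_symbol, frac_names)
  for (i in which(!is.na(truth$kinase))) {
    base <- kinase_profiles[truth$kinase[i], ]
    noisy <- pmax(base + stats::rnorm(config$n_fractions, 0, 0.05), 0)
    if (sum(noisy) == 0) noisy <- base
    site_profiles[i, ] <- noisy / sum(noisy)
  }

  # activity annotations: planted kinases match their shape's 15-min
  # direction; a scattering of the others carry (possibly wrong) annotations
  shapes <- temporal_shapes()
  activity <- stats::setNames(
    sample(c("increase", "decrease", "regulated_unknown", "none"),
           length(symbols), replace = TRUE, prob = c(0.1, 0.1, 0.1, 0.7)),
    symbols)
  for (k in seq_len(nrow(planted))) {
    end <- shapes[[planted$shape[k]]][length(TIMEPOINTS)]
    activity[planted$kinase[k]] <- if (end > 0) "increase" else "decrease"
  }

  evidence_bundle(
    registry = registry,
    transcript = transcript, protein_a = protein_a, protein_b = protein_b,
    substrates = substrates,
    kinase_profiles = kinase_profiles,
    site_profiles = site_profiles,
    activity = activity,
    pivots = list(transcript = 1, protein_a = 1, protein_b = 1, sty = 1 / 9),
    background_windows = sites$window
  )
}

#' Simulate a complete phosphoproteomic time-course experiment
#'
#' Generates a phosphosite quantification table (means and 3 replicates at 1,
#' 2, 5, 15 min), a full evidence bundle consistent with the planted kinases
#' (high expression, matching phosphoacceptor preference, shared
#' fractionation profiles, correct activity direction, motif-bearing
#' substrate records), and a ground-truth table mapping each site to its
#' planted kinase and intended cluster.
#'
#' @param config A [sim_config()].
#' @return List with `sites`, `bundle`, `truth`, and `registry`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  set.seed(config$seed)
  registry <- make_registry(config)
  st <- simulate_sites(config, null = FALSE)
  bundle <- simulate_bundle(config, st$sites, st$truth, registry)
  list(sites = st$sites, bundle = bundle, truth = st$truth, registry = registry)
}

#' Simulate a null experiment (no planted effects)
#'
#' All sites are unregulated: replicate log2 ratios are pure noise under the
#' configured SDs. Used for calibration of the regulation filter.
#'
#' @param config A [sim_config()].
#' @return Phosphosite `data.frame`.
#' @export
simulate_null_experiment <- function(config = sim_config()) {
  set.seed(config$seed)
  simulate_sites(config, null = TRUE)$sites
}
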