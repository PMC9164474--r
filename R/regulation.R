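# Regulation filter: dual significance criteria. A site is called regulated
# when, at one or more time points, the one-sample t-test of its replicate
# log2 ratios gives p < alpha AND its mean log2 ratio falls outside the
# empirical 95% confidence range [-h, +h], where h = 2 x the largest
# per-time-point across-site SD, rounded to two decimals.

#' Configuration for the dual-criteria regulation filter
#'
#' @param alpha_p Per-time-point p-value threshold (default 0.05).
#' @param ci_multiplier SD multiplier for the confidence half-range. Default 2
#'   (not 1.96): 2 x 0.148 = 0.296 rounds to the reference half-width 0.30.
#' @param use_max_sd Use the largest per-time-point SD for a single global
#'   range (default `TRUE`).
#' @return A list of class `significance_config`.
#' @export
significance_config <- function(alpha_p = 0.05, ci_multiplier = 2,
                                use_max_sd = TRUE) {
  if (alpha_p <= 0 || alpha_p >= 1) stop("`alpha_p` must be in (0, 1)", call. = FALSE)
  if (ci_multiplier <= 0) stop("`ci_multiplier` must be positive", call. = FALSE)
  structure(list(alpha_p = alpha_p, ci_multiplier = ci_multiplier,
                 use_max_sd = use_max_sd), class = "significance_config")
}

ratio_matrix <- function(sites) {
  as.matrix(sites[, ratio_cols(), drop = FALSE])
}

#' Per-time-point standard deviation of mean log2 ratios across sites
#'
#' The empirical noise scale of the experiment: for each time point, the
#' sample SD of the per-site mean log2(treated/vehicle) ratios across all
#' quantified sites.
#'
#' @param sites Phosphosite `data.frame`.
#' @return Named numeric vector, one SD per time point.
#' @export
per_timepoint_sd <- function(sites) {
  if (nrow(sites) < 2L) {
    stop("at least 2 sites are required to estimate per-time-point SDs",
         call. = FALSE)
  }
  stats::setNames(apply(ratio_matrix(sites), 2L, stats::sd),
                  paste0(TIMEPOINTS, "min"))
}

#' Empirical confidence half-width
#'
#' `ci_multiplier` times the largest per-time-point SD, rounded to two
#' decimals; the confidence range is `[-h, +h]`. With the reference SDs
#' (0.104, 0.104, 0.128, 0.148) and multiplier 2 this gives 0.30.
#'
#' @param sds Non-negative numeric vector of per-time-point SDs.
#' @param config A [significance_config()].
#' @return Single numeric half-width.
#' @export
confidence_half_width <- function(sds, config = significance_config()) {
  if (length(sds) == 0L) stop("`sds` must be non-empty", call. = FALSE)
  if (any(sds < 0)) stop("`sds` must be non-negative", call. = FALSE)
  base <- if (isTRUE(config$use_max_sd)) max(sds) else sds
  round(config$ci_multiplier * base, 2L)
}

#' One-sample t-test p-value for replicate log2 ratios at one time point
#'
#' Two-sided test of the mean replicate log2 ratio against 0. Degenerate
#' inputs follow the convention: all replicates exactly 0 gives p = 1; zero
#' variance with nonzero mean gives p = 0 with a warning.
#'
#' @param replicate_ratios Numeric vector of at least 2 replicate log2 ratios.
#' @return P-value in `[0, 1]`.
#' @export
site_p_value <- function(replicate_ratios) {
  replicate_ratios <- replicate_ratios[!is.na(replicate_ratios)]
  n <- length(replicate_ratios)
  if (n < 2L) stop("at least 2 replicates are required", call. = FALSE)
  m <- mean(replicate_ratios)
  s <- stats::sd(replicate_ratios)
  if (s == 0) {
    if (m == 0) return(1)
    warning("zero replicate variance with nonzero mean; returning p = 0",
            call. = FALSE)
    return(0)
  }
  tval <- m / (s / sqrt(n))
  2 * stats::pt(-abs(tval), df = n - 1L)
}

site_p_matrix <- function(sites) {
  out <- sapply(TIMEPOINTS, function(t) {
    reps <- as.matrix(sites[, rep_cols_at(t), drop = FALSE])
    apply(reps, 1L, site_p_value)
  })
  out <- matrix(out, nrow = nrow(sites), ncol = length(TIMEPOINTS))
  colnames(out) <- p_cols()
  out
}

#' Estimated false discovery rate of the dual criteria
#'
#' The product of the two criterion levels: the p-value threshold and the
#' tail mass of the confidence range (0.05 for a 95% range). This treats the
#' two criteria as independent; see the package vignette for why the realised
#' null pass rate exceeds this product.
#'
#' @param alpha_p P-value threshold in (0, 1).
#' @param alpha_range Confidence-range tail mass in (0, 1).
#' @return `alpha_p * alpha_range`.
#' @export
#' @examples
#' fdr_product(0.05, 0.05)  # 0.0025
fdr_product <- function(alpha_p, alpha_range) {
  stopifnot(alpha_p > 0, alpha_p < 1, alpha_range > 0, alpha_range < 1)
  alpha_p * alpha_range
}

#' Apply the dual significance criteria
#'
#' A site is regulated iff at one or more time points BOTH its t-test p-value
#' is below `alpha_p` AND the absolute mean log2 ratio exceeds `half_width`,
#' with both conditions evaluated at the same time point.
#'
#' @param sites Phosphosite `data.frame`.
#' @param half_width Confidence half-width (see [confidence_half_width()]).
#' @param alpha_p P-value threshold.
#' @param p_values Optional precomputed p-value matrix (sites x time points);
#'   computed from the replicate columns when `NULL`.
#' @return Character vector of regulated `site_id`s.
#' @export
dual_criteria_filter <- function(sites, half_width, alpha_p = 0.05,
                                 p_values = NULL) {
  if (nrow(sites) == 0L) return(character())
  if (is.null(p_values)) p_values <- site_p_matrix(sites)
  ratios <- ratio_matrix(sites)
  hit <- (p_values < alpha_p) & (abs(ratios) > half_width)
  sites$site_id[rowSums(hit, na.rm = TRUE) > 0L]
}

#' Identify regulated phosphosites and report the confidence range
#'
#' Runs the full regulation filter: estimates per-time-point SDs across all
#' sites, derives the confidence half-width, computes per-site per-time
#' p-values, applies the dual criteria, and reports the estimated FDR
#' product.
#'
#' @param sites Phosphosite `data.frame` (all quantified sites, not only
#'   candidates: the SDs are estimated from the full table).
#' @param config A [significance_config()].
#' @return An object of class `regulation_report` with elements
#'   `per_time_sd`, `half_width`, `fdr_estimate`, `regulated_ids`,
#'   `p_values`, `n_sites`, and `config`.
#' @export
filter_regulated <- function(sites, config = significance_config()) {
  sds <- per_timepoint_sd(sites)
  hw <- confidence_half_width(sds, config)
  pv <- site_p_matrix(sites)
  ids <- dual_criteria_filter(sites, hw, config$alpha_p, p_values = pv)
  structure(list(
    per_time_sd = sds,
    half_width = hw,
    fdr_estimate = fdr_product(config$alpha_p, 0.05),
    regulated_ids = ids,
    p_values = pv,
    n_sites = nrow(sites),
    config = config
  ), class = "regulation_report")
}

#' @export
print.regulation_report <- function(x, ...) {
  cat("Regulation filter report\n")
  cat(sprintf("  sites tested: %d\n", x$n_sites))
  cat(sprintf("  per-time SDs: %s\n",
              paste(sprintf("%s=%.3f", names(x$per_time_sd), x$per_time_sd),
                    collapse = ", ")))
  cat(sprintf("  confidence range: [%.2f, %.2f] (multiplier %g)\n",
              -x$half_width, x$half_width, x$config$ci_multiplier))
  cat(sprintf("  estimated FDR (product rule): %.4f\n", x$fdr_estimate))
  cat(sprintf("  regulated sites: %d (%.2f%%)\n", length(x$regulated_ids),
              100 * length(x$regulated_ids) / max(1L, x$n_sites)))
  invisible(x)
}
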