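# The sequential Bayesian engine. Evidence scores are converted into
# likelihoods with the complement of the minimum Bayes factor,
#   cMBF(z*) = 1 - exp(-z*^2 / 2),   z* = score / pivot,
# floored at 0.5 so that absent or zero evidence can never eliminate a
# kinase, and combined with Bayes' Rule starting from a uniform prior.

#' Complement of the minimum Bayes factor
#'
#' `1 - exp(-z^2 / 2)`; symmetric in the sign of `z`, 0 at `z = 0`, and
#' approaching 1 for strong evidence.
#'
#' @param z_star Numeric vector of standardized evidence scores
#'   (score / pivot).
#' @return Values in `[0, 1)`.
#' @export
#' @examples
#' cmbf(0)  # 0
#' cmbf(1)  # 1 - exp(-0.5)
cmbf <- function(z_star) {
  if (any(!is.finite(z_star))) stop("`z_star` must be finite", call. = FALSE)
  1 - exp(-z_star^2 / 2)
}

#' Floor a likelihood vector at the coin-flip probability
#'
#' Values below `floor` (default 0.5) are reset to `floor`, so zero evidence
#' (annotation gaps, technical dropouts) cannot wrongly eliminate a kinase.
#'
#' @param values Numeric vector of likelihoods in `[0, 1]`.
#' @param floor Floor value (default 0.5).
#' @return Elementwise `max(values, floor)`.
#' @export
floor_likelihood <- function(values, floor = 0.5) {
  pmax(values, floor)
}

#' One application of Bayes' Rule over the kinase vector
#'
#' @param prior Named numeric vector summing to 1.
#' @param likelihood Named numeric vector in `[0, 1]`, aligned with `prior`.
#' @return Posterior vector summing to 1.
#' @export
bayes_update <- function(prior, likelihood) {
  stopifnot(length(prior) == length(likelihood))
  if (!is.null(names(prior)) && !is.null(names(likelihood))) {
    likelihood <- likelihood[names(prior)]
  }
  num <- prior * likelihood
  z <- sum(num)
  if (z <= 0) stop("all prior x likelihood products are zero; cannot normalize",
                   call. = FALSE)
  num / z
}

#' Uniform prior over a kinase registry
#'
#' @param symbols Character vector of kinase symbols.
#' @return Named vector, each element `1 / length(symbols)`.
#' @export
uniform_prior <- function(symbols) {
  stats::setNames(rep(1 / length(symbols), length(symbols)), symbols)
}

#' Expression-based likelihood (steps 1-3)
#'
#' Translates per-kinase expression values (transcript or protein) into
#' likelihoods: `cmbf(value / pivot)` floored at 0.5. Kinases absent from the
#' table score 0 and are floored to 0.5.
#'
#' @param values Named numeric vector of non-negative expression values.
#' @param pivot Positive noise scale of the dataset.
#' @param symbols Registry kinase symbols (output order).
#' @param floor Likelihood floor.
#' @return Named likelihood vector over `symbols`.
#' @export
expression_likelihood <- function(values, pivot, symbols, floor = 0.5) {
  if (!is.numeric(pivot) || length(pivot) != 1L || pivot <= 0) {
    stop("`pivot` must be a single positive value", call. = FALSE)
  }
  if (any(values < 0)) stop("expression values must be non-negative", call. = FALSE)
  x <- stats::setNames(rep(0, length(symbols)), symbols)
  shared <- intersect(symbols, names(values))
  x[shared] <- values[shared]
  floor_likelihood(cmbf(x / pivot), floor)
}

#' Phosphoacceptor (S/T/Y) preference likelihood (step 4)
#'
#' Scores each kinase by the dot product of its (S, T, Y) frequency triple at
#' the phosphorylated position with the cluster's triple; the default pivot
#' 1/9 keeps serine/threonine kinases high while penalizing tyrosine kinases
#' against S/T clusters.
#'
#' @param kinase_sty Matrix kinases x 3 (columns `S`, `T`, `Y`), rows named
#'   by kinase symbol; each row sums to at most 1.
#' @param cluster_sty Length-3 numeric (S, T, Y frequencies of the cluster).
#' @param pivot Positive pivot (default 1/9).
#' @param floor Likelihood floor.
#' @return Named likelihood vector over the rows of `kinase_sty`.
#' @export
sty_preference_likelihood <- function(kinase_sty, cluster_sty, pivot = 1 / 9,
                                      floor = 0.5) {
  if (any(kinase_sty < 0) || any(cluster_sty < 0)) {
    stop("frequencies must be non-negative", call. = FALSE)
  }
  if (any(rowSums(kinase_sty) > 1 + 1e-9)) {
    stop("each kinase S/T/Y triple must sum to at most 1", call. = FALSE)
  }
  scores <- as.numeric(kinase_sty %*% cluster_sty)
  stats::setNames(floor_likelihood(cmbf(scores / pivot), floor),
                  rownames(kinase_sty))
}

#' Subcellular colocalization likelihood (step 5)
#'
#' Dot product of each kinase's fractionation profile with the cluster's
#' aggregate substrate profile; the pivot defaults to the Poisson-rate
#' estimate (sample mean) of the non-negative scores.
#'
#' @param kinase_profiles Matrix kinases x fractions (rownames = symbols).
#' @param cluster_profile Numeric vector over the same fractions.
#' @param pivot Positive pivot, or `NULL` to estimate via
#'   [estimate_poisson_pivot()] from the scores.
#' @param floor Likelihood floor.
#' @return Named likelihood vector; attribute `pivot` records the value used.
#' @export
colocalization_likelihood <- function(kinase_profiles, cluster_profile,
                                      pivot = NULL, floor = 0.5) {
  if (ncol(kinase_profiles) != length(cluster_profile)) {
    stop("kinase profiles and cluster profile are over different fraction sets",
         call. = FALSE)
  }
  if (any(kinase_profiles < 0) || any(cluster_profile < 0)) {
    stop("fractionation profiles must be non-negative", call. = FALSE)
  }
  scores <- as.numeric(kinase_profiles %*% cluster_profile)
  if (is.null(pivot)) {
    # all-zero scores carry no signal: every likelihood is floored and the
    # pivot is immaterial
    pivot <- if (all(scores == 0)) 1 else estimate_poisson_pivot(scores)$value
  }
  out <- stats::setNames(floor_likelihood(cmbf(scores / pivot), floor),
                         rownames(kinase_profiles))
  attr(out, "pivot") <- pivot
  out
}

#' Activity-direction likelihood (step 6)
#'
#' Discrete likelihood from curated kinase activity annotations: a kinase
#' whose known activity direction matches the cluster's 15-min direction gets
#' 0.9; a non-matching direction gets 0.1; `regulated_unknown` gets 0.7; no
#' annotation gets 0.5. These are explicit assignments and are not floored.
#'
#' @param activity Named character vector over kinase symbols with values
#'   `increase`, `decrease`, `regulated_unknown`, or `none`.
#' @param direction Cluster direction: `"increased"` or `"decreased"`.
#' @param symbols Registry kinase symbols (output order).
#' @return Named likelihood vector over `symbols`.
#' @export
activity_likelihood <- function(activity, direction, symbols) {
  if (!direction %in% c("increased", "decreased")) {
    stop('`direction` must be "increased" or "decreased"', call. = FALSE)
  }
  ann <- stats::setNames(rep("none", length(symbols)), symbols)
  shared <- intersect(symbols, names(activity))
  ann[shared] <- activity[shared]
  match_dir <- if (direction == "increased") "increase" else "decrease"
  mismatch_dir <- if (direction == "increased") "decrease" else "increase"
  out <- rep(0.5, length(symbols))
  out[ann == match_dir] <- 0.9
  out[ann == mismatch_dir] <- 0.1
  out[ann == "regulated_unknown"] <- 0.7
  stats::setNames(out, symbols)
}

#' Position-residue information content
#'
#' `IC(a, i) = P(a, i) * log2(P(a, i) / Pref(a))`. Entries with
#' `P(a, i) = 0` contribute 0 by convention; a background frequency of 0 for
#' a residue observed with positive frequency is an error.
#'
#' @param freqs Matrix positions x residues of observed frequencies.
#' @param background Named numeric vector of background residue frequencies.
#' @return IC matrix (bits), same shape as `freqs`.
#' @export
#' @examples
#' information_content(matrix(1, 1, 1, dimnames = list("0", "S")),
#'                     c(S = 0.25))  # 2 bits
information_content <- function(freqs, background) {
  bg <- background[colnames(freqs)]
  zero_bg <- colSums(freqs > 0) > 0 & (is.na(bg) | bg == 0)
  if (any(zero_bg)) {
    stop(sprintf("background frequency is zero for observed residue(s): %s",
                 paste(colnames(freqs)[zero_bg], collapse = ", ")),
         call. = FALSE)
  }
  ic <- freqs * log2(sweep(freqs, 2L, bg, "/"))
  ic[freqs == 0] <- 0
  ic
}

#' Motif-matching likelihood (step 7)
#'
#' Matches each kinase's substrate-motif information content against the
#' cluster's information content by a dot product over the residues at the
#' selected window positions (the positions that defined the cluster, e.g.
#' +1 for Group I, -3/-2 for Group II.A). Negative elementwise products are
#' clipped at 0 before summing so anti-motifs cannot inflate the likelihood.
#' The pivot defaults to the Poisson-rate estimate of the non-negative
#' scores.
#'
#' @param kinase_ic Named list of IC matrices (positions x residues), one per
#'   kinase; a kinase may be `NULL` (no substrate data), scoring `NA` for
#'   interpolation by the caller.
#' @param cluster_ic Cluster IC matrix over the same layout.
#' @param positions Integer vector of selected signed positions (non-empty).
#' @param pivot Positive pivot or `NULL` (estimate from scores).
#' @param floor Likelihood floor.
#' @param neighbor_map Optional neighbor map for interpolating kinases
#'   without substrate data (see [interpolate_missing()]).
#' @return Named likelihood vector; attributes `pivot` and `scores`.
#' @export
motif_match_likelihood <- function(kinase_ic, cluster_ic, positions,
                                   pivot = NULL, floor = 0.5,
                                   neighbor_map = NULL) {
  if (length(positions) == 0L) {
    stop("`positions` must be non-empty", call. = FALSE)
  }
  rows <- as.character(positions)
  if (!all(rows %in% rownames(cluster_ic))) {
    stop("selected positions outside the window", call. = FALSE)
  }
  scores <- vapply(kinase_ic, function(ic) {
    if (is.null(ic)) return(NA_real_)
    prod <- ic[rows, , drop = FALSE] * cluster_ic[rows, , drop = FALSE]
    sum(pmax(prod, 0))
  }, numeric(1L))
  scores <- interpolate_missing(scores, neighbor_map)
  if (is.null(pivot)) {
    pivot <- if (all(scores == 0)) 1 else estimate_poisson_pivot(scores)$value
  }
  out <- floor_likelihood(cmbf(scores / pivot), floor)
  attr(out, "pivot") <- pivot
  attr(out, "scores") <- scores
  out
}

#' Interpolate missing kinase scores from kinome-tree neighbors
#'
#' Kinases with `NA` scores receive the score of their nearest mapped
#' neighbor; chains of missing neighbors are resolved by walking the map, and
#' cycles (or kinases absent from both the scores and the map) resolve to 0
#' (with a warning for unmapped kinases).
#'
#' @param scores Named numeric vector, `NA` for missing kinases.
#' @param neighbor_map Named character vector kinase -> neighbor symbol.
#' @return Completed score vector (no `NA`s).
#' @export
interpolate_missing <- function(scores, neighbor_map = NULL) {
  miss <- names(scores)[is.na(scores)]
  if (length(miss) == 0L) return(scores)
  if (is.null(neighbor_map)) neighbor_map <- character()
  unmapped <- setdiff(miss, names(neighbor_map))
  if (length(unmapped) > 0L) {
    warning(sprintf("kinase(s) absent from neighbor map assigned score 0: %s",
                    paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  for (k in miss) {
    cur <- k
    seen <- character()
    val <- 0
    repeat {
      if (cur %in% seen || !cur %in% names(neighbor_map)) break  # cycle/dead end
      seen <- c(seen, cur)
      cur <- neighbor_map[[cur]]
      if (!is.na(scores[cur])) { val <- scores[[cur]]; break }
    }
    scores[[k]] <- val
  }
  scores
}

#' Poisson-rate pivot estimate
#'
#' The pivot for dot-product evidence layers is the maximum-likelihood rate
#' of an assumed Poisson distribution of the non-negative scores, i.e. their
#' sample mean.
#'
#' @param scores Non-negative numeric vector with at least one positive
#'   value.
#' @return List of class `pivot_estimate`: `method`, `value`, `rate_lambda`.
#' @export
estimate_poisson_pivot <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (any(scores < 0)) stop("scores must be non-negative", call. = FALSE)
  if (length(scores) == 0L || all(scores == 0)) {
    stop("cannot estimate a Poisson rate from all-zero scores", call. = FALSE)
  }
  lambda <- mean(scores)
  structure(list(method = "poisson_rate", value = lambda,
                 rate_lambda = lambda), class = "pivot_estimate")
}
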