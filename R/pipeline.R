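# Orchestration of the seven-step Bayesian ranking over the clusters
# produced by the regulation filter and the motif/time-course clustering.
#
# Step order (each a Bayes' Rule update of the kinase probability vector):
#   1-3  expression (transcript + two protein datasets)
#   4    phosphoacceptor (S/T/Y) preference
#   5    subcellular colocalization
#   6    curated activity direction (discrete 0.9 / 0.1 / 0.7 / 0.5)
#   7    substrate-motif information-content match
# Updates are multiplicative, so the final posterior is order-invariant.

# --- evidence derived from the bundle --------------------------------------

bundle_kinase_windows <- function(bundle) {
  split(bundle$substrates$window, bundle$substrates$kinase)
}

# Per-kinase (S, T, Y) frequency triples at the phosphorylated position,
# interpolated to registry kinases without substrate data via the neighbor
# map.
kinase_sty_matrix <- function(bundle) {
  symbols <- bundle$registry$kinases$symbol
  wins <- bundle_kinase_windows(bundle)
  m <- matrix(NA_real_, nrow = length(symbols), ncol = 3L,
              dimnames = list(symbols, c("S", "T", "Y")))
  for (k in intersect(symbols, names(wins))) {
    centers <- vapply(wins[[k]], window_residue, character(1L), pos = 0L)
    m[k, ] <- as.numeric(table(factor(centers, levels = c("S", "T", "Y")))) /
      length(centers)
  }
  for (col in colnames(m)) {
    v <- m[, col]
    m[, col] <- suppressWarnings(
      interpolate_missing(v, bundle$registry$neighbor_map))
  }
  m
}

sty_frequencies <- function(windows) {
  centers <- vapply(windows, window_residue, character(1L), pos = 0L)
  as.numeric(table(factor(centers, levels = c("S", "T", "Y")))) / length(centers)
}

# Kinase fractionation profiles aligned to the registry (zero rows for
# kinases without profile data; zero scores are floored downstream).
aligned_kinase_profiles <- function(bundle) {
  symbols <- bundle$registry$kinases$symbol
  m <- matrix(0, nrow = length(symbols), ncol = ncol(bundle$kinase_profiles),
              dimnames = list(symbols, colnames(bundle$kinase_profiles)))
  shared <- intersect(symbols, rownames(bundle$kinase_profiles))
  m[shared, ] <- bundle$kinase_profiles[shared, , drop = FALSE]
  m
}

cluster_fraction_profile <- function(bundle, genes) {
  shared <- intersect(unique(genes), rownames(bundle$site_profiles))
  if (length(shared) == 0L) {
    return(stats::setNames(rep(0, ncol(bundle$site_profiles)),
                           colnames(bundle$site_profiles)))
  }
  colMeans(bundle$site_profiles[shared, , drop = FALSE])
}

# Per-kinase substrate-motif IC matrices against the pooled substrate
# background; NULL for kinases without substrate data (interpolated at
# scoring time).
kinase_ic_matrices <- function(bundle) {
  symbols <- bundle$registry$kinases$symbol
  wins <- bundle_kinase_windows(bundle)
  pref <- background_residue_freqs(bundle$substrates$window)
  out <- stats::setNames(vector("list", length(symbols)), symbols)
  for (k in intersect(symbols, names(wins))) {
    fm <- frequency_matrix(wins[[k]])
    keep <- pref > 0
    ic <- matrix(0, nrow = nrow(fm$mat), ncol = ncol(fm$mat),
                 dimnames = dimnames(fm$mat))
    ic[, keep] <- information_content(fm$mat[, keep, drop = FALSE], pref[keep])
    out[[k]] <- ic
  }
  out
}

cluster_ic_matrix <- function(windows, background_windows) {
  if (length(background_windows) == 0L) background_windows <- windows
  pref <- background_residue_freqs(background_windows)
  fm <- frequency_matrix(windows)
  keep <- pref > 0
  ic <- matrix(0, nrow = nrow(fm$mat), ncol = ncol(fm$mat),
               dimnames = dimnames(fm$mat))
  ic[, keep] <- information_content(fm$mat[, keep, drop = FALSE], pref[keep])
  # residues absent from the background but present in the cluster carry no
  # usable enrichment signal against that background
  ic
}

#' Default selected motif positions per cluster
#'
#' The step-7 dot product is restricted to the window positions that defined
#' the cluster: +1 for Group I, -3/-2 for II.A, -3 for II.B, -3/-2 for Group
#' III, -2/-1 for Group IV.
#'
#' @param label Cluster leaf label (e.g. `"II.A.1.b"`) or top group.
#' @return Integer vector of signed positions.
#' @export
default_selected_positions <- function(label) {
  if (startsWith(label, "IV")) return(c(-2L, -1L))
  if (startsWith(label, "III")) return(c(-3L, -2L))
  if (startsWith(label, "II.A")) return(c(-3L, -2L))
  if (startsWith(label, "II")) return(-3L)
  if (startsWith(label, "I")) return(1L)
  stop(sprintf("unknown cluster label: %s", label), call. = FALSE)
}

# Majority direction of member sites at 15 min (mean ratio breaks a tie).
cluster_direction <- function(ratios15) {
  n_up <- sum(ratios15 > 0)
  n_down <- sum(ratios15 < 0)
  if (n_up > n_down) "increased"
  else if (n_down > n_up) "decreased"
  else if (mean(ratios15) >= 0) "increased" else "decreased"
}

# --- the seven-step engine --------------------------------------------------

#' Rank the kinase registry for one phosphosite cluster
#'
#' Starts from the uniform prior 1/N over the registry and applies the seven
#' evidence layers in order, flooring each computed likelihood at 0.5
#' (the discrete step-6 assignments are exempt). Returns posteriors and
#' probability ratios (posterior divided by the uniform prior), sorted by
#' descending posterior with ties broken alphabetically.
#'
#' @param windows Member 13-mer windows of the cluster.
#' @param ratios Matrix (members x 4) of mean log2 ratios, or a vector for a
#'   single member.
#' @param genes Member gene symbols (for the colocalization profile).
#' @param bundle An [evidence_bundle()].
#' @param label Cluster label controlling the step-7 position selection
#'   (see [default_selected_positions()]); any leaf or top-group label.
#' @param positions Optional explicit step-7 positions (overrides `label`).
#' @param floor Likelihood floor for the computed (non-discrete) steps.
#' @return `data.frame` with columns `rank`, `kinase`, `family`, `posterior`,
#'   `probability_ratio`; attributes `likelihoods` (7 x N matrix), `pivots`,
#'   and `direction`.
#' @export
rank_cluster_kinases <- function(windows, ratios, genes, bundle, label,
                                 positions = NULL, floor = 0.5) {
  if (is.null(dim(ratios))) ratios <- matrix(ratios, nrow = 1L)
  symbols <- bundle$registry$kinases$symbol
  if (is.null(positions)) positions <- default_selected_positions(label)
  direction <- cluster_direction(ratios[, ncol(ratios)])

  lik <- matrix(NA_real_, nrow = 7L, ncol = length(symbols),
                dimnames = list(paste0("step", 1:7), symbols))
  lik[1L, ] <- expression_likelihood(bundle$transcript,
                                     bundle$pivots$transcript, symbols, floor)
  lik[2L, ] <- expression_likelihood(bundle$protein_a,
                                     bundle$pivots$protein_a, symbols, floor)
  lik[3L, ] <- expression_likelihood(bundle$protein_b,
                                     bundle$pivots$protein_b, symbols, floor)
  lik[4L, ] <- sty_preference_likelihood(kinase_sty_matrix(bundle),
                                         sty_frequencies(windows),
                                         bundle$pivots$sty, floor)
  l5 <- colocalization_likelihood(aligned_kinase_profiles(bundle),
                                  cluster_fraction_profile(bundle, genes),
                                  pivot = bundle$pivots$colocalization, floor = floor)
  lik[5L, ] <- l5
  lik[6L, ] <- activity_likelihood(bundle$activity, direction, symbols)
  l7 <- motif_match_likelihood(kinase_ic_matrices(bundle),
                               cluster_ic_matrix(windows, bundle$background_windows),
                               positions,
                               pivot = bundle$pivots$motif, floor = floor,
                               neighbor_map = bundle$registry$neighbor_map)
  lik[7L, ] <- l7

  post <- uniform_prior(symbols)
  for (s in 1:7) post <- bayes_update(post, lik[s, ])

  n <- length(symbols)
  ord <- order(-post, symbols)
  out <- data.frame(
    rank = seq_len(n),
    kinase = symbols[ord],
    family = bundle$registry$kinases$family[ord],
    posterior = unname(post[ord]),
    probability_ratio = unname(post[ord] * n),
    stringsAsFactors = FALSE
  )
  attr(out, "likelihoods") <- lik
  attr(out, "pivots") <- list(
    transcript = bundle$pivots$transcript,
    protein_a = bundle$pivots$protein_a,
    protein_b = bundle$pivots$protein_b,
    sty = bundle$pivots$sty,
    colocalization = attr(l5, "pivot"),
    motif = attr(l7, "pivot")
  )
  attr(out, "direction") <- direction
  attr(out, "positions") <- positions
  out
}

#' Rank kinases for every leaf cluster
#'
#' Runs [rank_cluster_kinases()] for each assigned leaf cluster with at
#' least `min_cluster_size` members.
#'
#' @param sites Phosphosite `data.frame` (at least the regulated sites).
#' @param clusters A `cluster_table` from [cluster_sites()].
#' @param bundle An [evidence_bundle()].
#' @param min_cluster_size Smallest cluster to rank (default 3).
#' @param floor Likelihood floor.
#' @return Object of class `kinase_ranking`: a long `data.frame` with columns
#'   `cluster`, `rank`, `kinase`, `family`, `posterior`,
#'   `probability_ratio`; attribute `meta` holds per-cluster size,
#'   direction, selected positions, and pivots.
#' @export
rank_kinases <- function(sites, clusters, bundle, min_cluster_size = 3L,
                         floor = 0.5) {
  assigned <- clusters[!clusters$unassigned & !is.na(clusters$leaf), , drop = FALSE]
  leaves <- sort(unique(assigned$leaf))
  keep <- leaves[vapply(leaves, function(l) sum(assigned$leaf == l),
                        integer(1L)) >= min_cluster_size]
  out <- list()
  meta <- list()
  for (leaf in keep) {
    ids <- assigned$site_id[assigned$leaf == leaf]
    member <- sites[match(ids, sites$site_id), , drop = FALSE]
    r <- rank_cluster_kinases(member$window, ratio_matrix(member),
                              member$gene_symbol, bundle, label = leaf,
                              floor = floor)
    out[[leaf]] <- cbind(data.frame(cluster = leaf, stringsAsFactors = FALSE), r)
    meta[[leaf]] <- list(n_members = length(ids),
                         direction = attr(r, "direction"),
                         positions = attr(r, "positions"),
                         pivots = attr(r, "pivots"))
  }
  res <- if (length(out) > 0L) do.call(rbind, c(out, make.row.names = FALSE)) else {
    data.frame(cluster = character(), rank = integer(), kinase = character(),
               family = character(), posterior = numeric(),
               probability_ratio = numeric(), stringsAsFactors = FALSE)
  }
  structure(res, meta = meta, class = c("kinase_ranking", class(res)))
}

#' @export
print.kinase_ranking <- function(x, top = 5L, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("Kinase ranking over %d cluster(s)\n", length(meta)))
  for (leaf in names(meta)) {
    m <- meta[[leaf]]
    cat(sprintf("  %s (n=%d, %s): ", leaf, m$n_members, m$direction))
    sub <- x[x$cluster == leaf, , drop = FALSE]
    sub <- sub[seq_len(min(top, nrow(sub))), , drop = FALSE]
    cat(paste(sprintf("%s (%.1f)", sub$kinase, sub$probability_ratio),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.kinase_ranking <- function(object, ...) {
  meta <- attr(object, "meta")
  data.frame(
    cluster = names(meta),
    n_members = vapply(meta, `[[`, numeric(1L), "n_members"),
    direction = vapply(meta, `[[`, character(1L), "direction"),
    top_kinase = vapply(names(meta), function(l) {
      object$kinase[object$cluster == l][1L]
    }, character(1L)),
    top_ratio = vapply(names(meta), function(l) {
      object$probability_ratio[object$cluster == l][1L]
    }, numeric(1L)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
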