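# Hierarchical motif / time-course clustering of regulated phosphosites.
#
# First level: positional sequence rules with strict precedence
#   P at +1            -> Group I   (proline-directed)
#   else Psi at -3     -> Group II  (basophilic)
#   else Delta at -3/-2-> Group III
#   else               -> Group IV
# Leaves: direction at 15 min, response speed (time to half-maximum), and
# time-course shape split each group into the named subclusters.

#' First-level partition of windows into Groups I-IV
#'
#' Precedence order: proline at +1 gives Group I; otherwise a basic residue
#' (R/K/H) at -3 gives Group II; otherwise S/T/Y at -3 and/or -2 gives Group
#' III; everything else is Group IV. Total: every valid window maps to
#' exactly one group.
#'
#' @param windows Character vector of 13-mer windows.
#' @return Factor with levels `I`, `II`, `III`, `IV`.
#' @export
#' @examples
#' first_level_partition(c("AAAAAASPAAAAA", "AAARAASAAAAAA",
#'                         "AAASAATAAAAAA", "AAAAAGSAAAAAA"))
first_level_partition <- function(windows) {
  bad <- !is_valid_window(windows)
  if (any(bad)) {
    stop(sprintf("malformed window(s): %s",
                 paste(windows[bad], collapse = ", ")), call. = FALSE)
  }
  psi <- RESIDUE_CLASSES$Psi
  delta <- RESIDUE_CLASSES$Delta
  grp <- vapply(windows, function(w) {
    if (window_residue(w, +1L) == "P") return("I")
    if (window_residue(w, -3L) %in% psi) return("II")
    if (window_residue(w, -3L) %in% delta ||
        window_residue(w, -2L) %in% delta) return("III")
    "IV"
  }, character(1L), USE.NAMES = FALSE)
  factor(grp, levels = c("I", "II", "III", "IV"))
}

#' Direction of the response at 15 minutes
#'
#' @param ratios Numeric vector of mean log2 ratios at 1, 2, 5, 15 min.
#' @return `"increased"` or `"decreased"`. An exact 0 at 15 min is a tie and
#'   raises an error (callers exclude such sites from direction-based
#'   subclustering).
#' @export
direction_at_15 <- function(ratios) {
  x <- ratios[length(TIMEPOINTS)]
  if (is.na(x) || x == 0) {
    stop("tie: 15-min log2 ratio is exactly zero (or missing)", call. = FALSE)
  }
  if (x > 0) "increased" else "decreased"
}

#' Time to half-maximal response and speed class
#'
#' The first time point at which the absolute log2 ratio reaches half of the
#' maximum absolute log2 ratio over the course. Speed class: `fast` if within
#' 1 min, `slow` if not until 5 or 15 min, otherwise `intermediate`.
#'
#' @param ratios Numeric vector of mean log2 ratios at 1, 2, 5, 15 min.
#' @return List with `time` (minutes) and `speed`.
#' @export
half_max_time <- function(ratios) {
  peak <- max(abs(ratios))
  if (peak == 0) stop("all-zero time course: speed undefined", call. = FALSE)
  t <- TIMEPOINTS[which(abs(ratios) >= peak / 2)[1L]]
  speed <- if (t <= 1L) "fast" else if (t >= 5L) "slow" else "intermediate"
  list(time = t, speed = speed)
}

#' Shape class of a time course
#'
#' Classifies the sign pattern of successive differences (baseline 0 at t=0):
#' `d1 = x(1) - 0`, `d2 = x(2) - x(1)`, `d3 = x(5) - x(2)`,
#' `d4 = x(15) - x(5)`.
#' \itemize{
#'   \item `monotonic`: d1, d2, d3 all <= 0 (monotonic decrease through 5 min)
#'   \item `dip_then_rise_at_5`: d1 < 0, d2 <= 0, d3 > 0
#'   \item `dip_then_rise_by_2`: d1 < 0, d2 > 0
#'   \item `rise_dip_rise`: d1 > 0, d2 < 0, d3 > 0
#'   \item `other`: anything else
#' }
#'
#' @param ratios Numeric vector of mean log2 ratios at 1, 2, 5, 15 min.
#' @return Single string naming the class.
#' @export
pattern_class <- function(ratios) {
  d1 <- ratios[1L]
  d2 <- ratios[2L] - ratios[1L]
  d3 <- ratios[3L] - ratios[2L]
  if (d1 <= 0 && d2 <= 0 && d3 <= 0) return("monotonic")
  if (d1 < 0 && d2 <= 0 && d3 > 0) return("dip_then_rise_at_5")
  if (d1 < 0 && d2 > 0) return("dip_then_rise_by_2")
  if (d1 > 0 && d2 < 0 && d3 > 0) return("rise_dip_rise")
  "other"
}

has_psi <- function(window, pos) {
  window_residue(window, pos) %in% RESIDUE_CLASSES$Psi
}

#' Assign a regulated phosphosite to its leaf subcluster
#'
#' Deterministic decision tree over the window and time course. Group I
#' splits by direction (decreased I.A / increased I.B); I.A splits off sites
#' with basic residues at both +5 and +6 (I.A.1), the rest by shape class
#' (monotonic a / dip-then-rise-at-5 b / dip-then-rise-by-2 c). Group II
#' splits by a basic residue at -2 (II.A) or not (II.B); increased II.A sites
#' split by speed (slow a / fast b); II.B splits by direction (increased
#' II.B.2, decreased II.B.1, the latter by shape: rise-dip-rise a /
#' dip-then-rise-by-2 b). Group III splits by direction (increased III.A),
#' decreased sites by a basic residue at -1 (III.B.2) or not (III.B.1).
#' Group IV splits by direction only (IV.A / IV.B). Sites the rules cannot
#' cleanly place (including 15-min ties) get `unassigned = TRUE`.
#'
#' @param window 13-mer window string.
#' @param ratios Mean log2 ratios at 1, 2, 5, 15 min.
#' @param top_group Optional precomputed first-level group.
#' @return List with `top_group`, `leaf` (`NA` when unassigned),
#'   `unassigned`, and `trail` (character vector of "rule=outcome" steps).
#' @export
assign_leaf <- function(window, ratios, top_group = NULL) {
  if (is.null(top_group)) {
    top_group <- as.character(first_level_partition(window))
  }
  top_group <- as.character(top_group)
  trail <- sprintf("first_level=%s", top_group)
  dir <- tryCatch(direction_at_15(ratios), error = function(e) NA_character_)
  trail <- c(trail, sprintf("direction_15min=%s",
                            if (is.na(dir)) "tie" else dir))
  done <- function(leaf, unassigned = FALSE) {
    list(top_group = top_group, leaf = leaf, unassigned = unassigned,
         trail = trail)
  }
  if (is.na(dir)) return(done(NA_character_, unassigned = TRUE))

  if (top_group == "I") {
    if (dir == "increased") return(done("I.B"))
    if (has_psi(window, 5L) && has_psi(window, 6L)) {
      trail <- c(trail, "psi_at_+5_+6=yes")
      return(done("I.A.1"))
    }
    trail <- c(trail, "psi_at_+5_+6=no")
    pc <- pattern_class(ratios)
    trail <- c(trail, sprintf("pattern=%s", pc))
    leaf <- switch(pc,
                   monotonic = "I.A.2.a",
                   dip_then_rise_at_5 = "I.A.2.b",
                   dip_then_rise_by_2 = "I.A.2.c",
                   NA_character_)
    return(done(leaf, unassigned = is.na(leaf)))
  }

  if (top_group == "II") {
    if (has_psi(window, -2L)) {
      trail <- c(trail, "psi_at_-2=yes")
      if (dir == "decreased") return(done(NA_character_, unassigned = TRUE))
      sp <- half_max_time(ratios)$speed
      trail <- c(trail, sprintf("speed=%s", sp))
      leaf <- switch(sp, slow = "II.A.1.a", fast = "II.A.1.b", NA_character_)
      return(done(leaf, unassigned = is.na(leaf)))
    }
    trail <- c(trail, "psi_at_-2=no")
    if (dir == "increased") return(done("II.B.2"))
    pc <- pattern_class(ratios)
    trail <- c(trail, sprintf("pattern=%s", pc))
    leaf <- switch(pc,
                   rise_dip_rise = "II.B.1.a",
                   dip_then_rise_by_2 = "II.B.1.b",
                   dip_then_rise_at_5 = "II.B.1.b",
                   NA_character_)
    return(done(leaf, unassigned = is.na(leaf)))
  }

  if (top_group == "III") {
    if (dir == "increased") return(done("III.A"))
    if (has_psi(window, -1L)) {
      trail <- c(trail, "psi_at_-1=yes")
      return(done("III.B.2"))
    }
    trail <- c(trail, "psi_at_-1=no")
    return(done("III.B.1"))
  }

  done(if (dir == "increased") "IV.A" else "IV.B")
}

#' Cluster a table of regulated phosphosites
#'
#' Applies [first_level_partition()] and [assign_leaf()] to every site.
#' Assignment is deterministic and order-independent.
#'
#' @param sites Phosphosite `data.frame`.
#' @param regulated_ids Optional character vector restricting clustering to a
#'   subset of `site_id`s (typically the output of [filter_regulated()]).
#' @return A `data.frame` of class `cluster_table` with columns `site_id`,
#'   `top_group`, `leaf`, `unassigned`, `trail`.
#' @export
cluster_sites <- function(sites, regulated_ids = NULL) {
  if (!is.null(regulated_ids)) {
    sites <- sites[sites$site_id %in% regulated_ids, , drop = FALSE]
  }
  ratios <- ratio_matrix(sites)
  top <- if (nrow(sites) > 0L) {
    as.character(first_level_partition(sites$window))
  } else character()
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    a <- assign_leaf(sites$window[i], ratios[i, ], top_group = top[i])
    data.frame(site_id = sites$site_id[i],
               top_group = a$top_group,
               leaf = if (is.na(a$leaf)) NA_character_ else a$leaf,
               unassigned = a$unassigned,
               trail = paste(a$trail, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else {
    data.frame(site_id = character(), top_group = character(),
               leaf = character(), unassigned = logical(),
               trail = character(), stringsAsFactors = FALSE)
  }
  class(out) <- c("cluster_table", class(out))
  out
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("Cluster assignments for %d regulated sites\n", nrow(x)))
  if (nrow(x) > 0L) {
    tg <- table(factor(x$top_group, levels = c("I", "II", "III", "IV")))
    cat(sprintf("  top groups: I=%d II=%d III=%d IV=%d\n",
                tg[["I"]], tg[["II"]], tg[["III"]], tg[["IV"]]))
    assigned <- x[!x$unassigned, , drop = FALSE]
    if (nrow(assigned) > 0L) {
      lf <- sort(table(assigned$leaf), decreasing = TRUE)
      cat("  leaves:", paste(sprintf("%s=%d", names(lf), lf), collapse = " "), "\n")
    }
    cat(sprintf("  unassigned: %d\n", sum(x$unassigned)))
  }
  invisible(x)
}

#' Position-by-residue frequency matrix for a set of windows
#'
#' Per-position relative frequencies over observed standard residues; `"J"`
#' padding is excluded from the denominators so terminal-padded windows do
#' not dilute the frequencies. An optional background window set yields the
#' overall background residue frequencies used for information-content
#' scoring.
#'
#' @param windows Character vector of equal-width windows (at least one).
#' @param background_windows Optional reference window set.
#' @return Object of class `frequency_matrix`: list with `mat` (positions x
#'   20 residues, rownames `-6 ... 6`), `n` (window count), and `background`
#'   (named residue frequency vector, or `NULL`).
#' @export
frequency_matrix <- function(windows, background_windows = NULL) {
  if (length(windows) == 0L) stop("at least one window is required", call. = FALSE)
  width <- nchar(windows[1L])
  if (any(nchar(windows) != width)) {
    stop("all windows must have the same width", call. = FALSE)
  }
  flank <- (width - 1L) %/% 2L
  chars <- do.call(rbind, strsplit(windows, ""))
  mat <- matrix(0, nrow = width, ncol = length(AA_STANDARD),
                dimnames = list(as.character(-flank:flank), AA_STANDARD))
  for (i in seq_len(width)) {
    col <- chars[, i]
    col <- col[col != PAD_CHAR]
    if (length(col) > 0L) {
      tab <- table(factor(col, levels = AA_STANDARD))
      mat[i, ] <- as.numeric(tab) / length(col)
    }
  }
  bg <- NULL
  if (!is.null(background_windows) && length(background_windows) > 0L) {
    bg <- background_residue_freqs(background_windows)
  }
  structure(list(mat = mat, n = length(windows), background = bg),
            class = "frequency_matrix")
}

# Overall residue frequencies (all non-pad positions pooled).
background_residue_freqs <- function(windows) {
  ch <- unlist(strsplit(windows, ""))
  ch <- ch[ch != PAD_CHAR]
  tab <- table(factor(ch, levels = AA_STANDARD))
  as.numeric(tab) / sum(tab) -> f
  stats::setNames(f, AA_STANDARD)
}

#' Collapse a frequency matrix to residue-class frequencies
#'
#' @param fm A [frequency_matrix()].
#' @return Matrix positions x classes (`Phi`, `Delta`, `Theta`, `Psi`,
#'   `Sigma`, `P`, `G`).
#' @export
class_frequencies <- function(fm) {
  stopifnot(inherits(fm, "frequency_matrix"))
  sapply(RESIDUE_CLASSES, function(res) {
    rowSums(fm$mat[, res, drop = FALSE])
  })
}

#' 2x2 chi-square enrichment test for a motif feature
#'
#' Compares the incidence of a feature (e.g. glycine at -4) in a cluster
#' against a reference set, without continuity correction by default (a
#' Yates-corrected variant is selectable).
#'
#' @param k_cluster,n_cluster Feature count and total in the cluster.
#' @param k_background,n_background Feature count and total in the reference.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return List with `statistic`, `p_value`, `df`, and `low_expected`
#'   (`TRUE` when any expected cell is below 1, flagging an unreliable
#'   approximation).
#' @export
enrichment_chisq <- function(k_cluster, n_cluster, k_background, n_background,
                             correct = FALSE) {
  stopifnot(k_cluster <= n_cluster, k_background <= n_background,
            n_cluster > 0, n_background > 0)
  obs <- matrix(c(k_cluster, n_cluster - k_cluster,
                  k_background, n_background - k_background),
                nrow = 2L, byrow = TRUE)
  rowtot <- rowSums(obs)
  coltot <- colSums(obs)
  expected <- outer(rowtot, coltot) / sum(obs)
  if (any(coltot == 0)) {
    return(list(statistic = 0, p_value = 1, df = 1L, low_expected = TRUE))
  }
  dev <- abs(obs - expected)
  if (correct) dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / expected)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       df = 1L,
       low_expected = any(expected < 1))
}
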