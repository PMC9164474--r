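# Table readers/writers for all pipeline inputs and outputs. Everything is
# plain UTF-8 TSV with a header row; the kinase registry and neighbor map are
# JSON (or YAML). Numeric columns are written with full precision so that
# read(write(x)) round-trips exactly.

PHOSPHOSITE_KEY_COLS <- c("site_id", "gene_symbol", "residue", "position", "window")

phosphosite_cols <- function() c(PHOSPHOSITE_KEY_COLS, ratio_cols(), rep_cols())

write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, required = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing) > 0L) {
      stop(sprintf("table %s is missing required column(s): %s",
                   basename(path), paste(missing, collapse = ", ")),
           call. = FALSE)
    }
  }
  df
}

#' Read a phosphosite quantification table
#'
#' Expects a tab-separated file with columns `site_id`, `gene_symbol`,
#' `residue`, `position`, `window`, mean log2 ratio columns `ratio_1`,
#' `ratio_2`, `ratio_5`, `ratio_15`, and replicate columns `rep<r>_<t>` for
#' three replicates at each time point. Optional per-time p-value columns
#' `p_<t>` are preserved when present.
#'
#' Rows whose window fails validation (malformed window, or central residue
#' not matching the reported phosphoacceptor) are dropped with a warning
#' naming the offending `site_id`s. Duplicate `site_id`s are an error.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of phosphosites, one row per site.
#' @export
read_phosphosite_table <- function(path) {
  df <- read_tsv(path, required = phosphosite_cols())
  if (anyDuplicated(df$site_id)) {
    stop(sprintf("duplicate site_id(s): %s",
                 paste(unique(df$site_id[duplicated(df$site_id)]), collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(df) == 0L) return(df)
  ok <- is_valid_window(df$window) &
    mapply(validate_site_match, df$window, df$residue)
  if (any(!ok)) {
    warning(sprintf("dropping %d site(s) with invalid window or residue mismatch: %s",
                    sum(!ok), paste(df$site_id[!ok], collapse = ", ")),
            call. = FALSE)
    df <- df[ok, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write a phosphosite table
#'
#' @param sites Phosphosite `data.frame` (see [read_phosphosite_table()]).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_phosphosite_table <- function(sites, path) {
  missing <- setdiff(phosphosite_cols(), names(sites))
  if (length(missing) > 0L) {
    stop(sprintf("phosphosite table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  write_tsv(sites, path)
}

#' Filter kinase-substrate records by localization confidence
#'
#' Retains records that have site-determining ions and a localization
#' probability strictly greater than `p_min` (default 0.75), preserving the
#' input order. The operation is idempotent.
#'
#' @param records `data.frame` with columns `kinase`, `window`,
#'   `localization_probability`, `has_site_determining_ions`.
#' @param p_min Localization probability threshold in `[0, 1]`.
#' @return The retained rows of `records`.
#' @export
filter_substrate_records <- function(records, p_min = 0.75) {
  if (!is.numeric(p_min) || length(p_min) != 1L || p_min < 0 || p_min > 1) {
    stop("`p_min` must be a single value in [0, 1]", call. = FALSE)
  }
  keep <- records$has_site_determining_ions &
    records$localization_probability > p_min
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a kinase registry (symbols, families, neighbor map)
#'
#' Accepts JSON or YAML with top-level fields `kinases` (list of objects with
#' `symbol` and `family`) and `neighbors` (map symbol -> nearest-neighbor
#' symbol on the kinome tree). Symbols must be unique, every neighbor must be
#' a registry member, and no kinase may be its own neighbor.
#'
#' @param path Path to a `.json`, `.yml`, or `.yaml` file.
#' @return A list with `kinases` (`data.frame`: `symbol`, `family`) and
#'   `neighbor_map` (named character vector).
#' @export
read_registry <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  kin <- data.frame(
    symbol = vapply(raw$kinases, `[[`, character(1L), "symbol"),
    family = vapply(raw$kinases, `[[`, character(1L), "family"),
    stringsAsFactors = FALSE
  )
  nb <- unlist(raw$neighbors)
  validate_registry(kin, nb)
  list(kinases = kin, neighbor_map = nb)
}

validate_registry <- function(kinases, neighbor_map) {
  if (anyDuplicated(kinases$symbol)) {
    stop("registry kinase symbols must be unique", call. = FALSE)
  }
  if (length(neighbor_map) > 0L) {
    if (!all(names(neighbor_map) %in% kinases$symbol) ||
        !all(neighbor_map %in% kinases$symbol)) {
      stop("every neighbor-map entry must reference registry members", call. = FALSE)
    }
    if (any(names(neighbor_map) == neighbor_map)) {
      stop("no kinase may be its own neighbor", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write a kinase registry to JSON
#'
#' @param registry List as returned by [read_registry()].
#' @param path Output `.json` path.
#' @return The path, invisibly.
#' @export
write_registry <- function(registry, path) {
  validate_registry(registry$kinases, registry$neighbor_map)
  obj <- list(
    kinases = lapply(seq_len(nrow(registry$kinases)), function(i) {
      list(symbol = registry$kinases$symbol[i],
           family = registry$kinases$family[i])
    }),
    neighbors = as.list(registry$neighbor_map)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Assemble the evidence bundle used by the Bayesian engine
#'
#' Bundles the seven per-step evidence inputs: three expression tables
#' (one transcript, two protein), kinase-substrate records (from which
#' phosphoacceptor preference triples and motif matrices are derived),
#' subcellular fractionation profiles for kinases and for substrate proteins,
#' curated activity-direction annotations, the kinase registry with its
#' neighbor map, per-step pivot parameters, and the background window set for
#' information-content scoring.
#'
#' @param registry List with `kinases` (`data.frame`: `symbol`, `family`) and
#'   `neighbor_map` (named character).
#' @param transcript,protein_a,protein_b Named numeric vectors of expression
#'   values keyed by kinase symbol (missing kinases allowed; they score 0 and
#'   are floored downstream).
#' @param substrates Kinase-substrate `data.frame` (see
#'   [filter_substrate_records()]); filtering is applied here.
#' @param kinase_profiles Numeric matrix, kinases x fractions (rownames are
#'   kinase symbols), of subcellular abundance profiles.
#' @param site_profiles Numeric matrix, proteins (gene symbols) x fractions,
#'   for substrate proteins; must share column names with `kinase_profiles`.
#' @param activity Named character vector over kinase symbols with values in
#'   `increase`, `decrease`, `regulated_unknown`, `none`.
#' @param pivots List of pivot parameters: `transcript`, `protein_a`,
#'   `protein_b` (expression noise scales), `sty` (default 1/9);
#'   colocalization and motif pivots are estimated at run time from the score
#'   distribution (Poisson rate) unless supplied as `colocalization` /
#'   `motif`.
#' @param background_windows Character vector of 13-mer windows serving as
#'   the frequency background for cluster information content.
#' @param substrate_p_min Localization-probability cut for substrate records.
#' @return An object of class `evidence_bundle`.
#' @export
evidence_bundle <- function(registry, transcript, protein_a, protein_b,
                            substrates, kinase_profiles, site_profiles,
                            activity, pivots = list(),
                            background_windows = character(),
                            substrate_p_min = 0.75) {
  validate_registry(registry$kinases, registry$neighbor_map)
  if (!identical(colnames(kinase_profiles), colnames(site_profiles))) {
    stop("kinase and substrate fractionation profiles must share the same fraction set",
         call. = FALSE)
  }
  bad <- setdiff(unique(activity), c("increase", "decrease", "regulated_unknown", "none"))
  if (length(bad) > 0L) {
    stop(sprintf("unknown activity annotation(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  defaults <- list(transcript = 1, protein_a = 1, protein_b = 1, sty = 1 / 9)
  pivots <- utils::modifyList(defaults, pivots)
  substrates <- filter_substrate_records(substrates, p_min = substrate_p_min)
  structure(list(
    registry = registry,
    transcript = transcript,
    protein_a = protein_a,
    protein_b = protein_b,
    substrates = substrates,
    kinase_profiles = kinase_profiles,
    site_profiles = site_profiles,
    activity = activity,
    pivots = pivots,
    background_windows = background_windows
  ), class = "evidence_bundle")
}

#' @export
print.evidence_bundle <- function(x, ...) {
  cat("Evidence bundle\n")
  cat(sprintf("  registry: %d kinases, %d neighbor links\n",
              nrow(x$registry$kinases), length(x$registry$neighbor_map)))
  cat(sprintf("  expression: %d transcript, %d + %d protein values\n",
              length(x$transcript), length(x$protein_a), length(x$protein_b)))
  cat(sprintf("  substrate records (filtered): %d\n", nrow(x$substrates)))
  cat(sprintf("  fractionation: %d kinase and %d substrate profiles over %d fractions\n",
              nrow(x$kinase_profiles), nrow(x$site_profiles), ncol(x$kinase_profiles)))
  cat(sprintf("  activity annotations: %d; background windows: %d\n",
              length(x$activity), length(x$background_windows)))
  invisible(x)
}

#' Read the evidence tables from disk into an evidence bundle
#'
#' @param paths Named list of file paths with elements `registry` (JSON/YAML),
#'   `transcript`, `protein_a`, `protein_b` (TSV: `kinase`, `value`),
#'   `substrates` (TSV: `kinase`, `window`, `localization_probability`,
#'   `has_site_determining_ions`), `kinase_profiles`, `site_profiles`
#'   (TSV: `name` + one column per fraction), `activity` (TSV: `kinase`,
#'   `activity`).
#' @param background_windows Character vector of background windows (usually
#'   all windows of the full phosphosite table).
#' @param pivots,substrate_p_min Passed to [evidence_bundle()].
#' @return An `evidence_bundle`.
#' @export
read_evidence_tables <- function(paths, background_windows = character(),
                                 pivots = list(), substrate_p_min = 0.75) {
  need <- c("registry", "transcript", "protein_a", "protein_b", "substrates",
            "kinase_profiles", "site_profiles", "activity")
  missing <- setdiff(need, names(paths))
  if (length(missing) > 0L) {
    stop(sprintf("missing evidence path(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  for (p in unlist(paths[need])) {
    if (!file.exists(p)) stop(sprintf("evidence file not found: %s", p), call. = FALSE)
  }
  expr_vec <- function(path) {
    df <- read_tsv(path, required = c("kinase", "value"))
    stats::setNames(df$value, df$kinase)
  }
  prof_mat <- function(path) {
    df <- read_tsv(path, required = "name")
    m <- as.matrix(df[, setdiff(names(df), "name"), drop = FALSE])
    rownames(m) <- df$name
    m
  }
  subs <- read_tsv(paths$substrates,
                   required = c("kinase", "window", "localization_probability",
                                "has_site_determining_ions"))
  subs$has_site_determining_ions <- as.logical(subs$has_site_determining_ions)
  act <- read_tsv(paths$activity, required = c("kinase", "activity"))
  evidence_bundle(
    registry = read_registry(paths$registry),
    transcript = expr_vec(paths$transcript),
    protein_a = expr_vec(paths$protein_a),
    protein_b = expr_vec(paths$protein_b),
    substrates = subs,
    kinase_profiles = prof_mat(paths$kinase_profiles),
    site_profiles = prof_mat(paths$site_profiles),
    activity = stats::setNames(act$activity, act$kinase),
    pivots = pivots,
    background_windows = background_windows,
    substrate_p_min = substrate_p_min
  )
}

#' Write an evidence bundle to a directory of plain-text tables
#'
#' Inverse of [read_evidence_tables()]; file names are fixed
#' (`registry.json`, `transcript.tsv`, ...). Background windows are written
#' one per line to `background_windows.txt`.
#'
#' @param bundle An `evidence_bundle`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_evidence_tables <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list(
    registry = file.path(dir, "registry.json"),
    transcript = file.path(dir, "transcript.tsv"),
    protein_a = file.path(dir, "protein_a.tsv"),
    protein_b = file.path(dir, "protein_b.tsv"),
    substrates = file.path(dir, "substrates.tsv"),
    kinase_profiles = file.path(dir, "kinase_profiles.tsv"),
    site_profiles = file.path(dir, "site_profiles.tsv"),
    activity = file.path(dir, "activity.tsv")
  )
  write_registry(bundle$registry, p$registry)
  expr_df <- function(v) data.frame(kinase = names(v), value = unname(v),
                                    stringsAsFactors = FALSE)
  write_tsv(expr_df(bundle$transcript), p$transcript)
  write_tsv(expr_df(bundle$protein_a), p$protein_a)
  write_tsv(expr_df(bundle$protein_b), p$protein_b)
  write_tsv(bundle$substrates, p$substrates)
  prof_df <- function(m) cbind(data.frame(name = rownames(m), stringsAsFactors = FALSE),
                               as.data.frame(m))
  write_tsv(prof_df(bundle$kinase_profiles), p$kinase_profiles)
  write_tsv(prof_df(bundle$site_profiles), p$site_profiles)
  write_tsv(data.frame(kinase = names(bundle$activity),
                       activity = unname(bundle$activity),
                       stringsAsFactors = FALSE), p$activity)
  writeLines(bundle$background_windows, file.path(dir, "background_windows.txt"))
  invisible(p)
}

#' Write / read a kinase ranking table
#'
#' Long-format TSV with one row per (cluster, kinase): columns `cluster`,
#' `rank`, `kinase`, `family`, `posterior`, `probability_ratio`.
#'
#' @param rankings Ranking `data.frame` (see [rank_kinases()]).
#' @param path TSV path.
#' @return `write_ranking_table` returns the path invisibly;
#'   `read_ranking_table` returns the `data.frame`.
#' @export
write_ranking_table <- function(rankings, path) {
  write_tsv(as.data.frame(rankings), path)
}

#' @rdname write_ranking_table
#' @export
read_ranking_table <- function(path) {
  read_tsv(path, required = c("cluster", "rank", "kinase", "family",
                              "posterior", "probability_ratio"))
}
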