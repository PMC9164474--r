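# Top-kinase compilation and causal-network edge export (SIF + attribute
# table, the import format of network viewers), plus the end-to-end runner.

EDGE_DIRECTIONS <- c("enhancing", "inhibitory")
EDGE_BASES <- c("direct", "indirect")
EDGE_ACTIVITIES <- c("increased", "decreased", "complex")

#' Compile the unique top-ranked kinases across clusters
#'
#' Union of the top `k` kinases of every cluster ranking, deduplicated, each
#' annotated with the clusters (and ranks) that contributed it.
#'
#' @param rankings A `kinase_ranking` (or any `data.frame` with `cluster`,
#'   `rank`, `kinase`, `family` columns).
#' @param k Top ranks to take per cluster (default 5).
#' @return `data.frame` with `kinase`, `family`, `best_rank`, `n_clusters`,
#'   `clusters` (comma-separated `cluster:rank` pairs), ordered by
#'   `best_rank` then symbol.
#' @export
compile_top_kinases <- function(rankings, k = 5L) {
  if (k < 1L) stop("`k` must be at least 1", call. = FALSE)
  if (nrow(rankings) == 0L) stop("`rankings` must be non-empty", call. = FALSE)
  top <- rankings[rankings$rank <= k, , drop = FALSE]
  split_by <- split(top, top$kinase)
  out <- do.call(rbind, lapply(split_by, function(d) {
    data.frame(
      kinase = d$kinase[1L],
      family = d$family[1L],
      best_rank = min(d$rank),
      n_clusters = nrow(d),
      clusters = paste(sprintf("%s:%d", d$cluster, d$rank), collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$best_rank, out$kinase), , drop = FALSE]
  rownames(out) <- NULL
  out
}

validate_edges <- function(edges) {
  need <- c("source", "target", "direction", "basis", "target_activity")
  missing <- setdiff(need, names(edges))
  if (length(missing) > 0L) {
    stop(sprintf("edge table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(edges) == 0L) return(invisible(TRUE))
  if (any(!nzchar(edges$source)) || any(!nzchar(edges$target))) {
    stop("edge node names must be non-empty", call. = FALSE)
  }
  for (fld in list(c("direction", "EDGE_DIRECTIONS"),
                   c("basis", "EDGE_BASES"),
                   c("target_activity", "EDGE_ACTIVITIES"))) {
    vocab <- get(fld[2L])
    bad <- setdiff(unique(edges[[fld[1L]]]), vocab)
    if (length(bad) > 0L) {
      stop(sprintf("invalid %s value(s): %s (allowed: %s)", fld[1L],
                   paste(bad, collapse = ", "), paste(vocab, collapse = ", ")),
           call. = FALSE)
    }
  }
  key <- paste(edges$source, edges$target, sep = "\r")
  for (dupkey in unique(key[duplicated(key)])) {
    rows <- edges[key == dupkey, , drop = FALSE]
    if (nrow(unique(rows)) > 1L) {
      stop(sprintf("conflicting duplicate edge %s -> %s:\n%s",
                   rows$source[1L], rows$target[1L],
                   paste(utils::capture.output(print(rows)), collapse = "\n")),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Export a causal network as SIF plus an edge attribute table
#'
#' Writes a simple-interaction-format file (`source <TAB> direction <TAB>
#' target`) and a companion TSV of edge attributes (`direction`, `basis`,
#' `target_activity`). When `allowed` is given, only edges whose endpoints
#' are both in the allowed node set (the compiled top kinases plus any
#' whitelist) are exported. Identical duplicate edges are collapsed;
#' duplicates with conflicting annotation are an error listing both records.
#'
#' @param edges `data.frame` with columns `source`, `target`, `direction`
#'   (`enhancing`/`inhibitory`), `basis` (`direct`/`indirect`),
#'   `target_activity` (`increased`/`decreased`/`complex`).
#' @param sif_path Output SIF path.
#' @param attr_path Output attribute TSV path.
#' @param allowed Optional character vector of permitted node names.
#' @return List of the two paths, invisibly.
#' @export
export_network <- function(edges, sif_path, attr_path, allowed = NULL) {
  validate_edges(edges)
  edges <- unique(edges)
  if (!is.null(allowed)) {
    keep <- edges$source %in% allowed & edges$target %in% allowed
    edges <- edges[keep, , drop = FALSE]
  }
  sif <- data.frame(source = edges$source, interaction = edges$direction,
                    target = edges$target, stringsAsFactors = FALSE)
  utils::write.table(sif, sif_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv(edges[, c("source", "target", "direction", "basis",
                      "target_activity"), drop = FALSE], attr_path)
  invisible(list(sif = sif_path, attributes = attr_path))
}

#' Read a SIF file and its attribute table back
#'
#' @param sif_path SIF path written by [export_network()].
#' @param attr_path Optional attribute TSV path.
#' @return `data.frame` of edges (with attributes when `attr_path` given).
#' @export
read_sif <- function(sif_path, attr_path = NULL) {
  if (file.size(sif_path) == 0L) {
    sif <- data.frame(source = character(), interaction = character(),
                      target = character(), stringsAsFactors = FALSE)
  } else {
    sif <- utils::read.delim(sif_path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE,
                             col.names = c("source", "interaction", "target"))
  }
  if (is.null(attr_path)) return(sif)
  read_tsv(attr_path, required = c("source", "target", "direction", "basis",
                                   "target_activity"))
}

#' Run the whole pipeline end to end
#'
#' Simulates (or reads) the inputs, applies the regulation filter, clusters
#' the regulated sites, ranks kinases per cluster, compiles the top list,
#' and writes every stage output plus a run manifest (package version, seed,
#' thresholds, pivots, input checksums) to `out_dir`, so a run is
#' reproducible bit for bit from the manifest alone.
#'
#' @param config List (or path to a YAML file) with optional elements
#'   `seed`, `alpha_p`, `ci_multiplier`, `min_cluster_size`, `top_k`, and
#'   either `input_dir` (a directory previously written by `run_all` or
#'   [write_evidence_tables()] plus `sites.tsv`) or simulation settings
#'   (`n_sites`, `n_regulated`, `effect`, ...) forwarded to [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisible list with the stage objects and output paths.
#' @export
run_all <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  get_opt <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$input_dir)) {
    ind <- config$input_dir
    sites_path <- file.path(ind, "sites.tsv")
    if (!file.exists(sites_path)) {
      stop(sprintf("configuration error: missing input file %s", sites_path),
           call. = FALSE)
    }
    sites <- read_phosphosite_table(sites_path)
    paths <- list(
      registry = file.path(ind, "registry.json"),
      transcript = file.path(ind, "transcript.tsv"),
      protein_a = file.path(ind, "protein_a.tsv"),
      protein_b = file.path(ind, "protein_b.tsv"),
      substrates = file.path(ind, "substrates.tsv"),
      kinase_profiles = file.path(ind, "kinase_profiles.tsv"),
      site_profiles = file.path(ind, "site_profiles.tsv"),
      activity = file.path(ind, "activity.tsv")
    )
    bundle <- read_evidence_tables(paths, background_windows = sites$window)
    input_files <- c(sites_path, unlist(paths))
  } else {
    sim_args <- config[intersect(names(config),
                                 names(formals(sim_config)))]
    cfg <- do.call(sim_config, sim_args)
    sim <- simulate_experiment(cfg)
    sites <- sim$sites
    bundle <- sim$bundle
    input_dir <- file.path(out_dir, "inputs")
    dir.create(input_dir, showWarnings = FALSE, recursive = TRUE)
    write_phosphosite_table(sites, file.path(input_dir, "sites.tsv"))
    ev_paths <- write_evidence_tables(bundle, input_dir)
    write_tsv(sim$truth, file.path(input_dir, "truth.tsv"))
    input_files <- c(file.path(input_dir, "sites.tsv"), unlist(ev_paths))
  }

  scfg <- significance_config(alpha_p = get_opt("alpha_p", 0.05),
                              ci_multiplier = get_opt("ci_multiplier", 2))
  report <- filter_regulated(sites, scfg)
  clusters <- cluster_sites(sites, report$regulated_ids)
  ranking <- rank_kinases(sites, clusters, bundle,
                          min_cluster_size = get_opt("min_cluster_size", 3L))
  top <- if (nrow(ranking) > 0L) {
    compile_top_kinases(ranking, k = get_opt("top_k", 5L))
  } else {
    data.frame(kinase = character(), family = character(),
               best_rank = integer(), n_clusters = integer(),
               clusters = character(), stringsAsFactors = FALSE)
  }

  paths_out <- list(
    report = file.path(out_dir, "regulation_report.tsv"),
    regulated = file.path(out_dir, "regulated_sites.tsv"),
    clusters = file.path(out_dir, "cluster_assignments.tsv"),
    ranking = file.path(out_dir, "kinase_ranking.tsv"),
    top = file.path(out_dir, "top_kinases.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_tsv(data.frame(time_min = TIMEPOINTS, sd = unname(report$per_time_sd),
                       half_width = report$half_width,
                       fdr_estimate = report$fdr_estimate),
            paths_out$report)
  write_phosphosite_table(sites[sites$site_id %in% report$regulated_ids, ,
                                drop = FALSE], paths_out$regulated)
  write_tsv(as.data.frame(clusters), paths_out$clusters)
  write_ranking_table(ranking, paths_out$ranking)
  write_tsv(top, paths_out$top)

  meta <- attr(ranking, "meta")
  manifest <- list(
    package = "kinbayes",
    version = as.character(utils::packageVersion("kinbayes")),
    seed = get_opt("seed", formals(sim_config)$seed),
    alpha_p = scfg$alpha_p,
    ci_multiplier = scfg$ci_multiplier,
    half_width = report$half_width,
    min_cluster_size = get_opt("min_cluster_size", 3L),
    top_k = get_opt("top_k", 5L),
    clusters = lapply(meta, function(m) {
      list(n_members = m$n_members, direction = m$direction,
           positions = m$positions, pivots = m$pivots)
    }),
    input_md5 = as.list(tools::md5sum(input_files))
  )
  jsonlite::write_json(manifest, paths_out$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(sites = sites, bundle = bundle, report = report,
                 clusters = clusters, ranking = ranking, top = top,
                 paths = paths_out))
}
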