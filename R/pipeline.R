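#' Read and validate an analysis configuration
#'
#' The whole analysis is driven by one YAML or JSON file. Recognised keys
#' (defaults follow the standard protocol): `abundance` (path, required),
#' `abundance_layout` (`"long"`/`"wide"`, default long), `metadata` (path,
#' optional), `reduction_n` (10), `exclude_taxa` (character vector),
#' `site_grouping` (named map sample id -> site id), `metric` (`"ppd"`),
#' `iterations` (1000), `seed` (1), `depth_grouping` (`"median"`,
#' `"tertile"`, or a named map), `distance_method` (`"spearman"`),
#' `nmds_k` (2), `nmds_restarts` (20), `permutations` (999), `output_dir`.
#'
#' @param path config file path (`.yaml`/`.yml`/`.json`).
#' @return a validated `analysis_config` list.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  as_analysis_config(raw, dir = dirname(path))
}

as_analysis_config <- function(raw, dir = ".") {
  cfg <- list(
    abundance = raw$abundance %||% stop("config requires 'abundance' path"),
    abundance_layout = raw$abundance_layout %||% "long",
    metadata = raw$metadata,
    reduction_n = raw$reduction_n %||% 10,
    exclude_taxa = raw$exclude_taxa %||% character(0),
    site_grouping = raw$site_grouping,
    metric = raw$metric %||% "ppd",
    iterations = raw$iterations %||% 1000,
    seed = raw$seed %||% 1,
    depth_grouping = raw$depth_grouping %||% "median",
    distance_method = raw$distance_method %||% "spearman",
    nmds_k = raw$nmds_k %||% 2,
    nmds_restarts = raw$nmds_restarts %||% 20,
    permutations = raw$permutations %||% 999,
    output_dir = raw$output_dir %||% "reefbeta_out")
  for (key in c("abundance", "metadata")) {
    if (is.null(cfg[[key]])) next
    if (!file.exists(cfg[[key]])) {
      alt <- file.path(dir, cfg[[key]])
      if (file.exists(alt)) cfg[[key]] <- alt
      else stop("referenced file does not exist: ", cfg[[key]])
    }
  }
  if (cfg$reduction_n < 1) stop("reduction_n must be >= 1")
  if (cfg$iterations < 1) stop("iterations must be >= 1")
  structure(cfg, class = "analysis_config")
}

#' Run the full beta-diversity analysis
#'
#' Executes the standard pipeline: read counts, exclude taxa, merge
#' replicate samples into sites, reduce to the top-n taxa per sample,
#' alpha-diversity table, pairwise dissimilarity matrix, mean summaries
#' (overall, per sample, within/between and pooled depth groups), the
#' gamma-pool null model, distance decay, alpha-depth correlations, the
#' depth-group Kruskal-Wallis test, PERMANOVA for depth (and age when an
#' `age_zone` column is present), and NMDS. Writes CSV/JSON outputs plus a
#' run log (package version, seed, config hash, per-stage record counts)
#' into `config$output_dir`; any stage failure aborts with the stage name.
#'
#' @param config an `analysis_config` or path to one.
#' @return the report as a nested list, invisibly.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("reefbeta %s", as.character(utils::packageVersion("reefbeta"))),
                 sprintf("seed: %s", config$seed),
                 sprintf("config hash: %s",
                         content_hash(paste(names(config),
                                            vapply(config, function(x)
                                              paste(format(x), collapse = ","),
                                              character(1)), sep = "="))))
  note <- function(stage, msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, msg))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  report <- list(seed = config$seed)

  tab <- stage("read", read_abundance_table(config$abundance,
                                            config$abundance_layout))
  note("read", sprintf("%d samples, %d taxa, %d specimens",
                       nrow(tab), ncol(tab), sum(tab)))
  meta <- if (!is.null(config$metadata))
    stage("read", read_sample_metadata(config$metadata)) else NULL

  if (length(config$exclude_taxa)) {
    tab <- stage("exclude", exclude_taxa(tab, config$exclude_taxa))
    note("exclude", sprintf("removed %d specimens",
                            sum(attr(tab, "exclusion_log")$removed)))
  }
  if (!is.null(config$site_grouping)) {
    grouping <- unlist(config$site_grouping)
    merged <- stage("merge", merge_by_site(tab, grouping, metadata = meta))
    if (is.list(merged) && !is_abundance_table(merged)) {
      tab <- merged$table; meta <- merged$metadata
    } else tab <- merged
    note("merge", sprintf("%d sites", nrow(tab)))
  }
  tab <- stage("reduce", top_n_reduce(tab, config$reduction_n))
  note("reduce", sprintf("top-%d: %d taxa retained", config$reduction_n, ncol(tab)))

  alpha <- stage("alpha", alpha_summary(tab))
  utils::write.csv(alpha, file.path(out_dir, "alpha_summary.csv"),
                   row.names = FALSE)
  report$alpha <- alpha

  diss <- stage("dissimilarity",
                dissimilarity_matrix(tab, metric = config$metric))
  write_dissimilarity_matrix(diss, file.path(out_dir, "dissimilarity_matrix.csv"))
  overall <- mean_dissimilarity(diss, "all")
  per_sample <- vapply(rownames(diss), function(id)
    mean_dissimilarity(diss, "per-sample", sample = id)$mean, numeric(1))
  report$beta <- list(overall_mean = overall$mean, overall_se = overall$se,
                      n_pairs = overall$n_pairs, per_sample_mean = as.list(per_sample))
  note("dissimilarity", sprintf("mean %s = %.4f +/- %.4f",
                                config$metric, overall$mean, overall$se))

  depth <- NULL
  if (!is.null(meta)) {
    dcol <- if (!is.null(meta$depth_rank) && !all(is.na(meta$depth_rank)))
      "depth_rank" else if (!is.null(meta$depth_m)) "depth_m" else NULL
    if (!is.null(dcol)) {
      depth <- stats::setNames(meta[[dcol]], meta$sample_id)[rownames(diss)]
    }
  }
  if (!is.null(depth) && !anyNA(depth)) {
    grouping <- if (is.character(config$depth_grouping) &&
                    length(config$depth_grouping) == 1) {
      switch(config$depth_grouping,
             median = depth_groups(depth, 2),
             tertile = depth_groups(depth, 3),
             stop("unknown depth_grouping rule: ", config$depth_grouping))
    } else stats::setNames(as.character(unlist(config$depth_grouping)),
                           names(unlist(config$depth_grouping)))
    report$depth_groups <- as.list(grouping)
    within <- mean_dissimilarity(diss, "within-group", grouping = grouping)
    between <- mean_dissimilarity(diss, "between-group", grouping = grouping)
    pooled <- stage("pooled-groups", pooled_group_dissimilarity(tab, grouping))
    report$beta$within_group_mean <- within$mean
    report$beta$between_group_mean <- between$mean
    report$beta$pooled_group_ppd <- as.list(lower_pairs(unclass(pooled)))
    kw <- stage("kruskal-wallis", kruskal_wallis_depth_groups(tab, grouping))
    report$kruskal_wallis <- kw[c("statistic", "p_value", "df")]
    pmv <- stage("permanova-depth",
                 permanova(diss, grouping, permutations = config$permutations,
                           seed = derive_seed(config$seed, 11)))
    report$permanova_depth <- pmv[c("r_squared", "pseudo_F", "p_value",
                                    "permutations")]
    note("permanova-depth", sprintf("R2 = %.4f, p = %.4g",
                                    pmv$r_squared, pmv$p_value))
    alpha_depth <- stage("alpha-depth", list(
      berger_parker = alpha_depth_correlation(alpha$berger_parker, depth),
      pielou_J = if (!all(is.na(alpha$pielou_J)))
        alpha_depth_correlation(alpha$pielou_J, depth) else NULL))
    report$alpha_depth <- alpha_depth
  }
  if (!is.null(meta) && !is.null(meta$age_zone) &&
      length(unique(meta$age_zone)) > 1) {
    age <- stats::setNames(meta$age_zone, meta$sample_id)[rownames(diss)]
    pma <- stage("permanova-age",
                 permanova(diss, age, permutations = config$permutations,
                           seed = derive_seed(config$seed, 12)))
    report$permanova_age <- pma[c("r_squared", "pseudo_F", "p_value",
                                  "permutations")]
  }

  nm <- stage("null-model",
              null_distribution(tab, iterations = config$iterations,
                                seed = derive_seed(config$seed, 13)))
  write_null_result(nm, csv_path = file.path(out_dir, "null_iterations.csv"))
  report$null_model <- nm[c("iterations", "null_mean", "null_sd", "null_se",
                            "observed_mean", "empirical_p", "ses")]
  note("null-model", sprintf("null mean %.4f +/- %.4f (se), p = %.4g",
                             nm$null_mean, nm$null_se, nm$empirical_p))

  if (!is.null(meta) && !is.null(meta$latitude) && !anyNA(meta$latitude)) {
    geo <- geo_distance_matrix(meta[match(rownames(diss), meta$sample_id), ])
    decay <- stage("distance-decay",
                   distance_decay(diss, geo, method = config$distance_method))
    report$distance_decay <- decay
    utils::write.csv(
      data.frame(distance_km = lower_pairs(unclass(geo)),
                 dissimilarity = lower_pairs(unclass(diss))),
      file.path(out_dir, "distance_decay_pairs.csv"), row.names = FALSE)
    note("distance-decay", sprintf("%s = %.4f, p = %.4g",
                                   decay$method, decay$coefficient,
                                   decay$p_value))
  }

  ord <- stage("nmds", nmds(diss, k = config$nmds_k,
                            restarts = config$nmds_restarts,
                            seed = derive_seed(config$seed, 14)))
  utils::write.csv(data.frame(sample_id = rownames(ord$coordinates),
                              ord$coordinates),
                   file.path(out_dir, "nmds_coordinates.csv"),
                   row.names = FALSE)
  report$nmds <- list(stress = ord$stress, k = config$nmds_k,
                      converged = ord$converged)
  note("nmds", sprintf("stress = %.4f (k = %d)", ord$stress, config$nmds_k))

  jsonlite::write_json(report, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(report)
}
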