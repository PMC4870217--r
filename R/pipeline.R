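## End-to-end pipeline orchestration: kin pruning, diversity, isolation by
## distance, phylogeographic R_ST test, and (optionally) a scaled ABC run,
## driven by a YAML/JSON configuration with seeds recorded in every output.

#' Run the full analysis pipeline
#'
#' Stages, mirroring the natural analysis order: kin pruning, the
#' per-population diversity table, isolation-by-distance Mantel tests,
#' the allele-size permutation test for phylogeographic signal, and an
#' optional ABC stage (reference table, scenario choice, parameter
#' estimates with generation-time conversion to years). Each stage writes a
#' CSV into `out_dir` and its settings (including the seed) into a JSON
#' manifest; identical configurations reproduce identical outputs.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   Recognized entries: `genepop` (input path) or `dataset` (an
#'   [msat_dataset()], list form only), `meta_csv`, `out_dir`, `seed`,
#'   `prune` (threshold, exempt), `diversity` (rarefaction_g), `ibd`
#'   (min_n, n_perm, log_distance), `rst` (n_perm, grouping column name),
#'   `abc` (enabled, kinds, n_per_scenario, tolerance, partition column),
#'   `generation_time` (alpha, s, lambda).
#' @return list of stage results, invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  if (is.null(cfg$out_dir)) stop("config: out_dir is required")
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  # validate inputs before any compute
  for (f in c(cfg$genepop, cfg$meta_csv))
    if (!is.null(f) && !file.exists(f)) stop("config: missing input file ", f)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(seed = seed)
  ds <- if (!is.null(cfg$dataset)) cfg$dataset
  else if (!is.null(cfg$genepop)) read_genepop(cfg$genepop)
  else stop("config: need genepop or dataset")
  if (!is.null(cfg$meta_csv)) ds$meta <- read_population_meta(cfg$meta_csv)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  # -- prune ------------------------------------------------------------
  thr <- if (is.null(cfg$prune$threshold)) 0.25 else cfg$prune$threshold
  exempt <- if (is.null(cfg$prune$exempt)) character() else cfg$prune$exempt
  pr <- stage("prune", prune_dataset(ds, threshold = thr,
                                     exempt_populations = exempt))
  utils::write.csv(pr$removed, file.path(cfg$out_dir, "prune_removed.csv"),
                   row.names = FALSE)
  writeLines(pr$kept, file.path(cfg$out_dir, "kept_ids.txt"))
  ds <- pr$dataset
  res$prune <- pr[c("kept", "removed")]
  # -- diversity --------------------------------------------------------
  g <- if (is.null(cfg$diversity$rarefaction_g)) 5 else cfg$diversity$rarefaction_g
  dt <- stage("diversity", diversity_table(ds, g = g))
  utils::write.csv(dt, file.path(cfg$out_dir, "diversity.csv"), row.names = FALSE)
  res$diversity <- dt
  # -- isolation by distance -------------------------------------------
  if (!is.null(ds$meta)) {
    set.seed(seed)
    min_n <- if (is.null(cfg$ibd$min_n)) 10 else cfg$ibd$min_n
    n_perm <- if (is.null(cfg$ibd$n_perm)) 30000 else cfg$ibd$n_perm
    fl <- stage("ibd", filter_small_populations(ds, min_n))
    sub <- fl$dataset
    if (length(unique(sub$pop)) < 4) {
      res$ibd <- paste("skipped:", length(unique(sub$pop)),
                       "populations after the sample-size filter")
    } else {
    meta <- ds$meta[ds$meta$population_id %in% unique(sub$pop), ]
    fst <- wc_fst(sub)$pairwise[meta$population_id, meta$population_id]
    gen <- rousset_distance(fst)
    geo <- great_circle_matrix(meta)
    ind <- indicator_matrix(meta)
    logd <- !isFALSE(cfg$ibd$log_distance)
    mt <- stage("ibd", mantel_test(gen, geo, n_perm = n_perm, seed = seed,
                                   log_transform_B = logd))
    pm <- stage("ibd", partial_mantel_test(gen, if (logd) log(geo + diag(nrow(geo))) else geo,
                                           ind, n_perm = min(n_perm, 10000),
                                           seed = seed))
    ibd_df <- data.frame(test = c("mantel_geo", "partial_geo_given_groups"),
                         r = c(mt$r, pm$r), p = c(mt$p, pm$p),
                         n_perm = c(mt$n_perm, pm$n_perm), seed = seed)
    utils::write.csv(ibd_df, file.path(cfg$out_dir, "ibd.csv"), row.names = FALSE)
    res$ibd <- ibd_df
    }
  }
  # -- phylogeographic signal ------------------------------------------
  n_perm_rst <- if (is.null(cfg$rst$n_perm)) 20000 else cfg$rst$n_perm
  grouping <- NULL
  if (!is.null(cfg$rst$group_column) && !is.null(ds$meta))
    grouping <- stats::setNames(ds$meta[[cfg$rst$group_column]],
                                ds$meta$population_id)
  ast <- stage("rst", allele_size_permutation_test(ds, grouping,
                                                   n_perm = n_perm_rst,
                                                   seed = seed))
  rst_df <- data.frame(rst_obs = ast$rst_obs, mean_rst_perm = ast$mean_rst_perm,
                       p = ast$p, n_perm = ast$n_perm, seed = seed)
  utils::write.csv(rst_df, file.path(cfg$out_dir, "rst_test.csv"), row.names = FALSE)
  res$rst <- rst_df
  # -- ABC (optional, scaled by config) --------------------------------
  if (isTRUE(cfg$abc$enabled)) {
    kinds <- if (is.null(cfg$abc$kinds)) SCENARIO_KINDS else cfg$abc$kinds
    nps <- if (is.null(cfg$abc$n_per_scenario)) 2000 else cfg$abc$n_per_scenario
    tol <- if (is.null(cfg$abc$tolerance)) 0.05 else cfg$abc$tolerance
    partition <- NULL
    if (!is.null(cfg$abc$partition_column) && !is.null(ds$meta))
      partition <- stats::setNames(ds$meta[[cfg$abc$partition_column]],
                                   ds$meta$population_id)
    pc <- cfg$abc$pop_config
    tab <- stage("abc", build_reference_table(kinds, n_per_scenario = nps,
                                              seed = seed, pop_config = pc))
    obs <- stage("abc", summary_vector(ds, partition))
    mc <- stage("abc", model_choice_logistic(tab, obs, tol))
    utils::write.csv(mc$posterior, file.path(cfg$out_dir, "abc_model_choice.csv"),
                     row.names = FALSE)
    best <- mc$posterior$scenario[which.max(mc$posterior$prob)]
    pe <- stage("abc", estimate_parameters(tab, obs, best, tol))
    est <- pe$estimates
    gt <- cfg$generation_time
    Ty <- if (is.null(gt)) 305 else
      generation_time(gt$alpha, gt$s, if (is.null(gt$lambda)) 1 else gt$lambda)
    tm <- grepl("^t_", est$parameter)
    est$median_years <- ifelse(tm, est$median * Ty, NA)
    est$lower_years <- ifelse(tm, est$lower * Ty, NA)
    est$upper_years <- ifelse(tm, est$upper * Ty, NA)
    utils::write.csv(est, file.path(cfg$out_dir, "abc_parameters.csv"),
                     row.names = FALSE)
    res$abc <- list(model_choice = mc, estimates = est, best = best,
                    generation_time_years = Ty)
  }
  manifest <- list(seed = seed, stages = names(res),
                   settings = cfg[setdiff(names(cfg), "dataset")])
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
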