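#' Run configuration
#'
#' Collects every setting of the analysis in one object. Inputs come either
#' from a named scenario `preset` (see [scenario_presets()]) or from `paths`,
#' a list with `stack` (named character vector of ASCII grid paths),
#' `regions` (region grid path) and `occurrences` (CSV path).
#'
#' @param preset scenario preset name, or `NULL` when `paths` is given.
#' @param paths input file paths (see above), or `NULL`.
#' @param scenario optional [scenario_config()] object used verbatim instead
#'   of the named preset (its landscape/sampling seeds are still re-derived
#'   from `seed`).
#' @param variables model variables (default: all stack variables).
#' @param select_variables run correlation-screened variable selection
#'   ([variable_selection()]) before fitting (default FALSE).
#' @param r_threshold absolute-correlation cutoff for admissible variable
#'   sets (default 0.7).
#' @param thin_d_min optional minimum-distance thinning (km) applied after
#'   the one-per-cell thinning; `NA` (default) disables it.
#' @param compare_thinning also fit on 5-km-thinned data and report the map
#'   correlation between the two ensembles (default FALSE).
#' @param n_background number of background points (default 10000).
#' @param cv_runs,train_fraction cross-validation settings (defaults 3, 0.8).
#' @param weight_metric ensemble weighting metric, `"roc"` or `"tss"`.
#' @param algorithms named list of fit functions (default
#'   [default_algorithms()]).
#' @param importance_reps permutation-importance repetitions (default 5).
#' @param seed master integer seed; stage seeds are derived from it.
#' @return an object of class `sdm_run_config`.
#' @export
run_config <- function(preset = "homogeneous", paths = NULL,
                       scenario = NULL,
                       variables = NULL, select_variables = FALSE,
                       r_threshold = 0.7, thin_d_min = NA,
                       compare_thinning = FALSE, n_background = 10000L,
                       cv_runs = 3L, train_fraction = 0.8,
                       weight_metric = "roc",
                       algorithms = default_algorithms(),
                       importance_reps = 5L, seed = 1L) {
  if (is.null(preset) && is.null(paths) && is.null(scenario))
    stop("one of `preset`, `scenario` or `paths` must be given")
  structure(list(preset = preset, paths = paths, scenario = scenario,
                 variables = variables,
                 select_variables = select_variables,
                 r_threshold = r_threshold, thin_d_min = thin_d_min,
                 compare_thinning = compare_thinning,
                 n_background = as.integer(n_background),
                 cv_runs = as.integer(cv_runs),
                 train_fraction = train_fraction,
                 weight_metric = weight_metric, algorithms = algorithms,
                 importance_reps = as.integer(importance_reps),
                 seed = as.integer(seed)),
            class = "sdm_run_config")
}

#' Read a run configuration from JSON
#'
#' Recognized keys mirror the arguments of [run_config()]; unknown keys
#' error. `algorithms` cannot be configured from JSON (pass fit functions in
#' R instead).
#'
#' @param path JSON file path.
#' @return an `sdm_run_config`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- setdiff(names(formals(run_config)), c("algorithms", "scenario"))
  bad <- setdiff(names(j), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, j)
}

# stage seeds derived deterministically from the master seed (kept < 2^31)
stage_seed <- function(seed, stage) {
  offsets <- c(landscape = 11L, sampling = 23L, thin = 37L, background = 41L,
               cv = 53L, validation = 67L, selection = 79L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) * 131L + offsets[[stage]]) %% 2147483587L
}

# Inputs from a preset or from files; presences are raw (unthinned) points.
load_inputs <- function(config) {
  if (!is.null(config$scenario) || !is.null(config$preset)) {
    sc <- config$scenario
    if (is.null(sc)) {
      presets <- scenario_presets()
      if (!config$preset %in% names(presets))
        stop("unknown preset: ", config$preset)
      sc <- presets[[config$preset]]
    }
    sc$seed_landscape <- stage_seed(config$seed, "landscape")
    sc$seed_sampling <- stage_seed(config$seed, "sampling")
    land <- generate_landscape(sc)
    pres <- sample_presences(land$truth, sc$n_presences,
                             seed = sc$seed_sampling, regions = land$regions)
    list(stack = land$stack, regions = land$regions, presences = pres,
         truth = land$truth, scenario = sc)
  } else {
    p <- config$paths
    gs <- lapply(p$stack, read_ascii_grid)
    names(gs) <- names(p$stack)
    regions <- read_ascii_grid(p$regions, categorical = TRUE)
    pres <- read_occurrences(p$occurrences)
    pres <- label_regions(pres, regions)
    list(stack = sdm_stack(gs), regions = regions, presences = pres,
         truth = NULL, scenario = NULL)
  }
}

#' Correlation-screened variable selection by GLM cross-validation
#'
#' Enumerates all admissible variable subsets (no pair with `|r| >=
#' r_threshold`, see [admissible_variable_sets()]) and screens each with a
#' cross-validated logistic model, ranking by mean evaluation ROC, ties
#' broken by mean evaluation sensitivity, then by smaller set size. GLM-only
#' screening keeps the all-subsets scan affordable; full-ensemble screening
#' of the winner happens downstream anyway.
#'
#' @param design an `sdm_design` holding all candidate variables.
#' @param candidate_sets list of character vectors (e.g. from
#'   [admissible_variable_sets()]).
#' @param runs,train_fraction,seed cross-validation settings.
#' @return list: `best` (winning variable set), `ranking` (data.frame with
#'   one row per candidate set, ranked).
#' @export
variable_selection <- function(design, candidate_sets, runs = 3L,
                               train_fraction = 0.8, seed = 1L) {
  if (!length(candidate_sets)) stop("need at least one candidate set")
  splits <- split_cv(design, runs = runs, train_fraction = train_fraction,
                     seed = seed)
  score_one <- function(vars) {
    d <- design
    d$X <- design$X[vars]
    d$variables <- vars
    m <- vapply(splits, function(s) {
      fit <- fit_glm(design_subset(d, s$train))
      tst <- predict(fit, d$X[s$test, , drop = FALSE])
      y <- design$y[s$test]
      o <- optimize_threshold(tst[y == 1L], tst[y == 0L])
      c(o$auc, o$sensitivity)
    }, numeric(2L))
    rowMeans(m)
  }
  sc <- vapply(candidate_sets, score_one, numeric(2L))
  ranking <- data.frame(
    variables = vapply(candidate_sets, paste, character(1L), collapse = "+"),
    n_variables = lengths(candidate_sets),
    mean_roc = sc[1L, ], mean_sensitivity = sc[2L, ])
  ord <- order(-ranking$mean_roc, -ranking$mean_sensitivity,
               ranking$n_variables)
  ranking <- ranking[ord, ]
  rownames(ranking) <- NULL
  list(best = candidate_sets[[ord[1L]]], ranking = ranking)
}

write_table <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  path
}

write_manifest <- function(out_dir, config, files, extra = list()) {
  files <- files[!vapply(files, is.null, logical(1L))]
  hashes <- tools::md5sum(unlist(files))
  manifest <- c(list(
    seed = config$seed,
    preset = config$preset,
    n_background = config$n_background,
    cv_runs = config$cv_runs,
    weight_metric = config$weight_metric,
    files = lapply(seq_along(hashes), function(i)
      list(path = basename(names(hashes)[i]), md5 = unname(hashes[i])))
  ), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  file.path(out_dir, "manifest.json")
}

#' Fit the regional ensemble model end to end
#'
#' Executes thinning, optional correlation-screened variable selection,
#' background sampling, cross-validated fits of every algorithm, the
#' performance-weighted ensemble and committee maps, threshold optimization,
#' binary map with per-region areas, permutation importance and response
#' curves. All randomness derives from `config$seed`; re-running with the
#' same configuration reproduces identical outputs. When `out_dir` is given,
#' tables (CSV), maps (ASCII grid) and a manifest with content hashes are
#' written there.
#'
#' @param config an [run_config()].
#' @param out_dir optional output directory.
#' @return list of artifacts: `ensemble`, `map`, `committee`, `binary`,
#'   `area`, `importance`, `response_curves`, `evaluation`, `design`,
#'   `inputs`, and (with `compare_thinning`) `thinning_comparison`.
#' @export
run_regional <- function(config, out_dir = NULL) {
  inputs <- load_inputs(config)
  stack <- inputs$stack; regions <- inputs$regions
  domain <- stack[[1L]]
  pres <- thin_one_per_cell(inputs$presences, domain,
                            seed = stage_seed(config$seed, "thin"))
  if (!is.na(config$thin_d_min))
    pres <- thin_min_distance(pres, config$thin_d_min,
                              seed = stage_seed(config$seed, "thin"))
  bg <- sample_background(domain, config$n_background,
                          seed = stage_seed(config$seed, "background"),
                          regions = regions)
  variables <- if (is.null(config$variables)) names(stack) else config$variables
  design <- build_design(pres, bg, stack, variables)
  selection <- NULL
  if (config$select_variables) {
    corr <- correlation_matrix(stack)
    sets <- admissible_variable_sets(variables, corr, config$r_threshold)
    selection <- variable_selection(design, sets, runs = config$cv_runs,
                                    train_fraction = config$train_fraction,
                                    seed = stage_seed(config$seed, "selection"))
    variables <- selection$best
    design <- build_design(pres, bg, stack, variables)
  }
  ens <- fit_ensemble(design, algorithms = config$algorithms,
                      runs = config$cv_runs,
                      train_fraction = config$train_fraction,
                      seed = stage_seed(config$seed, "cv"),
                      weight_metric = config$weight_metric)
  mmaps <- member_maps(ens, stack)
  map <- weighted_average_map(mmaps, ens$weights)
  committee <- committee_map(mmaps, ens$member_info$threshold)
  ba <- binarize_and_area(map, ens$threshold, regions)
  importance <- importance_table(
    stats::setNames(ens$members,
                    paste0(ens$member_info$algorithm, "_run",
                           ens$member_info$run)),
    design, reps = config$importance_reps,
    seed = stage_seed(config$seed, "cv"))
  curves <- do.call(rbind, lapply(variables, function(v) {
    rc <- response_curve(ens, design, v)
    data.frame(variable = v, rc)
  }))
  evaluation <- ens$member_info
  evaluation$weight <- ens$weights
  thin_cmp <- NULL
  if (config$compare_thinning) {
    pres5 <- thin_min_distance(pres, 5,
                               seed = stage_seed(config$seed, "thin"))
    design5 <- build_design(pres5, bg, stack, variables)
    ens5 <- fit_ensemble(design5, algorithms = config$algorithms,
                         runs = config$cv_runs,
                         train_fraction = config$train_fraction,
                         seed = stage_seed(config$seed, "cv"),
                         weight_metric = config$weight_metric)
    map5 <- weighted_average_map(member_maps(ens5, stack), ens5$weights)
    thin_cmp <- list(
      map_5km = map5,
      map_correlation = map_correlation(map, map5),
      internal = list(cell = ens$internal, km5 = ens5$internal),
      n_points = c(cell = nrow(pres), km5 = nrow(pres5)))
  }
  out <- list(ensemble = ens, map = map, committee = committee,
              binary = ba$binary, area = ba$area, importance = importance,
              response_curves = curves, evaluation = evaluation,
              selection = selection, design = design, inputs = inputs,
              thinning_comparison = thin_cmp)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      write_ascii_grid(map, file.path(out_dir, "regional_suitability.asc")),
      write_ascii_grid(committee, file.path(out_dir, "regional_committee.asc")),
      write_ascii_grid(ba$binary, file.path(out_dir, "regional_binary.asc")),
      write_table(ba$area, file.path(out_dir, "regional_area.csv")),
      write_table(importance, file.path(out_dir, "regional_importance.csv")),
      write_table(curves, file.path(out_dir, "regional_response_curves.csv")),
      write_table(evaluation, file.path(out_dir, "regional_evaluation.csv")),
      if (!is.null(selection))
        write_table(selection$ranking, file.path(out_dir, "variable_selection.csv")),
      if (!is.null(thin_cmp))
        write_table(
          data.frame(map_correlation = thin_cmp$map_correlation,
                     n_points_cell = thin_cmp$n_points["cell"],
                     n_points_5km = thin_cmp$n_points["km5"]),
          file.path(out_dir, "thinning_comparison.csv"))
    )
    write_manifest(out_dir, config, files,
                   extra = list(threshold = ens$threshold,
                                internal = ens$internal))
  }
  out
}

#' Run the full spatial-transferability assessment
#'
#' Thins and balances per-region presence sets to the smallest region's
#' count, then runs all (region x scheme) combinations -- region
#' cross-validation (domain-wide background) and extrapolation (background
#' restricted to the focal region) -- validating each run against the other
#' regions' presences and a fresh domain-wide background sample shared by
#' all runs so validation ROCs are comparable. Sensitivity uses each run's
#' own optimized threshold.
#'
#' @param config an [run_config()].
#' @param regional_map domain-wide regional suitability map; if `NULL`,
#'   [run_regional()] is executed first (without writing outputs).
#' @param out_dir optional output directory.
#' @return list: `report` (see [transfer_report()]), `runs` (all 2 x regions
#'   scheme runs), `regional_map`, `balanced` (the balanced occurrence sets).
#' @export
run_transfer <- function(config, regional_map = NULL, out_dir = NULL) {
  inputs <- load_inputs(config)
  stack <- inputs$stack; regions <- inputs$regions
  domain <- stack[[1L]]
  pres <- thin_one_per_cell(inputs$presences, domain,
                            seed = stage_seed(config$seed, "thin"))
  if (is.null(pres$region)) pres <- label_regions(pres, regions)
  labs <- sort(unique(pres$region[!is.na(pres$region)]))
  if (length(labs) < 2L) stop("need at least 2 regions with presences")
  occ_by_region <- lapply(labs, function(l)
    pres[!is.na(pres$region) & pres$region == l, , drop = FALSE])
  names(occ_by_region) <- as.character(labs)
  balanced <- subsample_balanced(occ_by_region,
                                 seed = stage_seed(config$seed, "sampling"))
  if (is.null(regional_map)) {
    regional <- run_regional(config)
    regional_map <- regional$map
  }
  val_bg <- sample_background(domain, config$n_background,
                              seed = stage_seed(config$seed, "validation"),
                              regions = regions)
  variables <- if (is.null(config$variables)) names(stack) else config$variables
  runs <- list()
  for (scope in c("regional", "focal-only")) {
    for (l in labs) {
      sch <- scheme_spec(l, scope, n_background = config$n_background,
                         seed = stage_seed(config$seed, "background"))
      r <- run_scheme(balanced, stack, regions, sch, variables = variables,
                      algorithms = config$algorithms, runs = config$cv_runs,
                      weight_metric = config$weight_metric)
      val_pres <- do.call(rbind, balanced[names(balanced) != as.character(l)])
      r$validation <- validate_map(r$map, val_pres, val_bg,
                                   tau = r$ensemble$threshold)
      runs[[length(runs) + 1L]] <- r
    }
  }
  report <- transfer_report(regional_map, runs)
  out <- list(report = report, runs = runs, regional_map = regional_map,
              balanced = balanced)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      write_table(report$table, file.path(out_dir, "transfer_report.csv")),
      write_table(report$summary, file.path(out_dir, "transfer_summary.csv"))
    )
    for (r in runs) {
      nm <- sprintf("%s_region%s_suitability.asc",
                    if (r$scheme$background_scope == "focal-only")
                      "extrapolation" else "crossvalidation",
                    r$scheme$focal_region)
      files[[length(files) + 1L]] <- write_ascii_grid(r$map,
                                                      file.path(out_dir, nm))
    }
    jsonlite::write_json(report, file.path(out_dir, "transfer_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows")
    files[[length(files) + 1L]] <- file.path(out_dir, "transfer_report.json")
    write_manifest(out_dir, config, files,
                   extra = list(n_balanced = nrow(balanced[[1L]])))
  }
  out
}
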