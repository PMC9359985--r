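#' Default base-algorithm roster
#'
#' Named list of fit functions for the four native algorithms: weighted
#' logistic regression (GLM), surface range envelope (SRE), classification
#' tree (CTA) and gradient boosting (GBM). Further algorithms can be added
#' through [sdm_adapter()].
#'
#' @param glm_terms,sre_alpha,cta_max_depth,gbm_n_trees,gbm_learning_rate,gbm_tree_depth
#'   per-algorithm settings (see the individual fit functions).
#' @return named list of functions `design -> sdm_model`.
#' @export
default_algorithms <- function(glm_terms = "quadratic", sre_alpha = 0.025,
                               cta_max_depth = 5L, gbm_n_trees = 500L,
                               gbm_learning_rate = 0.1, gbm_tree_depth = 2L) {
  list(
    GLM = function(design) fit_glm(design, terms = glm_terms),
    SRE = function(design) fit_sre(design, alpha = sre_alpha),
    CTA = function(design) fit_cta(design, max_depth = cta_max_depth),
    GBM = function(design) fit_gbm(design, n_trees = gbm_n_trees,
                                   learning_rate = gbm_learning_rate,
                                   tree_depth = gbm_tree_depth)
  )
}

design_subset <- function(design, rows) {
  structure(list(
    X = design$X[rows, , drop = FALSE],
    y = design$y[rows], w = design$w[rows],
    coords = design$coords[rows, , drop = FALSE],
    region = design$region[rows],
    variables = design$variables,
    n_dropped = design$n_dropped
  ), class = "sdm_design")
}

#' Skill-proportional ensemble weights
#'
#' `w_i = max(score_i - baseline, 0) / sum_j max(score_j - baseline, 0)`.
#' Subtracting the no-skill floor (0.5 for ROC, 0 for TSS) keeps near-random
#' members from receiving substantial weight.
#'
#' @param member_scores numeric member skill scores.
#' @param baseline no-skill floor subtracted before normalizing.
#' @return nonnegative weights summing to 1.
#' @export
ensemble_weights <- function(member_scores, baseline = 0.5) {
  s <- pmax(member_scores - baseline, 0)
  if (sum(s) <= 0) stop("no member scores above the baseline: no skillful member")
  s / sum(s)
}

#' Fit the performance-weighted ensemble
#'
#' Runs repeated stratified calibration/evaluation splits ([split_cv()]);
#' every (algorithm x run) fit becomes an ensemble member, weighted by its
#' run's evaluation-set skill (ROC above 0.5 by default, or TSS above 0).
#' Each member's own threshold is optimized by maximum sensitivity +
#' specificity on its calibration scores; the ensemble threshold is
#' re-optimized on the ensemble's scores over the full design (not averaged
#' from member thresholds). Internal skill is reported as the mean over runs
#' of the run-level ensemble's evaluation-set metrics.
#'
#' @param design an `sdm_design`.
#' @param algorithms named list of fit functions (default
#'   [default_algorithms()]).
#' @param runs,train_fraction,seed cross-validation settings (see
#'   [split_cv()]).
#' @param weight_metric `"roc"` (default) or `"tss"`.
#' @return an object of class `sdm_ensemble`: `members` (fitted models),
#'   `member_info` (per-member evaluation table), `weights`, `threshold`,
#'   and `internal` (mean internal ROC / sensitivity / specificity / TSS).
#' @export
fit_ensemble <- function(design, algorithms = default_algorithms(),
                         runs = 3L, train_fraction = 0.8, seed = 1L,
                         weight_metric = c("roc", "tss")) {
  weight_metric <- match.arg(weight_metric)
  baseline <- if (weight_metric == "roc") 0.5 else 0
  splits <- split_cv(design, runs = runs, train_fraction = train_fraction,
                     seed = seed)
  members <- list()
  info <- list()
  run_pred_test <- lapply(splits, function(s) list())
  for (s in splits) {
    d_tr <- design_subset(design, s$train)
    for (a in names(algorithms)) {
      model <- algorithms[[a]](d_tr)
      cal <- predict(model, d_tr$X)
      opt <- optimize_threshold(cal[d_tr$y == 1L], cal[d_tr$y == 0L])
      tst <- predict(model, design$X[s$test, , drop = FALSE])
      y_tst <- design$y[s$test]
      m_auc <- auc(tst[y_tst == 1L], tst[y_tst == 0L])
      cm <- confusion_metrics(tst[y_tst == 1L], tst[y_tst == 0L],
                              opt$threshold)
      members[[length(members) + 1L]] <- model
      info[[length(info) + 1L]] <- data.frame(
        algorithm = a, run = s$run, threshold = opt$threshold,
        auc_test = m_auc, sensitivity_test = cm$sensitivity,
        specificity_test = cm$specificity, tss_test = cm$tss)
      run_pred_test[[s$run]][[a]] <- tst
    }
  }
  member_info <- do.call(rbind, info)
  scores <- if (weight_metric == "roc") member_info$auc_test
            else member_info$tss_test
  weights <- ensemble_weights(scores, baseline)
  ens <- structure(list(
    algorithm = "ensemble", members = members, member_info = member_info,
    weights = weights, weight_metric = weight_metric, baseline = baseline,
    variables = design$variables
  ), class = c("sdm_ensemble", "sdm_model"))
  # ensemble threshold: max sens + spec on full-design ensemble scores
  full <- predict(ens, design$X)
  opt <- optimize_threshold(full[design$y == 1L], full[design$y == 0L])
  ens$threshold <- opt$threshold
  # internal skill: run-level ensembles scored on their own evaluation rows
  run_metrics <- lapply(splits, function(s) {
    rows <- member_info$run == s$run
    # equal weights if no member in this run beats the baseline (reporting
    # only; the overall ensemble still requires a skillful member)
    w_run <- if (any(scores[rows] > baseline))
      ensemble_weights(scores[rows], baseline)
    else rep(1 / sum(rows), sum(rows))
    preds <- run_pred_test[[s$run]][member_info$algorithm[rows]]
    p_run <- Reduce(`+`, Map(`*`, preds, w_run))
    y_tst <- design$y[s$test]
    o <- optimize_threshold(p_run[y_tst == 1L], p_run[y_tst == 0L])
    c(roc = o$auc, sensitivity = o$sensitivity,
      specificity = o$specificity, tss = o$tss)
  })
  ens$internal <- as.list(colMeans(do.call(rbind, run_metrics)))
  ens
}

#' @export
predict.sdm_ensemble <- function(object, newdata, ...) {
  p <- 0
  for (i in seq_along(object$members))
    p <- p + object$weights[i] * predict(object$members[[i]], newdata)
  pmin(pmax(p, 0), 1)
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("<sdm_ensemble> %d members (%s), weighted by %s\n",
              length(x$members),
              paste(unique(x$member_info$algorithm), collapse = ", "),
              x$weight_metric))
  cat(sprintf("  threshold %.4f, internal ROC %.3f\n", x$threshold,
              x$internal$roc))
  invisible(x)
}

#' Weighted average of aligned suitability maps
#'
#' Cellwise `sum(w_i map_i)`; a cell is nodata iff any member map is nodata
#' there.
#'
#' @param maps list of aligned [sdm_grid()]s.
#' @param weights nonnegative weights summing to 1 (checked to 1e-8).
#' @return an [sdm_grid()].
#' @export
weighted_average_map <- function(maps, weights) {
  if (length(maps) != length(weights)) stop("one weight per map required")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  for (m in maps[-1L]) stop_unless_aligned(maps[[1L]], m)
  acc <- maps[[1L]]$values * weights[1L]
  for (i in seq_along(maps)[-1L]) acc <- acc + weights[i] * maps[[i]]$values
  sdm_grid(acc, maps[[1L]]$cell_size, maps[[1L]]$origin)
}

#' Committee-averaging (vote fraction) map
#'
#' Each member map is binarized at its own optimized threshold
#' (`value >= tau` votes "present"); the committee map holds the fraction of
#' members voting present, an agreement/uncertainty surface: 1 or 0 means
#' unanimity, values near 0.5 mean about half the members disagree.
#'
#' @param maps list of aligned member [sdm_grid()]s.
#' @param thresholds numeric vector, one threshold per map.
#' @return an [sdm_grid()] of vote fractions in `{0, 1/m, ..., 1}`.
#' @export
committee_map <- function(maps, thresholds) {
  if (length(maps) != length(thresholds)) stop("one threshold per map required")
  for (m in maps[-1L]) stop_unless_aligned(maps[[1L]], m)
  acc <- (maps[[1L]]$values >= thresholds[1L]) + 0
  for (i in seq_along(maps)[-1L])
    acc <- acc + (maps[[i]]$values >= thresholds[i])
  sdm_grid(acc / length(maps), maps[[1L]]$cell_size, maps[[1L]]$origin)
}

#' Binarize a suitability map and account suitable area
#'
#' Cells with `value >= tau` are suitable; area = suitable cell count times
#' `cell_size^2` (km^2), totalled and, when a region partition is given,
#' broken down by region (regional areas sum to the total).
#'
#' @param map an [sdm_grid()] of suitability.
#' @param tau threshold in `[0, 1]`.
#' @param regions optional [sdm_categorical()] region partition.
#' @return list: `binary` ([sdm_grid()] of 0/1), `area` (data.frame with
#'   columns `region`, `area_km2`; region `"total"` last).
#' @export
binarize_and_area <- function(map, tau, regions = NULL) {
  if (tau < 0 || tau > 1) stop("`tau` must be in [0, 1]")
  b <- (map$values >= tau) + 0
  b[is.na(map$values)] <- NA
  cell_area <- map$cell_size^2
  total <- sum(b, na.rm = TRUE) * cell_area
  if (is.null(regions)) {
    area <- data.frame(region = "total", area_km2 = total)
  } else {
    stop_unless_aligned(map, regions)
    labs <- sort(unique(regions$values[!is.na(regions$values)]))
    per <- vapply(labs, function(l)
      sum(b[!is.na(regions$values) & regions$values == l], na.rm = TRUE) *
        cell_area, numeric(1L))
    area <- data.frame(region = c(as.character(labs), "total"),
                       area_km2 = c(per, total))
  }
  list(binary = sdm_grid(b, map$cell_size, map$origin), area = area)
}

#' Member suitability maps of an ensemble
#' @param ensemble an `sdm_ensemble`.
#' @param stack an [sdm_stack()].
#' @return list of [sdm_grid()]s, one per member.
#' @export
member_maps <- function(ensemble, stack) {
  lapply(ensemble$members, predict_map, stack = stack)
}
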