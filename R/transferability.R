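normalize_joint <- function(map1, map2) {
  ok <- joint_valid(map1, map2)
  if (!any(ok)) stop("no jointly valid cells")
  s1 <- map1$values[ok]; s2 <- map2$values[ok]
  if (any(s1 < 0) || any(s2 < 0)) stop("suitability maps must be nonnegative")
  if (sum(s1) <= 0 || sum(s2) <= 0) stop("all-zero map: overlap undefined")
  list(p1 = s1 / sum(s1), p2 = s2 / sum(s2))
}

#' Schoener's D niche overlap between two suitability maps
#'
#' Each map is normalized to sum to 1 over the jointly valid cells, then
#' `D = 1 - 0.5 sum |p1 - p2|`: 0 means no overlap, 1 complete overlap.
#' Symmetric and invariant to rescaling either map by a positive constant.
#'
#' @param map1,map2 aligned nonnegative [sdm_grid()]s with positive totals.
#' @return D in `[0, 1]`.
#' @export
schoener_d <- function(map1, map2) {
  p <- normalize_joint(map1, map2)
  1 - 0.5 * sum(abs(p$p1 - p$p2))
}

#' Hellinger-based I niche overlap between two suitability maps
#'
#' With the same cell normalization as [schoener_d()],
#' `I = 1 - 0.5 sum (sqrt(p1) - sqrt(p2))^2`; ranges 0 (no overlap) to 1
#' (complete overlap).
#'
#' @inheritParams schoener_d
#' @return I in `[0, 1]`.
#' @export
hellinger_i <- function(map1, map2) {
  p <- normalize_joint(map1, map2)
  1 - 0.5 * sum((sqrt(p$p1) - sqrt(p$p2))^2)
}

#' Spearman rank correlation between two aligned maps
#'
#' Pearson correlation of midrank-transformed cell values over all jointly
#' valid cells.
#'
#' @inheritParams schoener_d
#' @return Spearman r in `[-1, 1]`, `NA` (with warning) if a map is constant.
#' @export
spearman_maps <- function(map1, map2) {
  ok <- joint_valid(map1, map2)
  if (sum(ok) < 3L) stop("need at least 3 jointly valid cells")
  x <- map1$values[ok]; y <- map2$values[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant map: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Specification of one single-region transfer run
#'
#' @param focal_region region label whose presences calibrate the model.
#' @param background_scope `"regional"` (background drawn from the whole
#'   domain: the region cross-validation scheme) or `"focal-only"`
#'   (background restricted to the focal region: the extrapolation scheme).
#' @param n_background number of background points (default 10000).
#' @param seed integer seed for background sampling and CV splits.
#' @return an object of class `sdm_scheme`.
#' @export
scheme_spec <- function(focal_region,
                        background_scope = c("regional", "focal-only"),
                        n_background = 10000L, seed = 1L) {
  background_scope <- match.arg(background_scope)
  structure(list(focal_region = focal_region,
                 background_scope = background_scope,
                 n_background = as.integer(n_background),
                 seed = as.integer(seed)),
            class = "sdm_scheme")
}

#' Run one single-region scheme: fit the ensemble, predict the whole domain
#'
#' Fits the full ensemble pipeline using presences of the focal region only,
#' with background drawn from the whole domain (`"regional"` scope) or
#' restricted to the focal region (`"focal-only"` scope, the extrapolation
#' scheme), then predicts suitability over the entire domain including the
#' non-focal regions.
#'
#' @param occ_by_region named list of per-region occurrence data.frames
#'   (balance them with [subsample_balanced()] first for comparable runs).
#' @param stack an [sdm_stack()].
#' @param regions an [sdm_categorical()] region partition.
#' @param scheme an [scheme_spec()].
#' @param variables model variables (default all stack names).
#' @param algorithms,runs,weight_metric passed to [fit_ensemble()].
#' @return list: `ensemble` (`sdm_ensemble`), `map` (domain-wide suitability
#'   [sdm_grid()]), `scheme`, `design`.
#' @export
run_scheme <- function(occ_by_region, stack, regions, scheme,
                       variables = names(stack),
                       algorithms = default_algorithms(), runs = 3L,
                       weight_metric = "roc") {
  key <- as.character(scheme$focal_region)
  if (!key %in% names(occ_by_region) || !nrow(occ_by_region[[key]]))
    stop("empty focal region: ", key)
  pres <- occ_by_region[[key]]
  domain <- stack[[1L]]
  bg <- if (scheme$background_scope == "focal-only") {
    sample_background(domain, scheme$n_background, seed = scheme$seed,
                      regions = regions, restrict = scheme$focal_region)
  } else {
    sample_background(domain, scheme$n_background, seed = scheme$seed,
                      regions = regions)
  }
  design <- build_design(pres, bg, stack, variables)
  ens <- fit_ensemble(design, algorithms = algorithms, runs = runs,
                      seed = scheme$seed, weight_metric = weight_metric)
  map <- predict_map(ens, stack)
  list(ensemble = ens, map = map, scheme = scheme, design = design)
}

#' Validate a suitability map against held-out presences
#'
#' Scores are read off the map at the validation coordinates (points on
#' nodata are dropped and counted); ROC contrasts validation presences with
#' validation background, and sensitivity is the fraction of validation
#' presences at or above the supplied threshold.
#'
#' @param map suitability [sdm_grid()].
#' @param validation_presences,validation_background occurrence data.frames.
#' @param tau classification threshold (typically the run's own optimized
#'   threshold).
#' @return list: `roc`, `sensitivity`, `n_dropped`.
#' @export
validate_map <- function(map, validation_presences, validation_background,
                         tau) {
  sp <- grid_extract(map, validation_presences$x, validation_presences$y)
  sb <- grid_extract(map, validation_background$x, validation_background$y)
  n_dropped <- sum(is.na(sp)) + sum(is.na(sb))
  sp <- sp[!is.na(sp)]; sb <- sb[!is.na(sb)]
  if (!length(sp) || !length(sb)) stop("validation sets empty after drops")
  list(roc = auc(sp, sb),
       sensitivity = mean(sp >= tau),
       n_dropped = n_dropped)
}

#' Assemble the transferability report
#'
#' One row per (scheme, focal region) run with the six comparison metrics:
#' internal ROC (CV mean of the run's ensemble), validation ROC, validation
#' sensitivity, Spearman r against the regional map, Schoener's D and
#' Hellinger's I against the regional map. Also returns the per-scheme
#' summary (mean of each metric) contrasting region cross-validation with
#' extrapolation.
#'
#' @param regional_map domain-wide regional ensemble suitability
#'   [sdm_grid()].
#' @param runs list of completed scheme runs, each a list with `scheme`,
#'   `ensemble`, `map`, `validation` (as returned by [validate_map()]).
#' @return list: `table` (one row per run), `summary` (one row per scheme).
#' @export
transfer_report <- function(regional_map, runs) {
  rows <- lapply(runs, function(r) {
    data.frame(
      scheme = if (r$scheme$background_scope == "focal-only")
        "extrapolation" else "cross-validation",
      region = as.character(r$scheme$focal_region),
      roc_internal = r$ensemble$internal$roc,
      roc_validation = r$validation$roc,
      sensitivity_validation = r$validation$sensitivity,
      spearman = spearman_maps(r$map, regional_map),
      schoener_d = schoener_d(r$map, regional_map),
      hellinger_i = hellinger_i(r$map, regional_map)
    )
  })
  tab <- do.call(rbind, rows)
  metrics <- c("roc_internal", "roc_validation", "sensitivity_validation",
               "spearman", "schoener_d", "hellinger_i")
  summ <- do.call(rbind, lapply(split(tab, tab$scheme), function(d)
    data.frame(scheme = d$scheme[1L],
               as.list(colMeans(d[metrics])))))
  rownames(summ) <- NULL
  list(table = tab, summary = summ)
}
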