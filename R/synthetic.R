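# Virtual-species landscape generator. Provides every input the pipeline
# needs -- spatially autocorrelated covariates, a region partition, and a
# known logistic suitability surface -- so the full workflow can be validated
# against ground truth (the real survey data it emulates are not public).

running_mean_1d <- function(v, k) {
  n <- length(v)
  cs <- c(0, cumsum(v))
  i <- seq_len(n)
  lo <- pmax(i - k, 1L); hi <- pmin(i + k, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# separable moving-average smoothing (window half-width k, edge-clipped)
box_smooth <- function(m, k) {
  m <- apply(m, 2L, running_mean_1d, k = k)
  t(apply(m, 1L, running_mean_1d, k = k))
}

rescale01 <- function(m) {
  r <- range(m)
  if (diff(r) == 0) return(m * 0)
  (m - r[1L]) / (r[2L] - r[1L])
}

#' Scenario configuration for the virtual landscape
#'
#' @param nrows,ncols grid size (default 240 x 360 cells).
#' @param cell_size cell side in km (default 1).
#' @param n_regions number of vertical region bands (default 3, emulating a
#'   three-state study area).
#' @param smooth_k moving-average half-width in cells controlling covariate
#'   spatial autocorrelation (default 10, i.e. ~20-km patches).
#' @param crops_frac fraction of the landscape under crops (default 0.3,
#'   matching a heavily cultivated region).
#' @param developed_frac fraction developed (default 0.07).
#' @param beta named true coefficients of the logistic suitability surface:
#'   `intercept`, `natural_prop`, `log1p_dist_crops`, `road_density`,
#'   `snowfall`, `snowfall_sq` (distance to crops enters on a log1p scale so
#'   suitability saturates within a few km of crops). `dist_developed` is
#'   generated but carries no true effect (a nuisance covariate).
#' @param n_presences number of presence points sampled (default 500).
#' @param truncated_region optional region label in which crops are planted
#'   densely everywhere, truncating that region's distance-to-crops range
#'   relative to the full landscape.
#' @param seed_landscape,seed_sampling seeds for field generation and
#'   presence sampling.
#' @return an object of class `sdm_scenario_config`.
#' @export
scenario_config <- function(nrows = 240L, ncols = 360L, cell_size = 1,
                            n_regions = 3L, smooth_k = 10L,
                            crops_frac = 0.3, developed_frac = 0.07,
                            beta = c(intercept = -4, natural_prop = 3.5,
                                     log1p_dist_crops = 1.0,
                                     road_density = -0.6,
                                     snowfall = 1.0, snowfall_sq = -0.2),
                            n_presences = 500L, truncated_region = NA,
                            seed_landscape = 101L, seed_sampling = 202L) {
  need <- c("intercept", "natural_prop", "log1p_dist_crops", "road_density",
            "snowfall", "snowfall_sq")
  if (!all(need %in% names(beta)))
    stop("`beta` must name: ", paste(need, collapse = ", "))
  if (n_regions < 2L || ncols %/% n_regions < 2L) stop("degenerate region bands")
  structure(list(nrows = as.integer(nrows), ncols = as.integer(ncols),
                 cell_size = cell_size, n_regions = as.integer(n_regions),
                 smooth_k = as.integer(smooth_k), crops_frac = crops_frac,
                 developed_frac = developed_frac, beta = beta[need],
                 n_presences = as.integer(n_presences),
                 truncated_region = truncated_region,
                 seed_landscape = as.integer(seed_landscape),
                 seed_sampling = as.integer(seed_sampling)),
            class = "sdm_scenario_config")
}

#' Named scenario presets
#'
#' * `homogeneous`: the same generating process everywhere with overlapping
#'   covariate ranges across regions;
#' * `range_truncated`: region 1 has crops planted densely throughout, so its
#'   distance-to-crops range is truncated relative to the landscape (models
#'   calibrated there never see large distances and must extrapolate);
#' * `null`: every slope coefficient is 0 (no covariate signal), for
#'   checking that fitted skill stays at chance.
#'
#' @return named list of [scenario_config()] objects.
#' @export
scenario_presets <- function() {
  null_beta <- c(intercept = stats::qlogis(0.2), natural_prop = 0,
                 log1p_dist_crops = 0, road_density = 0, snowfall = 0,
                 snowfall_sq = 0)
  list(
    homogeneous = scenario_config(),
    range_truncated = scenario_config(truncated_region = 1L),
    null = scenario_config(beta = null_beta)
  )
}

#' Generate the virtual landscape, region partition and truth surface
#'
#' Covariate fields are smoothed seeded uniform noise plus deterministic
#' north-south gradients; the crops and developed masks threshold latent
#' fields at the configured landscape fractions and the `dist_*` covariates
#' are exact distance transforms of those masks ([distance_to_class()]).
#' The true suitability is exactly the inverse-logit of the declared linear
#' predictor. Bit-identical for a fixed `seed_landscape`.
#'
#' @param config an [scenario_config()].
#' @return list: `stack` ([sdm_stack()] with `natural_prop`, `dist_crops`,
#'   `dist_developed`, `road_density`, `snowfall`), `regions`
#'   ([sdm_categorical()]), `truth` (list: `psi` [sdm_grid()], `beta`,
#'   `ranges` per-region covariate range table).
#' @export
generate_landscape <- function(config) {
  nr <- config$nrows; nc <- config$ncols; cs <- config$cell_size
  k <- config$smooth_k
  fields <- with_seed(config$seed_landscape, {
    lapply(1:3, function(i) box_smooth(matrix(stats::runif(nr * nc), nr, nc), k))
  })
  north <- matrix((nr:1) / nr, nr, nc)  # row 1 = north => high values north
  # natural cover: patchy field with more natural cover in the north
  natural <- rescale01(0.7 * rescale01(fields[[1L]]) + 0.3 * north)
  # region bands: vertical thirds (or n_regions-ths) by column
  band_w <- nc %/% config$n_regions
  lab <- pmin((col(natural) - 1L) %/% band_w + 1L, config$n_regions)
  regions <- sdm_categorical(matrix(as.numeric(lab), nr, nc), cs, c(0, 0),
                             codes = seq_len(config$n_regions))
  # crops where natural cover is lowest (negatively associated by build)
  crops <- natural <= stats::quantile(natural, config$crops_frac)
  if (!is.na(config$truncated_region)) {
    in_tr <- regions$values == config$truncated_region
    lattice <- (row(natural) %% 4L == 0L) & (col(natural) %% 4L == 0L)
    crops <- crops | (in_tr & lattice)
  }
  dev_field <- fields[[2L]]
  developed <- dev_field >= stats::quantile(dev_field, 1 - config$developed_frac)
  dist_crops <- distance_to_class(sdm_grid(crops + 0, cs, c(0, 0)))
  dist_developed <- distance_to_class(sdm_grid(developed + 0, cs, c(0, 0)))
  road <- 3 * rescale01(fields[[3L]])            # km of road per km^2
  snow <- 4 * rescale01(0.5 * rescale01(fields[[2L]]) + 0.5 * north)  # m
  b <- config$beta
  eta <- b["intercept"] + b["natural_prop"] * natural +
    b["log1p_dist_crops"] * log1p(dist_crops$values) +
    b["road_density"] * road + b["snowfall"] * snow +
    b["snowfall_sq"] * snow^2
  psi <- sdm_grid(stats::plogis(eta), cs, c(0, 0))
  stack <- sdm_stack(list(
    natural_prop = sdm_grid(natural, cs, c(0, 0)),
    dist_crops = dist_crops,
    dist_developed = dist_developed,
    road_density = sdm_grid(road, cs, c(0, 0)),
    snowfall = sdm_grid(snow, cs, c(0, 0))
  ))
  ranges <- do.call(rbind, lapply(names(stack), function(v) {
    do.call(rbind, lapply(seq_len(config$n_regions), function(rg) {
      vals <- stack[[v]]$values[regions$values == rg]
      data.frame(variable = v, region = rg, min = min(vals), max = max(vals))
    }))
  }))
  list(stack = stack, regions = regions,
       truth = list(psi = psi, beta = b, ranges = ranges))
}

#' Sample presence points proportional to true suitability
#'
#' Draws `n` distinct cells with probability proportional to the true
#' suitability (times an optional bias mask), placing one uniformly jittered
#' point in each drawn cell; region labels are attached when a partition is
#' given.
#'
#' @param truth the `truth` element of [generate_landscape()] (needs `psi`).
#' @param n number of presences.
#' @param seed integer seed.
#' @param regions optional [sdm_categorical()] region partition.
#' @param bias_mask optional [sdm_grid()] of nonnegative sampling weights.
#' @return occurrence data.frame with `x`, `y` (and `region`).
#' @export
sample_presences <- function(truth, n, seed = 1L, regions = NULL,
                             bias_mask = NULL) {
  psi <- truth$psi
  p <- psi$values
  if (!is.null(bias_mask)) {
    stop_unless_aligned(psi, bias_mask)
    p <- p * bias_mask$values
  }
  p[is.na(p)] <- 0
  pos <- which(p > 0)
  if (sum(p) <= 0) stop("no cells with positive suitability")
  if (n > length(pos))
    stop("`n` exceeds cells with positive suitability (sampling without replacement)")
  nr <- grid_nrows(psi)
  out <- with_seed(seed, {
    pick <- pos[sample.int(length(pos), n, replace = FALSE, prob = p[pos])]
    row <- ((pick - 1L) %% nr) + 1L
    col <- ((pick - 1L) %/% nr) + 1L
    ctr <- cell_center(psi, row, col)
    cs <- psi$cell_size
    data.frame(x = ctr$x + stats::runif(n, -0.5, 0.5) * cs,
               y = ctr$y + stats::runif(n, -0.5, 0.5) * cs)
  })
  if (!is.null(regions)) out <- label_regions(out, regions)
  out
}

#' Write a full synthetic input bundle to a directory
#'
#' Emits covariate grids, region grid and true suitability as ASCII grids,
#' presence points as CSV, and a `scenario.json` echoing the configuration
#' and seeds. Filenames carry a `synthetic_` prefix: these are simulated
#' stand-ins for restricted survey data, not observations.
#'
#' @param config an [scenario_config()].
#' @param dir output directory (created if needed).
#' @return invisible list with the generated `landscape` and `presences`.
#' @export
write_scenario_bundle <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  land <- generate_landscape(config)
  pres <- sample_presences(land$truth, config$n_presences,
                           seed = config$seed_sampling,
                           regions = land$regions)
  for (v in names(land$stack))
    write_ascii_grid(land$stack[[v]],
                     file.path(dir, paste0("synthetic_", v, ".asc")))
  write_ascii_grid(land$regions, file.path(dir, "synthetic_regions.asc"))
  write_ascii_grid(land$truth$psi,
                   file.path(dir, "synthetic_true_suitability.asc"))
  write_occurrences(pres, file.path(dir, "synthetic_presences.csv"),
                    role = "presence")
  cfg <- unclass(config)
  cfg$beta <- as.list(cfg$beta)
  jsonlite::write_json(cfg, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(landscape = land, presences = pres))
}
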