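# Occurrence records are plain data.frames with numeric columns `x`, `y`
# (projected km) and an optional integer `region` column.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Read occurrence points from CSV
#'
#' Expects a header with columns `x,y` and optionally `region` and `role`;
#' coordinates in projected km.
#'
#' @param path CSV path.
#' @return data.frame of occurrence records.
#' @export
read_occurrences <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(d))) stop("occurrence CSV needs x,y columns")
  d
}

#' Write occurrence points to CSV
#' @param occ occurrence data.frame.
#' @param path output path.
#' @param role optional single string (`"presence"` or `"background"`) added
#'   as a `role` column.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path, role = NULL) {
  if (!is.null(role)) occ$role <- role
  utils::write.csv(occ, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach region labels to occurrence points
#' @param occ occurrence data.frame.
#' @param regions an [sdm_categorical()] region partition.
#' @return `occ` with a `region` column (NA outside the partition).
#' @export
label_regions <- function(occ, regions) {
  occ$region <- as.integer(grid_extract(regions, occ$x, occ$y))
  occ
}

#' Thin occurrences to at most one point per grid cell
#'
#' The retained point in each occupied cell is chosen uniformly at random
#' (seeded). Points outside the grid extent or on nodata cells are excluded;
#' the exclusion count is attached as attribute `n_excluded`.
#'
#' @param occ occurrence data.frame.
#' @param grid an [sdm_grid()] defining the thinning cells.
#' @param seed integer seed; same seed, same result.
#' @return thinned occurrence data.frame (original row order preserved).
#' @export
thin_one_per_cell <- function(occ, grid, seed = 1L) {
  idx <- cell_index(grid, occ$x, occ$y)
  on_data <- !is.na(idx$row) &
    !is.na(grid$values[cbind(pmax(idx$row, 1L), pmax(idx$col, 1L))])
  n_excluded <- sum(!on_data)
  occ <- occ[on_data, , drop = FALSE]
  cell <- (idx$col[on_data] - 1L) * grid_nrows(grid) + idx$row[on_data]
  keep <- with_seed(seed, {
    perm <- sample.int(nrow(occ))
    sort(perm[!duplicated(cell[perm])])
  })
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Thin occurrences to a minimum pairwise distance
#'
#' Greedy retention in seeded-random order: a point is kept iff its distance
#' to every already-kept point is at least `d_min`. The result is an
#' approximate maximum independent set; all pairwise distances in the output
#' are >= `d_min`, and every excluded point is within `d_min` of a kept one.
#'
#' @param occ occurrence data.frame.
#' @param d_min minimum distance in km (> 0).
#' @param seed integer seed.
#' @return thinned occurrence data.frame (original row order preserved).
#' @export
thin_min_distance <- function(occ, d_min, seed = 1L) {
  if (d_min <= 0) stop("`d_min` must be positive")
  n <- nrow(occ)
  if (n <= 1L) return(occ)
  ord <- with_seed(seed, sample.int(n))
  kept <- integer(0L)
  kx <- numeric(0L); ky <- numeric(0L)
  d2 <- d_min^2
  for (i in ord) {
    if (!length(kept) ||
        min((kx - occ$x[i])^2 + (ky - occ$y[i])^2) >= d2) {
      kept <- c(kept, i)
      kx <- c(kx, occ$x[i]); ky <- c(ky, occ$y[i])
    }
  }
  out <- occ[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample background (pseudo-absence) points over the valid domain
#'
#' Draws `n` points uniformly over valid cells of `domain` (optionally
#' restricted to one region), placing each point at a uniformly jittered
#' position within its cell. By default cells may repeat (sampling with
#' replacement over cells), matching the plain "n random background points"
#' design; set `replace_cells = FALSE` to forbid duplicate cells.
#'
#' @param domain an [sdm_grid()] whose valid (non-`NA`) cells define the
#'   sampling domain.
#' @param n number of points (>= 1).
#' @param seed integer seed.
#' @param regions optional [sdm_categorical()] region partition.
#' @param restrict optional region label; with `regions`, restricts sampling
#'   to that region.
#' @param replace_cells sample cells with replacement (default TRUE).
#' @return occurrence data.frame with `x`, `y` (and `region` if `regions`
#'   was supplied).
#' @export
sample_background <- function(domain, n, seed = 1L, regions = NULL,
                              restrict = NULL, replace_cells = TRUE) {
  if (n < 1L) stop("`n` must be >= 1")
  ok <- !is.na(domain$values)
  if (!is.null(restrict)) {
    if (is.null(regions)) stop("`restrict` requires `regions`")
    stop_unless_aligned(domain, regions)
    ok <- ok & !is.na(regions$values) & regions$values == restrict
  }
  cells <- which(ok)  # column-major linear indices
  if (!length(cells)) stop("no valid cells to sample from")
  if (!replace_cells && n > length(cells))
    stop("`n` exceeds available distinct cells")
  nr <- grid_nrows(domain)
  out <- with_seed(seed, {
    pick <- cells[sample.int(length(cells), n, replace = replace_cells)]
    row <- ((pick - 1L) %% nr) + 1L
    col <- ((pick - 1L) %/% nr) + 1L
    ctr <- cell_center(domain, row, col)
    cs <- domain$cell_size
    data.frame(x = ctr$x + stats::runif(n, -0.5, 0.5) * cs,
               y = ctr$y + stats::runif(n, -0.5, 0.5) * cs)
  })
  if (!is.null(regions)) out <- label_regions(out, regions)
  out
}

#' Build a presence/background design matrix with balanced class weights
#'
#' Extracts covariates for presence and background points, drops rows with
#' any missing covariate (counts reported), and assigns weights realizing
#' equal total weight for the two classes (prevalence 0.5): presences weigh 1
#' each, background rows weigh `n_presence / n_background` each.
#'
#' @param presences,background occurrence data.frames.
#' @param stack an [sdm_stack()].
#' @param variables character subset of stack names (default all).
#' @return an object of class `sdm_design`: list with `X` (covariate
#'   data.frame), `y` (1 presence / 0 background), `w` (weights), `coords`,
#'   `region`, and `n_dropped` (named count of rows dropped per class).
#' @export
build_design <- function(presences, background, stack,
                         variables = names(stack)) {
  xp <- stack_extract(stack, presences$x, presences$y, variables)
  xb <- stack_extract(stack, background$x, background$y, variables)
  okp <- stats::complete.cases(xp)
  okb <- stats::complete.cases(xb)
  n_dropped <- c(presence = sum(!okp), background = sum(!okb))
  np <- sum(okp); nb <- sum(okb)
  if (np == 0L || nb == 0L)
    stop("no usable presence or background rows after dropping missing covariates")
  X <- rbind(xp[okp, , drop = FALSE], xb[okb, , drop = FALSE])
  rownames(X) <- NULL
  region <- c(
    if ("region" %in% names(presences)) presences$region[okp] else rep(NA_integer_, np),
    if ("region" %in% names(background)) background$region[okb] else rep(NA_integer_, nb)
  )
  structure(list(
    X = X,
    y = c(rep(1L, np), rep(0L, nb)),
    w = c(rep(1, np), rep(np / nb, nb)),
    coords = data.frame(
      x = c(presences$x[okp], background$x[okb]),
      y = c(presences$y[okp], background$y[okb])
    ),
    region = region,
    variables = variables,
    n_dropped = n_dropped
  ), class = "sdm_design")
}

#' @export
print.sdm_design <- function(x, ...) {
  cat(sprintf("<sdm_design> %d presences, %d background, %d variables\n",
              sum(x$y == 1L), sum(x$y == 0L), ncol(x$X)))
  invisible(x)
}

#' Subsample regional occurrence sets to a common size
#'
#' Every region is downsampled (uniformly, seeded) to the smallest region's
#' count, giving each region equal weight in transferability comparisons; the
#' smallest region is returned unchanged.
#'
#' @param occ_by_region named list of occurrence data.frames (>= 2 regions,
#'   each non-empty).
#' @param seed integer seed.
#' @return named list of occurrence data.frames, all with equal row counts.
#' @export
subsample_balanced <- function(occ_by_region, seed = 1L) {
  if (length(occ_by_region) < 2L) stop("need at least 2 regions")
  counts <- vapply(occ_by_region, nrow, integer(1L))
  if (any(counts == 0L)) stop("every region must be non-empty")
  n_min <- min(counts)
  with_seed(seed, lapply(occ_by_region, function(d) {
    if (nrow(d) == n_min) return(d)
    out <- d[sort(sample.int(nrow(d), n_min)), , drop = FALSE]
    rownames(out) <- NULL
    out
  }))
}
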