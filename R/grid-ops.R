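#' Aggregate a fine categorical grid to class proportions
#'
#' Coarsens a categorical grid by an integer factor, each coarse cell holding
#' the fraction of valid fine cells in its `factor` x `factor` block whose
#' class belongs to `target_classes` (e.g. proportion of natural cover at
#' 1-km scale from a 30-m land-cover product). Trailing partial blocks are
#' dropped, which avoids proportion bias from undersized blocks; because the
#' origin is the lower-left corner and partial rows are dropped at the
#' southern/eastern edge, the origin shifts north accordingly.
#'
#' @param fine an [sdm_categorical()].
#' @param target_classes integer class codes to count (non-empty).
#' @param factor positive integer aggregation factor.
#' @return an [sdm_grid()] of proportions in `[0, 1]`; blocks with no valid
#'   fine cell are nodata.
#' @export
aggregate_proportion <- function(fine, target_classes, factor) {
  if (length(target_classes) == 0L) stop("`target_classes` must be non-empty")
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be a positive integer")
  nr <- grid_nrows(fine); nc <- grid_ncols(fine)
  nr2 <- nr %/% factor; nc2 <- nc %/% factor
  if (nr2 < 1L || nc2 < 1L) stop("grid smaller than aggregation factor")
  v <- fine$values[seq_len(nr2 * factor), seq_len(nc2 * factor), drop = FALSE]
  valid <- !is.na(v)
  hit <- valid & matrix(v %in% target_classes, nrow(v), ncol(v))
  # block id for every fine cell, column-major over the coarse grid
  bi <- rep(seq_len(nr2), each = factor)
  bj <- rep(seq_len(nc2), each = factor)
  block <- matrix(bi, nrow(v), ncol(v)) +
    matrix((bj - 1L) * nr2, nrow(v), ncol(v), byrow = TRUE)
  n_valid <- tabulate(block[valid], nbins = nr2 * nc2)
  n_hit <- tabulate(block[hit], nbins = nr2 * nc2)
  out <- ifelse(n_valid > 0L, n_hit / n_valid, NA_real_)
  cs2 <- fine$cell_size * factor
  y0 <- fine$origin[2L] + (nr - nr2 * factor) * fine$cell_size
  sdm_grid(matrix(out, nr2, nc2), cs2, c(fine$origin[1L], y0))
}

# 1-D squared-distance transform (lower envelope of parabolas); f may
# contain Inf for "no source here"; exact, O(n).
dt1d <- function(f) {
  n <- length(f)
  d <- rep(Inf, n)
  fin <- which(is.finite(f))
  if (!length(fin)) return(d)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- fin[1L]; z[1L] <- -Inf; z[2L] <- Inf
  if (length(fin) > 1L) for (q in fin[-1L]) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * (q - v[k]))
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * (q - v[k]))
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Euclidean distance to the nearest target cell
#'
#' Exact Euclidean distance (km, between cell centers) from every valid cell
#' to the nearest cell where `target_mask` equals 1, computed with the
#' two-pass separable squared-distance transform. Target cells hold 0.
#'
#' @param target_mask an [sdm_grid()] of 0/1 values (`NA` = nodata; nodata
#'   cells are never targets and stay nodata in the output).
#' @return an [sdm_grid()] of distances in km.
#' @export
distance_to_class <- function(target_mask) {
  v <- target_mask$values
  tgt <- !is.na(v) & v == 1
  if (!any(tgt)) stop("no target cells: distance undefined")
  f <- matrix(Inf, nrow(v), ncol(v))
  f[tgt] <- 0
  # columns then rows; separability of squared Euclidean distance
  f <- apply(f, 2L, dt1d)
  f <- t(apply(f, 1L, dt1d))
  out <- sqrt(f) * target_mask$cell_size
  out[is.na(v)] <- NA_real_
  sdm_grid(out, target_mask$cell_size, target_mask$origin)
}

#' Pairwise Pearson correlation matrix of stack variables
#'
#' Computed over cells jointly valid in every member. Zero-variance
#' variables get `NA` off-diagonal entries (flagged with a warning), never a
#' silent 0.
#'
#' @param stack an [sdm_stack()] with at least two variables.
#' @param cells optional logical matrix selecting cells to use.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(stack, cells = NULL) {
  if (length(stack) < 2L) stop("need at least two variables")
  ok <- do.call(joint_valid, unname(as.list(stack)))
  if (!is.null(cells)) ok <- ok & cells
  if (sum(ok) < 3L) stop("need at least 3 jointly valid cells")
  m <- vapply(stack, function(g) g$values[ok], numeric(sum(ok)))
  sds <- apply(m, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(m))
  if (any(sds == 0)) {
    warning("zero-variance variable(s): ",
            paste(names(stack)[sds == 0], collapse = ", "),
            "; correlations undefined (NA)")
  }
  diag(r) <- 1
  r
}

#' Enumerate variable subsets free of strongly correlated pairs
#'
#' All non-empty subsets of `variables` that contain no pair with
#' `|r| >= r_threshold`, in lexicographic order of variable positions. This
#' realizes the "all possible combinations, never including two correlated
#' variables in the same model" screening design.
#'
#' @param variables character vector of variable names.
#' @param corr correlation matrix with dimnames covering `variables`.
#' @param r_threshold absolute-correlation cutoff in (0, 1]; default 0.7, the
#'   common SDM convention.
#' @return list of character vectors (subsets).
#' @export
admissible_variable_sets <- function(variables, corr, r_threshold = 0.7) {
  if (r_threshold <= 0 || r_threshold > 1) stop("`r_threshold` must be in (0, 1]")
  n <- length(variables)
  if (!all(variables %in% rownames(corr)))
    stop("`corr` must cover all variables")
  r <- abs(corr[variables, variables, drop = FALSE])
  incompatible <- !is.na(r) & r >= r_threshold
  diag(incompatible) <- FALSE
  out <- vector("list", 0L)
  emit <- function(prefix, start) {
    for (i in start:n) {
      if (any(incompatible[prefix, i])) next
      s <- c(prefix, i)
      out[[length(out) + 1L]] <<- variables[s]
      if (i < n) emit(s, i + 1L)
    }
  }
  emit(integer(0L), 1L)
  out
}

#' Pearson correlation between two aligned maps
#'
#' Computed over jointly valid cells; used e.g. to compare suitability maps
#' built from differently thinned occurrence sets.
#'
#' @param a,b aligned [sdm_grid()]s.
#' @return Pearson r, or `NA` (with a warning) if either map has zero
#'   variance over the joint support.
#' @export
map_correlation <- function(a, b) {
  ok <- joint_valid(a, b)
  if (sum(ok) < 3L) stop("need at least 3 jointly valid cells")
  x <- a$values[ok]; y <- b$values[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: map correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}
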