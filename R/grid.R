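#' Gridded raster of real values
#'
#' A minimal in-memory raster: a numeric matrix plus georeferencing. Cells
#' with `NA` are nodata; the `NA` pattern is the authoritative validity mask.
#' Row 1 of `values` is the northernmost row (standard raster file order);
#' `origin` is the lower-left corner of the grid in projected km.
#'
#' Point-to-cell assignment uses half-open intervals: a point with
#' `x0 + j*cell_size <= x < x0 + (j+1)*cell_size` falls in column `j + 1`,
#' and likewise for y measured from the lower-left corner.
#'
#' @param values numeric matrix (row 1 = north). `NA` marks nodata.
#' @param cell_size cell side length in km (> 0).
#' @param origin numeric length-2, `(x0, y0)` lower-left corner in km.
#' @return an object of class `sdm_grid`.
#' @export
sdm_grid <- function(values, cell_size = 1, origin = c(0, 0)) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (length(origin) != 2L || anyNA(origin)) stop("`origin` must be (x0, y0)")
  if (any(is.infinite(values), na.rm = TRUE))
    stop("grid values must be finite where not NA")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin)),
    class = "sdm_grid"
  )
}

#' Categorical raster of integer class codes
#'
#' Same georeferencing as [sdm_grid()]; values are integer class codes drawn
#' from a declared code table (e.g. natural / crops / developed / water land
#' cover classes, or region labels).
#'
#' @inheritParams sdm_grid
#' @param codes named integer vector declaring the admissible class codes.
#' @return an object of class `sdm_categorical` (inherits `sdm_grid`).
#' @export
sdm_categorical <- function(values, cell_size = 1, origin = c(0, 0), codes) {
  if (missing(codes)) {
    codes <- sort(unique(as.integer(values[!is.na(values)])))
    names(codes) <- as.character(codes)
  }
  if (!all(values[!is.na(values)] %in% codes))
    stop("categorical grid contains values outside the declared code table")
  g <- sdm_grid(values, cell_size, origin)
  g$codes <- as.integer(codes)
  names(g$codes) <- names(codes)
  class(g) <- c("sdm_categorical", "sdm_grid")
  g
}

#' @export
print.sdm_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<%s> %d x %d cells, %.3g km cells, origin (%.6g, %.6g)\n",
              class(x)[1L], nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1L], x$origin[2L]))
  if (length(v))
    cat(sprintf("  valid: %d cells, range [%.4g, %.4g]\n", length(v),
                min(v), max(v)))
  else cat("  no valid cells\n")
  invisible(x)
}

grid_nrows <- function(g) nrow(g$values)
grid_ncols <- function(g) ncol(g$values)

#' Do two grids share dimensions, cell size, and origin?
#' @param a,b grids.
#' @return logical scalar.
#' @export
grids_aligned <- function(a, b) {
  nrow(a$values) == nrow(b$values) && ncol(a$values) == ncol(b$values) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stop_unless_aligned <- function(a, b) {
  if (!grids_aligned(a, b)) stop("grids are not aligned")
  invisible(TRUE)
}

#' Map point coordinates to cell row/column indices
#'
#' Half-open cell intervals; points outside the grid extent get `NA` indices.
#'
#' @param g an [sdm_grid()].
#' @param x,y point coordinates in km.
#' @return data.frame with integer columns `row`, `col` (`NA` when outside).
#' @export
cell_index <- function(g, x, y) {
  cs <- g$cell_size
  j <- floor((x - g$origin[1L]) / cs) + 1L
  i_from_bottom <- floor((y - g$origin[2L]) / cs) + 1L
  i <- grid_nrows(g) - i_from_bottom + 1L
  bad <- j < 1L | j > grid_ncols(g) | i < 1L | i > grid_nrows(g) |
    is.na(x) | is.na(y)
  i[bad] <- NA_integer_
  j[bad] <- NA_integer_
  data.frame(row = as.integer(i), col = as.integer(j))
}

#' Cell-center coordinates for row/column indices
#' @param g an [sdm_grid()].
#' @param row,col integer indices (row 1 = north).
#' @return data.frame with columns `x`, `y` in km.
#' @export
cell_center <- function(g, row, col) {
  cs <- g$cell_size
  x <- g$origin[1L] + (col - 0.5) * cs
  y <- g$origin[2L] + (grid_nrows(g) - row + 0.5) * cs
  data.frame(x = x, y = y)
}

#' Extract grid values at point locations
#' @param g an [sdm_grid()].
#' @param x,y point coordinates in km.
#' @return numeric vector; `NA` for points outside the grid or on nodata.
#' @export
grid_extract <- function(g, x, y) {
  idx <- cell_index(g, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- g$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Named stack of mutually aligned covariate grids
#'
#' @param ... named [sdm_grid()] objects, or a single named list of them.
#' @return an object of class `sdm_stack`: a named list of aligned grids.
#' @export
sdm_stack <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && !inherits(gs[[1L]], "sdm_grid")) gs <- gs[[1L]]
  if (is.null(names(gs)) || any(names(gs) == "") || anyDuplicated(names(gs)))
    stop("stack members must have unique names")
  for (g in gs) if (!inherits(g, "sdm_grid")) stop("stack members must be sdm_grid")
  for (g in gs[-1L]) stop_unless_aligned(gs[[1L]], g)
  structure(gs, class = "sdm_stack")
}

#' @export
print.sdm_stack <- function(x, ...) {
  cat(sprintf("<sdm_stack> %d variables: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  cat(sprintf("  %d x %d cells, %.3g km\n", nrow(x[[1L]]$values),
              ncol(x[[1L]]$values), x[[1L]]$cell_size))
  invisible(x)
}

#' Extract covariate rows for point locations from a stack
#' @param stack an [sdm_stack()].
#' @param x,y point coordinates in km.
#' @param variables character subset of stack names (default all).
#' @return data.frame, one column per variable; `NA` on nodata/outside cells.
#' @export
stack_extract <- function(stack, x, y, variables = names(stack)) {
  if (!all(variables %in% names(stack)))
    stop("unknown variables: ",
         paste(setdiff(variables, names(stack)), collapse = ", "))
  out <- lapply(stack[variables], grid_extract, x = x, y = y)
  as.data.frame(out, optional = FALSE)
}

#' Jointly valid cells of two or more grids
#' @param ... aligned grids.
#' @return logical matrix, TRUE where every grid has data.
#' @export
joint_valid <- function(...) {
  gs <- list(...)
  ok <- !is.na(gs[[1L]]$values)
  for (g in gs[-1L]) {
    stop_unless_aligned(gs[[1L]], g)
    ok <- ok & !is.na(g$values)
  }
  ok
}
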