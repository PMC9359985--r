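#' Read an ESRI ASCII grid file
#'
#' Parses the standard `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`
#' header followed by row-major values (first data row = northernmost).
#' `NODATA_value` cells become `NA`.
#'
#' @param path file path.
#' @param categorical if TRUE return an [sdm_categorical()].
#' @return an [sdm_grid()] (or [sdm_categorical()]).
#' @export
read_ascii_grid <- function(path, categorical = FALSE) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("missing ASCII grid header fields: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d", nr * nc, length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  org <- c(hdr$xllcorner, hdr$yllcorner)
  if (categorical) sdm_categorical(m, hdr$cellsize, org)
  else sdm_grid(m, hdr$cellsize, org)
}

#' Write a grid as an ESRI ASCII grid file
#'
#' Round-trips value-exactly with [read_ascii_grid()] (values are printed
#' with 17 significant digits, enough to reproduce doubles).
#'
#' @param g an [sdm_grid()].
#' @param path output path.
#' @param nodata value standing in for `NA` cells (must not collide with data).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(g, path, nodata = -9999) {
  v <- g$values
  if (any(v == nodata, na.rm = TRUE))
    stop("nodata sentinel collides with a data value")
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", g$origin[1L]),
    sprintf("yllcorner %.10g", g$origin[2L]),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  v[is.na(v)] <- nodata
  rows <- apply(v, 1L, function(r) paste(formatC(r, digits = 17, format = "g"),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
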