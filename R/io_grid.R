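#' Construct a raster grid
#'
#' A regular grid in a projected equal-area frame. `values` is stored
#' row-major from the north-west corner (row 1 = northernmost row), matching
#' the ESRI ASCII grid layout. Coordinates are in the same units as the
#' projection (km here); `cell_size` defaults to 1 km so one cell is 1 km2.
#'
#' @param values Numeric matrix (rows = north to south).
#' @param xll,yll Coordinates of the lower-left (south-west) corner.
#' @param cell_size Cell side length, same units as the coordinates.
#' @param nodata Sentinel value for missing cells.
#' @return A `cpi_grid` object.
#' @export
raster_grid <- function(values, xll, yll, cell_size = 1, nodata = -9999) {
  values <- as.matrix(values)
  if (nrow(values) < 1 || ncol(values) < 1) {
    stop_validation("raster grid must have positive dimensions")
  }
  if (any(!is.finite(values[values != nodata]))) {
    stop_validation("raster grid values must be finite or the nodata sentinel")
  }
  structure(list(values = values, xll = xll, yll = yll,
                 cell_size = cell_size, nodata = nodata),
            class = "cpi_grid")
}

#' @export
print.cpi_grid <- function(x, ...) {
  cat(sprintf("<raster grid %d x %d, cell %g, origin (%g, %g), nodata %g>\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$xll, x$yll, x$nodata))
  invisible(x)
}

# Cell-center coordinates; returns list(x = ncol vector, y = nrow vector),
# y ordered north -> south to match row order.
grid_cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  list(x = grid$xll + (seq_len(nc) - 0.5) * cs,
       y = grid$yll + (nr - seq_len(nr) + 0.5) * cs)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file with the standard six-line header
#'   (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#'   `NODATA_value`).
#' @return A [raster_grid()].
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop_schema("file not found: %s", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(req, names(hdr))
  if (length(miss)) {
    stop_schema("ASCII grid '%s' missing header field(s): %s",
                path, paste(miss, collapse = ", "))
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop_validation("ASCII grid '%s': expected %d values, found %d",
                    path, hdr$ncols * hdr$nrows, length(vals))
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  raster_grid(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
              cell_size = hdr$cellsize, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' Values are written with up to 17 significant digits so that a
#' write-then-read round trip reproduces the matrix bit-exactly.
#'
#' @param grid A [raster_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "cpi_grid"))
  hdr <- c(sprintf("ncols %d", ncol(grid$values)),
           sprintf("nrows %d", nrow(grid$values)),
           sprintf("xllcorner %.17g", grid$xll),
           sprintf("yllcorner %.17g", grid$yll),
           sprintf("cellsize %.17g", grid$cell_size),
           sprintf("NODATA_value %.17g", grid$nodata))
  body <- apply(grid$values, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
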