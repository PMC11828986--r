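# Minimal single-band raster container. North-up, square cells, planar
# meters. Row 1 of `values` is the northernmost row (as rendered on a map);
# (xll, yll) is the lower-left corner of the grid extent.

#' Create a raster grid
#'
#' A lightweight single-band raster in projected planar meters. Cells are
#' square; `values` is a numeric or integer matrix whose first row is the
#' top (north) row. Nodata is represented as `NA`.
#'
#' @param values numeric/integer matrix, row 1 = northernmost row.
#' @param xll,yll coordinates (meters) of the lower-left corner of the extent.
#' @param cellsize cell edge length in meters (> 0).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xll, yll, cellsize) {
  stopifnot(is.matrix(values), is.numeric(cellsize), length(cellsize) == 1L,
            cellsize > 0, is.finite(xll), is.finite(yll))
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize,
         nrow = nrow(values), ncol = ncol(values)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d cells @ %g m, origin (%g, %g)\n",
              x$nrow, x$ncol, x$cellsize, x$xll, x$yll))
  v <- x$values[is.finite(x$values)]
  if (length(v)) {
    cat(sprintf("  finite cells: %d (range %g..%g), NA: %d\n",
                length(v), min(v), max(v), sum(is.na(x$values))))
  }
  invisible(x)
}

#' Cell centroid coordinates
#'
#' @param grid a `raster_grid`.
#' @return list with `x` (length ncol, west to east) and `y` (length nrow,
#'   north to south, matching row order of `values`).
#' @export
cell_centers <- function(grid) {
  list(
    x = grid$xll + (seq_len(grid$ncol) - 0.5) * grid$cellsize,
    y = grid$yll + (grid$nrow - seq_len(grid$nrow) + 0.5) * grid$cellsize
  )
}

#' Test whether two grids share geometry
#' @param a,b `raster_grid` objects.
#' @param tol coordinate tolerance in meters.
#' @return logical.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$cellsize - b$cellsize) < tol &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol
}

#' Read a single-band ESRI ASCII grid
#'
#' Reads the plain-text `.asc` raster format (ncols/nrows/xllcorner/
#' yllcorner/cellsize/NODATA_value header followed by rows top-down).
#' Headers using `dx`/`dy` (non-square cells) are refused: the pipeline
#' assumes square cells. Nodata values map to `NA`.
#'
#' @param path file path.
#' @return a `raster_grid`; attribute `n_nodata` carries the nodata count.
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^\\s*[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(kv) != 2L) stop("malformed ASCII grid header line: ", lines[i])
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  if (any(c("dx", "dy") %in% names(hdr)))
    stop("non-square cells (dx/dy header) are not supported")
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header missing fields: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else NA_real_
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("ASCII grid has %d values, expected %d", length(vals), nr * nc))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  n_nodata <- 0L
  if (!is.na(nodata)) {
    nd <- m == nodata
    n_nodata <- sum(nd)
    m[nd] <- NA_real_
  }
  g <- raster_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
  attr(g, "n_nodata") <- n_nodata
  g
}

#' Write a raster grid as ESRI ASCII
#'
#' `NA` and non-finite values are written as the nodata value.
#'
#' @param grid a `raster_grid`.
#' @param path output file path.
#' @param nodata numeric nodata sentinel written to the file.
#' @return `path`, invisibly.
#' @export
write_asc <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "raster_grid"))
  m <- grid$values
  m[!is.finite(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", grid$ncol),
    sprintf("nrows %d", grid$nrow),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  # 17 significant digits: doubles round-trip bit-exactly through text
  rows <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
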