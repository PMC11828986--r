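# Land-use recoding and dasymetric population disaggregation.
#
# Raw land-use rasters carry six morphology classes (integer codes below).
# They are collapsed to three analysis classes: informal residential
# (atomistic + informal subdivision), formal residential (formal
# subdivision + housing project) and other (open space, non-residential,
# nodata). Nodata never maps to a residential class.

#' Land-use class codes
#'
#' Integer codes for the six-class morphology raster and the three-class
#' recoded raster.
#'
#' @format named integer vectors.
#' @export
LANDUSE_CODES <- c(atomistic = 1L, informal_subdivision = 2L,
                   formal_subdivision = 3L, housing_project = 4L,
                   open_space = 5L, non_residential = 6L)

#' @rdname LANDUSE_CODES
#' @export
RECODED_CODES <- c(informal = 1L, formal = 2L, other = 3L)

#' Recode a six-class land-use raster to informal/formal/other
#'
#' Mapping: atomistic, informal_subdivision -> informal; formal_subdivision,
#' housing_project -> formal; open_space, non_residential, nodata -> other.
#' Raster geometry is unchanged. Recoding an already-recoded raster is a
#' no-op (identity extension), so the operation is idempotent.
#'
#' @param lu a `raster_grid` of `LANDUSE_CODES` values (NA = nodata).
#' @return a `raster_grid` of `RECODED_CODES` with class `recoded_landuse`.
#' @export
recode_landuse <- function(lu) {
  stopifnot(inherits(lu, "raster_grid"))
  if (inherits(lu, "recoded_landuse")) return(lu)
  v <- lu$values
  known <- v %in% LANDUSE_CODES | is.na(v)
  if (!all(known)) {
    bad <- sort(unique(v[!known]))
    stop("unknown land-use codes: ", paste(bad, collapse = ", "))
  }
  map <- c(RECODED_CODES[["informal"]], RECODED_CODES[["informal"]],
           RECODED_CODES[["formal"]], RECODED_CODES[["formal"]],
           RECODED_CODES[["other"]], RECODED_CODES[["other"]])
  out <- matrix(map[v], nrow(v), ncol(v))
  out[is.na(v)] <- RECODED_CODES[["other"]]
  g <- raster_grid(out, lu$xll, lu$yll, lu$cellsize)
  class(g) <- c("recoded_landuse", class(g))
  g
}

# Index of the coarse population cell containing each fine-cell centroid
# (half-open cell intervals, origin-anchored). Returns NA outside the
# population grid extent.
.pop_cell_index <- function(rlu, pop) {
  cc <- cell_centers(rlu)
  col_p <- floor((cc$x - pop$xll) / pop$cellsize) + 1L
  row_from_bottom <- floor((cc$y - pop$yll) / pop$cellsize) + 1L
  row_p <- pop$nrow - row_from_bottom + 1L
  col_p[col_p < 1L | col_p > pop$ncol] <- NA_integer_
  row_p[row_p < 1L | row_p > pop$nrow] <- NA_integer_
  # linear index matrix [fine rows x fine cols] into pop$values
  outer(row_p, col_p, function(r, co) (co - 1L) * pop$nrow + r)
}

#' Disaggregate a coarse population raster onto the fine land-use grid
#'
#' Each coarse (typically 100-m) population cell is split over the fine
#' (typically 5-m) cells whose centroids fall inside it. Mode
#' `"uniform_all"` splits equally over all such subcells regardless of
#' class (the uniform-distribution assumption); `"residential_only"` splits
#' equally over subcells with a residential class (informal or formal) —
#' coarse cells with no residential subcell fall back to their `other`
#' subcells and are counted in attribute `n_fallback_cells`. Both modes
#' conserve the source total over the covered extent; source population in
#' cells with no subcell at all is reported in attribute `unallocated`.
#' Nodata source cells contribute 0.
#'
#' @param pop coarse population `raster_grid` (counts per cell, NA = nodata).
#' @param rlu a `recoded_landuse` raster (the target grid).
#' @param mode `"uniform_all"` or `"residential_only"`.
#' @return object of class `cell_population`: list with `grid`, `pop`
#'   (matrix of persons per fine cell) and `class` (matrix of
#'   `RECODED_CODES`).
#' @export
disaggregate <- function(pop, rlu,
                         mode = c("uniform_all", "residential_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pop, "raster_grid"), inherits(rlu, "recoded_landuse"))
  pv <- as.numeric(pop$values)
  if (any(pv < 0, na.rm = TRUE)) stop("negative population counts in source")
  pv[is.na(pv)] <- 0

  k <- .pop_cell_index(rlu, pop)       # coarse cell per fine cell
  cls <- rlu$values
  valid <- !is.na(k)
  nK <- length(pv)

  count_in <- function(sel) tabulate(k[valid & sel], nbins = nK)
  n_all <- count_in(TRUE)

  if (mode == "uniform_all") {
    denom <- n_all
    weight_sel <- valid
    n_fallback <- 0L
  } else {
    res_sel <- cls %in% RECODED_CODES[c("informal", "formal")]
    n_res <- count_in(res_sel)
    fallback <- n_res == 0L & n_all > 0L & pv > 0
    n_fallback <- sum(fallback)
    denom <- ifelse(n_res > 0L, n_res, n_all)
    # fine cell receives weight if residential, or if its coarse cell fell back
    weight_sel <- valid & (res_sel | matrix(fallback[k], nrow(k), ncol(k)))
  }

  popm <- matrix(0, rlu$nrow, rlu$ncol)
  idx <- which(weight_sel)
  kk <- k[idx]
  share <- pv[kk] / denom[kk]
  share[!is.finite(share)] <- 0
  popm[idx] <- share

  covered <- n_all > 0L
  unallocated <- sum(pv[!covered])

  out <- structure(list(grid = raster_grid(matrix(0, rlu$nrow, rlu$ncol),
                                           rlu$xll, rlu$yll, rlu$cellsize),
                        pop = popm, class = cls, mode = mode),
                   class = "cell_population")
  attr(out, "unallocated") <- unallocated
  attr(out, "n_fallback_cells") <- n_fallback
  out
}

#' @export
print.cell_population <- function(x, ...) {
  ct <- class_totals(x)
  cat(sprintf(
    "<cell_population> %d x %d cells @ %g m (mode %s)\n",
    x$grid$nrow, x$grid$ncol, x$grid$cellsize, x$mode))
  cat(sprintf("  informal %.1f, formal %.1f, other %.1f persons (share informal %.3f)\n",
              ct$informal, ct$formal, ct$other,
              if (is.na(ct$informal_share)) NA else ct$informal_share))
  invisible(x)
}

#' Population totals per settlement class
#'
#' The reported "city total" follows the convention of counting only
#' residential land uses: informal + formal. The informal share is
#' informal / (informal + formal); it is `NA` (flagged) when the
#' residential total is zero.
#'
#' @param cp a `cell_population`.
#' @return list with `informal`, `formal`, `other`, `residential_total`,
#'   `city_total` (= residential total), `informal_share` and
#'   `share_defined`.
#' @export
class_totals <- function(cp) {
  stopifnot(inherits(cp, "cell_population"))
  s <- function(code) sum(cp$pop[cp$class == code], na.rm = TRUE)
  informal <- s(RECODED_CODES[["informal"]])
  formal <- s(RECODED_CODES[["formal"]])
  other <- s(RECODED_CODES[["other"]])
  res <- informal + formal
  list(informal = informal, formal = formal, other = other,
       residential_total = res, city_total = res,
       informal_share = if (res > 0) informal / res else NA_real_,
       share_defined = res > 0)
}
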