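# Spatial accessibility (SA) curves: share of a (class-filtered) population
# whose travel time to the nearest facility is at or below t minutes, for
# integer t = 1..max_minutes.

#' Compute an SA curve
#'
#' `shares[t]` is the population of filtered cells with travel time <= t
#' divided by the total population of filtered cells (closed threshold).
#' The `"all"` filter covers residential population only (informal +
#' formal); `other`-class population is excluded from every denominator,
#' matching the convention that city totals count residential land uses.
#' A zero-population filter yields an undefined-curve sentinel
#' (`shares = NA`, `undefined = TRUE`).
#'
#' @param cp a `cell_population`.
#' @param field a `travel_time_field` on the same grid.
#' @param class_filter `"all"`, `"informal"` or `"formal"`.
#' @param max_minutes curve horizon (default 120).
#' @param city city label carried into outputs.
#' @param speed_factor speed-scenario label carried into outputs.
#' @return object of class `sa_curve`: list with `shares` (length
#'   `max_minutes`, indexed by minute), `denom` (class population),
#'   `undefined`, plus labels.
#' @export
sa_curve <- function(cp, field, class_filter = c("all", "informal", "formal"),
                     max_minutes = 120L, city = "", speed_factor = 1.0) {
  class_filter <- match.arg(class_filter)
  stopifnot(inherits(cp, "cell_population"),
            inherits(field, "raster_grid"))
  if (!same_grid(cp$grid, field))
    stop("cell population and travel-time field are on different grids")
  max_minutes <- as.integer(max_minutes)

  sel <- switch(class_filter,
    all = cp$class %in% RECODED_CODES[c("informal", "formal")],
    informal = cp$class == RECODED_CODES[["informal"]],
    formal = cp$class == RECODED_CODES[["formal"]])
  w <- cp$pop[sel]
  m <- field$values[sel]
  denom <- sum(w)
  if (!(denom > 0)) {
    return(structure(list(city = city, class_filter = class_filter,
                          speed_factor = speed_factor,
                          shares = rep(NA_real_, max_minutes),
                          denom = 0, undefined = TRUE),
                     class = "sa_curve"))
  }
  # minutes <= t for integer t iff ceiling(minutes) <= t; times of exactly
  # 0 count from t = 1 on; +Inf (and anything beyond the horizon) never.
  bin <- ceiling(m)
  keep <- is.finite(bin) & bin <= max_minutes & w > 0
  mass <- numeric(max_minutes)
  if (any(keep)) {
    rs <- rowsum(w[keep], pmax(as.integer(bin[keep]), 1L))
    mass[as.integer(rownames(rs))] <- rs[, 1]
  }
  # clamp the rounding tail of cumsum: shares are a probability by contract
  shares <- pmin(cumsum(mass) / denom, 1)
  structure(list(city = city, class_filter = class_filter,
                 speed_factor = speed_factor, shares = shares,
                 denom = denom, undefined = FALSE),
            class = "sa_curve")
}

#' @export
print.sa_curve <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("<sa_curve> %s/%s: undefined (zero class population)\n",
                x$city, x$class_filter))
  } else {
    cat(sprintf(
      "<sa_curve> %s/%s @ factor %.1f: SA(15)=%.3f SA(30)=%.3f SA(60)=%.3f SA(%d)=%.3f\n",
      x$city, x$class_filter, x$speed_factor,
      x$shares[min(15, length(x$shares))],
      x$shares[min(30, length(x$shares))],
      x$shares[min(60, length(x$shares))],
      length(x$shares), x$shares[length(x$shares)]))
  }
  invisible(x)
}

bundle_key <- function(class_filter, factor) {
  sprintf("%s@%.6g", class_filter, factor)
}

#' Run speed-sensitivity scenarios
#'
#' Computes the SA curves for classes all/informal/formal at every speed
#' factor in the configuration. Because on- and off-network travel use the
#' same speed, travel times at factor f equal the base-speed times divided
#' by f exactly, so scenario fields are obtained by rescaling the base
#' field; results are identical to recomputing from scratch.
#'
#' @param cp a `cell_population`.
#' @param base_field `travel_time_field` at the base speed (factor 1.0).
#' @param config a `city_config`.
#' @return object of class `curve_bundle`: list of `sa_curve`s keyed
#'   `"<class>@<factor>"` plus `factors`, `classes`, `city`.
#' @export
run_speed_scenarios <- function(cp, base_field, config) {
  stopifnot(inherits(config, "city_config"))
  classes <- c("all", "informal", "formal")
  curves <- list()
  for (f in config$speed_factors) {
    field_f <- scale_field(base_field, f)
    for (cl in classes) {
      curves[[bundle_key(cl, f)]] <-
        sa_curve(cp, field_f, cl, config$max_minutes,
                 city = config$city_name, speed_factor = f)
    }
  }
  structure(list(curves = curves, factors = config$speed_factors,
                 classes = classes, city = config$city_name),
            class = "curve_bundle")
}

#' Extract one curve from a bundle
#' @param bundle a `curve_bundle`.
#' @param class_filter curve class.
#' @param factor speed factor (must be one of the bundle's factors).
#' @return an `sa_curve`.
#' @export
bundle_curve <- function(bundle, class_filter, factor = 1.0) {
  stopifnot(inherits(bundle, "curve_bundle"))
  cv <- bundle$curves[[bundle_key(class_filter, factor)]]
  if (is.null(cv)) stop("no curve for ", class_filter, " @ factor ", factor)
  cv
}

#' @export
print.curve_bundle <- function(x, ...) {
  cat(sprintf("<curve_bundle> %s: %d curves (%s x factors %s)\n",
              x$city, length(x$curves), paste(x$classes, collapse = "/"),
              paste(x$factors, collapse = "/")))
  invisible(x)
}

#' Threshold report with speed-scenario brackets
#'
#' For a bare `sa_curve`, returns the shares at the requested minutes. For
#' a `curve_bundle`, reports the factor-1.0 share with the `[lo-hi]`
#' bracket over the slow/fast scenarios (min and max across factors).
#'
#' @param x an `sa_curve` or `curve_bundle`.
#' @param thresholds integer minutes within the curve horizon.
#' @param class_filter class to report when `x` is a bundle.
#' @return data.frame with columns `threshold_min`, `share` (and `lo`,
#'   `hi` for bundles).
#' @export
threshold_report <- function(x, thresholds = c(15L, 30L, 60L),
                             class_filter = "all") {
  thresholds <- as.integer(thresholds)
  if (inherits(x, "sa_curve")) {
    if (any(thresholds < 1L) || any(thresholds > length(x$shares)))
      stop("thresholds outside curve horizon")
    return(data.frame(threshold_min = thresholds,
                      share = x$shares[thresholds]))
  }
  stopifnot(inherits(x, "curve_bundle"))
  mid <- bundle_curve(x, class_filter, 1.0)
  if (any(thresholds < 1L) || any(thresholds > length(mid$shares)))
    stop("thresholds outside curve horizon")
  per_factor <- vapply(x$factors, function(f)
    bundle_curve(x, class_filter, f)$shares[thresholds],
    numeric(length(thresholds)))
  per_factor <- matrix(per_factor, nrow = length(thresholds))
  data.frame(threshold_min = thresholds,
             share = mid$shares[thresholds],
             lo = apply(per_factor, 1L, min),
             hi = apply(per_factor, 1L, max))
}

#' Share of population outside 2 hours
#'
#' The complement of the curve's terminal share, `1 - shares[horizon]`.
#' Unreachable cells (travel time `+Inf`) are never clipped to the horizon,
#' so this is exactly the population with travel time above 2 h.
#'
#' @param curve an `sa_curve` with a 120-minute horizon.
#' @return share in `[0, 1]`, or `NA` for an undefined curve.
#' @export
pct_outside_2h <- function(curve) {
  stopifnot(inherits(curve, "sa_curve"))
  if (curve$undefined) return(NA_real_)
  1 - curve$shares[length(curve$shares)]
}

#' Surgical-care benchmark
#'
#' TRUE iff at least 80% of the population reaches surgical care within 2 h
#' (closed inequality: exactly 0.80 passes). Meaningful on a curve computed
#' with the hospitals facility set.
#'
#' @param curve an `sa_curve` over 120 minutes for the hospitals set.
#' @return logical (`NA` for an undefined curve).
#' @export
surgical_benchmark <- function(curve) {
  stopifnot(inherits(curve, "sa_curve"))
  if (curve$undefined) return(NA)
  curve$shares[length(curve$shares)] >= 0.80
}
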