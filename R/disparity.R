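# Relative-risk disparity between formal and informal residents, speed-
# scenario uncertainty intervals, UN-Habitat city-size classes and
# multi-city aggregation.

#' Relative risk of worse access for informal residents
#'
#' Two variants on the same disparity axis. `coverage_ratio` is
#' `SA_F / SA_IF` — the ratio of formal to informal coverage at the
#' threshold. `exceedance_ratio` is `(1 - SA_IF) / (1 - SA_F)` — how many
#' times more likely an informal resident is to have a travel time above
#' the threshold. Both exceed 1 exactly when formal coverage exceeds
#' informal coverage. A zero denominator yields the undefined sentinel
#' (`NA`).
#'
#' @param sa_f,sa_if formal and informal SA shares in `[0, 1]`.
#' @param variant `"coverage_ratio"` or `"exceedance_ratio"`.
#' @return positive real, or `NA_real_` when undefined.
#' @export
relative_risk <- function(sa_f, sa_if,
                          variant = c("coverage_ratio", "exceedance_ratio")) {
  variant <- match.arg(variant)
  if (any(sa_f < 0 | sa_f > 1, na.rm = FALSE) ||
      any(sa_if < 0 | sa_if > 1, na.rm = FALSE) ||
      any(is.na(c(sa_f, sa_if))))
    stop("SA shares must lie in [0, 1]")
  if (variant == "coverage_ratio") {
    ifelse(sa_if > 0, sa_f / sa_if, NA_real_)
  } else {
    ifelse(sa_f < 1, (1 - sa_if) / (1 - sa_f), NA_real_)
  }
}

#' Relative risk with a speed-scenario uncertainty interval
#'
#' The point estimate is computed at speed factor 1.0; the `[lo, hi]`
#' interval is the min and max of the relative risk over the bundle's
#' factors, the same factor applied to both classes (speed is a city-level
#' perturbation, not a class-level one). The `significant` flag is the
#' entire-interval-above-one rule: `lo > 1`.
#'
#' @param bundle a `curve_bundle` with informal and formal curves at all
#'   factors.
#' @param threshold minutes at which to evaluate.
#' @param variant relative-risk variant.
#' @return one-row data.frame of class `rr_result`: `city`,
#'   `threshold_min`, `variant`, `rr`, `lo`, `hi`, `significant`. All-`NA`
#'   statistics (flagged) if any scenario's RR is undefined.
#' @export
rr_interval <- function(bundle, threshold,
                        variant = c("coverage_ratio", "exceedance_ratio")) {
  variant <- match.arg(variant)
  stopifnot(inherits(bundle, "curve_bundle"))
  threshold <- as.integer(threshold)
  rr_at <- function(f) {
    cf <- bundle_curve(bundle, "formal", f)
    ci <- bundle_curve(bundle, "informal", f)
    if (cf$undefined || ci$undefined) return(NA_real_)
    relative_risk(cf$shares[threshold], ci$shares[threshold], variant)
  }
  rrs <- vapply(bundle$factors, rr_at, numeric(1))
  mid <- rrs[which(abs(bundle$factors - 1.0) < 1e-12)][1]
  if (anyNA(rrs)) {
    res <- data.frame(city = bundle$city, threshold_min = threshold,
                      variant = variant, rr = NA_real_, lo = NA_real_,
                      hi = NA_real_, significant = NA)
  } else {
    res <- data.frame(city = bundle$city, threshold_min = threshold,
                      variant = variant, rr = mid, lo = min(rrs),
                      hi = max(rrs), significant = min(rrs) > 1)
  }
  class(res) <- c("rr_result", "data.frame")
  res
}

#' UN-Habitat city-size class
#'
#' Small < 0.25 M, medium 0.25–1 M, large 1–5 M, very large >= 5 M
#' inhabitants; boundaries go to the larger class (half-open intervals).
#'
#' @param total_pop_millions population in millions (> 0), vectorized.
#' @return character vector of `"small"`, `"medium"`, `"large"`,
#'   `"very_large"`.
#' @export
classify_city_size <- function(total_pop_millions) {
  if (any(!(total_pop_millions > 0))) stop("population must be > 0")
  cut(total_pop_millions, breaks = c(0, 0.25, 1, 5, Inf),
      labels = c("small", "medium", "large", "very_large"),
      right = FALSE) |> as.character()
}

#' Build a per-city summary row
#'
#' @param city city label.
#' @param total_pop residential (informal + formal) population in persons.
#' @param informal_share fraction of residential population in informal
#'   areas.
#' @param n_facilities,n_hospitals facility counts (hospitals <= all).
#' @return one-row data.frame of class `city_summary` including the
#'   UN-Habitat `size_class`.
#' @export
city_summary <- function(city, total_pop, informal_share,
                         n_facilities, n_hospitals) {
  stopifnot(informal_share >= 0, informal_share <= 1,
            n_hospitals <= n_facilities)
  res <- data.frame(city = city, total_pop = total_pop,
                    informal_share = informal_share,
                    n_facilities = as.integer(n_facilities),
                    n_hospitals = as.integer(n_hospitals),
                    size_class = classify_city_size(total_pop / 1e6))
  class(res) <- c("city_summary", "data.frame")
  res
}

#' Aggregate city summaries
#'
#' Population totals sum; the pooled informal share is the
#' population-weighted mean of per-city shares; facility counts sum;
#' size-class counts are tallied.
#'
#' @param summaries data.frame with `city_summary` columns (one row per
#'   city).
#' @return list with `total_pop`, `pooled_informal_share`,
#'   `n_facilities`, `n_hospitals`, `n_cities` and `size_class_counts`
#'   (named integer vector over the four classes).
#' @export
aggregate_cities <- function(summaries) {
  s <- as.data.frame(summaries)
  stopifnot(nrow(s) >= 1L,
            all(c("total_pop", "informal_share", "n_facilities") %in% names(s)))
  total <- sum(s$total_pop)
  list(
    total_pop = total,
    pooled_informal_share = sum(s$total_pop * s$informal_share) / total,
    n_facilities = sum(s$n_facilities),
    n_hospitals = if ("n_hospitals" %in% names(s)) sum(s$n_hospitals) else NA,
    n_cities = nrow(s),
    size_class_counts = vapply(
      c("small", "medium", "large", "very_large"),
      function(k) sum(s$size_class == k), integer(1))
  )
}

#' Published 19-city summary table
#'
#' Summary statistics for 19 sub-Saharan African cities: 2020 residential
#' population (millions), percentage of residential population in informal
#' areas, and healthcare facility / hospital counts within the facility
#' inclusion buffer. Shipped as a plain CSV; used as the reference input
#' for aggregation and city-size classification.
#'
#' @return data.frame with columns `city`, `total_pop_mio`, `pct_informal`,
#'   `n_facilities`, `n_hospitals`, `size_class_published`.
#' @export
ssa19_city_summary <- function() {
  path <- system.file("extdata", "ssa19_city_summary.csv",
                      package = "walkshed", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
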