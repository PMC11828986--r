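#' City run configuration
#'
#' Bundles every tunable of a per-city accessibility run. Defaults follow
#' the study design this package implements: 3.6 km/h walking speed, a
#' +/-20% speed sensitivity (factors 0.8/1.0/1.2), one-minute isochrone
#' steps up to 120 minutes, reporting thresholds at 15/30/60 minutes, and a
#' 9-km facility inclusion buffer around the city boundary (the maximum
#' rounded distance walkable in 2 h at 3.6 km/h with a +20% margin).
#'
#' @param city_name label used in outputs.
#' @param base_speed_kmh walking speed in km/h (> 0).
#' @param speed_factors multiplicative speed scenarios; must contain 1.0.
#' @param max_minutes isochrone horizon in minutes (integer > 0).
#' @param thresholds_min reporting thresholds, integers within
#'   `[1, max_minutes]`.
#' @param facility_set `"all"` facilities or `"hospitals"` (surgical-care
#'   group) only.
#' @param buffer_km boundary dilation for facility selection, kilometers.
#' @param snap_radius_m maximum facility-to-network and cell-to-network
#'   snapping distance, meters.
#' @param disaggregation_mode `"uniform_all"` splits each coarse population
#'   cell over all fine subcells; `"residential_only"` splits over
#'   residential (informal/formal) subcells.
#' @param rr_variant default relative-risk variant for reporting.
#' @param seed optional integer seed controlling all randomness of a run.
#' @return A validated object of class `city_config`.
#' @export
city_config <- function(city_name = "city",
                        base_speed_kmh = 3.6,
                        speed_factors = c(0.8, 1.0, 1.2),
                        max_minutes = 120L,
                        thresholds_min = c(15L, 30L, 60L),
                        facility_set = c("all", "hospitals"),
                        buffer_km = 9,
                        snap_radius_m = 500,
                        disaggregation_mode = c("uniform_all", "residential_only"),
                        rr_variant = c("coverage_ratio", "exceedance_ratio"),
                        seed = NULL) {
  facility_set <- match.arg(facility_set)
  disaggregation_mode <- match.arg(disaggregation_mode)
  rr_variant <- match.arg(rr_variant)
  max_minutes <- as.integer(max_minutes)
  thresholds_min <- sort(unique(as.integer(thresholds_min)))
  speed_factors <- sort(unique(as.numeric(speed_factors)))

  if (!is.character(city_name) || length(city_name) != 1L)
    stop("city_name must be a single string")
  if (!(base_speed_kmh > 0)) stop("base_speed_kmh must be > 0")
  if (!all(speed_factors > 0)) stop("speed_factors must all be > 0")
  if (!any(abs(speed_factors - 1.0) < 1e-12))
    stop("speed_factors must contain 1.0 (the base scenario)")
  if (!(max_minutes > 0)) stop("max_minutes must be a positive integer")
  if (any(thresholds_min < 1L) || any(thresholds_min > max_minutes))
    stop("thresholds_min must lie within [1, max_minutes]")
  if (!(buffer_km > 0)) stop("buffer_km must be > 0")
  if (!(snap_radius_m > 0)) stop("snap_radius_m must be > 0")
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("seed must be an integer or NULL")
  }

  structure(
    list(city_name = city_name, base_speed_kmh = base_speed_kmh,
         speed_factors = speed_factors, max_minutes = max_minutes,
         thresholds_min = thresholds_min, facility_set = facility_set,
         buffer_km = buffer_km, snap_radius_m = snap_radius_m,
         disaggregation_mode = disaggregation_mode, rr_variant = rr_variant,
         seed = seed),
    class = "city_config"
  )
}

#' @export
print.city_config <- function(x, ...) {
  cat(sprintf("<city_config> %s: %.2f km/h (factors %s), horizon %d min,\n",
              x$city_name, x$base_speed_kmh,
              paste(x$speed_factors, collapse = "/"), x$max_minutes))
  cat(sprintf("  thresholds %s min, facilities = %s, buffer %g km, snap %g m\n",
              paste(x$thresholds_min, collapse = "/"), x$facility_set,
              x$buffer_km, x$snap_radius_m))
  invisible(x)
}

#' Read a city configuration from YAML or JSON
#'
#' Unknown fields are rejected so typos do not silently fall back to
#' defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file with `city_config` fields.
#' @return a `city_config`.
#' @export
read_city_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, " (use YAML or JSON)")
  )
  known <- names(formals(city_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config fields: ", paste(extra, collapse = ", "))
  do.call(city_config, raw)
}
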