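# Per-city and multi-city orchestration: facility selection -> multi-source
# travel times -> rasterization -> land-use recoding -> population
# disaggregation -> speed scenarios -> threshold/2-h reports -> relative
# risks -> outputs.

#' Write a city bundle to disk through the standard writers
#'
#' Network and boundary as GeoJSON, facilities as GeoJSON Points, rasters
#' as ESRI ASCII grids, ledger as JSON — so synthetic fixtures exercise the
#' real file paths.
#'
#' @param bundle a `city_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_city_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "city_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network_geojson(bundle$network, file.path(dir, "network.geojson"))
  write_facilities_geojson(bundle$facilities, file.path(dir, "facilities.geojson"))
  write_asc(bundle$landuse, file.path(dir, "landuse.asc"))
  write_asc(bundle$population, file.path(dir, "population.asc"))
  write_boundary(bundle$boundary, file.path(dir, "boundary.geojson"))
  jsonlite::write_json(bundle$ledger, file.path(dir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a city bundle written by [write_city_bundle()]
#' @param dir bundle directory.
#' @return a `city_bundle` (ledger restored from JSON).
#' @export
read_city_bundle <- function(dir) {
  net <- read_network(file.path(dir, "network.geojson"), "geojson_lines")
  fs <- read_facilities(file.path(dir, "facilities.geojson"),
                        category_field = "category",
                        mapping = c(group_i = "group_i",
                                    group_ii_other = "group_ii_other"))
  landuse <- read_asc(file.path(dir, "landuse.asc"))
  population <- read_asc(file.path(dir, "population.asc"))
  boundary <- read_boundary(file.path(dir, "boundary.geojson"))
  ledger <- jsonlite::read_json(file.path(dir, "ledger.json"),
                                simplifyVector = TRUE)
  city_bundle(net, fs, landuse, population, boundary, ledger)
}

#' Run the full accessibility analysis for one city
#'
#' Executes every pipeline stage in order and collects the results; any
#' stage failure aborts with the stage name. Curves, threshold reports and
#' relative risks use the configured facility set; the surgical-care
#' benchmark and the outside-2-h metric are additionally computed on the
#' hospitals (group_i) set.
#'
#' @param inputs a `city_bundle`, or a directory path holding one (see
#'   [write_city_bundle()]).
#' @param config a `city_config`.
#' @param out_dir optional output directory; when given, results are
#'   written via [write_outputs()].
#' @return object of class `city_run`: list with `config`, `bundle` (the
#'   curve bundle), `thresholds` (per-class threshold report), `rr` (both
#'   variants at every threshold), `summary` (a `city_summary` row),
#'   `outside_2h`, `hospital_outside_2h`, `surgical_ok`, warnings and
#'   per-stage timings (`manifest`).
#' @export
run_city <- function(inputs, config, out_dir = NULL) {
  stopifnot(inherits(config, "city_config"))
  if (is.character(inputs)) inputs <- read_city_bundle(inputs)
  stopifnot(inherits(inputs, "city_bundle"))
  if (!is.null(config$seed)) set.seed(config$seed)

  warnings_log <- character(0)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  fs_run <- stage("select_facilities",
    select_facilities(inputs$facilities, config$facility_set,
                      inputs$boundary, config$buffer_km))
  fs_hosp <- stage("select_hospitals",
    select_facilities(inputs$facilities, "hospitals",
                      inputs$boundary, config$buffer_km))

  ntt <- stage("multi_source_travel_times",
    multi_source_travel_times(inputs$network, fs_run,
                              config$snap_radius_m, config$base_speed_kmh))
  rlu <- stage("recode_landuse", recode_landuse(inputs$landuse))
  field <- stage("raster_travel_times",
    raster_travel_times(ntt, inputs$network, rlu,
                        config$snap_radius_m, config$base_speed_kmh))
  cp <- stage("disaggregate",
    disaggregate(inputs$population, rlu, config$disaggregation_mode))
  bundle <- stage("run_speed_scenarios",
    run_speed_scenarios(cp, field, config))

  thresholds <- stage("threshold_report", {
    do.call(rbind, lapply(c("all", "informal", "formal"), function(cl) {
      cv <- bundle_curve(bundle, cl, 1.0)
      if (cv$undefined) return(NULL)
      cbind(city = config$city_name, class = cl,
            threshold_report(bundle, config$thresholds_min, cl))
    }))
  })

  rr <- stage("rr_interval", {
    do.call(rbind, lapply(c("coverage_ratio", "exceedance_ratio"),
      function(vr) do.call(rbind, lapply(config$thresholds_min,
        function(th) rr_interval(bundle, th, vr)))))
  })

  all_curve <- bundle_curve(bundle, "all", 1.0)
  outside_2h <- stage("pct_outside_2h", pct_outside_2h(all_curve))

  hosp <- stage("hospital_curves", {
    ntt_h <- multi_source_travel_times(inputs$network, fs_hosp,
                                       config$snap_radius_m,
                                       config$base_speed_kmh)
    field_h <- raster_travel_times(ntt_h, inputs$network, rlu,
                                   config$snap_radius_m,
                                   config$base_speed_kmh)
    sa_curve(cp, field_h, "all", config$max_minutes,
             city = config$city_name)
  })
  surgical_ok <- stage("surgical_benchmark", surgical_benchmark(hosp))
  hospital_outside_2h <- pct_outside_2h(hosp)

  ct <- class_totals(cp)
  summary <- city_summary(config$city_name, ct$city_total,
                          if (ct$share_defined) ct$informal_share else 0,
                          n_facilities = nrow(fs_run),
                          n_hospitals = nrow(fs_hosp))

  run <- structure(
    list(config = config, bundle = bundle, thresholds = thresholds, rr = rr,
         summary = summary, class_totals = ct, outside_2h = outside_2h,
         hospital_outside_2h = hospital_outside_2h,
         surgical_ok = surgical_ok, hospital_curve = hosp,
         manifest = list(config = unclass(config), timings = timings,
                         warnings = warnings_log,
                         n_facilities_used = nrow(fs_run))),
    class = "city_run")
  if (!is.null(out_dir)) write_outputs(run, out_dir)
  run
}

#' @export
print.city_run <- function(x, ...) {
  cat(sprintf("<city_run> %s (facility set: %s)\n", x$config$city_name,
              x$config$facility_set))
  cat(sprintf("  residential pop %.0f (informal share %.3f), outside 2 h %.3f\n",
              x$summary$total_pop, x$summary$informal_share, x$outside_2h))
  cat(sprintf("  surgical 2-h benchmark (hospitals): %s\n",
              ifelse(isTRUE(x$surgical_ok), "met", "not met")))
  invisible(x)
}

curves_long <- function(run) {
  b <- run$bundle
  do.call(rbind, lapply(b$curves, function(cv) {
    if (cv$undefined) return(NULL)
    data.frame(city = cv$city, class = cv$class_filter,
               speed_factor = cv$speed_factor,
               minute = seq_along(cv$shares), share = cv$shares)
  }))
}

#' Write run outputs
#'
#' Writes `sa_curves.csv` (city, class, speed_factor, minute, share),
#' `rr_table.csv` (city, threshold_min, variant, rr, lo, hi, significant),
#' `summary.json` (per-city summary; plus a `total` entry for multi-city
#' runs) and `run.log` (config echo, warnings, timings). Fails before
#' writing anything if the directory cannot be created.
#'
#' @param run a `city_run` or `multi_city_run`.
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
write_outputs <- function(run, dir) {
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  UseMethod("write_outputs", run)
}

#' @export
write_outputs.city_run <- function(run, dir) {
  paths <- file.path(dir, c("sa_curves.csv", "rr_table.csv", "summary.json",
                            "run.log"))
  utils::write.csv(curves_long(run), paths[1], row.names = FALSE)
  utils::write.csv(as.data.frame(run$rr), paths[2], row.names = FALSE)
  summ <- as.list(run$summary)
  summ$outside_2h <- run$outside_2h
  summ$hospital_outside_2h <- run$hospital_outside_2h
  summ$surgical_benchmark_met <- run$surgical_ok
  jsonlite::write_json(setNames(list(summ), run$config$city_name),
                       paths[3], auto_unbox = TRUE, digits = NA)
  writeLines(c(
    paste0("city: ", run$config$city_name),
    paste0("config: ", jsonlite::toJSON(unclass(run$config),
                                        auto_unbox = TRUE, null = "null")),
    paste0("warnings: ",
           if (length(run$manifest$warnings))
             paste(run$manifest$warnings, collapse = " | ") else "(none)"),
    vapply(names(run$manifest$timings), function(nm)
      sprintf("timing %s: %.3fs", nm, run$manifest$timings[[nm]]),
      character(1))), paths[4])
  invisible(paths)
}

#' Run several cities and aggregate
#'
#' Runs each (inputs, config) pair; a failing city is recorded in the
#' aggregate manifest and the others complete. Pooled SA shares are
#' population-weighted over the cities' residential (informal + formal)
#' populations, per class and speed factor.
#'
#' @param runs list of `list(inputs = , config = )` pairs.
#' @param out_dir optional output directory for aggregate files.
#' @return object of class `multi_city_run`: `runs` (successful
#'   `city_run`s), `failures` (named error messages), `aggregate`
#'   ([aggregate_cities()] output), `pooled_curves` (data.frame city-pooled
#'   SA by class/factor/minute) and `rr_by_size` (city, size_class,
#'   threshold, rr, lo, hi).
#' @export
run_multi_city <- function(runs, out_dir = NULL) {
  results <- list(); failures <- character(0)
  for (k in seq_along(runs)) {
    r <- runs[[k]]
    nm <- r$config$city_name
    res <- tryCatch(run_city(r$inputs, r$config),
                    error = function(e) conditionMessage(e))
    if (inherits(res, "city_run")) results[[nm]] <- res
    else failures[nm] <- res
  }
  if (!length(results)) stop("all cities failed")

  summaries <- do.call(rbind, lapply(results, function(r) r$summary))
  agg <- aggregate_cities(summaries)

  # population-weighted pooling of SA curves (weights: per-class population)
  pooled <- do.call(rbind, lapply(results[[1]]$bundle$factors, function(f) {
    do.call(rbind, lapply(c("all", "informal", "formal"), function(cl) {
      ws <- vapply(results, function(r)
        bundle_curve(r$bundle, cl, f)$denom, numeric(1))
      if (sum(ws) == 0) return(NULL)
      sh <- vapply(results, function(r) {
        cv <- bundle_curve(r$bundle, cl, f)
        if (cv$undefined) rep(0, length(cv$shares)) else cv$shares
      }, numeric(results[[1]]$config$max_minutes))
      data.frame(class = cl, speed_factor = f,
                 minute = seq_len(nrow(sh)),
                 share = as.numeric(sh %*% ws) / sum(ws))
    }))
  }))

  rr_by_size <- do.call(rbind, lapply(results, function(r) {
    rrc <- r$rr[r$rr$variant == "coverage_ratio", , drop = FALSE]
    if (!nrow(rrc)) return(NULL)
    data.frame(city = rrc$city, size_class = r$summary$size_class,
               threshold_min = rrc$threshold_min, rr = rrc$rr,
               lo = rrc$lo, hi = rrc$hi)
  }))

  out <- structure(list(runs = results, failures = failures,
                        aggregate = agg, summaries = summaries,
                        pooled_curves = pooled, rr_by_size = rr_by_size),
                   class = "multi_city_run")
  if (!is.null(out_dir)) write_outputs(out, out_dir)
  out
}

#' @export
write_outputs.multi_city_run <- function(run, dir) {
  for (r in run$runs)
    write_outputs(r, file.path(dir, r$config$city_name))
  paths <- file.path(dir, c("pooled_sa_curves.csv", "rr_by_size.csv",
                            "summary.json"))
  utils::write.csv(run$pooled_curves, paths[1], row.names = FALSE)
  utils::write.csv(run$rr_by_size, paths[2], row.names = FALSE)
  entries <- lapply(run$runs, function(r) as.list(r$summary))
  entries$total <- run$aggregate
  if (length(run$failures)) entries$failures <- as.list(run$failures)
  jsonlite::write_json(entries, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @export
print.multi_city_run <- function(x, ...) {
  cat(sprintf("<multi_city_run> %d cities (%d failed), total pop %.0f, pooled informal share %.3f\n",
              length(x$runs), length(x$failures),
              x$aggregate$total_pop, x$aggregate$pooled_informal_share))
  invisible(x)
}
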