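#' Construct a road network
#'
#' An undirected weighted street graph in projected planar meters. Parallel
#' edges are allowed (the shortest is effective in routing); the graph may
#' be disconnected.
#'
#' @param nodes data.frame with columns `id` (unique integer or character),
#'   `x`, `y` (meters).
#' @param edges data.frame with columns `u`, `v` (node ids) and `length_m`
#'   (> 0).
#' @return object of class `road_network`.
#' @export
road_network <- function(nodes, edges) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  stopifnot(all(c("id", "x", "y") %in% names(nodes)),
            all(c("u", "v", "length_m") %in% names(edges)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!all(is.finite(nodes$x)) || !all(is.finite(nodes$y)))
    stop("node coordinates must be finite")
  if (nrow(edges)) {
    if (!all(edges$length_m > 0)) stop("edge lengths must be > 0")
    if (!all(edges$u %in% nodes$id) || !all(edges$v %in% nodes$id))
      stop("edge endpoints must reference existing node ids")
  }
  structure(list(nodes = nodes[c("id", "x", "y")],
                 edges = edges[c("u", "v", "length_m")]),
            class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d nodes, %d edges, total length %.1f m\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$length_m)))
  invisible(x)
}

#' Construct a facility set
#'
#' @param facilities data.frame with columns `id`, `x`, `y`, `group`
#'   (`"group_i"` = hospitals/surgical care, `"group_ii_other"` = clinics
#'   and other facilities) and optionally `name`.
#' @return object of class `facility_set` (a data.frame).
#' @export
facility_set <- function(facilities) {
  f <- as.data.frame(facilities)
  stopifnot(all(c("id", "x", "y", "group") %in% names(f)))
  if (nrow(f)) {
    if (!all(is.finite(f$x)) || !all(is.finite(f$y)))
      stop("facility coordinates must be finite")
    if (!all(f$group %in% c("group_i", "group_ii_other")))
      stop("facility group must be 'group_i' or 'group_ii_other'")
  }
  if (!"name" %in% names(f)) f$name <- NA_character_
  class(f) <- c("facility_set", "data.frame")
  f
}

#' Convert edge length to walking minutes
#'
#' Exact arithmetic contract: `length_m / (speed_kmh * 1000 / 60)`, no
#' rounding. At 3.6 km/h one meter takes 1/60 minute, so 60 m = 1 minute.
#'
#' @param length_m length in meters (> 0).
#' @param speed_kmh walking speed in km/h (> 0).
#' @return minutes (numeric, vectorized).
#' @export
edge_minutes <- function(length_m, speed_kmh) {
  if (any(!(length_m > 0))) stop("length_m must be > 0")
  if (any(!(speed_kmh > 0))) stop("speed_kmh must be > 0")
  length_m / (speed_kmh * 1000 / 60)
}

# meters per minute at a given km/h
meters_per_minute <- function(speed_kmh) speed_kmh * 1000 / 60

#' Select facilities for a run
#'
#' Keeps the requested facility group and restricts to facilities within the
#' city boundary dilated by `buffer_km` kilometers, so facilities just
#' outside the boundary that residents can plausibly reach are retained.
#'
#' @param fs a `facility_set`.
#' @param which `"hospitals"` keeps group_i only; `"all"` keeps every group.
#' @param boundary polygon exterior ring (two-column matrix/data.frame).
#' @param buffer_km dilation in kilometers.
#' @return filtered `facility_set`; empty result gives a warning (downstream
#'   accessibility is zero everywhere, not an error).
#' @export
select_facilities <- function(fs, which = c("all", "hospitals"),
                              boundary, buffer_km = 9) {
  which <- match.arg(which)
  stopifnot(inherits(fs, "facility_set"), buffer_km > 0)
  keep <- if (which == "hospitals") fs$group == "group_i" else rep(TRUE, nrow(fs))
  out <- fs[keep, , drop = FALSE]
  if (nrow(out)) {
    inb <- in_buffered_polygon(out$x, out$y, boundary, buffer_km * 1000)
    out <- out[inb, , drop = FALSE]
  }
  if (!nrow(out))
    warning("no facilities retained (set '", which,
            "'); accessibility will be zero everywhere")
  class(out) <- c("facility_set", "data.frame")
  out
}

# Snap each facility to its nearest network node within snap_radius_m.
# Ties broken by lowest node id (order of `sort`). Facilities with no node
# in range are dropped with a warning.
snap_facilities <- function(net, fs, snap_radius_m) {
  if (!nrow(fs))
    return(data.frame(facility_id = character(0), node_id = character(0),
                      offset_m = numeric(0)))
  nd <- net$nodes
  ord <- order(as.character(nd$id))  # deterministic tie-break: lowest id
  nd <- nd[ord, ]
  res <- lapply(seq_len(nrow(fs)), function(i) {
    d <- sqrt((nd$x - fs$x[i])^2 + (nd$y - fs$y[i])^2)
    j <- which.min(d)  # first minimum = lowest id after sorting
    if (d[j] <= snap_radius_m)
      data.frame(facility_id = as.character(fs$id[i]),
                 node_id = as.character(nd$id[j]), offset_m = d[j])
    else NULL
  })
  dropped <- vapply(res, is.null, logical(1))
  if (any(dropped))
    warning(sum(dropped), " facility(ies) beyond snap radius dropped: ",
            paste(fs$id[dropped], collapse = ", "))
  kept <- res[!dropped]
  if (!length(kept))
    return(data.frame(facility_id = character(0), node_id = character(0),
                      offset_m = numeric(0)))
  do.call(rbind, kept)
}

#' Minutes to the nearest facility for every network node
#'
#' Multi-source shortest paths: each facility is snapped to its nearest
#' network node within `snap_radius_m` (ties to the lowest node id) and
#' contributes an initial offset of straight-line distance / walking speed;
#' every node's value is the minimum over facilities of offset plus network
#' travel time. This is the exact dissolve of per-facility one-minute
#' isochrones: overlapping service areas merge by taking the minimum.
#'
#' @param net a `road_network` (non-empty).
#' @param fs a `facility_set`.
#' @param snap_radius_m snapping radius in meters.
#' @param speed_kmh walking speed in km/h.
#' @return object of class `node_travel_times`: list with `minutes` (named
#'   numeric, `+Inf` where unreachable), `snapped` (facility/node/offset
#'   table) and `speed_kmh`.
#' @export
multi_source_travel_times <- function(net, fs, snap_radius_m, speed_kmh) {
  stopifnot(inherits(net, "road_network"), nrow(net$nodes) > 0,
            snap_radius_m > 0, speed_kmh > 0)
  ids <- as.character(net$nodes$id)
  minutes <- setNames(rep(Inf, length(ids)), ids)

  snapped <- snap_facilities(net, fs, snap_radius_m)
  if (is.null(snapped) || !nrow(snapped)) {
    if (nrow(fs)) warning("no facility snapped to the network; all times +Inf")
    return(structure(list(minutes = minutes,
                          snapped = data.frame(facility_id = character(0),
                                               node_id = character(0),
                                               offset_m = numeric(0)),
                          speed_kmh = speed_kmh),
                     class = "node_travel_times"))
  }

  mpm <- meters_per_minute(speed_kmh)
  # minimum initial offset per distinct snapped node
  off_min <- tapply(snapped$offset_m / mpm, snapped$node_id, min)
  src <- names(off_min)

  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(net$edges$u),
               to = as.character(net$edges$v),
               weight = edge_minutes(net$edges$length_m, speed_kmh)),
    directed = FALSE, vertices = data.frame(name = ids))
  d <- igraph::distances(g, v = src, to = igraph::V(g), mode = "all")
  d <- d + as.numeric(off_min)  # recycle offsets down rows
  best <- apply(d, 2L, min)
  minutes[colnames(d)] <- best
  minutes <- minutes[ids]

  structure(list(minutes = minutes, snapped = snapped, speed_kmh = speed_kmh),
            class = "node_travel_times")
}

#' @export
print.node_travel_times <- function(x, ...) {
  fin <- is.finite(x$minutes)
  cat(sprintf(
    "<node_travel_times> %d nodes (%d reachable), %d source node(s), %.2f km/h\n",
    length(x$minutes), sum(fin), length(unique(x$snapped$node_id)), x$speed_kmh))
  if (any(fin))
    cat(sprintf("  minutes: %.2f .. %.2f\n", min(x$minutes[fin]),
                max(x$minutes[fin])))
  invisible(x)
}

#' Rasterize node travel times onto a fine grid
#'
#' For each cell centroid the travel time is the minimum, over network nodes
#' within `snap_radius_m`, of the node's time plus the straight-line
#' distance from centroid to node at the same walking speed. Cells with no
#' node in range get `+Inf`. This is the raster analogue of dissolved
#' service-area polygons.
#'
#' @param ntt a `node_travel_times`.
#' @param net the `road_network` the times were computed on.
#' @param grid target `raster_grid` (geometry only; values ignored).
#' @param snap_radius_m cell-to-network radius in meters.
#' @param speed_kmh walking speed (off-network time uses the same speed).
#' @return a `travel_time_field` (a `raster_grid` of minutes).
#' @export
raster_travel_times <- function(ntt, net, grid, snap_radius_m, speed_kmh) {
  stopifnot(inherits(ntt, "node_travel_times"), inherits(grid, "raster_grid"),
            snap_radius_m > 0, speed_kmh > 0)
  out <- matrix(Inf, grid$nrow, grid$ncol)
  nodes <- net$nodes
  if (nrow(nodes)) {
    cc <- cell_centers(grid)
    mpm <- meters_per_minute(speed_kmh)
    tmin <- ntt$minutes[as.character(nodes$id)]
    cs <- grid$cellsize
    for (k in seq_len(nrow(nodes))) {
      # window of cells possibly within the snap radius of this node
      cols <- which(abs(cc$x - nodes$x[k]) <= snap_radius_m)
      rows <- which(abs(cc$y - nodes$y[k]) <= snap_radius_m)
      if (!length(cols) || !length(rows)) next
      dx <- cc$x[cols] - nodes$x[k]
      dy <- cc$y[rows] - nodes$y[k]
      d <- sqrt(outer(dy^2, dx^2, `+`))
      cand <- tmin[k] + d / mpm
      cand[d > snap_radius_m] <- Inf
      out[rows, cols] <- pmin(out[rows, cols], cand)
    }
  }
  f <- raster_grid(out, grid$xll, grid$yll, grid$cellsize)
  class(f) <- c("travel_time_field", class(f))
  f
}

#' Isochrone membership mask
#'
#' `TRUE` where the travel time is at or below `t` minutes (closed
#' threshold, the service-area convention: the 1-minute isochrone includes
#' its boundary). Masks are nested in `t`.
#'
#' @param field a `travel_time_field`.
#' @param t threshold in minutes, in `(0, max_minutes]`.
#' @param max_minutes isochrone horizon (default 120).
#' @return logical matrix of the field's dimensions.
#' @export
isochrone_mask <- function(field, t, max_minutes = 120) {
  stopifnot(inherits(field, "raster_grid"))
  if (!is.numeric(t) || length(t) != 1L || !(t > 0) || t > max_minutes)
    stop("t must lie in (0, ", max_minutes, "]")
  field$values <= t
}

#' Rescale a travel-time field to another speed factor
#'
#' Times scale exactly as 1/factor because on-network and off-network legs
#' use the same walking speed: the field at speed `s * f` equals the field
#' at `s` divided by `f`, offsets included.
#'
#' @param field a `travel_time_field` computed at the base speed.
#' @param factor speed multiplier (> 0).
#' @return rescaled `travel_time_field`.
#' @export
scale_field <- function(field, factor) {
  stopifnot(inherits(field, "raster_grid"), factor > 0)
  field$values <- field$values / factor
  field
}
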