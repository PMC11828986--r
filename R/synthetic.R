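# Synthetic city bundles with analytically known structure. These stand in
# for the real data layers (street network, facility points, land-use
# raster, gridded population, boundary) so that every pipeline stage can be
# checked against closed forms or exhaustive enumeration.
#
# Grid cities use 60-m spacing at 3.6 km/h so one edge is exactly one
# minute: all oracle travel times are small integers and no floating-point
# tolerance questions arise.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

city_bundle <- function(network, facilities, landuse, population, boundary,
                        ledger) {
  structure(list(network = network, facilities = facilities,
                 landuse = landuse, population = population,
                 boundary = boundary, ledger = ledger),
            class = "city_bundle")
}

#' @export
print.city_bundle <- function(x, ...) {
  cat(sprintf(
    "<city_bundle> %s: %d nodes, %d facilities, %dx%d land-use cells @ %g m\n",
    if (!is.null(x$ledger$city)) x$ledger$city else "synthetic",
    nrow(x$network$nodes), nrow(x$facilities),
    x$landuse$nrow, x$landuse$ncol, x$landuse$cellsize))
  invisible(x)
}

# Independent bookkeeping used for bundle ledgers: plain per-coarse-cell
# loop, deliberately not sharing code with disaggregate().
ledger_class_pop <- function(pop, lu6) {
  rlu_codes <- c(1L, 1L, 2L, 2L, 3L, 3L)  # six classes -> informal/formal/other
  cc <- cell_centers(raster_grid(lu6$values, lu6$xll, lu6$yll, lu6$cellsize))
  totals <- c(informal = 0, formal = 0, other = 0)
  for (r in seq_len(pop$nrow)) {
    for (co in seq_len(pop$ncol)) {
      count <- pop$values[r, co]
      if (is.na(count) || count == 0) next
      x0 <- pop$xll + (co - 1) * pop$cellsize
      y0 <- pop$yll + (pop$nrow - r) * pop$cellsize
      in_cols <- which(cc$x >= x0 & cc$x < x0 + pop$cellsize)
      in_rows <- which(cc$y >= y0 & cc$y < y0 + pop$cellsize)
      n_sub <- length(in_cols) * length(in_rows)
      if (n_sub == 0) next
      cls <- lu6$values[in_rows, in_cols, drop = FALSE]
      rc <- ifelse(is.na(cls), 3L, rlu_codes[cls])
      for (code in 1:3)
        totals[code] <- totals[code] + count * sum(rc == code) / n_sub
    }
  }
  totals
}

#' Generate a deterministic grid city
#'
#' A Manhattan street lattice of `n x n` nodes with edge length
#' `spacing_m`, facilities at given lattice positions, land use assigned by
#' a simple rule (street cells are non-residential; off-street cells are
#' formal inside `core_radius_m` of the center and informal outside,
#' emulating the central-formal / peripheral-informal pattern), and a
#' coarse population raster filled by depositing `pop_per_node` persons in
#' the coarse cell containing each lattice node. Shortest-path travel
#' times between lattice nodes are exactly
#' `spacing_m * L1-distance / walking speed`; the ledger records them.
#'
#' @param n nodes per side (>= 2).
#' @param spacing_m lattice edge length in meters (default 60, so one edge
#'   is one minute at 3.6 km/h).
#' @param facility_nodes list of `c(i, j)` 1-based lattice positions.
#' @param landuse_rule `"formal_core_informal_ring"`, `"checkerboard"` or
#'   `"uniform_informal"`.
#' @param core_radius_m radius of the formal core (euclidean, from the
#'   lattice center).
#' @param pop_per_node persons deposited per lattice node.
#' @param speed_kmh walking speed used for the ledger's travel times.
#' @param facility_groups group labels recycled over facilities (default
#'   all `"group_i"`, so the hospitals set is non-degenerate).
#' @param cellsize_m fine (land-use) cell size; must divide `spacing_m`.
#' @param pop_cellsize_m coarse (population) cell size; must be a multiple
#'   of `cellsize_m`.
#' @param seed unused (the generator is deterministic); kept for interface
#'   symmetry.
#' @return a `city_bundle` whose `ledger` holds exact node travel times
#'   (`node_minutes`), class populations under uniform disaggregation
#'   (`class_pop`), `total_pop` and the parameters.
#' @export
generate_grid_city <- function(n = 11, spacing_m = 60,
                               facility_nodes = list(c((n + 1) %/% 2, (n + 1) %/% 2)),
                               landuse_rule = c("formal_core_informal_ring",
                                                "checkerboard",
                                                "uniform_informal"),
                               core_radius_m = (n - 1) * spacing_m / 4,
                               pop_per_node = 100,
                               speed_kmh = 3.6,
                               facility_groups = "group_i",
                               cellsize_m = 5,
                               pop_cellsize_m = 100,
                               seed = NULL) {
  landuse_rule <- match.arg(landuse_rule)
  stopifnot(n >= 2, spacing_m > 0, pop_per_node >= 0,
            spacing_m %% cellsize_m == 0, pop_cellsize_m %% cellsize_m == 0)
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  nodes <- data.frame(id = seq_len(n * n),
                      x = (ij$i - 1) * spacing_m, y = (ij$j - 1) * spacing_m)
  # horizontal + vertical lattice edges
  h <- subset(ij, i < n); v <- subset(ij, j < n)
  nid <- function(i, j) (j - 1L) * n + i
  edges <- rbind(
    data.frame(u = nid(h$i, h$j), v = nid(h$i + 1L, h$j), length_m = spacing_m),
    data.frame(u = nid(v$i, v$j), v = nid(v$i, v$j + 1L), length_m = spacing_m))
  net <- road_network(nodes, edges)

  for (fn in facility_nodes)
    if (length(fn) != 2L || any(fn < 1) || any(fn > n) || any(fn != round(fn)))
      stop("facility position off-lattice: ", paste(fn, collapse = ","))
  fxy <- t(vapply(facility_nodes, function(fn) (fn - 1) * spacing_m, numeric(2)))
  fs <- facility_set(data.frame(
    id = seq_along(facility_nodes), x = fxy[, 1], y = fxy[, 2],
    group = rep_len(facility_groups, length(facility_nodes))))

  extent <- (n - 1) * spacing_m
  half <- cellsize_m / 2
  lu_g <- raster_grid(matrix(0L, extent / cellsize_m + 1, extent / cellsize_m + 1),
                      -half, -half, cellsize_m)
  cc <- cell_centers(lu_g)
  on_line <- function(u) pmin(u %% spacing_m, spacing_m - u %% spacing_m) < half
  street <- outer(on_line(cc$y), on_line(cc$x), `|`)
  ctr <- extent / 2
  lu <- switch(landuse_rule,
    formal_core_informal_ring = {
      d <- sqrt(outer((cc$y - ctr)^2, (cc$x - ctr)^2, `+`))
      ifelse(d <= core_radius_m, LANDUSE_CODES[["formal_subdivision"]],
             LANDUSE_CODES[["atomistic"]])
    },
    checkerboard = {
      bi <- floor(cc$x / spacing_m); bj <- floor(cc$y / spacing_m)
      par <- outer(bj, bi, function(a, b) (a + b) %% 2 == 0)
      ifelse(par, LANDUSE_CODES[["formal_subdivision"]],
             LANDUSE_CODES[["atomistic"]])
    },
    uniform_informal = matrix(LANDUSE_CODES[["atomistic"]],
                              lu_g$nrow, lu_g$ncol))
  lu[street] <- LANDUSE_CODES[["non_residential"]]
  landuse <- raster_grid(lu, -half, -half, cellsize_m)

  np <- ceiling((extent + cellsize_m) / pop_cellsize_m)
  popm <- matrix(0, np, np)
  for (k in seq_len(nrow(nodes))) {
    co <- floor((nodes$x[k] + half) / pop_cellsize_m) + 1L
    rb <- floor((nodes$y[k] + half) / pop_cellsize_m) + 1L
    popm[np - rb + 1L, co] <- popm[np - rb + 1L, co] + pop_per_node
  }
  population <- raster_grid(popm, -half, -half, pop_cellsize_m)

  margin <- spacing_m / 2
  boundary <- cbind(x = c(-margin, extent + margin, extent + margin, -margin),
                    y = c(-margin, -margin, extent + margin, extent + margin))

  mpm <- meters_per_minute(speed_kmh)
  l1 <- vapply(seq_len(nrow(nodes)), function(k) {
    min(vapply(facility_nodes, function(fn)
      abs(ij$i[k] - fn[1]) + abs(ij$j[k] - fn[2]), numeric(1)))
  }, numeric(1))
  node_minutes <- setNames(l1 * spacing_m / mpm, nodes$id)

  ledger <- list(city = "grid_city", node_minutes = node_minutes,
                 class_pop = ledger_class_pop(population, landuse),
                 total_pop = sum(popm),
                 params = list(n = n, spacing_m = spacing_m,
                               landuse_rule = landuse_rule,
                               core_radius_m = core_radius_m,
                               pop_per_node = pop_per_node,
                               speed_kmh = speed_kmh))
  city_bundle(net, fs, landuse, population, boundary, ledger)
}

#' Generate a random synthetic city
#'
#' A connected random geometric street graph (uniform nodes, edges between
#' pairs within `connect_radius_m`; regenerated up to `max_tries` times
#' until connected), uniformly sampled facilities, a six-class land-use
#' raster drawn cell-wise and smoothed by a fixed two-pass 3x3 majority
#' filter (produces contiguous patches), and log-normal population per
#' coarse cell. Fully reproducible from `seed`.
#'
#' @param seed integer seed.
#' @param n_nodes number of street nodes.
#' @param area_m side of the square city extent in meters (multiple of
#'   `pop_cellsize_m` keeps the grids aligned).
#' @param connect_radius_m edge-creation radius, meters.
#' @param n_facilities number of facilities (group_i with prob. 0.3).
#' @param cellsize_m fine cell size.
#' @param pop_cellsize_m coarse cell size.
#' @param pop_meanlog,pop_sdlog log-normal parameters of persons per coarse
#'   cell (defaults emulate dense urban WorldPop cells, ~150 persons per
#'   100-m cell).
#' @param max_tries connectivity retries before erroring.
#' @return a `city_bundle`; the ledger records `total_pop`, independently
#'   computed `class_pop` (uniform mode) and the parameters.
#' @export
generate_random_city <- function(seed, n_nodes = 60, area_m = 1200,
                                 connect_radius_m = 250, n_facilities = 4,
                                 cellsize_m = 5, pop_cellsize_m = 100,
                                 pop_meanlog = log(150), pop_sdlog = 0.8,
                                 max_tries = 25L) {
  stopifnot(n_nodes >= 2, area_m > 0, area_m %% pop_cellsize_m == 0,
            pop_cellsize_m %% cellsize_m == 0)
  with_seed(seed, {
    net <- NULL
    for (try in seq_len(max_tries)) {
      x <- runif(n_nodes, 0, area_m); y <- runif(n_nodes, 0, area_m)
      d <- as.matrix(dist(cbind(x, y)))
      idx <- which(upper.tri(d) & d <= connect_radius_m & d > 0, arr.ind = TRUE)
      if (!nrow(idx)) next
      cand <- road_network(
        data.frame(id = seq_len(n_nodes), x = x, y = y),
        data.frame(u = idx[, 1], v = idx[, 2], length_m = d[idx]))
      g <- igraph::graph_from_data_frame(
        data.frame(from = cand$edges$u, to = cand$edges$v),
        directed = FALSE,
        vertices = data.frame(name = cand$nodes$id))
      if (igraph::is_connected(g)) { net <- cand; break }
    }
    if (is.null(net))
      stop("could not generate a connected street graph in ", max_tries,
           " tries; increase connect_radius_m")

    fi <- sample.int(n_nodes, n_facilities, replace = FALSE)
    fs <- facility_set(data.frame(
      id = seq_len(n_facilities),
      x = net$nodes$x[fi], y = net$nodes$y[fi],
      group = ifelse(runif(n_facilities) < 0.3, "group_i", "group_ii_other")))

    nc <- area_m / cellsize_m
    probs <- c(atomistic = 0.25, informal_subdivision = 0.15,
               formal_subdivision = 0.15, housing_project = 0.05,
               open_space = 0.15, non_residential = 0.25)
    lu <- matrix(sample(LANDUSE_CODES, nc * nc, replace = TRUE, prob = probs),
                 nc, nc)
    lu <- majority_filter(majority_filter(lu))
    landuse <- raster_grid(lu, 0, 0, cellsize_m)

    npc <- area_m / pop_cellsize_m
    popm <- matrix(rlnorm(npc * npc, pop_meanlog, pop_sdlog), npc, npc)
    population <- raster_grid(popm, 0, 0, pop_cellsize_m)

    boundary <- cbind(x = c(0, area_m, area_m, 0),
                      y = c(0, 0, area_m, area_m))
    ledger <- list(city = paste0("random_city_", seed),
                   total_pop = sum(popm),
                   class_pop = ledger_class_pop(population, landuse),
                   params = list(seed = seed, n_nodes = n_nodes,
                                 area_m = area_m,
                                 connect_radius_m = connect_radius_m,
                                 n_facilities = n_facilities))
    city_bundle(net, fs, landuse, population, boundary, ledger)
  })
}

# 3x3 modal smoothing of an integer class raster (edge cells use the
# available neighbourhood). Ties go to the lowest class code.
majority_filter <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  codes <- sort(unique(as.vector(m)))
  counts <- array(0L, c(nr, nc, length(codes)))
  for (k in seq_along(codes)) {
    ind <- (m == codes[k]) * 1L
    acc <- matrix(0L, nr, nc)
    for (dr in -1:1) for (dco in -1:1) {
      rs <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
      cs <- pmin(pmax(seq_len(nc) + dco, 1L), nc)
      acc <- acc + ind[rs, cs]
    }
    counts[, , k] <- acc
  }
  best <- apply(counts, c(1, 2), which.max)
  matrix(codes[best], nr, nc)
}

#' Two-cluster disparity fixture
#'
#' A collinear network purpose-built for relative-risk direction tests: a
#' single facility at the origin of a straight east-west street, the formal
#' cluster `formal_minutes` of walking east of it, the informal cluster
#' `formal_minutes + gap_minutes` west of it. Everything lies on one line,
#' so the rasterized travel time at each cluster cell equals the cluster's
#' network time exactly (no straight-line shortcut can undercut the
#' street); each cluster is a single residential fine cell centered on its
#' node, making both SA curves exact step functions (ledger fields
#' `t_formal`, `t_informal`). `gap_minutes` is snapped to the nearest 1/12
#' minute (5 m at 3.6 km/h) so cluster nodes sit on fine-cell centroids.
#'
#' @param gap_minutes extra walking minutes to the informal cluster (>= 0).
#' @param formal_minutes walking minutes to the formal cluster (integer
#'   >= 1).
#' @param pop_per_cluster persons deposited in each cluster's coarse cell.
#' @param speed_kmh walking speed (default 3.6, one minute per 60 m).
#' @param seed unused; interface symmetry.
#' @return a `city_bundle`; ledger has `t_formal`, `t_informal`,
#'   `pop_per_cluster`.
#' @export
two_cluster_disparity_city <- function(gap_minutes, formal_minutes = 5,
                                       pop_per_cluster = 1000,
                                       speed_kmh = 3.6, seed = NULL) {
  stopifnot(gap_minutes >= 0, formal_minutes >= 1,
            formal_minutes == round(formal_minutes))
  # all geometry in integer 5-m units (1/12 minute at the given speed), so
  # node and cell-centroid coordinates are exact floats
  units_if <- as.integer(formal_minutes * 12L + round(gap_minutes * 12))
  gap <- (units_if - formal_minutes * 12L) / 12
  sp <- meters_per_minute(speed_kmh)  # 1-min edge length in meters
  unit_m <- sp / 12                   # 5 m at 3.6 km/h
  t_f <- formal_minutes
  t_if <- units_if / 12

  # east side: nodes at 0, 60, ..., t_f*60; west side: one node per whole
  # minute plus a fractional last edge to land exactly at -t_if*60
  x_east <- (0:t_f) * sp
  n_w <- ceiling(units_if / 12)
  x_west <- -seq_len(n_w) * sp
  if (n_w >= 1) x_west[n_w] <- -units_if * unit_m
  xs <- c(x_east, x_west)
  nodes <- data.frame(id = seq_along(xs), x = xs, y = 0)
  ord <- order(xs)
  edges <- data.frame(u = nodes$id[ord][-length(xs)],
                      v = nodes$id[ord][-1],
                      length_m = diff(xs[ord]))
  edges <- edges[edges$length_m > 0, ]
  net <- road_network(nodes, edges)
  fs <- facility_set(data.frame(id = 1, x = 0, y = 0, group = "group_i"))

  cell <- unit_m
  half <- cell / 2
  xll <- -units_if * unit_m - half
  lu_ncol <- t_f * 12L + units_if + 1L
  lu_nrow <- 20                      # one 100-m population row
  lu <- matrix(LANDUSE_CODES[["non_residential"]], lu_nrow, lu_ncol)
  g <- raster_grid(lu, xll, -half, cell)
  cc <- cell_centers(g)
  row0 <- which(cc$y == 0)
  col_formal <- units_if + t_f * 12L + 1L       # centroid at +t_f*60
  col_informal <- 1L                            # centroid at -t_if*60
  stopifnot(cc$x[col_formal] == t_f * sp,
            cc$x[col_informal] == -units_if * unit_m)
  lu[row0, col_formal] <- LANDUSE_CODES[["formal_subdivision"]]
  lu[row0, col_informal] <- LANDUSE_CODES[["atomistic"]]
  landuse <- raster_grid(lu, xll, -half, cell)

  pcs <- 20 * cell
  np_c <- ceiling(lu_ncol / 20)
  popm <- matrix(0, 1, np_c)
  deposit <- function(col) {
    co <- (col - 1L) %/% 20L + 1L
    popm[1, co] <<- popm[1, co] + pop_per_cluster
  }
  deposit(col_formal)
  deposit(col_informal)
  population <- raster_grid(popm, xll, -half, pcs)

  pad <- sp
  boundary <- cbind(x = c(xll - pad, t_f * sp + pad, t_f * sp + pad,
                          xll - pad),
                    y = c(-pad, -pad, 100 + pad, 100 + pad))

  ledger <- list(city = "two_cluster", t_formal = t_f, t_informal = t_if,
                 pop_per_cluster = pop_per_cluster,
                 params = list(gap_minutes = gap,
                               formal_minutes = formal_minutes,
                               speed_kmh = speed_kmh))
  city_bundle(net, fs, landuse, population, boundary, ledger)
}
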