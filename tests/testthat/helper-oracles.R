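# Independent reference implementations used as oracles. Deliberately
# naive (plain loops, O(n^2) Dijkstra) and sharing no code with the
# package's computation paths.

# Single-source Dijkstra over an undirected edge list with minute weights.
ref_dijkstra <- function(nodes, edges, source_id, speed_kmh) {
  ids <- as.character(nodes$id)
  n <- length(ids)
  w <- edges$length_m / (speed_kmh * 1000 / 60)
  adj <- vector("list", n)
  names(adj) <- ids
  for (k in seq_len(nrow(edges))) {
    u <- as.character(edges$u[k]); v <- as.character(edges$v[k])
    adj[[u]] <- rbind(adj[[u]], c(match(v, ids), w[k]))
    adj[[v]] <- rbind(adj[[v]], c(match(u, ids), w[k]))
  }
  dist <- rep(Inf, n); names(dist) <- ids
  dist[as.character(source_id)] <- 0
  done <- rep(FALSE, n)
  for (iter in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1]
      if (dist[u] + nb[r, 2] < dist[v]) dist[v] <- dist[u] + nb[r, 2]
    }
  }
  dist
}

# Min-over-facilities of single-source distances, with brute-force snapping
# (nearest node within radius, ties to lowest id) and straight-line offset.
ref_multi_source <- function(net, fs, snap_radius_m, speed_kmh) {
  ids <- as.character(net$nodes$id)
  best <- rep(Inf, length(ids)); names(best) <- ids
  mpm <- speed_kmh * 1000 / 60
  ord <- order(as.character(net$nodes$id))
  for (i in seq_len(nrow(fs))) {
    d <- sqrt((net$nodes$x - fs$x[i])^2 + (net$nodes$y - fs$y[i])^2)
    j <- ord[which.min(d[ord])]
    if (d[j] > snap_radius_m) next
    dd <- ref_dijkstra(net$nodes, net$edges, net$nodes$id[j], speed_kmh) +
      d[j] / mpm
    best <- pmin(best, dd[ids])
  }
  best
}

# Exhaustive per-cell scan over every node for rasterized travel times.
ref_cell_scan <- function(ntt_minutes, net, grid, snap_radius_m, speed_kmh) {
  cc <- cell_centers(grid)
  mpm <- speed_kmh * 1000 / 60
  tm <- ntt_minutes[as.character(net$nodes$id)]
  out <- matrix(Inf, grid$nrow, grid$ncol)
  for (r in seq_len(grid$nrow)) {
    for (co in seq_len(grid$ncol)) {
      d <- sqrt((net$nodes$x - cc$x[co])^2 + (net$nodes$y - cc$y[r])^2)
      ok <- d <= snap_radius_m
      if (any(ok)) out[r, co] <- min(tm[ok] + d[ok] / mpm)
    }
  }
  out
}

# Direct per-threshold recount of SA shares (no binning/cumsum).
ref_sa_shares <- function(cp, field, class_codes, max_minutes = 120L) {
  sel <- cp$class %in% class_codes
  w <- cp$pop[sel]; m <- field$values[sel]
  denom <- sum(w)
  vapply(seq_len(max_minutes), function(t) sum(w[m <= t]) / denom, numeric(1))
}

# Small random connected graph for oracle comparisons.
random_graph <- function(n, p = 0.08, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    x <- runif(n, 0, 1000); y <- runif(n, 0, 1000)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < p
    e <- pairs[keep, , drop = FALSE]
    if (!nrow(e)) next
    len <- sqrt((x[e[, 1]] - x[e[, 2]])^2 + (y[e[, 1]] - y[e[, 2]])^2)
    len[len == 0] <- 1
    net <- road_network(data.frame(id = seq_len(n), x = x, y = y),
                        data.frame(u = e[, 1], v = e[, 2], length_m = len))
    g <- igraph::graph_from_data_frame(
      data.frame(from = e[, 1], to = e[, 2]), directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    if (igraph::is_connected(g)) return(net)
  }
}

# Tiny cell population on an explicit grid, for curve unit tests.
toy_cell_population <- function(pop, cls, cellsize = 5, xll = 0, yll = 0) {
  structure(list(grid = raster_grid(matrix(0, nrow(pop), ncol(pop)),
                                    xll, yll, cellsize),
                 pop = pop, class = cls, mode = "uniform_all"),
            class = "cell_population")
}

toy_field <- function(minutes, cellsize = 5, xll = 0, yll = 0) {
  g <- raster_grid(minutes, xll, yll, cellsize)
  class(g) <- c("travel_time_field", class(g))
  g
}
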