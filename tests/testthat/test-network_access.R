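# Walking-time graph, multi-source travel times, rasterization, isochrones.

path_network <- function(k, edge_m = 72) {
  # k nodes in a line, edge length edge_m meters
  road_network(data.frame(id = 1:k, x = (0:(k - 1)) * edge_m, y = 0),
               data.frame(u = 1:(k - 1), v = 2:k, length_m = edge_m))
}

test_that("edge_minutes is exact arithmetic", {
  expect_identical(edge_minutes(60, 3.6), 1.0)
  expect_identical(edge_minutes(8640, 4.32), 120.0)  # 2 h at 3.6 km/h +20%
  expect_equal(edge_minutes(100, 3.6), 5 / 3, tolerance = 1e-9)
  expect_error(edge_minutes(0, 3.6), "> 0")
  expect_error(edge_minutes(10, -1), "> 0")
})

test_that("select_facilities filters by group and buffered boundary", {
  fs <- facility_set(data.frame(
    id = 1:5, x = c(500, 600, 700, 800, 900), y = rep(500, 5),
    group = c("group_i", "group_i", rep("group_ii_other", 3))))
  boundary <- cbind(x = c(0, 1000, 1000, 0), y = c(0, 0, 1000, 1000))
  expect_equal(nrow(select_facilities(fs, "hospitals", boundary, 9)), 2)
  expect_equal(nrow(select_facilities(fs, "all", boundary, 9)), 5)

  # 8.9 km outside kept at 9-km buffer, 9.1 km dropped
  far <- facility_set(data.frame(id = 1:2, x = c(1000 + 8900, 1000 + 9100),
                                 y = c(500, 500), group = "group_i"))
  kept <- select_facilities(far, "all", boundary, 9)
  expect_equal(kept$id, 1)
  expect_warning(select_facilities(far[2, ], "all", boundary, 5),
                 "no facilities")
})

test_that("buffered-polygon membership matches a brute-force oracle", {
  set.seed(101)
  # non-convex boundary
  ring <- cbind(x = c(0, 400, 400, 200, 200, 0),
                y = c(0, 0, 400, 400, 200, 200))
  px <- runif(300, -300, 700); py <- runif(300, -300, 700)
  got <- in_buffered_polygon(px, py, ring, 75)
  # oracle: dense sampling of the dilated region via inside-test on a disc
  # of boundary points plus the polygon itself
  inside <- sp::point.in.polygon(px, py, ring[, 1], ring[, 2]) > 0
  ring_cl <- rbind(ring, ring[1, ])
  seg_pts <- do.call(rbind, lapply(seq_len(nrow(ring_cl) - 1), function(k) {
    t <- seq(0, 1, length.out = 200)
    cbind(ring_cl[k, 1] + t * (ring_cl[k + 1, 1] - ring_cl[k, 1]),
          ring_cl[k, 2] + t * (ring_cl[k + 1, 2] - ring_cl[k, 2]))
  }))
  dmin <- vapply(seq_along(px), function(i)
    min(sqrt((seg_pts[, 1] - px[i])^2 + (seg_pts[, 2] - py[i])^2)),
    numeric(1))
  want <- inside | dmin <= 75
  # discretized boundary sampling can flip points within ~2 m of the rim
  disagree <- which(got != want)
  expect_true(all(abs(dmin[disagree] - 75) < 2))
})

test_that("multi-source travel times on path graphs match hand values", {
  net <- path_network(3, edge_m = 60)
  fs <- facility_set(data.frame(id = 1, x = 0, y = 0, group = "group_i"))
  ntt <- multi_source_travel_times(net, fs, 500, 3.6)
  expect_equal(unname(ntt$minutes[c("1", "2", "3")]), c(0, 1, 2))

  # facilities at both ends of a 10-node path, 1 min per edge
  net10 <- path_network(10, edge_m = 60)
  fs2 <- facility_set(data.frame(id = 1:2, x = c(0, 9 * 60), y = 0,
                                 group = "group_i"))
  ntt2 <- multi_source_travel_times(net10, fs2, 500, 3.6)
  expect_equal(unname(ntt2$minutes[as.character(1:10)]),
               pmin(0:9, 9:0))
})

test_that("snapping honours the radius, offsets and tie-breaks", {
  net <- path_network(3, edge_m = 60)
  # facility 30 m off node 2: offset = 0.5 min at 3.6 km/h
  fs <- facility_set(data.frame(id = 1, x = 60, y = 30, group = "group_i"))
  ntt <- multi_source_travel_times(net, fs, 500, 3.6)
  expect_equal(unname(ntt$minutes[c("1", "2", "3")]), c(1.5, 0.5, 1.5))

  # beyond the radius: dropped with warning, all +Inf
  fs_far <- facility_set(data.frame(id = 1, x = 60, y = 800,
                                    group = "group_i"))
  expect_warning(
    expect_warning(ntt2 <- multi_source_travel_times(net, fs_far, 500, 3.6),
                   "dropped"),
    "no facility snapped")
  expect_true(all(is.infinite(ntt2$minutes)))

  # equidistant between nodes 1 and 2: ties go to the lowest node id
  fs_tie <- facility_set(data.frame(id = 1, x = 30, y = 0, group = "group_i"))
  ntt3 <- multi_source_travel_times(net, fs_tie, 500, 3.6)
  expect_equal(ntt3$snapped$node_id, "1")
})

test_that("multi-source equals the min-over-sources Dijkstra oracle", {
  for (s in 1:8) {
    net <- random_graph(n = 20 + 5 * s, p = 0.15, seed = 500 + s)
    set.seed(600 + s)
    k <- sample(2:4, 1)
    fi <- sample(nrow(net$nodes), k)
    fs <- facility_set(data.frame(id = seq_len(k),
                                  x = net$nodes$x[fi] + runif(k, -50, 50),
                                  y = net$nodes$y[fi] + runif(k, -50, 50),
                                  group = "group_i"))
    got <- multi_source_travel_times(net, fs, 500, 3.6)$minutes
    want <- ref_multi_source(net, fs, 500, 3.6)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("triangle inequality holds along every edge", {
  net <- random_graph(n = 60, p = 0.1, seed = 77)
  fs <- facility_set(data.frame(id = 1, x = net$nodes$x[1],
                                y = net$nodes$y[1], group = "group_i"))
  m <- multi_source_travel_times(net, fs, 500, 3.6)$minutes
  em <- edge_minutes(net$edges$length_m, 3.6)
  du <- m[as.character(net$edges$u)]; dv <- m[as.character(net$edges$v)]
  fin <- is.finite(du) & is.finite(dv)
  expect_true(all(abs(du[fin] - dv[fin]) <= em[fin] + 1e-9))
})

test_that("rasterized travel times match hand values and the cell scan", {
  net <- path_network(3, edge_m = 60)
  fs <- facility_set(data.frame(id = 1, x = 0, y = 0, group = "group_i"))
  ntt <- multi_source_travel_times(net, fs, 500, 3.6)
  # node 2 (x=60) has ntt 1; shift times so the examples use ntt = 7
  ntt$minutes <- ntt$minutes + 6

  # grid with centroids exactly on y = 0, x = 0,5,...: node-coincident cell
  g <- raster_grid(matrix(0, 13, 25), -2.5, -32.5, 5)
  field <- raster_travel_times(ntt, net, g, snap_radius_m = 45,
                               speed_kmh = 3.6)
  cc <- cell_centers(g)
  r0 <- which(cc$y == 0)
  expect_equal(field$values[r0, which(cc$x == 60)], 7)     # on-node cell
  # 30 m straight down from node 2 only (radius 45 excludes nodes 1,3):
  # 7 + 30/60 = 7.5 min
  expect_equal(field$values[which(cc$y == -30), which(cc$x == 60)], 7.5)

  want <- ref_cell_scan(ntt$minutes, net, g, 45, 3.6)
  expect_equal(field$values, want)

  # dense-grid oracle on a random network
  net2 <- random_graph(n = 25, p = 0.2, seed = 9)
  fs2 <- facility_set(data.frame(id = 1, x = net2$nodes$x[3],
                                 y = net2$nodes$y[3], group = "group_i"))
  ntt2 <- multi_source_travel_times(net2, fs2, 500, 3.6)
  g2 <- raster_grid(matrix(0, 40, 40), 0, 0, 25)
  f2 <- raster_travel_times(ntt2, net2, g2, 300, 3.6)
  expect_equal(f2$values, ref_cell_scan(ntt2$minutes, net2, g2, 300, 3.6))

  # empty network: all +Inf
  empty <- road_network(data.frame(id = integer(0), x = numeric(0),
                                   y = numeric(0)),
                        data.frame(u = integer(0), v = integer(0),
                                   length_m = numeric(0)))
  ntt_e <- structure(list(minutes = setNames(numeric(0), character(0)),
                          snapped = data.frame(), speed_kmh = 3.6),
                     class = "node_travel_times")
  fe <- raster_travel_times(ntt_e, empty, g, 500, 3.6)
  expect_true(all(is.infinite(fe$values)))
})

test_that("speed scaling is exact and monotone", {
  net <- random_graph(n = 40, p = 0.12, seed = 55)
  fs <- facility_set(data.frame(id = 1:2,
                                x = net$nodes$x[c(2, 30)] + c(10, -20),
                                y = net$nodes$y[c(2, 30)] + c(-5, 15),
                                group = "group_i"))
  base <- multi_source_travel_times(net, fs, 500, 3.6)$minutes
  for (f in c(0.8, 1.2, 2)) {
    scaled <- multi_source_travel_times(net, fs, 500, 3.6 * f)$minutes
    expect_equal(scaled, base / f, tolerance = 1e-12)
  }
  fast <- multi_source_travel_times(net, fs, 500, 3.6 * 1.2)$minutes
  expect_true(all(fast <= base + 1e-12))
})

test_that("isochrone masks use closed thresholds and are nested", {
  f <- toy_field(matrix(c(10, 20, 130, 0), 2, 2))
  expect_equal(isochrone_mask(f, 120), matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2))
  expect_equal(isochrone_mask(f, 10)[1, 1], TRUE)   # boundary included
  expect_error(isochrone_mask(f, 0), "\\(0")
  expect_error(isochrone_mask(f, 121), "\\(0")

  z <- toy_field(matrix(0, 3, 3))
  expect_true(all(isochrone_mask(z, 1)))

  set.seed(8)
  rf <- toy_field(matrix(sample(c(runif(95, 0, 150), rep(Inf, 5))), 10, 10))
  prev <- isochrone_mask(rf, 1)
  for (t in 2:120) {
    cur <- isochrone_mask(rf, t)
    expect_true(all(cur[prev]))   # nestedness: mask(t-1) subset of mask(t)
    prev <- cur
  }
})
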