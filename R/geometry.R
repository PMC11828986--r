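# Small planar-geometry helpers. No geometry library in the stack provides
# point-to-segment distance, so the dilation test is done by hand; the
# point-in-polygon test itself uses sp.

# Distance from points (px, py) to segment (ax, ay)-(bx, by); vectorized
# over points.
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

# Minimum distance from each point to the polygon boundary (ring given as a
# two-column matrix; closure optional).
dist_to_ring <- function(px, py, ring) {
  ring <- as.matrix(ring)
  n <- nrow(ring)
  if (!isTRUE(all.equal(ring[1, ], ring[n, ], check.attributes = FALSE)))
    ring <- rbind(ring, ring[1, ])
  d <- rep(Inf, length(px))
  for (k in seq_len(nrow(ring) - 1L)) {
    d <- pmin(d, point_segment_distance(px, py,
                                        ring[k, 1], ring[k, 2],
                                        ring[k + 1, 1], ring[k + 1, 2]))
  }
  d
}

#' Point membership in a buffered polygon
#'
#' TRUE for points inside the polygon or within `buffer_m` meters of its
#' boundary — i.e. membership in the polygon dilated by `buffer_m`.
#'
#' @param x,y point coordinates (meters).
#' @param ring polygon exterior ring: two-column matrix or data.frame of
#'   (x, y) vertices; closure optional; holes unsupported.
#' @param buffer_m dilation radius in meters (>= 0).
#' @return logical vector.
#' @export
in_buffered_polygon <- function(x, y, ring, buffer_m = 0) {
  stopifnot(buffer_m >= 0)
  ring <- as.matrix(ring)
  if (nrow(ring) < 3L) stop("polygon ring needs at least 3 vertices")
  inside <- sp::point.in.polygon(x, y, ring[, 1], ring[, 2]) > 0
  if (buffer_m > 0) {
    out <- which(!inside)
    if (length(out))
      inside[out] <- dist_to_ring(x[out], y[out], ring) <= buffer_m
  }
  inside
}

# Bounding-box heuristic for geographic (degree) coordinates: a city-scale
# layer in degrees fits inside the lon/lat box with a tiny span, while a
# projected metric layer spans hundreds of meters or sits far outside it.
looks_geographic <- function(x, y) {
  if (!length(x)) return(FALSE)
  rx <- range(x, finite = TRUE); ry <- range(y, finite = TRUE)
  within <- rx[1] >= -180 && rx[2] <= 180 && ry[1] >= -90 && ry[2] <= 90
  small <- (rx[2] - rx[1]) < 10 && (ry[2] - ry[1]) < 10
  within && small
}

assert_planar_meters <- function(x, y, what) {
  if (looks_geographic(x, y))
    stop(what, " coordinates look geographic (degrees); the pipeline ",
         "requires projected planar meters. Reproject upstream.")
  invisible(TRUE)
}
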