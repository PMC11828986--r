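# GeoJSON and CSV readers/writers for the vector layers. GeoJSON is parsed
# with jsonlite (no simplification, so geometry nesting is explicit).
# Coordinates must be projected planar meters; a bounding-box heuristic
# refuses layers that look like lon/lat degrees, because silent unit errors
# corrupt every downstream number.

read_geojson <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection in ", path)
  gj
}

#' Read a road network
#'
#' Two dialects: `geojson_lines` (a FeatureCollection of LineStrings; each
#' feature becomes one edge between its endpoints, lines meeting at shared
#' endpoints share a graph vertex, edge length is the polyline length) and
#' `node_edge_csv` (a pair of CSVs, `<stem>_nodes.csv` with `id,x,y` and
#' `<stem>_edges.csv` with `u,v,length_m`; pass the stem, or a length-2
#' vector of the two paths).
#'
#' @param path file path (GeoJSON) or CSV stem / length-2 path vector.
#' @param dialect `"geojson_lines"` or `"node_edge_csv"`.
#' @return a `road_network`.
#' @export
read_network <- function(path, dialect = c("geojson_lines", "node_edge_csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "node_edge_csv") return(read_network_csv(path))
  gj <- read_geojson(path)
  feats <- gj$features
  if (!length(feats))
    return(road_network(data.frame(id = integer(0), x = numeric(0), y = numeric(0)),
                        data.frame(u = integer(0), v = integer(0),
                                   length_m = numeric(0))))
  ends <- list(); lens <- numeric(length(feats))
  for (i in seq_along(feats)) {
    geom <- feats[[i]]$geometry
    if (is.null(geom) || is.null(geom$type) || geom$type != "LineString")
      stop("feature ", i, ": expected LineString geometry")
    cds <- geom$coordinates
    if (length(cds) < 2L) stop("feature ", i, ": LineString with < 2 vertices")
    xy <- t(vapply(cds, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]])),
                   numeric(2)))
    if (any(!is.finite(xy))) stop("feature ", i, ": non-finite coordinates")
    seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
    lens[i] <- sum(seg)
    if (!(lens[i] > 0)) stop("feature ", i, ": zero-length LineString")
    ends[[i]] <- c(xy[1, ], xy[nrow(xy), ])
  }
  em <- do.call(rbind, ends)
  assert_planar_meters(c(em[, 1], em[, 3]), c(em[, 2], em[, 4]), "network")
  # vertices = distinct endpoints (exact coordinate match merges them);
  # keys formatted per element so shared endpoints hash identically
  ckey <- function(x, y) paste(sprintf("%.17g", x), sprintf("%.17g", y))
  key_a <- ckey(em[, 1], em[, 2])
  key_b <- ckey(em[, 3], em[, 4])
  keys <- unique(c(key_a, key_b))
  idx_a <- match(key_a, keys); idx_b <- match(key_b, keys)
  first_a <- !duplicated(c(key_a, key_b))
  allx <- c(em[, 1], em[, 3]); ally <- c(em[, 2], em[, 4])
  nodes <- data.frame(id = match(c(key_a, key_b)[first_a], keys),
                      x = allx[first_a], y = ally[first_a])
  nodes <- nodes[order(nodes$id), ]
  road_network(nodes,
               data.frame(u = idx_a, v = idx_b, length_m = lens))
}

read_network_csv <- function(path) {
  paths <- if (length(path) == 2L) path else
    paste0(path, c("_nodes.csv", "_edges.csv"))
  for (p in paths) if (!file.exists(p)) stop("file not found: ", p)
  nodes <- utils::read.csv(paths[1])
  edges <- utils::read.csv(paths[2])
  if (nrow(nodes)) assert_planar_meters(nodes$x, nodes$y, "network")
  road_network(nodes, edges)
}

#' Write a road network as node/edge CSVs
#'
#' @param net a `road_network`.
#' @param stem output stem; writes `<stem>_nodes.csv` and `<stem>_edges.csv`.
#' @return the two paths, invisibly.
#' @export
write_network_csv <- function(net, stem) {
  stopifnot(inherits(net, "road_network"))
  paths <- paste0(stem, c("_nodes.csv", "_edges.csv"))
  utils::write.csv(net$nodes, paths[1], row.names = FALSE)
  utils::write.csv(net$edges, paths[2], row.names = FALSE)
  invisible(paths)
}

#' Write a road network as GeoJSON LineStrings
#'
#' Each edge becomes a two-vertex LineString between its endpoint nodes.
#'
#' @param net a `road_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_geojson <- function(net, path) {
  stopifnot(inherits(net, "road_network"))
  nd <- net$nodes
  feats <- lapply(seq_len(nrow(net$edges)), function(i) {
    a <- nd[match(net$edges$u[i], nd$id), ]
    b <- nd[match(net$edges$v[i], nd$id), ]
    list(type = "Feature",
         properties = list(length_m = net$edges$length_m[i]),
         geometry = list(type = "LineString",
                         coordinates = list(list(a$x, a$y), list(b$x, b$y))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read healthcare facilities
#'
#' Accepts GeoJSON Points or a CSV with `x`, `y` columns. Raw categories in
#' `category_field` are mapped to the two analysis groups via `mapping`
#' (named character vector, e.g. `c(hospital = "group_i")`); unmapped
#' categories fall into `default_group` and are reported in the
#' `unmapped_categories` attribute. Records with missing coordinates are
#' skipped and reported in the `skipped` attribute (the run continues).
#'
#' @param path `.geojson`/`.json` or `.csv` file.
#' @param category_field name of the raw category property/column.
#' @param mapping named character vector raw category -> group.
#' @param default_group group for unmapped categories.
#' @return a `facility_set` with attributes `unmapped_categories`, `skipped`.
#' @export
read_facilities <- function(path, category_field = "category",
                            mapping = c(hospital = "group_i"),
                            default_group = "group_ii_other") {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path)
    if (!category_field %in% names(df))
      stop("category field '", category_field, "' not present")
    rec <- data.frame(id = if ("id" %in% names(df)) df$id else seq_len(nrow(df)),
                      x = df$x, y = df$y,
                      category = as.character(df[[category_field]]),
                      name = if ("name" %in% names(df)) df$name else NA_character_)
  } else {
    gj <- read_geojson(path)
    rec <- do.call(rbind, lapply(seq_along(gj$features), function(i) {
      f <- gj$features[[i]]
      cds <- f$geometry$coordinates
      data.frame(
        id = if (!is.null(f$properties$id)) f$properties$id else i,
        x = if (length(cds) >= 2) as.numeric(cds[[1]]) else NA_real_,
        y = if (length(cds) >= 2) as.numeric(cds[[2]]) else NA_real_,
        category = if (!is.null(f$properties[[category_field]]))
          as.character(f$properties[[category_field]]) else NA_character_,
        name = if (!is.null(f$properties$name)) f$properties$name
          else NA_character_)
    }))
    if (is.null(rec)) rec <- data.frame(id = integer(0), x = numeric(0),
                                        y = numeric(0),
                                        category = character(0),
                                        name = character(0))
  }
  bad <- !is.finite(rec$x) | !is.finite(rec$y)
  skipped <- rec[bad, , drop = FALSE]
  rec <- rec[!bad, , drop = FALSE]
  if (nrow(rec)) assert_planar_meters(rec$x, rec$y, "facility")
  grp <- unname(mapping[rec$category])
  unmapped <- sort(unique(rec$category[is.na(grp)]))
  grp[is.na(grp)] <- default_group
  out <- facility_set(data.frame(id = rec$id, x = rec$x, y = rec$y,
                                 group = grp, name = rec$name))
  attr(out, "unmapped_categories") <- unmapped
  attr(out, "skipped") <- skipped
  out
}

#' Write facilities as GeoJSON Points
#'
#' @param fs a `facility_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_facilities_geojson <- function(fs, path) {
  stopifnot(inherits(fs, "facility_set"))
  feats <- lapply(seq_len(nrow(fs)), function(i) {
    list(type = "Feature",
         properties = list(id = fs$id[i], category = fs$group[i],
                           name = fs$name[i]),
         geometry = list(type = "Point",
                         coordinates = list(fs$x[i], fs$y[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a city boundary polygon
#'
#' First Polygon feature of a GeoJSON FeatureCollection; exterior ring only.
#'
#' @param path GeoJSON path.
#' @return two-column matrix of ring vertices (meters).
#' @export
read_boundary <- function(path) {
  gj <- read_geojson(path)
  for (f in gj$features) {
    if (!is.null(f$geometry$type) && f$geometry$type == "Polygon") {
      ring <- t(vapply(f$geometry$coordinates[[1]],
                       function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]])),
                       numeric(2)))
      assert_planar_meters(ring[, 1], ring[, 2], "boundary")
      colnames(ring) <- c("x", "y")
      return(ring)
    }
  }
  stop("no Polygon feature found in ", path)
}

#' Write a boundary polygon as GeoJSON
#' @param ring two-column matrix of exterior-ring vertices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_boundary <- function(ring, path) {
  ring <- as.matrix(ring)
  n <- nrow(ring)
  if (!isTRUE(all.equal(ring[1, ], ring[n, ], check.attributes = FALSE)))
    ring <- rbind(ring, ring[1, ])
  coords <- lapply(seq_len(nrow(ring)),
                   function(i) list(ring[i, 1], ring[i, 2]))
  feat <- list(type = "Feature", properties = list(),
               geometry = list(type = "Polygon", coordinates = list(coords)))
  jsonlite::write_json(list(type = "FeatureCollection", features = list(feat)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
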