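#' Landscape container for covariate construction
#'
#' Holds the park boundary, road network, settlements, headquarters and
#' the deforestation grid on a planar km coordinate frame. Optional slope
#' and habitat grids (regular point lattices with nearest-neighbour
#' lookup) may be attached.
#'
#' @param boundary closed polygon as a two-column matrix (x_km, y_km);
#'   first and last vertex need not repeat.
#' @param roads list of polylines, each a two-column matrix (km).
#' @param villages,towns two-column matrices of points (km).
#' @param headquarters length-2 numeric (km).
#' @param grid deforestation grid: data frame with `cx_km`, `cy_km`,
#'   `cell_km`, `nonforest_t1_km2`, `nonforest_t2_km2`.
#' @param slope_grid optional data frame `x_km`, `y_km`, `slope_deg`.
#' @param habitat_grid optional data frame `x_km`, `y_km`, `habitat`.
#' @return object of class `landscape`.
#' @export
landscape <- function(boundary, roads, villages, towns, headquarters,
                      grid, slope_grid = NULL, habitat_grid = NULL) {
  boundary <- as.matrix(boundary)
  stopifnot(ncol(boundary) == 2, nrow(boundary) >= 3)
  if (!is.null(grid)) {
    need <- c("cx_km", "cy_km", "cell_km",
              "nonforest_t1_km2", "nonforest_t2_km2")
    miss <- setdiff(need, names(grid))
    if (length(miss) > 0) {
      stop("deforestation grid missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    cell_area <- grid$cell_km^2
    bad <- grid$nonforest_t1_km2 < 0 | grid$nonforest_t2_km2 < 0 |
      grid$nonforest_t1_km2 > cell_area | grid$nonforest_t2_km2 > cell_area
    if (any(bad)) {
      stop("non-forested area per cell must lie in [0, cell area]",
           call. = FALSE)
    }
  }
  structure(
    list(boundary = boundary,
         roads = lapply(roads, as.matrix),
         villages = as.matrix(villages),
         towns = as.matrix(towns),
         headquarters = as.numeric(headquarters),
         grid = grid,
         slope_grid = slope_grid,
         habitat_grid = habitat_grid),
    class = "landscape"
  )
}

#' @export
print.landscape <- function(x, ...) {
  cat("Landscape on planar km frame\n")
  cat(sprintf("  boundary: %d vertices; %d road(s); %d villages; %d towns\n",
              nrow(x$boundary), length(x$roads), nrow(x$villages),
              nrow(x$towns)))
  if (!is.null(x$grid)) {
    cat(sprintf("  deforestation grid: %d cells of %.1f km\n",
                nrow(x$grid), x$grid$cell_km[1]))
  }
  invisible(x)
}

# --- planar geometry primitives -------------------------------------------

#' Distance from points to a segment
#'
#' @param p two-column matrix of points.
#' @param a,b segment endpoints (length-2 numeric).
#' @return numeric vector of Euclidean distances (same units as inputs).
#' @keywords internal
dist_point_segment <- function(p, a, b) {
  p <- matrix(p, ncol = 2)
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return(sqrt((p[, 1] - a[1])^2 + (p[, 2] - a[2])^2))
  }
  t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  qx <- a[1] + t * ab[1]
  qy <- a[2] + t * ab[2]
  sqrt((p[, 1] - qx)^2 + (p[, 2] - qy)^2)
}

#' Distance from points to a polyline
#' @param p two-column matrix of points.
#' @param line two-column matrix of polyline vertices.
#' @param closed close the polyline (treat as polygon ring)?
#' @return minimum distance over all segments, per point.
#' @keywords internal
dist_point_polyline <- function(p, line, closed = FALSE) {
  p <- matrix(p, ncol = 2)
  line <- as.matrix(line)
  if (closed && any(line[1, ] != line[nrow(line), ])) {
    line <- rbind(line, line[1, ])
  }
  d <- rep(Inf, nrow(p))
  for (i in seq_len(nrow(line) - 1)) {
    d <- pmin(d, dist_point_segment(p, line[i, ], line[i + 1, ]))
  }
  d
}

#' Minimum distance from points to a set of points
#' @keywords internal
dist_point_points <- function(p, q) {
  p <- matrix(p, ncol = 2)
  q <- matrix(q, ncol = 2)
  apply(p, 1, function(pt) {
    min(sqrt((q[, 1] - pt[1])^2 + (q[, 2] - pt[2])^2))
  })
}

#' Point-in-polygon test (even-odd ray casting)
#' @param p two-column matrix of points.
#' @param poly polygon vertex matrix (closed or open ring).
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(p, poly) {
  p <- matrix(p, ncol = 2)
  poly <- as.matrix(poly)
  if (all(poly[1, ] == poly[nrow(poly), ])) {
    poly <- poly[-nrow(poly), , drop = FALSE]
  }
  nv <- nrow(poly)
  inside <- rep(FALSE, nrow(p))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > p[, 2]) != (yj > p[, 2])) &
      (p[, 1] < (xj - xi) * (p[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Transect midpoints
#'
#' Midpoint of each transect from its origin, bearing (degrees clockwise
#' from north) and length. Transects are represented by their midpoint
#' for all covariate calculations.
#'
#' @param transects transect table (`x_km`, `y_km`, `bearing_deg`,
#'   `length_km`).
#' @return two-column matrix of midpoints (km), rows named by transect_id.
#' @export
transect_midpoints <- function(transects) {
  theta <- transects$bearing_deg * pi / 180
  half <- transects$length_km / 2
  m <- cbind(x_km = transects$x_km + half * sin(theta),
             y_km = transects$y_km + half * cos(theta))
  rownames(m) <- as.character(transects$transect_id)
  m
}

# --- GeoJSON I/O ----------------------------------------------------------

#' Write a landscape to GeoJSON + grid CSV
#'
#' Geometry goes to an RFC 7946 FeatureCollection (coordinates are planar
#' km; each feature carries a `role` property identifying it as boundary,
#' road, village, town or headquarters). The deforestation grid goes to a
#' separate CSV.
#'
#' @param ls_obj a [landscape()].
#' @param geojson_path,grid_csv output paths (`grid_csv` may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_landscape <- function(ls_obj, geojson_path, grid_csv = NULL) {
  stopifnot(inherits(ls_obj, "landscape"))
  coords <- function(m) lapply(seq_len(nrow(m)), function(i) m[i, 1:2])
  ring <- ls_obj$boundary
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  features <- list(list(
    type = "Feature",
    properties = list(role = "boundary"),
    geometry = list(type = "Polygon", coordinates = list(coords(ring)))
  ))
  for (r in ls_obj$roads) {
    features[[length(features) + 1]] <- list(
      type = "Feature", properties = list(role = "road"),
      geometry = list(type = "LineString", coordinates = coords(r)))
  }
  pts <- function(m, role) lapply(seq_len(nrow(m)), function(i) list(
    type = "Feature", properties = list(role = role),
    geometry = list(type = "Point", coordinates = m[i, 1:2])))
  features <- c(features, pts(ls_obj$villages, "village"),
                pts(ls_obj$towns, "town"))
  features[[length(features) + 1]] <- list(
    type = "Feature", properties = list(role = "headquarters"),
    geometry = list(type = "Point",
                    coordinates = ls_obj$headquarters))
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, geojson_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(grid_csv) && !is.null(ls_obj$grid)) {
    utils::write.csv(ls_obj$grid, grid_csv, row.names = FALSE)
  }
  invisible(c(geojson_path, grid_csv))
}

#' Read a landscape from GeoJSON + grid CSV
#'
#' @param geojson_path FeatureCollection written by [write_landscape()]
#'   (or any collection whose features carry a `role` property).
#' @param grid_csv optional deforestation grid CSV.
#' @return a [landscape()] (without slope/habitat grids, which are not
#'   serialized to GeoJSON).
#' @export
read_landscape <- function(geojson_path, grid_csv = NULL) {
  fc <- jsonlite::read_json(geojson_path)
  if (is.null(fc$type) || fc$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection", call. = FALSE)
  }
  mat <- function(coord_list) {
    do.call(rbind, lapply(coord_list, function(c2) as.numeric(unlist(c2))))
  }
  boundary <- NULL; roads <- list()
  villages <- list(); towns <- list(); hq <- NULL
  for (f in fc$features) {
    role <- f$properties$role
    g <- f$geometry
    if (identical(role, "boundary")) {
      boundary <- mat(g$coordinates[[1]])
    } else if (identical(role, "road")) {
      roads[[length(roads) + 1]] <- mat(g$coordinates)
    } else if (identical(role, "village")) {
      villages[[length(villages) + 1]] <- as.numeric(unlist(g$coordinates))
    } else if (identical(role, "town")) {
      towns[[length(towns) + 1]] <- as.numeric(unlist(g$coordinates))
    } else if (identical(role, "headquarters")) {
      hq <- as.numeric(unlist(g$coordinates))
    }
  }
  if (is.null(boundary)) stop("no boundary feature found", call. = FALSE)
  grid <- if (!is.null(grid_csv)) utils::read.csv(grid_csv) else NULL
  landscape(boundary = boundary, roads = roads,
            villages = do.call(rbind, villages),
            towns = do.call(rbind, towns),
            headquarters = hq, grid = grid)
}
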