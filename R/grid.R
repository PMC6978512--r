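#' Define a pixel-aligned analysis grid
#'
#' A `grid_spec` pins down the geometry shared by every raster layer in an
#' analysis: the projected coordinate of the grid's north-west corner, the
#' pixel size in metres, the grid dimensions, and an identifier of the
#' projected metric CRS all layers live in. Layers are plain numeric matrices
#' whose row 1 is the northernmost row; a pixel at `(row, col)` has its centre
#' at `origin_x + (col - 0.5) * pixel_size`,
#' `origin_y - (row - 0.5) * pixel_size`.
#'
#' At the default 30-m pixel size each pixel covers 900 m^2 = 0.09 ha, the
#' conversion factor used throughout the dead-biomass allocation equations.
#'
#' @param origin_x,origin_y Projected coordinates (m) of the north-west grid
#'   corner (x of the west edge, y of the north edge).
#' @param n_rows,n_cols Grid dimensions.
#' @param pixel_size Pixel edge length in metres (default 30).
#' @param crs_id Identifier of the projected, metric CRS (free-form string;
#'   layers only combine when their `crs_id` strings match).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin_x, origin_y, n_rows, n_cols, pixel_size = 30,
                      crs_id = "LOCAL_METRIC") {
  stopifnot(is.numeric(origin_x), is.numeric(origin_y),
            n_rows >= 1, n_cols >= 1, pixel_size > 0)
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pixel_size = as.numeric(pixel_size), crs_id = as.character(crs_id)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels @ %g m, origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$pixel_size, x$origin_x, x$origin_y,
              x$crs_id))
  invisible(x)
}

#' Pixel area in hectares
#'
#' @param spec A [grid_spec()].
#' @return Pixel area in ha (0.09 for a 30-m grid).
#' @export
pixel_area_ha <- function(spec) spec$pixel_size^2 / 1e4

same_spec <- function(a, b, tol = 1e-6) {
  abs(a$origin_x - b$origin_x) < tol && abs(a$origin_y - b$origin_y) < tol &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$pixel_size - b$pixel_size) < tol && a$crs_id == b$crs_id
}

check_spec <- function(spec, expected, what = "layer") {
  if (!same_spec(spec, expected)) {
    stop(sprintf("%s grid is misaligned with the expected grid (origin/size/dims/crs must match)",
                 what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Coordinates of pixel centres
#'
#' @param spec A [grid_spec()].
#' @param rows,cols Optional parallel vectors of 1-based pixel indices; by
#'   default all pixels, in column-major order.
#' @return A tibble with columns `row`, `col`, `x`, `y`.
#' @export
pixel_centers <- function(spec, rows = NULL, cols = NULL) {
  if (is.null(rows)) {
    rows <- rep(seq_len(spec$n_rows), times = spec$n_cols)
    cols <- rep(seq_len(spec$n_cols), each = spec$n_rows)
  }
  tibble::tibble(
    row = as.integer(rows), col = as.integer(cols),
    x = spec$origin_x + (cols - 0.5) * spec$pixel_size,
    y = spec$origin_y - (rows - 0.5) * spec$pixel_size
  )
}

# ---- raster I/O: Esri ASCII grid + JSON sidecar carrying the CRS ------------

#' Write a raster layer as an Esri ASCII grid
#'
#' Layers are written in the plain-text Esri ASCII grid format (rows from
#' north to south) with a small JSON sidecar (`<path>.json`) recording the CRS
#' identifier so round-trips preserve full georeferencing.
#'
#' @param values Numeric matrix (row 1 = northernmost row).
#' @param spec The layer's [grid_spec()].
#' @param path Output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_grid <- function(values, spec, path) {
  stopifnot(is.matrix(values), nrow(values) == spec$n_rows,
            ncol(values) == spec$n_cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$origin_x),
    sprintf("yllcorner %.10g", spec$origin_y - spec$n_rows * spec$pixel_size),
    sprintf("cellsize %.10g", spec$pixel_size),
    "NODATA_value -9999"
  ), con)
  vals <- values
  vals[is.na(vals)] <- -9999
  writeLines(apply(vals, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                      scientific = FALSE),
                                               collapse = " ")), con)
  jsonlite::write_json(list(crs_id = spec$crs_id), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a raster layer from an Esri ASCII grid
#'
#' @param path Path to an `.asc` file written by [write_grid()] (or any Esri
#'   ASCII grid; the CRS sidecar is optional and defaults to
#'   `"LOCAL_METRIC"`).
#' @param expected_spec Optional [grid_spec()]; reading fails if the file's
#'   grid does not align with it exactly.
#' @return A list with elements `values` (matrix) and `spec`.
#' @export
read_grid <- function(path, expected_spec = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  n_rows <- as.integer(hdr$nrows); n_cols <- as.integer(hdr$ncols)
  body <- lines[i:(i + n_rows - 1L)]
  vals <- matrix(scan(text = paste(body, collapse = "\n"), quiet = TRUE),
                 nrow = n_rows, ncol = n_cols, byrow = TRUE)
  nodata <- hdr$nodata_value
  if (!is.null(nodata)) vals[vals == nodata] <- NA_real_
  crs_id <- "LOCAL_METRIC"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    crs_id <- jsonlite::read_json(sidecar)$crs_id
  }
  spec <- grid_spec(
    origin_x = hdr$xllcorner,
    origin_y = hdr$yllcorner + n_rows * hdr$cellsize,
    n_rows = n_rows, n_cols = n_cols, pixel_size = hdr$cellsize,
    crs_id = crs_id
  )
  if (!is.null(expected_spec)) check_spec(spec, expected_spec, basename(path))
  list(values = vals, spec = spec)
}

# ---- vector geometry -------------------------------------------------------

check_polygon <- function(coords) {
  if (!is.matrix(coords) || ncol(coords) < 2 || nrow(coords) < 3 ||
      anyNA(coords)) {
    stop("invalid polygon geometry: need a numeric matrix of >= 3 vertices",
         call. = FALSE)
  }
  # degenerate (zero-area) rings are invalid
  x <- coords[, 1]; y <- coords[, 2]
  area2 <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y))
  if (area2 <= 0) stop("invalid polygon geometry: zero area", call. = FALSE)
  invisible(TRUE)
}

#' Pixels whose centres fall inside a polygon
#'
#' Implements the pixel-selection rule used throughout the pipeline: a pixel
#' belongs to a polygon exactly when its centre lies inside or on the boundary
#' of the polygon (centre-containment; boundary counts as inside). The
#' candidate set is cropped to the polygon's bounding box before the
#' point-in-polygon test, so large grids are handled efficiently.
#'
#' @param coords Polygon ring as a 2-column matrix of vertices (closed or
#'   open; the ring is treated as closed).
#' @param spec The analysis [grid_spec()].
#' @return A tibble with columns `row`, `col`, `x`, `y` of member pixels
#'   (zero rows when the polygon misses the grid).
#' @export
pixels_in_polygon <- function(coords, spec) {
  check_polygon(coords)
  px <- spec$pixel_size
  # candidate rows/cols from the polygon bounding box
  xr <- range(coords[, 1]); yr <- range(coords[, 2])
  col_lo <- max(1L, ceiling((xr[1] - spec$origin_x) / px + 0.5 - 1e-9))
  col_hi <- min(spec$n_cols, floor((xr[2] - spec$origin_x) / px + 0.5 + 1e-9))
  row_lo <- max(1L, ceiling((spec$origin_y - yr[2]) / px + 0.5 - 1e-9))
  row_hi <- min(spec$n_rows, floor((spec$origin_y - yr[1]) / px + 0.5 + 1e-9))
  if (col_lo > col_hi || row_lo > row_hi) {
    return(pixel_centers(spec, integer(0), integer(0)))
  }
  rows <- rep(row_lo:row_hi, times = col_hi - col_lo + 1L)
  cols <- rep(col_lo:col_hi, each = row_hi - row_lo + 1L)
  cand <- pixel_centers(spec, rows, cols)
  inside <- sp::point.in.polygon(cand$x, cand$y, coords[, 1], coords[, 2]) > 0
  cand[inside, ]
}

#' Distance from points to the nearest road
#'
#' Straight-line (Euclidean) distance from each point to the nearest point on
#' any road centreline, the proximity measure used for the road-access cost
#' class. An empty road network yields `Inf` for every point (all pixels fall
#' beyond any cutoff).
#'
#' @param x,y Numeric vectors of point coordinates (m).
#' @param roads A list of polylines, each a 2-column coordinate matrix.
#' @return Numeric vector of distances (m).
#' @export
distance_to_nearest_road <- function(x, y, roads) {
  n <- length(x)
  if (length(roads) == 0) return(rep(Inf, n))
  best <- rep(Inf, n)
  for (line in roads) {
    stopifnot(is.matrix(line), nrow(line) >= 2)
    for (s in seq_len(nrow(line) - 1L)) {
      ax <- line[s, 1]; ay <- line[s, 2]
      bx <- line[s + 1L, 1]; by <- line[s + 1L, 2]
      dx <- bx - ax; dy <- by - ay
      len2 <- dx * dx + dy * dy
      if (len2 == 0) {
        d <- sqrt((x - ax)^2 + (y - ay)^2)
      } else {
        t <- pmin(1, pmax(0, ((x - ax) * dx + (y - ay) * dy) / len2))
        d <- sqrt((x - (ax + t * dx))^2 + (y - (ay + t * dy))^2)
      }
      best <- pmin(best, d)
    }
  }
  best
}

#' Membership in a buffer around the road network
#'
#' Tests whether points fall inside the `radius`-metre buffer of a polyline
#' network, built exactly as the union of per-segment capsules (an oriented
#' rectangle plus end-cap circles per segment, i.e. round joins and caps).
#' Thresholding [distance_to_nearest_road()] at `radius` gives the identical
#' classification; the two routes are kept as independent implementations.
#'
#' @inheritParams distance_to_nearest_road
#' @param radius Buffer radius (m).
#' @return Logical vector.
#' @export
in_road_buffer <- function(x, y, roads, radius) {
  n <- length(x)
  if (length(roads) == 0) return(rep(FALSE, n))
  inside <- rep(FALSE, n)
  r2 <- radius^2
  for (line in roads) {
    for (s in seq_len(nrow(line) - 1L)) {
      ax <- line[s, 1]; ay <- line[s, 2]
      bx <- line[s + 1L, 1]; by <- line[s + 1L, 2]
      # end-cap circles
      inside <- inside | ((x - ax)^2 + (y - ay)^2 <= r2) |
        ((x - bx)^2 + (y - by)^2 <= r2)
      dx <- bx - ax; dy <- by - ay
      len <- sqrt(dx * dx + dy * dy)
      if (len > 0) {
        # oriented rectangle: |cross| / len <= radius and projection in [0, len]
        proj <- ((x - ax) * dx + (y - ay) * dy) / len
        perp <- abs((x - ax) * dy - (y - ay) * dx) / len
        inside <- inside | (proj >= 0 & proj <= len & perp <= radius)
      }
    }
  }
  inside
}

# ---- vector I/O: GeoJSON ---------------------------------------------------

geojson_polygon <- function(coords) {
  ring <- coords
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  list(type = "Polygon", coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) c(ring[i, 1], ring[i, 2]))))
}

geojson_linestring <- function(coords) {
  list(type = "LineString",
       coordinates = lapply(seq_len(nrow(coords)),
                            function(i) c(coords[i, 1], coords[i, 2])))
}

coords_from_geojson <- function(geom) {
  if (geom$type == "Polygon") {
    ring <- geom$coordinates[[1]]
  } else if (geom$type == "LineString") {
    ring <- geom$coordinates
  } else {
    stop("unsupported GeoJSON geometry type: ", geom$type, call. = FALSE)
  }
  do.call(rbind, lapply(ring, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
}

#' Write geometries with attributes to GeoJSON
#'
#' @param geoms List of 2-column coordinate matrices.
#' @param properties A data frame of per-feature attributes (or `NULL`).
#' @param path Output path.
#' @param type `"Polygon"` or `"LineString"`.
#' @param crs_id CRS identifier recorded in the file's `crs` member.
#' @return `path`, invisibly.
#' @export
write_features <- function(geoms, properties = NULL, path,
                           type = c("Polygon", "LineString"),
                           crs_id = "LOCAL_METRIC") {
  type <- match.arg(type)
  make_geom <- if (type == "Polygon") geojson_polygon else geojson_linestring
  features <- lapply(seq_along(geoms), function(i) {
    props <- if (is.null(properties)) stats::setNames(list(), character(0)) else
      as.list(properties[i, , drop = FALSE])
    list(type = "Feature", properties = props, geometry = make_geom(geoms[[i]]))
  })
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name", properties = list(name = crs_id)),
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read geometries with attributes from GeoJSON
#'
#' @param path Path to a GeoJSON FeatureCollection.
#' @return A list with `geometry` (list of coordinate matrices), `properties`
#'   (tibble, one row per feature) and `crs_id`.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("vector file not found: ", path, call. = FALSE)
  fc <- jsonlite::read_json(path)
  geoms <- lapply(fc$features, function(f) coords_from_geojson(f$geometry))
  props <- purrr::map_dfr(fc$features, function(f) {
    p <- f$properties
    if (length(p) == 0) tibble::tibble(.rows = 1) else tibble::as_tibble(p)
  })
  crs_id <- tryCatch(fc$crs$properties$name, error = function(e) "LOCAL_METRIC")
  if (is.null(crs_id)) crs_id <- "LOCAL_METRIC"
  list(geometry = geoms, properties = props, crs_id = crs_id)
}
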