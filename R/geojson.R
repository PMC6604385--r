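# Thin GeoJSON layer (RFC 7946, WGS84 lon/lat order) on top of jsonlite,
# specialised to the vector layers the pipeline uses: point layers with
# properties, line layers, and polygon layers.

read_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection in ", path, call. = FALSE)
  }
  gj$features
}

gj_coords <- function(coords) {
  # coordinate array -> numeric matrix (lon, lat)
  do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
}

#' Read a GeoJSON point layer into a tibble
#'
#' @param path Path to a GeoJSON FeatureCollection of Points.
#' @param properties Character vector of property names to extract as columns.
#' @return A tibble with `lon`, `lat` and one column per requested property.
#' @export
read_geojson_points <- function(path, properties = character()) {
  feats <- read_geojson(path)
  rows <- lapply(feats, function(f) {
    if (f$geometry$type != "Point") stop("expected Point geometry in ", path, call. = FALSE)
    out <- list(lon = f$geometry$coordinates[[1]], lat = f$geometry$coordinates[[2]])
    for (p in properties) out[[p]] <- f$properties[[p]] %||% NA
    tibble::as_tibble(out)
  })
  dplyr::bind_rows(rows)
}

#' Read a GeoJSON line layer (roads)
#'
#' @param path Path to a FeatureCollection of LineString/MultiLineString.
#' @param properties Property names to extract.
#' @return A tibble with a list-column `geometry` (lon/lat matrices, one per
#'   linestring part) plus the requested properties.
#' @export
read_geojson_lines <- function(path, properties = character()) {
  feats <- read_geojson(path)
  rows <- lapply(feats, function(f) {
    geom <- switch(f$geometry$type,
      LineString = list(gj_coords(f$geometry$coordinates)),
      MultiLineString = lapply(f$geometry$coordinates, gj_coords),
      stop("expected LineString geometry in ", path, call. = FALSE)
    )
    out <- list(geometry = list(geom))
    for (p in properties) out[[p]] <- f$properties[[p]] %||% NA
    tibble::as_tibble(out)
  })
  dplyr::bind_rows(rows)
}

#' Read a GeoJSON polygon layer (smoke plumes)
#'
#' @param path Path to a FeatureCollection of Polygons.
#' @param properties Property names to extract.
#' @return A tibble with a list-column `rings` (list of lon/lat ring matrices)
#'   plus the requested properties.
#' @export
read_geojson_polygons <- function(path, properties = character()) {
  feats <- read_geojson(path)
  rows <- lapply(feats, function(f) {
    if (f$geometry$type != "Polygon") stop("expected Polygon geometry in ", path, call. = FALSE)
    rings <- lapply(f$geometry$coordinates, gj_coords)
    out <- list(rings = list(rings))
    for (p in properties) out[[p]] <- f$properties[[p]] %||% NA
    tibble::as_tibble(out)
  })
  dplyr::bind_rows(rows)
}

gj_feature <- function(geometry, properties) {
  list(type = "Feature", properties = properties, geometry = geometry)
}

write_geojson <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write point / line / polygon layers as GeoJSON
#'
#' @param df Tibble as returned by the matching reader (`lon`/`lat` columns
#'   for points, `geometry` list-column for lines, `rings` for polygons);
#'   remaining columns become feature properties.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson_points <- function(df, path) {
  props <- setdiff(names(df), c("lon", "lat"))
  feats <- lapply(seq_len(nrow(df)), function(i) {
    gj_feature(list(type = "Point", coordinates = c(df$lon[i], df$lat[i])),
               as.list(df[i, props, drop = FALSE]))
  })
  write_geojson(feats, path)
}

#' @rdname write_geojson_points
#' @export
write_geojson_lines <- function(df, path) {
  props <- setdiff(names(df), "geometry")
  feats <- lapply(seq_len(nrow(df)), function(i) {
    parts <- df$geometry[[i]]
    geom <- if (length(parts) == 1L) {
      list(type = "LineString", coordinates = coords_list(parts[[1]]))
    } else {
      list(type = "MultiLineString", coordinates = lapply(parts, coords_list))
    }
    gj_feature(geom, as.list(df[i, props, drop = FALSE]))
  })
  write_geojson(feats, path)
}

#' @rdname write_geojson_points
#' @export
write_geojson_polygons <- function(df, path) {
  props <- setdiff(names(df), "rings")
  feats <- lapply(seq_len(nrow(df)), function(i) {
    geom <- list(type = "Polygon", coordinates = lapply(df$rings[[i]], coords_list))
    gj_feature(geom, as.list(df[i, props, drop = FALSE]))
  })
  write_geojson(feats, path)
}

coords_list <- function(mat) {
  lapply(seq_len(nrow(mat)), function(i) c(mat[i, 1], mat[i, 2]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
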