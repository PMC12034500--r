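#' Construct a polygon layer
#'
#' A layer is a tibble with one row per feature: a `name` column, optional
#' extra attribute columns, and a `geometry` list-column. Each geometry is a
#' list of parts (multipolygon support), each part a list of rings (first
#' outer, rest holes), each ring an n x 2 matrix of WGS84 lon/lat vertices
#' without a repeated closing vertex.
#'
#' @param name Character vector of feature names.
#' @param geometry List of geometries (see description). A bare ring matrix
#'   is promoted to a single-part, single-ring geometry.
#' @param layer_name Name of the layer as a whole.
#' @param ... Additional attribute columns, recycled tidyverse-style.
#' @return A `cpi_layer` tibble.
#' @export
geo_layer <- function(name, geometry, layer_name = "layer", ...) {
  geometry <- lapply(geometry, function(g) {
    if (is.matrix(g)) g <- list(list(g))
    lapply(g, function(part) lapply(part, normalize_ring))
  })
  out <- tibble::tibble(name = as.character(name), ..., geometry = geometry)
  validate_layer_geometries(out, layer_name)
  attr(out, "layer_name") <- layer_name
  class(out) <- c("cpi_layer", class(out))
  out
}

validate_layer_geometries <- function(layer, layer_name) {
  for (i in seq_len(nrow(layer))) {
    geom <- layer$geometry[[i]]
    for (part in geom) {
      for (ring in part) {
        if (nrow(ring) < 3) {
          stop_validation("layer '%s', feature %d: ring with fewer than 3 distinct vertices",
                          layer_name, i)
        }
        if (abs(ring_area_signed(ring)) < 1e-12) {
          stop_validation("layer '%s', feature %d: degenerate (zero-area) ring",
                          layer_name, i)
        }
        if (any(abs(ring[, 1]) > 180) || any(abs(ring[, 2]) > 90)) {
          stop_validation("layer '%s', feature %d: coordinates outside WGS84 bounds",
                          layer_name, i)
        }
      }
    }
  }
  invisible(layer)
}

#' Read a GeoJSON polygon layer
#'
#' Reads a GeoJSON FeatureCollection of Polygon/MultiPolygon features
#' (WGS84). Feature names are taken from a `name` property when present,
#' else `feature_<i>`; all other scalar properties are kept as columns.
#'
#' @param path Path to a `.geojson` file.
#' @param layer_name Optional layer name; defaults to the FeatureCollection
#'   `name` member or the file name.
#' @return A [geo_layer()] tibble.
#' @export
read_geojson_layer <- function(path, layer_name = NULL) {
  if (!file.exists(path)) stop_schema("file not found: %s", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop_schema("'%s' is not a GeoJSON FeatureCollection", path)
  }
  layer_name <- layer_name %||% gj$name %||% sub("\\.[^.]*$", "", basename(path))
  feats <- gj$features
  if (length(feats) == 0) stop_validation("layer '%s' has no features", layer_name)
  parse_ring <- function(rg, i) {
    m <- do.call(rbind, lapply(rg, function(p) as.numeric(unlist(p)[1:2])))
    if (nrow(m) < 4 || any(abs(m[1, ] - m[nrow(m), ]) > 1e-12)) {
      stop_validation("feature %d: ring is not closed", i)
    }
    normalize_ring(m)
  }
  geoms <- vector("list", length(feats))
  props <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    g <- feats[[i]]$geometry
    if (is.null(g$type)) stop_validation("feature %d: missing geometry", i)
    geoms[[i]] <- switch(
      g$type,
      Polygon = list(lapply(g$coordinates, parse_ring, i = i)),
      MultiPolygon = lapply(g$coordinates, function(poly) lapply(poly, parse_ring, i = i)),
      stop_validation("feature %d: unsupported geometry type '%s'", i, g$type)
    )
    p <- feats[[i]]$properties
    props[[i]] <- if (is.null(p)) list() else p[vapply(p, function(v)
      is.atomic(v) && length(v) == 1, TRUE)]
  }
  nm <- vapply(seq_along(feats), function(i)
    as.character(props[[i]]$name %||% sprintf("feature_%d", i)), "")
  extra_names <- setdiff(unique(unlist(lapply(props, names))), "name")
  extras <- lapply(extra_names, function(k)
    unlist(lapply(props, function(p) p[[k]] %||% NA)))
  names(extras) <- extra_names
  do.call(geo_layer, c(list(name = nm, geometry = geoms, layer_name = layer_name),
                       extras))
}

#' Write a polygon layer to GeoJSON
#'
#' @param layer A [geo_layer()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson_layer <- function(layer, path) {
  close_ring <- function(r) {
    r <- rbind(r, r[1, ])
    lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
  }
  attr_cols <- setdiff(names(layer), c("geometry"))
  feats <- lapply(seq_len(nrow(layer)), function(i) {
    geom <- layer$geometry[[i]]
    coords <- lapply(geom, function(part) lapply(part, close_ring))
    gtype <- if (length(geom) == 1) "Polygon" else "MultiPolygon"
    if (gtype == "Polygon") coords <- coords[[1]]
    props <- lapply(attr_cols, function(k) layer[[k]][i])
    names(props) <- attr_cols
    list(type = "Feature", properties = props,
         geometry = list(type = gtype, coordinates = coords))
  })
  obj <- list(type = "FeatureCollection",
              name = attr(layer, "layer_name") %||% "layer",
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}
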