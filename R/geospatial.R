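#' Extent of occurrence by convex hull
#'
#' EOO is the area of the minimum convex polygon enclosing a species'
#' occurrence points, computed in a Lambert azimuthal equal-area projection
#' centered on the points.
#'
#' @param points Tibble with `longitude`, `latitude` (one species).
#' @param proj Optional [laea_projection()]; default centered on the points.
#' @return A list: `eoo_km2`, `hull` (lon/lat ring matrix of the hull) and
#'   `proj`. Fewer than 3 distinct points, or collinear points, raise a
#'   classed error with class `cycadcpi_degenerate` so callers can fall back
#'   to an occupancy-based area.
#' @export
eoo_convex_hull <- function(points, proj = NULL) {
  pts <- unique(cbind(points$longitude, points$latitude))
  if (nrow(pts) < 3) {
    rlang::abort("fewer than 3 distinct points: EOO degenerate",
                 class = c("cycadcpi_degenerate", "cycadcpi_validation_error"))
  }
  # collinearity in geographic coordinates: all cross products of edge
  # vectors from the first point vanish relative to the extent
  v <- sweep(pts[-1, , drop = FALSE], 2, pts[1, ])
  cross <- v[1, 1] * v[, 2] - v[1, 2] * v[, 1]
  if (max(abs(cross)) <= 1e-9 * max(abs(v))^2) {
    rlang::abort("collinear points: EOO degenerate",
                 class = c("cycadcpi_degenerate", "cycadcpi_validation_error"))
  }
  proj <- proj %||% projection_for(pts[, 1], pts[, 2])
  xy <- project_lonlat(proj, pts[, 1], pts[, 2])
  hull_idx <- grDevices::chull(xy[, 1], xy[, 2])
  area <- abs(ring_area_signed(xy[hull_idx, , drop = FALSE]))
  if (length(hull_idx) < 3 || area < 1e-9) {
    rlang::abort("collinear points: EOO degenerate",
                 class = c("cycadcpi_degenerate", "cycadcpi_validation_error"))
  }
  list(eoo_km2 = area,
       hull = pts[rev(hull_idx), , drop = FALSE],
       proj = proj)
}

#' Count occupied locations on a coarse grid
#'
#' The number of locations is approximated by the count of distinct
#' occupied grid cells of side `cell_km` in the equal-area plane (default
#' 10 km, the conR convention).
#'
#' @param points Tibble with `longitude`, `latitude`.
#' @param cell_km Cell side in km.
#' @param proj Optional projection (default centered on the points).
#' @return Integer count >= 1.
#' @export
count_locations <- function(points, cell_km = 10, proj = NULL) {
  proj <- proj %||% projection_for(points$longitude, points$latitude)
  xy <- project_lonlat(proj, points$longitude, points$latitude)
  # grid anchored at the occurrence extent's south-west corner, so a tight
  # point cluster is never split by an arbitrary cell boundary
  ix <- floor((xy[, 1] - min(xy[, 1])) / cell_km)
  iy <- floor((xy[, 2] - min(xy[, 2])) / cell_km)
  nrow(unique(cbind(ix, iy)))
}

#' Area of occupancy on a 2-km grid
#'
#' AOO is the summed area of occupied `cell_km` x `cell_km` cells (IUCN
#' convention: 2 km). Computed for reporting; it is not a CPI input.
#'
#' @inheritParams count_locations
#' @return Occupied area in km2.
#' @export
aoo_km2 <- function(points, cell_km = 2, proj = NULL) {
  count_locations(points, cell_km = cell_km, proj = proj) * cell_km^2
}

#' Preliminary IUCN Criterion B category
#'
#' Combines the EOO bands (CR < 100, EN < 5,000, VU < 20,000 km2) with the
#' location bands (CR = 1, EN <= 5, VU <= 10): the headline category is the
#' less severe of the two bands, i.e. the highest band whose EOO *and*
#' location conditions both hold; anything above VU on either axis yields
#' `NT/LC`.
#'
#' @param eoo_km2 Non-negative EOO in km2.
#' @param n_locations Positive integer number of locations.
#' @return One of `"CR"`, `"EN"`, `"VU"`, `"NT/LC"` (vectorized).
#' @export
#' @examples
#' preliminary_criterion_b(50, 1)      # CR
#' preliminary_criterion_b(3000, 7)    # VU
preliminary_criterion_b <- function(eoo_km2, n_locations) {
  check_nonneg(eoo_km2, "eoo_km2")
  check_count(n_locations, "n_locations")
  sev_eoo <- ifelse(eoo_km2 < 100, 3L, ifelse(eoo_km2 < 5000, 2L,
             ifelse(eoo_km2 < 20000, 1L, 0L)))
  sev_loc <- ifelse(n_locations <= 1, 3L, ifelse(n_locations <= 5, 2L,
             ifelse(n_locations <= 10, 1L, 0L)))
  sev <- pmin(sev_eoo, sev_loc)
  c("NT/LC", "VU", "EN", "CR")[sev + 1L]
}

# Resolve a feature's geometry and project it; layers are WGS84 lon/lat.
projected_feature <- function(layer, i, proj) {
  project_geometry(proj, layer$geometry[[i]])
}

# All outer rings of a layer, projected. Overlay clip polygons must be
# convex; validated here so errors name the layer.
projected_convex_rings <- function(layer, proj) {
  rings <- list()
  for (i in seq_len(nrow(layer))) {
    for (part in layer$geometry[[i]]) {
      r <- project_ring(proj, part[[1]])
      if (!is_convex_ring(r)) {
        stop_validation("layer '%s', feature %d: overlay requires convex polygons",
                        attr(layer, "layer_name") %||% "layer", i)
      }
      rings[[length(rings) + 1]] <- r
    }
  }
  rings
}

#' Percentage of a range inside a region
#'
#' @param range_geom A geometry (list of parts of rings, lon/lat) or a bare
#'   ring matrix.
#' @param region_layer A [geo_layer()] with one convex region feature (or a
#'   bare lon/lat ring matrix).
#' @param proj Optional projection; default centered on the range.
#' @return Percent of the range's area inside the region, in \[0, 100\].
#' @export
pct_polygon_in_region <- function(range_geom, region_layer, proj = NULL) {
  range_geom <- as_geometry(range_geom)
  proj <- proj %||% projection_for_geom(range_geom)
  g <- project_geometry(proj, range_geom)
  region_ring <- single_convex_ring(region_layer, proj, "region")
  total <- geometry_area(g)
  if (total <= 0) stop_validation("range polygon has zero area")
  inside <- geometry_clip_area(g, region_ring)
  # clipping noise can leave the ratio epsilon outside [0, 1]
  min(100, max(0, 100 * inside / total))
}

#' Percentage of a range outside protected areas
#'
#' The protected-area features are unioned (inclusion-exclusion over convex
#' polygons) before differencing.
#'
#' @param range_geom Range geometry or ring (lon/lat).
#' @param pa_layer A [geo_layer()] of convex protected-area polygons; may
#'   have zero rows.
#' @param proj Optional projection.
#' @return Percent outside, in \[0, 100\].
#' @export
pct_outside_protected <- function(range_geom, pa_layer, proj = NULL) {
  range_geom <- as_geometry(range_geom)
  proj <- proj %||% projection_for_geom(range_geom)
  g <- project_geometry(proj, range_geom)
  total <- geometry_area(g)
  if (total <= 0) stop_validation("range polygon has zero area")
  if (is.null(pa_layer) || nrow(pa_layer) == 0) return(100)
  rings <- projected_convex_rings(pa_layer, proj)
  covered <- geometry_union_clip_area(g, rings)
  min(100, max(0, 100 * (total - covered) / total))
}

#' Count municipalities overlapped by a range
#'
#' A municipality counts if the intersection area is strictly positive;
#' boundary touching does not count.
#'
#' @param range_geom Range geometry or ring (lon/lat).
#' @param municipal_layer A [geo_layer()] of convex municipality polygons.
#' @param proj Optional projection.
#' @return Integer count.
#' @export
count_municipalities <- function(range_geom, municipal_layer, proj = NULL) {
  range_geom <- as_geometry(range_geom)
  proj <- proj %||% projection_for_geom(range_geom)
  g <- project_geometry(proj, range_geom)
  count <- 0L
  for (i in seq_len(nrow(municipal_layer))) {
    ring <- project_ring(proj, municipal_layer$geometry[[i]][[1]][[1]])
    if (!is_convex_ring(ring)) {
      stop_validation("municipal layer feature %d is not convex", i)
    }
    if (geometry_clip_area(g, ring) > 1e-9) count <- count + 1L
  }
  count
}

#' Canopy-threshold habitat loss
#'
#' Percent of the canopy-height cells whose centers fall inside the range
#' and whose height is strictly below the genus-specific threshold --
#' below-threshold canopy is read as unsuitable (lost) habitat for a
#' forest-dependent species.
#'
#' @param range_geom Range geometry or ring in the raster's projected
#'   coordinate frame, or lon/lat with `proj` supplied.
#' @param canopy A [raster_grid()] of canopy heights (m) in projected km
#'   coordinates.
#' @param threshold_m Height threshold in metres (> 0); see
#'   [genus_threshold()].
#' @param proj Optional projection used to project a lon/lat range into the
#'   raster frame.
#' @return Percent in \[0, 100\]. Zero covered cells is an error.
#' @export
habitat_loss_pct <- function(range_geom, canopy, threshold_m, proj = NULL) {
  stopifnot(inherits(canopy, "cpi_grid"))
  if (threshold_m <= 0) stop_validation("threshold must be positive")
  range_geom <- as_geometry(range_geom)
  if (!is.null(proj)) range_geom <- project_geometry(proj, range_geom)
  ctr <- grid_cell_centers(canopy)
  px <- rep(ctr$x, each = length(ctr$y))
  py <- rep(ctr$y, times = length(ctr$x))
  vals <- as.vector(canopy$values)  # column-major: y fastest, matches px/py
  inside <- points_in_geometry(px, py, range_geom) & vals != canopy$nodata
  n_in <- sum(inside)
  if (n_in == 0) stop_validation("no raster cells covered by the range polygon")
  100 * sum(vals[inside] < threshold_m) / n_in
}

#' Genus-specific canopy-height thresholds
#'
#' Habitat-preference thresholds: 15 m for *Ceratozamia* (mature/cloud
#' forest), 5 m for *Dioon* (open, low deciduous forest), 10 m for *Zamia*
#' (medium sub-deciduous forest), with a 3 m override for the coastal-dune
#' *Zamia furfuracea*.
#'
#' @param species_name Species binomial (used for overrides).
#' @param genus Genus name.
#' @return Threshold in metres.
#' @export
genus_threshold <- function(species_name, genus) {
  base <- c(Ceratozamia = 15, Dioon = 5, Zamia = 10)
  out <- unname(base[genus])
  if (anyNA(out)) {
    stop_validation("no canopy threshold defined for genus '%s'",
                    genus[which(is.na(out))[1]])
  }
  override <- grepl("furfuracea", species_name, ignore.case = TRUE) &
    genus == "Zamia"
  out[override] <- 3
  out
}

#' Rasterize range polygons on a shared grid
#'
#' A cell is occupied when its center lies inside the range polygon.
#'
#' @param layer A [geo_layer()] of species ranges (lon/lat).
#' @param proj A [laea_projection()] shared by all layers of the analysis.
#' @param cell_km Cell side in km (default 1, i.e. 1-km2 cells).
#' @param extent Optional `c(xmin, xmax, ymin, ymax)` in projected km;
#'   default the projected bounding box of the layer padded by one cell.
#' @return Named list of binary [raster_grid()]s, one per feature.
#' @export
rasterize_ranges <- function(layer, proj, cell_km = 1, extent = NULL) {
  if (is.null(extent)) {
    all_xy <- do.call(rbind, lapply(seq_len(nrow(layer)), function(i)
      do.call(rbind, lapply(layer$geometry[[i]], function(p)
        project_ring(proj, p[[1]])))))
    extent <- c(min(all_xy[, 1]) - cell_km, max(all_xy[, 1]) + cell_km,
                min(all_xy[, 2]) - cell_km, max(all_xy[, 2]) + cell_km)
  }
  nc <- max(1L, ceiling((extent[2] - extent[1]) / cell_km))
  nr <- max(1L, ceiling((extent[4] - extent[3]) / cell_km))
  template <- raster_grid(matrix(0, nr, nc), xll = extent[1], yll = extent[3],
                          cell_size = cell_km)
  ctr <- grid_cell_centers(template)
  px <- rep(ctr$x, each = nr)
  py <- rep(ctr$y, times = nc)
  out <- vector("list", nrow(layer))
  for (i in seq_len(nrow(layer))) {
    g <- project_geometry(proj, layer$geometry[[i]])
    inside <- points_in_geometry(px, py, g)
    grid_i <- template
    grid_i$values <- matrix(as.numeric(inside), nr, nc)
    out[[i]] <- grid_i
  }
  names(out) <- layer$name
  out
}

#' Species richness raster
#'
#' @param binary_grids List of binary presence grids on a shared grid spec
#'   ([rasterize_ranges()]).
#' @return A [raster_grid()] whose cell values count the species present.
#' @export
richness_map <- function(binary_grids) {
  if (!length(binary_grids)) stop_validation("no grids to sum")
  ref <- binary_grids[[1]]
  vals <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (g in binary_grids) {
    if (!identical(dim(g$values), dim(vals)) ||
        g$xll != ref$xll || g$yll != ref$yll || g$cell_size != ref$cell_size) {
      stop_validation("grids do not share a common grid specification")
    }
    vals <- vals + g$values
  }
  out <- ref
  out$values <- vals
  out
}

#' Protected-area gap summary
#'
#' Tallies, for each positive richness level, the total area and the area
#' whose cell centers fall outside the protected-area union -- the
#' conservation gap.
#'
#' @param richness A richness [raster_grid()] (projected km frame).
#' @param pa_layer A [geo_layer()] of protected areas (lon/lat), or NULL
#'   for an empty network.
#' @param proj Projection shared with the richness grid.
#' @return Tibble with `richness`, `n_cells`, `total_km2`, `outside_pa_km2`.
#' @export
gap_summary <- function(richness, pa_layer, proj) {
  ctr <- grid_cell_centers(richness)
  nr <- nrow(richness$values)
  px <- rep(ctr$x, each = nr)
  py <- rep(ctr$y, times = length(ctr$x))
  vals <- as.vector(richness$values)
  protected <- rep(FALSE, length(vals))
  if (!is.null(pa_layer) && nrow(pa_layer) > 0) {
    for (i in seq_len(nrow(pa_layer))) {
      g <- project_geometry(proj, pa_layer$geometry[[i]])
      protected <- protected | points_in_geometry(px, py, g)
    }
  }
  cell_area <- richness$cell_size^2
  keep <- vals > 0 & vals != richness$nodata
  tibble::tibble(richness = sort(unique(vals[keep]))) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      n_cells = sum(vals == .data$richness & keep),
      total_km2 = .data$n_cells * cell_area,
      outside_pa_km2 = sum(vals == .data$richness & keep & !protected) * cell_area
    ) |>
    dplyr::ungroup()
}

#' Range-polygon centroids in lon/lat
#'
#' Area-weighted centroid of each range in the equal-area plane, mapped
#' back to geographic coordinates by inverse projection.
#'
#' @param layer A [geo_layer()] of ranges.
#' @param proj Optional shared projection.
#' @return Tibble `species_name`, `centroid_lon`, `centroid_lat`.
#' @export
range_centroids <- function(layer, proj = NULL) {
  proj <- proj %||% projection_for_layer(layer)
  out <- lapply(seq_len(nrow(layer)), function(i) {
    g <- project_geometry(proj, layer$geometry[[i]])
    ct <- geometry_centroid(g)
    ll <- laea_inverse(proj, ct[1], ct[2])
    tibble::tibble(species_name = layer$name[i],
                   centroid_lon = ll[1], centroid_lat = ll[2])
  })
  dplyr::bind_rows(out)
}

# Inverse LAEA (spherical closed form).
laea_inverse <- function(proj, x, y) {
  R <- proj$radius_km
  rad <- pi / 180
  rho <- sqrt(x^2 + y^2)
  if (rho < 1e-12) return(c(proj$lon0, proj$lat0))
  cc <- 2 * asin(pmin(1, rho / (2 * R)))
  f0 <- proj$lat0 * rad
  lat <- asin(cos(cc) * sin(f0) + y * sin(cc) * cos(f0) / rho) / rad
  lon <- proj$lon0 + atan2(x * sin(cc),
                           rho * cos(f0) * cos(cc) - y * sin(f0) * sin(cc)) / rad
  as.numeric(c(lon, lat))
}

as_geometry <- function(g) {
  if (is.matrix(g)) list(list(normalize_ring(g))) else g
}

projection_for_geom <- function(geom) {
  xy <- do.call(rbind, lapply(geom, function(p) p[[1]]))
  projection_for(xy[, 1], xy[, 2])
}

projection_for_layer <- function(layer) {
  xy <- do.call(rbind, lapply(seq_len(nrow(layer)), function(i)
    do.call(rbind, lapply(layer$geometry[[i]], function(p) p[[1]]))))
  projection_for(xy[, 1], xy[, 2])
}

single_convex_ring <- function(x, proj, what) {
  ring <- if (is.matrix(x)) {
    project_ring(proj, normalize_ring(x))
  } else {
    if (nrow(x) != 1) stop_validation("%s layer must have exactly one feature", what)
    project_ring(proj, x$geometry[[1]][[1]][[1]])
  }
  if (!is_convex_ring(ring)) {
    stop_validation("%s polygon must be convex for overlay operations", what)
  }
  ring
}

#' Full geospatial metric table for a set of species
#'
#' Convenience wrapper: per species, EOO (from points when available, else
#' from the range polygon vertices), locations, AOO, preliminary Criterion B
#' category, overlay percentages and municipality counts, and canopy-loss
#' percent when a canopy raster is given.
#'
#' @param ranges Range [geo_layer()] (feature names = species names), with a
#'   `genus` column or names like `"Genus species"`.
#' @param region_layer,pa_layer,municipal_layer Overlay layers (region must
#'   be a single convex feature).
#' @param points Optional occurrence tibble (`species_name`, `longitude`,
#'   `latitude`).
#' @param canopy Optional canopy [raster_grid()] in the shared projected
#'   frame.
#' @param proj Optional shared projection; default from the region extent.
#' @return Tibble of per-species metrics.
#' @export
spatial_metrics <- function(ranges, region_layer, pa_layer = NULL,
                            municipal_layer = NULL, points = NULL,
                            canopy = NULL, proj = NULL) {
  proj <- proj %||% projection_for_layer(region_layer)
  genus_of <- if ("genus" %in% names(ranges)) {
    ranges$genus
  } else sub("[ _].*$", "", ranges$name)
  rows <- lapply(seq_len(nrow(ranges)), function(i) {
    sp <- ranges$name[i]
    geom <- ranges$geometry[[i]]
    pts <- if (!is.null(points)) points[points$species_name == sp, ] else NULL
    if (!is.null(pts) && nrow(pts) >= 3) {
      eoo <- tryCatch(eoo_convex_hull(pts, proj)$eoo_km2,
                      cycadcpi_degenerate = function(e) NA_real_)
      nloc <- count_locations(pts, proj = proj)
      aoo <- aoo_km2(pts, proj = proj)
    } else {
      ring <- do.call(rbind, lapply(geom, function(p) p[[1]]))
      eoo <- abs(ring_area_signed(project_ring(proj, convex_hull_ring(ring))))
      nloc <- NA_integer_
      aoo <- NA_real_
    }
    tibble::tibble(
      species_name = sp,
      genus = genus_of[i],
      eoo_km2 = eoo,
      n_locations = nloc,
      aoo_km2 = aoo,
      preliminary_category = if (!is.na(nloc) && !is.na(eoo)) {
        preliminary_criterion_b(eoo, nloc)
      } else NA_character_,
      pct_area_in_region = pct_polygon_in_region(geom, region_layer, proj),
      pct_outside_pa = pct_outside_protected(geom, pa_layer, proj),
      n_municipalities = if (!is.null(municipal_layer)) {
        count_municipalities(geom, municipal_layer, proj)
      } else NA_integer_,
      pct_habitat_loss = if (!is.null(canopy)) {
        habitat_loss_pct(geom, canopy,
                         genus_threshold(sp, genus_of[i]), proj = proj)
      } else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}
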