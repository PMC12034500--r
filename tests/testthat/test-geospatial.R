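test_that("the equal-area projection maps its center to the origin", {
  proj <- laea_projection(-96, 19.5)
  expect_equal(unname(project_lonlat(proj, -96, 19.5)), cbind(0, 0),
               ignore_attr = TRUE, tolerance = 1e-9)
  # ~111 km per degree of latitude near the center
  xy <- project_lonlat(proj, -96, 20.5)
  expect_equal(unname(xy[1, 2]), 111.2, tolerance = 0.01)
})

test_that("convex-hull EOO agrees with a geodesic oracle within 0.5%", {
  skip_if_not_installed("geosphere")
  cases <- list(
    cbind(lon = c(0, 1, 1, 0), lat = c(0, 0, 1, 1)),            # equator box
    cbind(lon = c(-97, -96, -96, -97), lat = c(19, 19, 20, 20)) # study latitudes
  )
  for (ring in cases) {
    pts <- tibble::tibble(longitude = ring[, 1], latitude = ring[, 2])
    got <- eoo_convex_hull(pts)$eoo_km2
    ref <- geosphere::areaPolygon(ring) / 1e6
    expect_lt(abs(got - ref) / ref, 0.005)
  }
})

test_that("a small right triangle covers half its bounding box", {
  pts <- tibble::tibble(longitude = c(-96.2, -96.0, -96.2),
                        latitude = c(19.0, 19.0, 19.1))
  tri <- eoo_convex_hull(pts)$eoo_km2
  box <- eoo_convex_hull(tibble::tibble(
    longitude = c(-96.2, -96.0, -96.0, -96.2),
    latitude = c(19.0, 19.0, 19.1, 19.1)))$eoo_km2
  expect_equal(tri / box, 0.5, tolerance = 0.005)
})

test_that("degenerate point sets raise the DEGENERATE error class", {
  two <- tibble::tibble(longitude = c(0, 1), latitude = c(0, 0))
  expect_error(eoo_convex_hull(two), class = "cycadcpi_degenerate")
  collinear <- tibble::tibble(longitude = c(0, 0.5, 1), latitude = c(0, 0.5, 1))
  expect_error(eoo_convex_hull(collinear), class = "cycadcpi_degenerate")
})

test_that("EOO is invariant to duplicates/interior points, monotone in exterior points", {
  set.seed(3)
  pts <- tibble::tibble(longitude = runif(12, -97, -96),
                        latitude = runif(12, 19, 20))
  base <- eoo_convex_hull(pts)$eoo_km2
  dup <- eoo_convex_hull(dplyr::bind_rows(pts, pts))$eoo_km2
  expect_equal(dup, base, tolerance = 1e-12)
  interior <- dplyr::bind_rows(pts, tibble::tibble(
    longitude = mean(pts$longitude), latitude = mean(pts$latitude)))
  expect_equal(eoo_convex_hull(interior)$eoo_km2, base, tolerance = 1e-9)
  exterior <- dplyr::bind_rows(pts, tibble::tibble(longitude = -95, latitude = 21))
  expect_gt(eoo_convex_hull(exterior)$eoo_km2, base)
})

test_that("location counts match a brute-force cell indexing oracle", {
  one <- tibble::tibble(longitude = -96 + c(0, 0.001, 0.002),
                        latitude = 19 + c(0, 0.001, 0))
  expect_equal(count_locations(one), 1)
  far <- tibble::tibble(longitude = c(-98, -96, -94), latitude = c(18, 20, 22))
  expect_equal(count_locations(far), 3)
  set.seed(17)
  pts <- tibble::tibble(longitude = runif(60, -98, -94),
                        latitude = runif(60, 18, 22))
  proj <- laea_projection(-96, 20)
  got <- count_locations(pts, cell_km = 10, proj = proj)
  xy <- project_lonlat(proj, pts$longitude, pts$latitude)
  oracle <- length(unique(paste(floor((xy[, 1] - min(xy[, 1])) / 10),
                                floor((xy[, 2] - min(xy[, 2])) / 10))))
  expect_equal(got, oracle)
  expect_equal(aoo_km2(one, cell_km = 2, proj = proj), 4)
})

test_that("Criterion B combines EOO and location bands correctly", {
  expect_equal(preliminary_criterion_b(50, 1), "CR")
  expect_equal(preliminary_criterion_b(30000, 30), "NT/LC")
  expect_equal(preliminary_criterion_b(3000, 7), "VU")
  expect_equal(preliminary_criterion_b(50, 7), "VU")     # locations limit
  expect_equal(preliminary_criterion_b(12000, 2), "VU")  # EOO limits
  # monotone: worsening either axis never improves the category
  sev <- function(cat) match(cat, c("NT/LC", "VU", "EN", "CR"))
  eoos <- c(50, 99, 100, 4999, 5000, 19999, 20000, 50000)
  locs <- c(1, 2, 5, 6, 10, 11, 40)
  for (e in seq_along(eoos)[-1]) {
    for (l in seq_along(locs)[-1]) {
      expect_gte(sev(preliminary_criterion_b(eoos[e - 1], locs[l])),
                 sev(preliminary_criterion_b(eoos[e], locs[l])))
      expect_gte(sev(preliminary_criterion_b(eoos[e], locs[l - 1])),
                 sev(preliminary_criterion_b(eoos[e], locs[l])))
    }
  }
})

test_that("polygon overlays reproduce constructed overlap fractions", {
  sq <- cbind(c(0, 0.2, 0.2, 0), c(0, 0, 0.2, 0.2))  # small lon/lat square
  inside_region <- geo_layer("region", list(cbind(c(-1, 1, 1, -1),
                                                  c(-1, -1, 1, 1))))
  expect_equal(pct_polygon_in_region(sq, inside_region), 100, tolerance = 1e-9)
  # region sharing exactly half the square (split along its mid-meridian,
  # at the equator where the projection is symmetric about the center)
  half_region <- geo_layer("region", list(cbind(c(0.1, 1, 1, 0.1),
                                                c(-1, -1, 1, 1))))
  proj <- laea_projection(0.1, 0)
  expect_equal(pct_polygon_in_region(sq, half_region, proj = proj), 50,
               tolerance = 1e-6)
  expect_equal(pct_polygon_in_region(sq, half_region, proj = proj) +
                 (100 - pct_polygon_in_region(sq, half_region, proj = proj)),
               100, tolerance = 1e-9)
})

test_that("protected-area overlays union layers and respond monotonically", {
  sq <- cbind(c(0, 0.2, 0.2, 0), c(0, 0, 0.2, 0.2))
  expect_equal(pct_outside_protected(sq, NULL), 100)
  covering <- geo_layer("pa", list(cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1))))
  expect_equal(pct_outside_protected(sq, covering), 0, tolerance = 1e-9)
  # two overlapping PAs that jointly cover the left half must not be
  # double-counted by the union
  paA <- cbind(c(-1, 0.1, 0.1, -1), c(-1, -1, 1, 1))
  paB <- cbind(c(-1, 0.1, 0.1, -1), c(-0.5, -0.5, 0.5, 0.5))
  both <- geo_layer(c("A", "B"), list(paA, paB))
  proj <- laea_projection(0.1, 0)
  expect_equal(pct_outside_protected(sq, both, proj = proj), 50, tolerance = 1e-6)
  # growing the PA network can only decrease the outside percentage
  grown <- geo_layer(c("A", "B", "C"), list(paA, paB,
    cbind(c(0.1, 0.15, 0.15, 0.1), c(0, 0, 0.3, 0.3))))
  expect_lt(pct_outside_protected(sq, grown, proj = proj),
            pct_outside_protected(sq, both, proj = proj))
})

test_that("municipality counts need positive-area overlap, not edge contact", {
  rng <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  muns <- geo_layer(
    c("inside", "touching", "away"),
    list(cbind(c(0.2, 0.8, 0.8, 0.2), c(0.2, 0.2, 0.8, 0.8)),
         cbind(c(1, 2, 2, 1), c(0, 0, 1, 1)),     # shares the x = 1 edge
         cbind(c(3, 4, 4, 3), c(0, 0, 1, 1))))
  expect_equal(count_municipalities(rng, muns), 1L)
})

test_that("non-convex clip polygons are rejected rather than mis-clipped", {
  rng <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  lshape <- cbind(c(0, 2, 2, 1, 1, 0), c(0, 0, 1, 1, 2, 2))
  region <- geo_layer("L", list(lshape))
  expect_error(pct_polygon_in_region(rng, region), "convex",
               class = "cycadcpi_validation_error")
})

test_that("habitat loss counts covered below-threshold cells only", {
  ext <- c(0, 50, 0, 50)
  all_above <- generate_canopy_raster(ext, 5, below_fraction = 0, threshold = 10,
                                      seed = 1)
  all_below <- generate_canopy_raster(ext, 5, below_fraction = 1, threshold = 10,
                                      seed = 1)
  some <- generate_canopy_raster(ext, 5, below_fraction = 0.37, threshold = 10,
                                 seed = 2)
  cover <- cbind(c(-10, 60, 60, -10), c(-10, -10, 60, 60))  # projected frame
  expect_equal(habitat_loss_pct(cover, all_above, 10), 0)
  expect_equal(habitat_loss_pct(cover, all_below, 10), 100)
  expect_equal(habitat_loss_pct(cover, some, 10), 37)
  outside <- cbind(c(100, 110, 110, 100), c(100, 100, 110, 110))
  expect_error(habitat_loss_pct(outside, all_above, 10),
               class = "cycadcpi_validation_error")
  expect_error(habitat_loss_pct(cover, all_above, 0),
               class = "cycadcpi_validation_error")
})

test_that("genus thresholds follow habitat preferences with the dune override", {
  expect_equal(genus_threshold("Ceratozamia tenuis", "Ceratozamia"), 15)
  expect_equal(genus_threshold("Dioon edule", "Dioon"), 5)
  expect_equal(genus_threshold("Zamia purpurea", "Zamia"), 10)
  expect_equal(genus_threshold("Zamia furfuracea", "Zamia"), 3)
  expect_error(genus_threshold("Cycas revoluta", "Cycas"),
               class = "cycadcpi_validation_error")
})

test_that("point-in-polygon agrees with mgcv::in.out", {
  skip_if_not_installed("mgcv")
  set.seed(10)
  ang <- sort(runif(7, 0, 2 * pi))
  ring <- cbind(cos(ang), sin(ang))
  px <- runif(300, -1.2, 1.2); py <- runif(300, -1.2, 1.2)
  got <- cycadcpi:::points_in_ring(px, py, ring)
  bnd <- rbind(ring, ring[1, ])
  ref <- mgcv::in.out(bnd, cbind(px, py))
  expect_equal(got, ref)
})

test_that("rasterization obeys the cell-center rule and richness adds up", {
  proj <- laea_projection(0, 0)
  # ~0.09 degree square at the equator ~ 10 km x 10 km
  sq <- cbind(c(0, 0.09, 0.09, 0), c(0, 0, 0.09, 0.09))
  layer <- geo_layer(c("s1", "s2"), list(sq, sq))
  grids <- rasterize_ranges(layer, proj, cell_km = 1)
  k <- sum(grids[[1]]$values)
  expect_gt(k, 0)
  expect_equal(grids[[1]]$values, grids[[2]]$values)
  rich <- richness_map(grids)
  expect_equal(sum(rich$values == 2), k)
  expect_equal(sum(rich$values), sum(vapply(grids, function(g) sum(g$values), 0)))

  cfg <- sim_config(n_species = 8, seed = 23)
  lay <- generate_polygon_layers(cfg)
  grids <- rasterize_ranges(lay$ranges, lay$proj, cell_km = 10)
  rich <- richness_map(grids)
  expect_equal(sum(rich$values),
               sum(vapply(grids, function(g) sum(g$values), 0)))
  gaps <- gap_summary(rich, lay$pa, lay$proj)
  expect_true(all(gaps$outside_pa_km2 <= gaps$total_km2))
  expect_equal(sum(gaps$n_cells), sum(rich$values > 0))
  no_pa <- gap_summary(rich, NULL, lay$proj)
  expect_equal(no_pa$outside_pa_km2, no_pa$total_km2)
})

test_that("range centroids invert back to sensible geographic positions", {
  sq <- cbind(c(-96.5, -96.3, -96.3, -96.5), c(19.1, 19.1, 19.3, 19.3))
  layer <- geo_layer("sq", list(sq))
  ct <- range_centroids(layer)
  expect_equal(ct$centroid_lon, -96.4, tolerance = 1e-3)
  expect_equal(ct$centroid_lat, 19.2, tolerance = 1e-3)
})

test_that("spatial_metrics assembles the per-species table", {
  cfg <- sim_config(n_species = 9, seed = 29)
  lay <- generate_polygon_layers(cfg)
  ext <- {
    xy <- cycadcpi:::project_ring(lay$proj, lay$region$geometry[[1]][[1]][[1]])
    c(min(xy[, 1]), max(xy[, 1]), min(xy[, 2]), max(xy[, 2]))
  }
  canopy <- generate_canopy_raster(ext, cell_km = 10, below_fraction = 0.3,
                                   threshold = 15, seed = 5)
  lay$ranges$genus <- rep(c("Ceratozamia", "Zamia", "Dioon"), 3)
  met <- spatial_metrics(lay$ranges, lay$region, lay$pa, lay$municipalities,
                         canopy = canopy, proj = lay$proj)
  expect_equal(nrow(met), 9)
  expect_true(all(met$pct_area_in_region >= 0 & met$pct_area_in_region <= 100))
  expect_equal(met$pct_area_in_region, lay$truth$pct_area_in_region,
               tolerance = 0.01)
  expect_true(all(met$n_municipalities >= 1))
  expect_true(all(met$pct_habitat_loss >= 0 & met$pct_habitat_loss <= 100))
})
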