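#' Configuration for the synthetic study-system generator
#'
#' Defaults emulate the structure of the Veracruz cycad study: 21 species in
#' three genera, mixed 4-level IUCN / binary endemism / 2-level NOM-059
#' categories, right-skewed locality and municipality counts, bounded
#' percentages, and two planted risk groups separated on a latent risk
#' scale.
#'
#' @param n_species Number of species (>= 4).
#' @param seed Integer seed.
#' @param n_planted_clusters Number of planted risk groups.
#' @param cluster_separation Distance between consecutive group means on the
#'   latent risk score, in latent SD units. 0 makes groups exchangeable.
#' @param region_extent `c(lon_min, lon_max, lat_min, lat_max)` of the focal
#'   region (default a Veracruz-like box).
#' @param pa_coverage_fraction Fraction of the region covered by protected
#'   areas, in \[0, 1\].
#' @param canopy_below_fraction Fraction of canopy cells strictly below the
#'   height threshold, in \[0, 1\].
#' @param canopy_threshold_m Canopy height threshold used by the generator.
#' @return A `cpi_sim_config` list.
#' @export
sim_config <- function(n_species = 21, seed = 1, n_planted_clusters = 2,
                       cluster_separation = 2,
                       region_extent = c(-98.7, -93.6, 17.2, 22.5),
                       pa_coverage_fraction = 0.1,
                       canopy_below_fraction = 0.4,
                       canopy_threshold_m = 10) {
  if (n_species < 4) stop_validation("n_species must be >= 4")
  if (pa_coverage_fraction < 0 || pa_coverage_fraction > 1 ||
      canopy_below_fraction < 0 || canopy_below_fraction > 1) {
    stop_validation("coverage fractions must lie in [0, 1]")
  }
  if (n_planted_clusters < 1 || n_planted_clusters > n_species %/% 2) {
    stop_validation("n_planted_clusters must be in [1, n_species/2]")
  }
  structure(list(n_species = n_species, seed = seed,
                 n_planted_clusters = n_planted_clusters,
                 cluster_separation = cluster_separation,
                 region_extent = region_extent,
                 pa_coverage_fraction = pa_coverage_fraction,
                 canopy_below_fraction = canopy_below_fraction,
                 canopy_threshold_m = canopy_threshold_m),
            class = "cpi_sim_config")
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic species attribute table
#'
#' Species are assigned round-robin to planted risk groups; each species
#' draws a latent risk score `z ~ N(group mean, 1)` with group means spaced
#' `cluster_separation` apart. High-risk species stochastically receive more
#' severe IUCN/NOM-059 categories (ordered-logit style cutpoints on `z`),
#' endemism with probability increasing in `z`, fewer localities and
#' municipalities (negative binomial with mean decreasing in `z`), smaller
#' EOO (log-normal), and higher habitat-loss / outside-PA / area-in-region
#' percentages (beta with mean increasing in `z`).
#'
#' @param cfg A [sim_config()].
#' @return A tibble passing [read_species_table()] validation, plus
#'   `true_group` and `latent_risk` columns for recovery tests.
#' @export
generate_species_table <- function(cfg) {
  stopifnot(inherits(cfg, "cpi_sim_config"))
  n <- cfg$n_species
  k <- cfg$n_planted_clusters
  with_seed(cfg$seed, {
    group <- rep(seq_len(k), length.out = n)
    # `cluster_separation` is calibrated as a per-variable effect size:
    # every risk variable responds to the latent score with roughly unit
    # coefficient against roughly unit residual noise, so groups whose
    # latent means sit `separation` apart differ by ~`separation` SDs on
    # each variable.
    mu <- (group - (k + 1) / 2) * cfg$cluster_separation
    z <- stats::rnorm(n, mu, 0.25)
    # ordered categories via fixed cutpoints on the latent scale
    iucn <- cut(z + stats::rnorm(n, 0, 0.25),
                breaks = c(-Inf, -1.2, 0, 1.2, Inf),
                labels = c("NT", "VU", "EN", "CR"))
    nom <- ifelse(z + stats::rnorm(n, 0, 0.25) > 0, "P", "A")
    endemic <- stats::runif(n) < stats::plogis(2.5 * z)
    n_localities <- 1L + stats::rnbinom(n, size = 8, mu = pmax(0.2, exp(1.6 - z)))
    eoo <- stats::rlnorm(n, meanlog = 7.5 - 1.3 * z, sdlog = 0.3)
    beta_pct <- function(mean01, conc = 40) {
      mean01 <- pmin(0.98, pmax(0.02, mean01))
      100 * stats::rbeta(n, mean01 * conc, (1 - mean01) * conc)
    }
    area_region <- beta_pct(stats::plogis(1.2 * z + 0.5))
    habitat_loss <- beta_pct(stats::plogis(1.2 * z))
    outside_pa <- beta_pct(stats::plogis(1.2 * z + 1))
    n_municipalities <- 1L + stats::rnbinom(n, size = 8,
                                            mu = pmax(0.2, exp(1.5 - 0.9 * z)))
    genus <- sample(c("Ceratozamia", "Zamia", "Dioon"), n, replace = TRUE,
                    prob = c(13, 6, 2) / 21)
    tibble::tibble(
      species_name = sprintf("%s sim_sp%02d", genus, seq_len(n)),
      genus = genus,
      iucn_category = as.character(iucn),
      endemic = endemic,
      nom059_category = nom,
      n_localities = n_localities,
      eoo_km2 = round(eoo, 1),
      pct_area_in_region = round(area_region, 2),
      pct_habitat_loss = round(habitat_loss, 2),
      pct_outside_pa = round(outside_pa, 2),
      n_municipalities = n_municipalities,
      true_group = group,
      latent_risk = z
    )
  })
}

#' Generate synthetic polygon layers with controlled overlaps
#'
#' Produces a rectangular region, species ranges (random convex polygons
#' for interior species; rectangles straddling the region's western edge for
#' a controlled fraction of boundary species, so the constructed
#' area-in-region fraction is exact), a protected-area layer of disjoint
#' convex rectangles covering `pa_coverage_fraction` of the region, and a
#' municipal grid tiling the region.
#'
#' @param cfg A [sim_config()].
#' @param species_names Optional feature names; default from
#'   [generate_species_table()] sizing.
#' @param n_municipal_rows,n_municipal_cols Municipal grid dimensions.
#' @return List with `ranges`, `region`, `pa`, `municipalities` layers, the
#'   shared `proj`, and a `truth` tibble with the constructed
#'   `pct_area_in_region` per species.
#' @export
generate_polygon_layers <- function(cfg, species_names = NULL,
                                    n_municipal_rows = 4, n_municipal_cols = 5) {
  stopifnot(inherits(cfg, "cpi_sim_config"))
  ext <- cfg$region_extent
  n <- cfg$n_species
  if (is.null(species_names)) species_names <- sprintf("sim_sp%02d", seq_len(n))
  with_seed(cfg$seed + 1L, {
    region_ring <- cbind(c(ext[1], ext[2], ext[2], ext[1]),
                         c(ext[3], ext[3], ext[4], ext[4]))
    region <- geo_layer("region", list(region_ring), layer_name = "region")
    lon_w <- ext[2] - ext[1]; lat_h <- ext[4] - ext[3]

    straddle <- seq_len(n) %% 3 == 0  # every third species straddles the edge
    geoms <- vector("list", n)
    truth_in <- numeric(n)
    for (i in seq_len(n)) {
      cx <- stats::runif(1, ext[1] + 0.25 * lon_w, ext[2] - 0.25 * lon_w)
      cy <- stats::runif(1, ext[3] + 0.25 * lat_h, ext[4] - 0.25 * lat_h)
      if (straddle[i]) {
        # rectangle crossing the western boundary: exact inside fraction
        frac <- stats::runif(1, 0.2, 0.8)
        w <- stats::runif(1, 0.15, 0.3) * lon_w
        h <- stats::runif(1, 0.1, 0.2) * lat_h
        x0 <- ext[1] - (1 - frac) * w
        y0 <- min(max(cy - h / 2, ext[3]), ext[4] - h)
        geoms[[i]] <- cbind(c(x0, x0 + w, x0 + w, x0),
                            c(y0, y0, y0 + h, y0 + h))
        truth_in[i] <- 100 * frac
      } else {
        # random convex polygon fully inside the region
        rmax <- 0.12 * min(lon_w, lat_h)
        ang <- sort(stats::runif(stats::rpois(1, 6) + 5, 0, 2 * pi))
        rad <- stats::runif(length(ang), 0.4 * rmax, rmax)
        pts <- cbind(cx + rad * cos(ang), cy + rad * sin(ang))
        geoms[[i]] <- convex_hull_ring(pts)
        truth_in[i] <- 100
      }
    }
    ranges <- geo_layer(species_names, geoms, layer_name = "ranges")

    pa <- NULL
    if (cfg$pa_coverage_fraction > 0) {
      # disjoint vertical strips along the southern edge with the exact
      # requested total coverage
      n_pa <- 3L
      strip_w <- lon_w / (2 * n_pa)
      # height chosen so that n_pa strips cover the requested fraction
      strip_h <- cfg$pa_coverage_fraction * lon_w * lat_h / (n_pa * strip_w)
      strip_h <- min(strip_h, lat_h)
      pa_geoms <- lapply(seq_len(n_pa), function(j) {
        x0 <- ext[1] + (2 * j - 1.5) * strip_w
        cbind(c(x0, x0 + strip_w, x0 + strip_w, x0),
              c(ext[3], ext[3], ext[3] + strip_h, ext[3] + strip_h))
      })
      pa <- geo_layer(sprintf("pa_%d", seq_len(n_pa)), pa_geoms,
                      layer_name = "protected_areas")
    }

    mun_geoms <- list(); mun_names <- character(0)
    for (r in seq_len(n_municipal_rows)) {
      for (cc in seq_len(n_municipal_cols)) {
        x0 <- ext[1] + (cc - 1) * lon_w / n_municipal_cols
        x1 <- ext[1] + cc * lon_w / n_municipal_cols
        y0 <- ext[3] + (r - 1) * lat_h / n_municipal_rows
        y1 <- ext[3] + r * lat_h / n_municipal_rows
        mun_geoms[[length(mun_geoms) + 1]] <-
          cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
        mun_names <- c(mun_names, sprintf("mun_r%dc%d", r, cc))
      }
    }
    municipalities <- geo_layer(mun_names, mun_geoms, layer_name = "municipalities")

    list(ranges = ranges, region = region, pa = pa,
         municipalities = municipalities,
         proj = laea_projection(mean(ext[1:2]), mean(ext[3:4])),
         truth = tibble::tibble(species_name = species_names,
                                pct_area_in_region = truth_in,
                                straddles = straddle))
  })
}

#' Generate a canopy raster with an exact below-threshold fraction
#'
#' Exactly `round(below_fraction * n_cells)` cells take heights strictly
#' below `threshold`; the rest lie at or above it. Cell positions are
#' randomized under the seed.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in projected km.
#' @param cell_km Cell side (km).
#' @param below_fraction Fraction of cells below the threshold, in \[0, 1\].
#' @param threshold Height threshold (m).
#' @param seed Integer seed.
#' @return A [raster_grid()] of heights in metres.
#' @export
generate_canopy_raster <- function(extent, cell_km = 1, below_fraction = 0.4,
                                   threshold = 10, seed = 1) {
  if (below_fraction < 0 || below_fraction > 1) {
    stop_validation("below_fraction must lie in [0, 1]")
  }
  nc <- max(1L, ceiling((extent[2] - extent[1]) / cell_km))
  nr <- max(1L, ceiling((extent[4] - extent[3]) / cell_km))
  ncell <- nr * nc
  with_seed(seed, {
    n_below <- round(below_fraction * ncell)
    vals <- stats::runif(ncell, threshold, threshold + 25)
    if (n_below > 0) {
      idx <- sample.int(ncell, n_below)
      vals[idx] <- stats::runif(n_below, 0, threshold * (1 - 1e-9))
    }
    raster_grid(matrix(vals, nr, nc), xll = extent[1], yll = extent[3],
                cell_size = cell_km)
  })
}

#' Generate a synthetic knowledge table
#'
#' @param cfg A [sim_config()].
#' @param p_informed Probabilities that each of the five knowledge fields is
#'   informed.
#' @return A knowledge tibble with `shortfall_score`.
#' @export
generate_knowledge_table <- function(cfg,
                                     p_informed = c(0.5, 0.95, 1, 0.4, 0.5)) {
  stopifnot(inherits(cfg, "cpi_sim_config"), length(p_informed) == 5)
  with_seed(cfg$seed + 2L, {
    n <- cfg$n_species
    out <- tibble::tibble(species_name = sprintf("sim_sp%02d", seq_len(n)))
    for (j in seq_along(KNOWLEDGE_FIELDS)) {
      out[[KNOWLEDGE_FIELDS[j]]] <- stats::runif(n) < p_informed[j]
    }
    out$shortfall_score <- shortfall_score(out)
    out
  })
}
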