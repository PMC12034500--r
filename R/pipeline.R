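#' Select the ordination/clustering variable set
#'
#' The multivariate stages use every CPI ingredient except EOO (excluded for
#' its strong correlation with locations, municipalities and IUCN status),
#' with IUCN, endemism and NOM-059 treated as categorical at their original
#' values and the remaining variables numeric.
#'
#' @param data Species attribute tibble.
#' @param include_eoo Include `eoo_km2` (default FALSE).
#' @return Tibble with `species_name` and the analysis variables, with a
#'   `kinds` attribute naming each variable's type.
#' @export
cpi_analysis_variables <- function(data, include_eoo = FALSE) {
  data <- validate_species_table(data)
  vars <- c("iucn_category", "endemic", "nom059_category", "n_localities",
            if (include_eoo) "eoo_km2", "pct_area_in_region",
            "pct_habitat_loss", "pct_outside_pa", "n_municipalities")
  out <- data[, c("species_name", vars)]
  out$endemic <- factor(ifelse(out$endemic, "endemic", "non-endemic"))
  out$iucn_category <- factor(out$iucn_category)
  out$nom059_category <- factor(out$nom059_category)
  kinds <- ifelse(vars %in% c("iucn_category", "endemic", "nom059_category"),
                  "categorical", "numeric")
  names(kinds) <- vars
  attr(out, "kinds") <- kinds
  out
}

#' Run the full CPI analysis pipeline
#'
#' Orchestrates scoring, correlations, MFA, Gower/Ward clustering with AU
#' support, geographic trend GLMs, spatial overlay metrics, the richness /
#' protected-area gap map, and knowledge shortfalls, writing every stage's
#' output and a reproducibility manifest to `out_dir`. Runs either on
#' synthetic fixtures (`simulate = TRUE`, the default) or on file inputs
#' named in the config.
#'
#' @param config A named list, or path to a YAML file with the same fields:
#'   `simulate` (logical), `seed`, `out_dir`, `percent_mode`
#'   (`"div100"`/`"minmax"`), `ward_variant`, `k` (clusters to cut),
#'   `nboot`, `n_species`, `cluster_separation`, `cell_km`, and (when
#'   `simulate` is FALSE) `inputs:` paths `species_table`, optionally
#'   `ranges`, `region`, `pa`, `municipalities`, `canopy`, `knowledge`.
#' @return The manifest list, invisibly; side effect: `scored.csv`,
#'   `correlations.csv`, `mfa.json`, `clusters.json`, `trends.json`,
#'   `metrics.csv`, `richness.asc`, `shortfalls.csv`, `manifest.json` under
#'   `out_dir` (spatial outputs only when layers are available).
#' @export
run_cpi_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    simulate = TRUE, seed = 1L, out_dir = tempfile("cpi_run_"),
    percent_mode = "div100", ward_variant = "ward.D2", k = 4L,
    nboot = 1000L, n_species = 21L, cluster_separation = 2,
    cell_km = 1, au_scales = seq(0.5, 1.4, by = 0.1)
  ), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  made <- character(0)
  emit <- function(fname, writer) {
    path <- file.path(cfg$out_dir, fname)
    writer(path)
    made <<- c(made, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(made)
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = "cycadcpi_stage_error", parent = e)
    })
  }

  layers <- NULL; canopy <- NULL; knowledge <- NULL
  species <- stage("inputs", {
    if (isTRUE(cfg$simulate)) {
      sim <- sim_config(n_species = cfg$n_species, seed = cfg$seed,
                        cluster_separation = cfg$cluster_separation)
      tab <- generate_species_table(sim)
      layers <- generate_polygon_layers(sim, species_names = tab$species_name)
      ext_km <- {
        rr <- layers$region$geometry[[1]][[1]][[1]]
        xy <- project_ring(layers$proj, rr)
        c(min(xy[, 1]), max(xy[, 1]), min(xy[, 2]), max(xy[, 2]))
      }
      canopy <- generate_canopy_raster(ext_km, cell_km = max(cfg$cell_km, 5),
                                       below_fraction = sim$canopy_below_fraction,
                                       threshold = sim$canopy_threshold_m,
                                       seed = cfg$seed + 3L)
      knowledge <- generate_knowledge_table(sim)
      tab[, setdiff(names(tab), c("true_group", "latent_risk"))]
    } else {
      ins <- cfg$inputs
      if (is.null(ins$species_table)) {
        stop_schema("config$inputs$species_table is required when simulate is FALSE")
      }
      if (!is.null(ins$ranges)) {
        layers <- list(
          ranges = read_geojson_layer(ins$ranges),
          region = if (!is.null(ins$region)) read_geojson_layer(ins$region),
          pa = if (!is.null(ins$pa)) read_geojson_layer(ins$pa),
          municipalities = if (!is.null(ins$municipalities))
            read_geojson_layer(ins$municipalities))
        layers$proj <- projection_for_layer(layers$region %||% layers$ranges)
      }
      if (!is.null(ins$canopy)) canopy <- read_ascii_grid(ins$canopy)
      if (!is.null(ins$knowledge)) knowledge <- read_knowledge_table(ins$knowledge)
      read_species_table(ins$species_table)
    }
  })

  scored <- stage("score", {
    s <- build_scored_table(species, percent_mode = cfg$percent_mode)
    emit("scored.csv", function(p) readr::write_csv(s, p))
    s
  })

  stage("correlate", {
    cm <- cpi_correlations(scored)
    emit("correlations.csv", function(p)
      readr::write_csv(tibble::as_tibble(cm, rownames = "component"), p))
  })

  vars <- cpi_analysis_variables(species)
  mfa_fit <- stage("ordinate", {
    fit <- mfa(vars, group_spec = cfg$mfa_groups)
    emit("mfa.json", function(p) jsonlite::write_json(
      list(eigenvalues = fit$eig, coordinates = fit$coords,
           group_weights = as.list(fit$group_weights),
           total_inertia = fit$total_inertia),
      p, auto_unbox = TRUE, digits = NA))
    fit
  })

  clust <- stage("cluster", {
    au <- multiscale_bootstrap_au(vars, kinds = attr(vars, "kinds"),
                                  scales = cfg$au_scales, B = cfg$nboot,
                                  seed = cfg$seed, variant = cfg$ward_variant)
    labels <- cut_tree(au$tree, k = min(cfg$k, nrow(vars)))
    emit("clusters.json", function(p) jsonlite::write_json(
      list(k = min(cfg$k, nrow(vars)),
           labels = as.list(stats::setNames(unname(labels), vars$species_name)),
           support = au$support[, c("node", "members", "n_members", "bp", "au")],
           retained_au95 = au_retained_clusters(au, 0.95)$members),
      p, auto_unbox = TRUE, digits = NA))
    list(au = au, labels = labels)
  })

  if (!is.null(layers)) {
    stage("trends", {
      cents <- range_centroids(layers$ranges, layers$proj)
      tr <- cpi_trends(scored, cents)
      emit("trends.json", function(p) jsonlite::write_json(
        tr[, c("group", "predictor", "n", "d_squared", "p_value", "converged")],
        p, auto_unbox = TRUE, digits = NA))
    })
    stage("spatial", {
      met <- spatial_metrics(layers$ranges, layers$region, layers$pa,
                             layers$municipalities, canopy = canopy,
                             proj = layers$proj)
      emit("metrics.csv", function(p) readr::write_csv(met, p))
    })
    stage("gapmap", {
      grids <- rasterize_ranges(layers$ranges, layers$proj,
                                cell_km = max(cfg$cell_km, 5))
      rich <- richness_map(grids)
      emit("richness.asc", function(p) write_ascii_grid(rich, p))
      gaps <- gap_summary(rich, layers$pa, layers$proj)
      emit("gap_summary.csv", function(p) readr::write_csv(gaps, p))
    })
  }

  if (!is.null(knowledge)) {
    stage("shortfalls", {
      emit("shortfalls.csv", function(p) readr::write_csv(knowledge, p))
      emit("shortfall_summary.csv", function(p)
        readr::write_csv(shortfall_summary(knowledge), p))
    })
  }

  manifest <- stage("manifest", {
    files <- sort(basename(made))
    sums <- tools::md5sum(file.path(cfg$out_dir, files))
    man <- list(
      package = "cycadcpi",
      version = as.character(utils::packageVersion("cycadcpi")),
      seed = cfg$seed,
      config = cfg[setdiff(names(cfg), "out_dir")],
      outputs = as.list(stats::setNames(unname(sums), files))
    )
    jsonlite::write_json(man, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    man
  })
  invisible(manifest)
}
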