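#' Category-to-score maps for the CPI
#'
#' Risk categories are converted to ordinal scores before min-max
#' standardization: IUCN CR = 4, EN = 3, VU = 2, NT = 1 (LC = 0 as the
#' monotone extension below NT); NOM-059 P (in danger of extinction) = 2,
#' A (threatened) = 1, no listing = 0; endemism scores 1 for endemic, 0
#' otherwise.
#'
#' @return A list with `iucn_scores`, `nom059_scores` and `endemic_scores`
#'   named numeric vectors.
#' @export
category_score_map <- function() {
  list(iucn_scores   = c(CR = 4, EN = 3, VU = 2, NT = 1, LC = 0),
       nom059_scores = c(P = 2, A = 1, NONE = 0),
       endemic_scores = c(`TRUE` = 1, `FALSE` = 0))
}

#' Score the categorical risk attributes of a species table
#'
#' @param data A species attribute tibble (see [read_species_table()]).
#' @param map A [category_score_map()].
#' @return `data` with numeric columns `iucn_score`, `nom059_score`,
#'   `endemic_score` appended. An unresolved IUCN category (`NE`) is an
#'   error: run a preliminary Criterion B assessment
#'   ([preliminary_criterion_b()]) first.
#' @export
score_categories <- function(data, map = category_score_map()) {
  if (any(data$iucn_category == "NE", na.rm = TRUE)) {
    sp <- data$species_name[which(data$iucn_category == "NE")[1]]
    stop_validation(paste0(
      "species '%s' has IUCN category NE (Not Evaluated); resolve it with a ",
      "preliminary Criterion B assessment before scoring"), sp)
  }
  dplyr::mutate(
    data,
    iucn_score    = unname(map$iucn_scores[.data$iucn_category]),
    nom059_score  = unname(map$nom059_scores[.data$nom059_category]),
    endemic_score = as.numeric(.data$endemic)
  )
}

#' Min-max normalization to the unit interval
#'
#' `z_i = (x_i - min(x)) / (max(x) - min(x))`: the column minimum maps to 0,
#' the maximum to 1, order is preserved.
#'
#' @param x Numeric vector with at least two non-missing values and a
#'   positive range. Missing values pass through as missing.
#' @return Numeric vector in \[0, 1\].
#' @export
#' @examples
#' minmax_normalize(c(2, 4, 6))
minmax_normalize <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop_validation("min-max normalization needs >= 2 non-missing values")
  rng <- range(x[ok])
  if (rng[2] <= rng[1]) {
    stop_validation("min-max normalization undefined for a constant vector (min == max)")
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Invert a normalized vector
#'
#' `y_i = 1 - z_i`, so that small raw values (few localities, small ranges)
#' carry high risk scores. Applying the inversion twice is the identity.
#'
#' @param z Numeric vector with values in \[0, 1\] (missing allowed).
#' @return `1 - z`.
#' @export
invert_normalized <- function(z) {
  bad <- which(!is.na(z) & (z < 0 | z > 1))
  if (length(bad)) {
    stop_validation("invert_normalized: value %g at position %d outside [0, 1]",
                    z[bad[1]], bad[1])
  }
  1 - z
}

CPI_COMPONENTS <- c("iucn", "endemic", "nom059", "locations_inv", "eoo_inv",
                    "area_region", "habitat_loss", "outside_pa",
                    "municipalities_inv")

#' Build the standardized CPI component table
#'
#' Converts the raw attribute table into the nine unit-interval CPI
#' components and their sum:
#' \itemize{
#'   \item `iucn`, `nom059`: ordinal category scores, min-max normalized
#'     over the observed column;
#'   \item `endemic`: 1/0;
#'   \item `locations_inv`, `eoo_inv`, `municipalities_inv`: min-max
#'     normalized then inverted, so rarity scores high;
#'   \item `area_region`, `habitat_loss`, `outside_pa`: percentages mapped
#'     to \[0, 1\] -- divided by 100 under `percent_mode = "div100"`
#'     (default; 100% of the range in the region reads as 1), or min-max
#'     normalized over the column under `percent_mode = "minmax"`.
#' }
#' Missing raw attributes yield missing components, which are omitted from
#' the CPI sum; `n_components` records per-species completeness.
#'
#' @param data Species attribute tibble ([read_species_table()]).
#' @param percent_mode `"div100"` (default) or `"minmax"`.
#' @param map A [category_score_map()].
#' @return A tibble with `species_name`, `genus`, the nine components,
#'   `n_components`, `cpi` and `cpi_rank` (1 = highest priority), ordered as
#'   the input.
#' @export
#' @examples
#' scored <- build_scored_table(cycad_attributes_synthetic())
#' head(scored[order(scored$cpi_rank), c("species_name", "cpi")])
build_scored_table <- function(data, percent_mode = c("div100", "minmax"),
                               map = category_score_map()) {
  percent_mode <- match.arg(percent_mode)
  data <- validate_species_table(data)
  data <- score_categories(data, map)
  norm_col <- function(x, col) {
    tryCatch(minmax_normalize(x), error = function(e) {
      stop_validation("normalization failed for column '%s': %s", col,
                      conditionMessage(e))
    })
  }
  pct <- function(x, col) {
    if (percent_mode == "div100") x / 100 else norm_col(x, col)
  }
  out <- tibble::tibble(
    species_name = data$species_name,
    genus = data$genus,
    iucn = norm_col(data$iucn_score, "iucn_category"),
    endemic = data$endemic_score,
    nom059 = norm_col(data$nom059_score, "nom059_category"),
    locations_inv = invert_normalized(norm_col(data$n_localities, "n_localities")),
    eoo_inv = invert_normalized(norm_col(data$eoo_km2, "eoo_km2")),
    area_region = pct(data$pct_area_in_region, "pct_area_in_region"),
    habitat_loss = pct(data$pct_habitat_loss, "pct_habitat_loss"),
    outside_pa = pct(data$pct_outside_pa, "pct_outside_pa"),
    municipalities_inv = invert_normalized(norm_col(data$n_municipalities,
                                                    "n_municipalities"))
  )
  comp <- as.matrix(out[, CPI_COMPONENTS])
  out$n_components <- rowSums(!is.na(comp))
  out$cpi <- compute_cpi(out)
  out$cpi_rank <- rank(-out$cpi, ties.method = "min")
  attr(out, "percent_mode") <- percent_mode
  out
}

#' Sum the CPI from its standardized components
#'
#' The index is the plain sum of the non-missing components, so it lies in
#' \[0, 9\] with nine components; missing attributes contribute nothing.
#'
#' @param scored A tibble (or one-row slice) with the nine component
#'   columns.
#' @return Numeric vector of CPI values.
#' @export
compute_cpi <- function(scored) {
  comp <- as.matrix(scored[, CPI_COMPONENTS, drop = FALSE])
  bad <- which(!is.na(comp) & (comp < -1e-12 | comp > 1 + 1e-12), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_validation("component '%s' outside [0, 1] for row %d",
                    CPI_COMPONENTS[bad[1, 2]], bad[1, 1])
  }
  if (any(rowSums(!is.na(comp)) == 0)) {
    stop_validation("a species has no non-missing CPI components")
  }
  rowSums(comp, na.rm = TRUE)
}

#' Pearson correlation matrix of CPI components
#'
#' @param scored A scored tibble ([build_scored_table()]).
#' @param vars Component columns to correlate (default all nine).
#' @return A symmetric correlation matrix (pairwise-complete observations).
#'   A constant column is an error naming the column.
#' @export
cpi_correlations <- function(scored, vars = CPI_COMPONENTS) {
  m <- as.matrix(scored[, vars, drop = FALSE])
  if (nrow(m) < 3) stop_validation("correlation needs >= 3 rows")
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds))) {
    stop_validation("constant column '%s' has no defined correlation",
                    vars[which(sds == 0 | is.na(sds))[1]])
  }
  stats::cor(m, use = "pairwise.complete.obs", method = "pearson")
}

#' Knowledge-shortfall score
#'
#' Counts, per species, how many of the five knowledge fields (individual
#' counts, GenBank accessions, studies, population ecology, pollinator)
#' hold at least some information.
#'
#' @param knowledge A tibble with the five logical `has_*` columns.
#' @return Integer vector of scores in 0-5.
#' @export
shortfall_score <- function(knowledge) {
  m <- as.matrix(knowledge[, KNOWLEDGE_FIELDS, drop = FALSE])
  storage.mode(m) <- "logical"
  as.integer(rowSums(m, na.rm = TRUE))
}

#' Summarise knowledge shortfalls
#'
#' @param knowledge A knowledge tibble ([read_knowledge_table()] or
#'   [cycad_knowledge_reconstructed()]).
#' @return A one-row tibble with the percent of species informed for each
#'   field and the minimum/maximum shortfall scores.
#' @export
shortfall_summary <- function(knowledge) {
  scores <- shortfall_score(knowledge)
  shares <- vapply(KNOWLEDGE_FIELDS, function(f)
    100 * mean(knowledge[[f]], na.rm = TRUE), 0)
  tibble::tibble(
    pct_individual_count = shares[["has_individual_count"]],
    pct_genbank = shares[["has_genbank"]],
    pct_studies = shares[["has_studies"]],
    pct_popecol = shares[["has_popecol"]],
    pct_pollinator = shares[["has_pollinator"]],
    min_score = min(scores), max_score = max(scores)
  )
}
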