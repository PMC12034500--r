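#' Read a species attribute table
#'
#' Reads the one-row-per-species raw attribute CSV that feeds the CPI: IUCN
#' category, endemism, NOM-059 category, number of localities, extent of
#' occurrence (km2), percentage of the distribution inside the focal region,
#' percentage habitat loss, percentage of the distribution outside protected
#' areas, and number of municipalities of occurrence. Column order is free;
#' header names are matched case-insensitively, optionally through
#' `column_map`.
#'
#' @param path Path to a UTF-8 CSV file.
#' @param column_map Optional named character vector mapping canonical names
#'   (names of the vector) to the header names used in the file.
#' @return A tibble with one validated row per species, in file order.
#'   Categories are uppercased; `endemic` is logical. Unknown categories or
#'   out-of-range values raise a classed validation error naming the column
#'   and row.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' readr::write_csv(cycad_attributes_synthetic(), tf)
#' read_species_table(tf)
read_species_table <- function(path, column_map = NULL) {
  tab <- read_csv_strict(path)
  names(tab) <- tolower(names(tab))
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      have <- tolower(column_map[[canon]])
      if (!have %in% names(tab)) {
        stop_schema("column_map names '%s' for '%s', but the file has no such column",
                    column_map[[canon]], canon)
      }
      names(tab)[names(tab) == have] <- canon
    }
  }
  validate_species_table(tab)
}

#' Read an occurrence point set
#'
#' @param path CSV with columns `species_name`, `longitude`, `latitude`
#'   (WGS84 decimal degrees).
#' @return A tibble of validated points; longitudes in \[-180, 180\],
#'   latitudes in \[-90, 90\].
#' @export
read_points_csv <- function(path) {
  tab <- read_csv_strict(path)
  names(tab) <- tolower(names(tab))
  req <- c("species_name", "longitude", "latitude")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stop_schema("points file is missing column(s): %s", paste(miss, collapse = ", "))
  }
  bad <- which(!is.na(tab$longitude) & abs(tab$longitude) > 180)
  if (length(bad)) {
    stop_validation("column 'longitude': value %g at row %d outside [-180, 180]",
                    tab$longitude[bad[1]], bad[1])
  }
  bad <- which(!is.na(tab$latitude) & abs(tab$latitude) > 90)
  if (length(bad)) {
    stop_validation("column 'latitude': value %g at row %d outside [-90, 90]",
                    tab$latitude[bad[1]], bad[1])
  }
  if (nrow(tab) < 1) stop_validation("points file contains no rows")
  tibble::as_tibble(tab[, req])
}

#' Read a knowledge-shortfall table
#'
#' Five boolean fields record whether any information exists for a species:
#' individual counts, GenBank accessions, scholarly studies, population
#' ecology, and pollinator identity. The shortfall score is the count of
#' informed fields (0-5).
#'
#' @param path CSV with `species_name` plus the five `has_*` columns.
#' @return A tibble with the five logical columns and a recomputed
#'   `shortfall_score`.
#' @export
read_knowledge_table <- function(path) {
  tab <- read_csv_strict(path)
  names(tab) <- tolower(names(tab))
  req <- c("species_name", KNOWLEDGE_FIELDS)
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stop_schema("knowledge table is missing column(s): %s", paste(miss, collapse = ", "))
  }
  for (f in KNOWLEDGE_FIELDS) tab[[f]] <- check_logical(tab[[f]], f)
  out <- tibble::as_tibble(tab[, req])
  out$shortfall_score <- shortfall_score(out)
  out
}

KNOWLEDGE_FIELDS <- c("has_individual_count", "has_genbank", "has_studies",
                      "has_popecol", "has_pollinator")

# readr wrapper: consistent types, error (not warning) on parse failure.
read_csv_strict <- function(path) {
  if (!file.exists(path)) stop_schema("file not found: %s", path)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    stop_schema("malformed CSV '%s': %s (row %d)", path,
                probs$expected[1], probs$row[1])
  }
  tab
}
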