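# Internal validation helpers. All user-facing readers funnel through these
# so that malformed input always raises a classed condition (never a silent
# coercion), with the offending column/row named.

stop_schema <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "cycadcpi_schema_error")
}

stop_validation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "cycadcpi_validation_error")
}

IUCN_LEVELS   <- c("CR", "EN", "VU", "NT", "LC", "NE")
NOM059_LEVELS <- c("P", "A", "NONE")

check_percent <- function(x, name) {
  bad <- which(!is.na(x) & (x < 0 | x > 100))
  if (length(bad)) {
    stop_validation("column '%s': value %g at row %d outside [0, 100]",
                    name, x[bad[1]], bad[1])
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  bad <- which(!is.na(x) & (x < min | x != floor(x)))
  if (length(bad)) {
    stop_validation("column '%s': value %g at row %d is not an integer >= %d",
                    name, x[bad[1]], bad[1], min)
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  bad <- which(!is.na(x) & x < 0)
  if (length(bad)) {
    stop_validation("column '%s': value %g at row %d is negative",
                    name, x[bad[1]], bad[1])
  }
  invisible(x)
}

check_enum <- function(x, levels, name) {
  x <- toupper(trimws(as.character(x)))
  bad <- which(!is.na(x) & !x %in% levels)
  if (length(bad)) {
    stop_validation("column '%s': unknown category '%s' at row %d (allowed: %s)",
                    name, x[bad[1]], bad[1], paste(levels, collapse = ", "))
  }
  x
}

check_logical <- function(x, name) {
  if (is.logical(x)) return(x)
  x0 <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x0))
  out[x0 %in% c("TRUE", "T", "YES", "Y", "1")] <- TRUE
  out[x0 %in% c("FALSE", "F", "NO", "N", "0")] <- FALSE
  bad <- which(!is.na(x0) & is.na(out))
  if (length(bad)) {
    stop_validation("column '%s': value '%s' at row %d is not interpretable as logical",
                    name, x[bad[1]], bad[1])
  }
  out
}

# Validate a species attribute tibble in place; returns the (cleaned) tibble.
validate_species_table <- function(tab) {
  req <- c("species_name", "genus", "iucn_category", "endemic",
           "nom059_category", "n_localities", "eoo_km2", "pct_area_in_region",
           "pct_habitat_loss", "pct_outside_pa", "n_municipalities")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stop_schema("species table is missing column(s): %s",
                paste(miss, collapse = ", "))
  }
  if (anyDuplicated(tab$species_name)) {
    dup <- tab$species_name[duplicated(tab$species_name)][1]
    stop_validation("duplicated species_name '%s'", dup)
  }
  if (nrow(tab) == 0) {
    # header-only input: return a correctly typed empty table
    return(tibble::tibble(
      species_name = character(), genus = character(),
      iucn_category = character(), endemic = logical(),
      nom059_category = character(), n_localities = integer(),
      eoo_km2 = numeric(), pct_area_in_region = numeric(),
      pct_habitat_loss = numeric(), pct_outside_pa = numeric(),
      n_municipalities = integer()))
  }
  tab$iucn_category   <- check_enum(tab$iucn_category, IUCN_LEVELS, "iucn_category")
  tab$nom059_category <- check_enum(tab$nom059_category, NOM059_LEVELS, "nom059_category")
  tab$endemic         <- check_logical(tab$endemic, "endemic")
  check_count(tab$n_localities, "n_localities")
  check_count(tab$n_municipalities, "n_municipalities")
  check_nonneg(tab$eoo_km2, "eoo_km2")
  for (p in c("pct_area_in_region", "pct_habitat_loss", "pct_outside_pa")) {
    check_percent(tab[[p]], p)
  }
  tibble::as_tibble(tab[, union(req, names(tab))])
}
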