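#' Gower distance for mixed data
#'
#' Per-variable dissimilarities are `|x_i - x_j| / range(x)` for numeric
#' variables and 0/1 mismatch for categorical ones; the Gower distance is
#' their (weighted) mean over the variables non-missing in both rows.
#' Entries lie in \[0, 1\]; the triangle inequality is not guaranteed.
#'
#' @param data A data frame / tibble of the variables to compare (rows =
#'   objects). Character, factor and logical columns are treated as
#'   categorical unless overridden.
#' @param kinds Optional character vector (`"numeric"`/`"categorical"`),
#'   named by column or in column order.
#' @param weights Optional non-negative per-variable weights (default 1).
#' @return A `dist` object with `Labels` from row names / a `species_name`
#'   column when present.
#' @export
#' @examples
#' d <- gower_distance(data.frame(a = c(0, 1, 2), b = c("x", "x", "y")))
#' as.matrix(d)
gower_distance <- function(data, kinds = NULL, weights = NULL) {
  labels <- rownames(data)
  if ("species_name" %in% names(data)) {
    labels <- as.character(data$species_name)
    data <- data[, setdiff(names(data), "species_name"), drop = FALSE]
  }
  n <- nrow(data)
  if (n < 2) stop_validation("Gower distance needs >= 2 rows")
  parts <- gower_parts(data, kinds)
  combine_gower_parts(parts, weights = weights, n = n, labels = labels)
}

# Per-variable scaled dissimilarities as a list of dist-vectors (lower
# triangle, length n(n-1)/2), plus NA masks. Precomputing these makes the
# variable-resampling bootstrap a cheap weighted average.
gower_parts <- function(data, kinds = NULL) {
  vars <- names(data)
  if (is.null(kinds)) {
    kinds <- vapply(data, function(col)
      if (is.numeric(col)) "numeric" else "categorical", "")
  } else {
    if (is.null(names(kinds))) names(kinds) <- vars
    kinds <- kinds[vars]
  }
  if (!all(kinds %in% c("numeric", "categorical"))) {
    stop_validation("variable kinds must be 'numeric' or 'categorical'")
  }
  parts <- lapply(vars, function(v) {
    col <- data[[v]]
    if (kinds[[v]] == "numeric") {
      rng <- diff(range(col, na.rm = TRUE))
      if (!is.finite(rng) || rng <= 0) {
        stop_validation("numeric variable '%s' has zero range; Gower scaling undefined", v)
      }
      unclass(stats::dist(col / rng, method = "manhattan"))
    } else {
      f <- as.integer(factor(col))
      d <- unclass(stats::dist(f, method = "manhattan"))
      d[d > 0] <- 1
      miss <- is.na(col)
      if (any(miss)) {
        # dist() drops NA info; rebuild the NA mask pairwise
        na_pair <- unclass(stats::dist(ifelse(miss, NA, 0)))
        d[is.na(na_pair)] <- NA
      }
      d
    }
  })
  names(parts) <- vars
  parts
}

combine_gower_parts <- function(parts, weights = NULL, n, labels = NULL) {
  m <- length(parts)
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m || any(weights < 0)) {
    stop_validation("weights must be non-negative, one per variable")
  }
  num <- 0
  den <- 0
  for (k in seq_len(m)) {
    pk <- parts[[k]]
    ok <- !is.na(pk)
    contrib <- ifelse(ok, pk, 0) * weights[k]
    num <- num + contrib
    den <- den + ok * weights[k]
  }
  d <- num / den
  d[den == 0] <- NA
  attr(d, "Size") <- n
  attr(d, "Labels") <- labels
  attr(d, "Diag") <- FALSE
  attr(d, "Upper") <- FALSE
  attr(d, "method") <- "gower"
  class(d) <- "dist"
  d
}
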