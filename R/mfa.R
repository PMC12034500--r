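#' Multiple Factor Analysis of mixed data
#'
#' Ordinates species on mixed numeric/categorical variables organized in
#' groups, generalizing PCA/MCA. Numeric variables are centered and scaled
#' by the population standard deviation; each categorical variable is
#' expanded to centered indicator columns `(I_k - p_k) / sqrt(p_k)` (the MCA
#' column weighting). Every group is then divided by the square root of the
#' leading eigenvalue of its separate analysis -- the MFA balancing step
#' that stops any one group from dominating the first dimension -- and the
#' concatenated weighted matrix is eigen-decomposed (PCA with row weight
#' 1/n).
#'
#' With the default specification (each variable its own group) the analysis
#' coincides with factor analysis of mixed data: single standardized numeric
#' variables and single categorical variables both have leading separate
#' eigenvalue 1. With one all-numeric group and no categorical variables it
#' reduces to standard PCA of the correlation matrix.
#'
#' @param data Tibble of the variables to ordinate (a `species_name` column
#'   is used for labels). Character/factor/logical columns are categorical.
#' @param group_spec Optional named list of character vectors assigning
#'   variables to groups; default: one group per variable. A group must be
#'   all-numeric or all-categorical.
#' @param n_dims Number of dimensions for which coordinates are returned.
#' @return An object of class `cpi_mfa`: `eig` tibble (eigenvalue, percent
#'   and cumulative percent of variance per dimension, over all positive
#'   eigenvalues), `coords` (species coordinates), `loadings` (weighted
#'   column loadings), `group_weights`, and `total_inertia`.
#' @export
#' @examples
#' scored <- cycad_attributes_synthetic()
#' fit <- mfa(scored[, c("species_name", "iucn_category", "endemic",
#'                       "nom059_category", "n_localities",
#'                       "pct_area_in_region", "pct_habitat_loss",
#'                       "pct_outside_pa", "n_municipalities")])
#' tidy(fit)
mfa <- function(data, group_spec = NULL, n_dims = 5) {
  labels <- if ("species_name" %in% names(data)) {
    as.character(data$species_name)
  } else {
    rownames(data) %||% as.character(seq_len(nrow(data)))
  }
  vars <- data[, setdiff(names(data), "species_name"), drop = FALSE]
  n <- nrow(vars)
  if (n < 3) stop_validation("MFA needs >= 3 rows")
  if (is.null(group_spec)) {
    group_spec <- lapply(names(vars), identity)
    names(group_spec) <- names(vars)
  }
  unknown <- setdiff(unlist(group_spec), names(vars))
  if (length(unknown)) {
    stop_schema("group_spec names unknown variable(s): %s",
                paste(unknown, collapse = ", "))
  }

  encode_numeric <- function(x, v) {
    s <- stats::sd(x) * sqrt((n - 1) / n)
    if (!is.finite(s) || s == 0) {
      stop_validation("numeric variable '%s' is constant; cannot standardize", v)
    }
    m <- matrix((x - mean(x)) / s, ncol = 1)
    colnames(m) <- v
    m
  }
  encode_categorical <- function(x, v) {
    f <- factor(x)
    if (nlevels(f) < 2) {
      stop_validation("categorical variable '%s' has a single level", v)
    }
    ind <- stats::model.matrix(~ f - 1)
    p <- colMeans(ind)
    m <- sweep(sweep(ind, 2, p, "-"), 2, sqrt(p), "/")
    colnames(m) <- paste(v, levels(f), sep = ".")
    m
  }

  blocks <- list(); weights <- numeric(0); col_group <- character(0)
  for (g in names(group_spec)) {
    gv <- group_spec[[g]]
    numeric_g <- vapply(vars[gv], is.numeric, TRUE)
    if (length(unique(numeric_g)) > 1) {
      stop_validation("group '%s' mixes numeric and categorical variables", g)
    }
    enc <- if (all(numeric_g)) {
      do.call(cbind, lapply(gv, function(v) encode_numeric(vars[[v]], v)))
    } else {
      do.call(cbind, lapply(gv, function(v) encode_categorical(vars[[v]], v)))
    }
    lambda1 <- max(svd(enc / sqrt(n), nu = 0, nv = 0)$d)^2
    blocks[[g]] <- enc / sqrt(lambda1)
    weights[g] <- 1 / lambda1
    col_group <- c(col_group, rep(g, ncol(enc)))
  }

  X <- do.call(cbind, blocks)
  sv <- svd(X / sqrt(n))
  eig <- sv$d^2
  keep <- eig > max(eig) * 1e-10
  eig <- eig[keep]
  total <- sum(eig)
  pct <- 100 * eig / total
  ndim <- min(n_dims, length(eig))
  coords <- X %*% sv$v[, seq_len(ndim), drop = FALSE]
  colnames(coords) <- paste0("dim", seq_len(ndim))
  loadings <- sv$v[, seq_len(ndim), drop = FALSE]
  rownames(loadings) <- colnames(X)
  colnames(loadings) <- paste0("dim", seq_len(ndim))

  structure(list(
    eig = tibble::tibble(dim = seq_along(eig), eigenvalue = eig,
                         pct_variance = pct, cum_pct_variance = cumsum(pct)),
    coords = tibble::as_tibble(cbind(
      tibble::tibble(species_name = labels), as.data.frame(coords))),
    loadings = loadings,
    column_group = col_group,
    group_weights = weights,
    total_inertia = total,
    n = n
  ), class = "cpi_mfa")
}

#' @export
print.cpi_mfa <- function(x, ...) {
  cat(sprintf("Multiple Factor Analysis: %d species, %d groups, total inertia %.3f\n",
              x$n, length(x$group_weights), x$total_inertia))
  print(utils::head(as.data.frame(x$eig), 5))
  invisible(x)
}

#' @rdname mfa
#' @param x A `cpi_mfa` object.
#' @param ... Unused.
#' @method tidy cpi_mfa
#' @export
tidy.cpi_mfa <- function(x, ...) x$eig

#' @rdname mfa
#' @method glance cpi_mfa
#' @export
glance.cpi_mfa <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_groups = length(x$group_weights),
    total_inertia = x$total_inertia,
    eig1 = x$eig$eigenvalue[1],
    pct1 = x$eig$pct_variance[1],
    cum_pct2 = if (nrow(x$eig) >= 2) x$eig$cum_pct_variance[2] else 100
  )
}
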