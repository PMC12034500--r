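#' Orthogonal polynomial design matrix
#'
#' Columns are the orthonormal polynomial basis (QR of the centered
#' Vandermonde matrix, as in `stats::poly`); the intercept is left to the
#' fitter. Orthogonal columns keep quadratic geographic terms numerically
#' stable and make single-term tests independent, while fitted values are
#' identical to a raw-power basis.
#'
#' @param x Numeric predictor with more than `degree` distinct values.
#' @param degree Polynomial degree (default 2, the quadratic trend model).
#' @return An `n x degree` matrix.
#' @export
poly_design <- function(x, degree = 2) {
  if (anyNA(x)) stop_validation("poly_design: missing values in predictor")
  if (length(unique(x)) <= degree) {
    stop_validation("poly_design needs more than %d distinct values", degree)
  }
  m <- stats::poly(x, degree = degree)
  colnames(m) <- paste0("p", seq_len(degree))
  unclass(m)[, , drop = FALSE]
}

#' Fit a gamma log-link GLM
#'
#' Fits `y ~ X` with a gamma error distribution and log link by iteratively
#' reweighted least squares, the model used for geographic trends in a
#' strictly positive index. Reports the explained deviance
#' `D2 = 1 - residual deviance / null deviance`, the GLM analogue of R2,
#' and a dispersion-scaled F test against the intercept-only model.
#'
#' @param y Strictly positive response vector.
#' @param X Design matrix (without intercept), or NULL for the null model.
#' @return An object of class `cpi_glm` wrapping the `glm` fit with
#'   `d_squared`, `p_value`, `dispersion` (Pearson), `converged`.
#' @export
fit_gamma_glm <- function(y, X = NULL) {
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop_validation("gamma GLM requires strictly positive responses")
  }
  df <- data.frame(y = y)
  if (is.null(X) || NCOL(X) == 0) {
    form <- y ~ 1
  } else {
    X <- as.matrix(X)
    if (qr(X)$rank < ncol(X)) stop_validation("design matrix is rank deficient")
    colnames(X) <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
    df <- cbind(df, as.data.frame(X))
    form <- stats::as.formula(paste("y ~", paste(colnames(X), collapse = " + ")))
  }
  fit <- suppressWarnings(stats::glm(form, family = stats::Gamma(link = "log"),
                                     data = df,
                                     control = stats::glm.control(
                                       epsilon = 1e-8, maxit = 100)))
  p <- length(stats::coef(fit))
  pearson <- sum(stats::residuals(fit, type = "pearson")^2)
  dispersion <- pearson / (fit$df.residual)
  d2 <- 1 - fit$deviance / fit$null.deviance
  # F test of the fitted model against its own null (intercept-only)
  p_value <- if (p > 1) {
    fstat <- ((fit$null.deviance - fit$deviance) / (p - 1)) / dispersion
    stats::pf(fstat, p - 1, fit$df.residual, lower.tail = FALSE)
  } else 1
  structure(list(fit = fit, coefficients = stats::coef(fit),
                 fitted = stats::fitted(fit),
                 null_deviance = fit$null.deviance,
                 deviance = fit$deviance,
                 dispersion = dispersion,
                 d_squared = d2, p_value = p_value,
                 converged = fit$converged, n_iter = fit$iter,
                 n = length(y)),
            class = "cpi_glm")
}

#' Explained deviance of a GLM fit
#'
#' @param fit A `cpi_glm` object.
#' @return `D2 = 1 - residual/null deviance`, in \[0, 1\].
#' @export
explained_deviance <- function(fit) {
  stopifnot(inherits(fit, "cpi_glm"))
  if (fit$null_deviance <= 0) {
    stop_validation("null deviance is zero; D-squared undefined")
  }
  1 - fit$deviance / fit$null_deviance
}

#' F test between nested gamma GLMs
#'
#' Scaled-deviance F test using the Pearson dispersion of the larger model
#' (the standard test when the gamma dispersion is estimated).
#'
#' @param fit,null_fit `cpi_glm` objects on the same response, `null_fit`
#'   nested in `fit`.
#' @return p-value; identical models give 1.
#' @export
model_p_value <- function(fit, null_fit) {
  stopifnot(inherits(fit, "cpi_glm"), inherits(null_fit, "cpi_glm"))
  if (fit$n != null_fit$n) stop_validation("models were fitted to different data")
  df_diff <- null_fit$fit$df.residual - fit$fit$df.residual
  if (df_diff < 0) stop_validation("null model must be nested in the full model")
  if (df_diff == 0) return(1)
  if (null_fit$deviance < fit$deviance - 1e-8) {
    stop_validation("models are not nested: the smaller model fits better")
  }
  fstat <- ((null_fit$deviance - fit$deviance) / df_diff) / fit$dispersion
  stats::pf(fstat, df_diff, fit$fit$df.residual, lower.tail = FALSE)
}

#' @export
print.cpi_glm <- function(x, ...) {
  cat(sprintf("Gamma log-link GLM: n = %d, D2 = %.3f, p = %.4g%s\n",
              x$n, x$d_squared, x$p_value,
              if (!x$converged) " (NOT converged)" else ""))
  invisible(x)
}

#' @rdname fit_gamma_glm
#' @param x A `cpi_glm` object.
#' @param ... Unused.
#' @method tidy cpi_glm
#' @export
tidy.cpi_glm <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
                 statistic = s[, 3], p_value = s[, 4])
}

#' @rdname fit_gamma_glm
#' @method glance cpi_glm
#' @export
glance.cpi_glm <- function(x, ...) {
  tibble::tibble(n = x$n, null_deviance = x$null_deviance,
                 deviance = x$deviance, d_squared = x$d_squared,
                 dispersion = x$dispersion, p_value = x$p_value,
                 converged = x$converged, n_iter = x$n_iter)
}

#' Geographic trend models of the CPI
#'
#' Fits, for the pooled species set and per genus, gamma log-link GLMs of
#' CPI on second-degree polynomials of centroid longitude and of centroid
#' latitude (one model per predictor). Genera with fewer than `min_n`
#' species are dropped from the per-genus fits (with two species a
#' quadratic is saturated), mirroring the exclusion of *Dioon*.
#'
#' @param scored Scored tibble with `species_name`, `genus`, `cpi`.
#' @param centroids Tibble with `species_name`, `centroid_lon`,
#'   `centroid_lat` (see [range_centroids()]).
#' @param by `"all"`, `"genus"` or `"both"` (default).
#' @param degree Polynomial degree (default 2).
#' @param min_n Minimum group size for per-genus fits (default 5: two
#'   quadratic terms, an intercept, and residual df to estimate dispersion).
#' @return A tibble with one row per (group, predictor): `n`, `d_squared`,
#'   `p_value`, `converged`, and the fit object in a list-column.
#' @export
cpi_trends <- function(scored, centroids, by = c("both", "all", "genus"),
                       degree = 2, min_n = 5) {
  by <- match.arg(by)
  dat <- dplyr::inner_join(
    scored[, c("species_name", "genus", "cpi")], centroids,
    by = "species_name")
  if (nrow(dat) < nrow(scored)) {
    stop_validation("centroids missing for %d species", nrow(scored) - nrow(dat))
  }
  groups <- list()
  if (by %in% c("both", "all")) groups[["all"]] <- dat
  if (by %in% c("both", "genus")) {
    for (g in unique(dat$genus)) {
      sub <- dat[dat$genus == g, ]
      if (nrow(sub) >= min_n) groups[[g]] <- sub
    }
  }
  rows <- list()
  for (g in names(groups)) {
    sub <- groups[[g]]
    for (pred in c("longitude", "latitude")) {
      x <- if (pred == "longitude") sub$centroid_lon else sub$centroid_lat
      fit <- fit_gamma_glm(sub$cpi, poly_design(x, degree))
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = g, predictor = pred, n = nrow(sub),
        d_squared = fit$d_squared, p_value = fit$p_value,
        converged = fit$converged, fit = list(fit))
    }
  }
  dplyr::bind_rows(rows)
}
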