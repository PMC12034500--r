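test_that("the polynomial design is orthonormal and basis-equivalent", {
  x <- c(-3, -2, -1, 0, 1, 2, 3)
  m1 <- poly_design(x, 1)
  xc <- x - mean(x)
  expect_equal(unname(m1[, 1]), xc / sqrt(sum(xc^2)), tolerance = 1e-12)
  set.seed(33)
  x <- rnorm(40)
  M <- poly_design(x, 2)
  expect_equal(crossprod(M), diag(2), ignore_attr = TRUE, tolerance = 1e-10)
  # same fitted means as the raw-power basis
  y <- exp(0.3 + 0.2 * x - 0.1 * x^2) * rgamma(40, 20, 20)
  f_orth <- fit_gamma_glm(y, M)
  f_raw <- fit_gamma_glm(y, cbind(x = x, x2 = x^2))
  expect_equal(unname(f_orth$fitted), unname(f_raw$fitted), tolerance = 1e-6)
  expect_equal(f_orth$d_squared, f_raw$d_squared, tolerance = 1e-8)
  expect_error(poly_design(c(1, 1, 2), 2), class = "cycadcpi_validation_error")
})

test_that("the intercept-only gamma GLM fits the arithmetic mean with D2 = 0", {
  set.seed(2)
  y <- rgamma(30, 5, 1)
  fit <- fit_gamma_glm(y)
  expect_equal(unname(fit$fitted), rep(mean(y), 30), tolerance = 1e-8)
  expect_equal(fit$d_squared, 0)
  expect_equal(fit$p_value, 1)
  expect_error(fit_gamma_glm(c(1, -1, 2)), class = "cycadcpi_validation_error")
})

test_that("the reported deviance matches the gamma deviance formula", {
  set.seed(14)
  x <- rnorm(60)
  y <- exp(1 + 0.5 * x) * rgamma(60, 10, 10)
  fit <- fit_gamma_glm(y, cbind(x = x))
  mu <- fit$fitted
  expect_equal(fit$deviance, 2 * sum(-log(y / mu) + (y - mu) / mu),
               tolerance = 1e-8)
  expect_equal(explained_deviance(fit), 1 - fit$deviance / fit$null_deviance)
  expect_true(fit$d_squared >= 0 && fit$d_squared <= 1)
})

test_that("coefficients are recovered within 3 SE on simulated gamma data", {
  set.seed(77)
  n <- 200
  x <- rnorm(n)
  beta <- c(`(Intercept)` = 0.8, x = 0.4)
  shape <- 8
  y <- rgamma(n, shape = shape, rate = shape / exp(beta[1] + beta[2] * x))
  fit <- fit_gamma_glm(y, cbind(x = x))
  est <- tidy(fit)
  expect_equal(est$term, c("(Intercept)", "x"))
  expect_true(all(abs(est$estimate - beta) <= 3 * est$std_error))
})

test_that("a perfect fit has D2 = 1 and nested F tests behave", {
  x <- seq(-1, 1, length.out = 12)
  y <- exp(0.5 + 2 * x)  # exactly log-linear
  fit <- fit_gamma_glm(y, cbind(x = x))
  expect_equal(fit$d_squared, 1, tolerance = 1e-9)
  null <- fit_gamma_glm(y)
  expect_equal(explained_deviance(null), 0)
  expect_equal(model_p_value(fit, fit), 1)
  expect_error(model_p_value(null, fit), class = "cycadcpi_validation_error")

  set.seed(41)
  y2 <- exp(1 + 1.5 * x) * rgamma(12, 50, 50)
  f2 <- fit_gamma_glm(y2, poly_design(x, 2))
  n2 <- fit_gamma_glm(y2)
  expect_lt(model_p_value(f2, n2), 0.001)
})

test_that("adding a column never increases residual deviance", {
  set.seed(55)
  for (rep in 1:5) {
    x <- matrix(rnorm(25 * 3), 25)
    y <- rgamma(25, 4, 2)
    d1 <- fit_gamma_glm(y, x[, 1, drop = FALSE])$deviance
    d2 <- fit_gamma_glm(y, x[, 1:2])$deviance
    d3 <- fit_gamma_glm(y, x)$deviance
    expect_lte(d2, d1 + 1e-8)
    expect_lte(d3, d2 + 1e-8)
  }
})

test_that("D2 is invariant to positive rescaling of the response", {
  set.seed(66)
  x <- rnorm(30)
  y <- exp(0.2 + 0.3 * x) * rgamma(30, 6, 6)
  f1 <- fit_gamma_glm(y, cbind(x = x))
  f2 <- fit_gamma_glm(y * 37.5, cbind(x = x))
  expect_equal(f1$d_squared, f2$d_squared, tolerance = 1e-8)
  # under the log link only the intercept shifts
  expect_equal(unname(f1$coefficients["x"]), unname(f2$coefficients["x"]),
               tolerance = 1e-8)
})

test_that("cpi_trends fits pooled and per-genus quadratic models", {
  cfg <- sim_config(n_species = 18, seed = 19, cluster_separation = 2)
  tab <- generate_species_table(cfg)
  scored <- build_scored_table(tab)
  lay <- generate_polygon_layers(cfg, species_names = tab$species_name)
  cents <- range_centroids(lay$ranges, lay$proj)
  tr <- cpi_trends(scored, cents)
  expect_true(all(c("all") %in% tr$group))
  expect_setequal(unique(tr$predictor), c("longitude", "latitude"))
  expect_true(all(tr$d_squared >= 0 & tr$d_squared <= 1))
  expect_true(all(tr$p_value > 0 & tr$p_value <= 1))
  # small genera are excluded from per-genus fits
  small <- names(which(table(tab$genus) < 5))
  expect_false(any(small %in% tr$group))
})
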