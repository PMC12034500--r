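test_that("categorical risk levels map to the documented scores", {
  tab <- tibble::tibble(
    species_name = paste("sp", 1:5), genus = "Zamia",
    iucn_category = c("CR", "EN", "VU", "NT", "LC"),
    endemic = c(TRUE, FALSE, TRUE, FALSE, TRUE),
    nom059_category = c("P", "A", "NONE", "P", "A"),
    n_localities = 1:5, eoo_km2 = 1:5 * 10,
    pct_area_in_region = 50, pct_habitat_loss = 50, pct_outside_pa = 50,
    n_municipalities = 1:5)
  got <- score_categories(tab)
  expect_equal(got$iucn_score, c(4, 3, 2, 1, 0))
  expect_equal(got$nom059_score, c(2, 1, 0, 2, 1))
  expect_equal(got$endemic_score, c(1, 0, 1, 0, 1))
})

test_that("an unresolved NE category demands a preliminary assessment", {
  tab <- cycad_attributes_synthetic()
  tab$iucn_category[4] <- "NE"
  expect_error(score_categories(tab), "preliminary",
               class = "cycadcpi_validation_error")
  expect_error(build_scored_table(tab), class = "cycadcpi_validation_error")
})

test_that("min-max normalization matches its defining formula", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_error(minmax_normalize(c(5, 5, 5)), "constant",
               class = "cycadcpi_validation_error")
  expect_error(minmax_normalize(c(3, NA, NA)), class = "cycadcpi_validation_error")
  set.seed(101)
  for (rep in 1:20) {
    x <- rnorm(sample(3:40, 1), sd = runif(1, 0.1, 50))
    z <- minmax_normalize(x)
    expect_equal(z, (x - min(x)) / (max(x) - min(x)))
    expect_equal(range(z), c(0, 1))
    expect_equal(order(z), order(x))
  }
})

test_that("inversion is the unit-interval reflection and an involution", {
  expect_equal(invert_normalized(0), 1)
  expect_equal(invert_normalized(0.3), 0.7)
  expect_error(invert_normalized(c(0.5, 1.2)), "position 2",
               class = "cycadcpi_validation_error")
  set.seed(7)
  z <- runif(50)
  expect_equal(invert_normalized(invert_normalized(z)), z)
})

test_that("the scored toy table matches the hand-computed spreadsheet", {
  scored <- build_scored_table(toy_two_species(), percent_mode = "div100")
  a <- scored[scored$species_name == "sp A", ]
  # extremes normalize to 1/0; percents divide by 100
  expect_equal(a$iucn, 1); expect_equal(a$endemic, 1); expect_equal(a$nom059, 1)
  expect_equal(a$locations_inv, 1); expect_equal(a$eoo_inv, 1)
  expect_equal(a$municipalities_inv, 1)
  expect_equal(a$area_region, 0.5); expect_equal(a$habitat_loss, 0.8)
  expect_equal(a$outside_pa, 0.9)
  expect_equal(a$cpi, 8.2)
  b <- scored[scored$species_name == "sp B", ]
  expect_equal(b$cpi, 0.25 + 0.20 + 0.40)
  expect_equal(scored$cpi_rank, c(1L, 2L))

  # the minmax percent mode sends column extremes to 1/0 instead
  mm <- build_scored_table(toy_two_species(), percent_mode = "minmax")
  expect_equal(mm$cpi, c(9, 0))
})

test_that("a species at the observed maximum of localities scores 0 on locations", {
  tab <- cycad_attributes_synthetic()
  scored <- build_scored_table(tab)
  expect_equal(scored$locations_inv[which.max(tab$n_localities)], 0)
  expect_equal(scored$locations_inv[which.min(tab$n_localities)], 1)
})

test_that("CPI is the exact sum of non-missing components within [0, 9]", {
  ones <- tibble::as_tibble(setNames(as.list(rep(1, 9)), cycadcpi:::CPI_COMPONENTS))
  expect_equal(compute_cpi(ones), 9)
  zeros <- tibble::as_tibble(setNames(as.list(rep(0, 9)), cycadcpi:::CPI_COMPONENTS))
  expect_equal(compute_cpi(zeros), 0)
  for (seed in 1:5) {
    tab <- generate_species_table(sim_config(n_species = 15, seed = seed))
    scored <- build_scored_table(tab)
    comp <- as.matrix(scored[, cycadcpi:::CPI_COMPONENTS])
    expect_true(all(comp >= 0 & comp <= 1))
    expect_equal(scored$cpi, rowSums(comp))
    expect_true(all(scored$cpi >= 0 & scored$cpi <= 9))
  }
})

test_that("missing attributes drop out of the sum and are counted", {
  tab <- cycad_attributes_synthetic()
  tab$pct_habitat_loss[5] <- NA
  scored <- build_scored_table(tab)
  expect_true(is.na(scored$habitat_loss[5]))
  expect_equal(scored$n_components[5], 8)
  expect_equal(scored$cpi[5],
               sum(as.numeric(scored[5, cycadcpi:::CPI_COMPONENTS]), na.rm = TRUE))
})

test_that("CPI is monotone in risk-increasing inputs and row-order invariant", {
  tab <- cycad_attributes_synthetic()
  base <- build_scored_table(tab)
  up <- tab
  up$pct_habitat_loss <- pmin(100, up$pct_habitat_loss + 5)
  bumped <- build_scored_table(up)
  expect_true(all(bumped$cpi >= base$cpi))
  fewer <- tab
  i <- 5  # not the min/max locality holder, so column extremes are unchanged
  stopifnot(tab$n_localities[i] > min(tab$n_localities) + 1,
            tab$n_localities[i] < max(tab$n_localities))
  fewer$n_localities[i] <- fewer$n_localities[i] - 1L
  expect_gt(build_scored_table(fewer)$cpi[i], base$cpi[i])

  set.seed(3)
  perm <- sample(nrow(tab))
  shuffled <- build_scored_table(tab[perm, ])
  expect_equal(shuffled$cpi, base$cpi[perm])
})

test_that("component correlations behave like Pearson r", {
  scored <- build_scored_table(cycad_attributes_synthetic())
  cm <- cpi_correlations(scored)
  expect_equal(diag(cm), setNames(rep(1, 9), colnames(cm)))
  expect_equal(cm, t(cm))
  expect_true(all(abs(cm) <= 1 + 1e-12))
  # positive semi-definite on complete data
  expect_true(min(eigen(cm, symmetric = TRUE, only.values = TRUE)$values) > -1e-8)
  # y = -x exactly
  df <- scored
  df$endemic <- -df$iucn
  cm2 <- cpi_correlations(df, vars = c("iucn", "endemic"))
  expect_equal(cm2["iucn", "endemic"], -1)
  df$endemic <- 0.5
  expect_error(cpi_correlations(df), "endemic",
               class = "cycadcpi_validation_error")
})

test_that("shortfall scores count informed fields", {
  kn <- tibble::tibble(species_name = c("a", "b"),
                       has_individual_count = c(TRUE, FALSE),
                       has_genbank = c(TRUE, FALSE),
                       has_studies = c(TRUE, FALSE),
                       has_popecol = c(TRUE, FALSE),
                       has_pollinator = c(TRUE, FALSE))
  expect_equal(shortfall_score(kn), c(5L, 0L))
})

test_that("the reconstructed knowledge table honours every published constraint", {
  kn <- cycad_knowledge_reconstructed()
  expect_equal(nrow(kn), 21)
  expect_equal(sum(kn$has_individual_count), 11)
  expect_equal(sum(kn$has_genbank), 20)
  expect_false(kn$has_genbank[kn$species_name == "Ceratozamia dominguezii"])
  expect_true(all(kn$has_studies))
  expect_equal(sum(kn$has_popecol), 8)
  expect_equal(sum(kn$has_pollinator), 11)
  expect_equal(kn$shortfall_score[kn$species_name == "Ceratozamia dominguezii"], 1L)
  expect_equal(sort(kn$species_name[kn$shortfall_score == 5]),
               c("Ceratozamia miqueliana", "Zamia inermis"))
  expect_equal(min(kn$shortfall_score), 1L)
})
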