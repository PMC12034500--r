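test_that("analytic multiscale cases give the known AU values", {
  scales <- seq(0.5, 1.4, by = 0.1)
  bp <- rbind(rep(1, 10), rep(0, 10), rep(0.5, 10))
  fit <- cycadcpi:::au_from_bp(bp, scales, B = 1000)
  expect_equal(fit$au[1], 1)
  expect_equal(fit$au[2], 0)
  # BP = 1/2 at every scale: z = 0, so v = c = 0 and AU = 1/2
  expect_equal(fit$v[3], 0, tolerance = 1e-12)
  expect_equal(fit$c[3], 0, tolerance = 1e-12)
  expect_equal(fit$au[3], 0.5)
  expect_equal(fit$flag, c("saturated", "never-recovered", "fitted"))
})

test_that("the WLS fit recovers exact (v, c) from model-generated BP curves", {
  scales <- seq(0.5, 1.4, by = 0.1)
  for (truth in list(c(v = 0.8, c = 0.3), c(v = -0.4, c = 0.9),
                     c(v = 1.5, c = -0.2))) {
    bp <- matrix(1 - pnorm(truth["v"] * sqrt(scales) + truth["c"] / sqrt(scales)),
                 nrow = 1)
    fit <- cycadcpi:::au_from_bp(bp, scales, B = 5000)
    expect_equal(unname(fit$v[1]), unname(truth["v"]), tolerance = 1e-8)
    expect_equal(unname(fit$c[1]), unname(truth["c"]), tolerance = 1e-8)
    expect_equal(fit$au[1], unname(1 - pnorm(truth["v"] - truth["c"])),
                 tolerance = 1e-8)
  }
})

test_that("fewer than two informative scales is flagged, not fitted", {
  scales <- c(0.5, 1, 1.4)
  bp <- matrix(c(1, 0.6, 0), nrow = 1)
  fit <- cycadcpi:::au_from_bp(bp, scales, B = 100)
  expect_equal(fit$flag[1], "insufficient-scales")
  expect_equal(fit$au[1], 0.6)  # falls back to the scale-1 BP
})

test_that("bootstrap support is deterministic under a fixed seed", {
  tab <- generate_species_table(sim_config(n_species = 10, seed = 4,
                                           cluster_separation = 3))
  vars <- cpi_analysis_variables(
    tab[, setdiff(names(tab), c("true_group", "latent_risk"))])
  a1 <- multiscale_bootstrap_au(vars, kinds = attr(vars, "kinds"),
                                B = 100, seed = 42)
  a2 <- multiscale_bootstrap_au(vars, kinds = attr(vars, "kinds"),
                                B = 100, seed = 42)
  expect_identical(a1$support, a2$support)
  a3 <- multiscale_bootstrap_au(vars, kinds = attr(vars, "kinds"),
                                B = 100, seed = 43)
  expect_false(identical(a1$bp_by_scale, a3$bp_by_scale))
})

test_that("AU support is invariant to row order of the table", {
  tab <- generate_species_table(sim_config(n_species = 9, seed = 8,
                                           cluster_separation = 3))
  vars <- cpi_analysis_variables(
    tab[, setdiff(names(tab), c("true_group", "latent_risk"))])
  a1 <- multiscale_bootstrap_au(vars, kinds = attr(vars, "kinds"),
                                B = 200, seed = 5)
  perm <- c(4, 1, 9, 2, 8, 3, 7, 5, 6)
  a2 <- multiscale_bootstrap_au(vars[perm, ], kinds = attr(vars, "kinds"),
                                B = 200, seed = 5)
  norm_members <- function(au) sort(vapply(
    strsplit(au$support$members, ";"),
    function(mm) paste(sort(mm), collapse = ";"), ""))
  expect_equal(norm_members(a1), norm_members(a2))
  # same member sets carry similar AU despite different resample draws
  m1 <- setNames(a1$support$au, vapply(strsplit(a1$support$members, ";"),
                                       function(mm) paste(sort(mm), collapse = ";"), ""))
  m2 <- setNames(a2$support$au, vapply(strsplit(a2$support$members, ";"),
                                       function(mm) paste(sort(mm), collapse = ";"), ""))
  expect_equal(m1[names(m2)], m2, tolerance = 0.15)
})

test_that("well-separated planted clusters earn higher AU than group-straddling nodes", {
  tab <- generate_species_table(sim_config(n_species = 12, seed = 31,
                                           cluster_separation = 3))
  vars <- cpi_analysis_variables(
    tab[, setdiff(names(tab), c("true_group", "latent_risk"))])
  au <- multiscale_bootstrap_au(vars, kinds = attr(vars, "kinds"),
                                B = 400, seed = 7)
  key_of <- function(idx) paste(sort(vars$species_name[idx]), collapse = ";")
  planted <- vapply(1:2, function(g) key_of(which(tab$true_group == g)), "")
  members <- strsplit(au$support$members, ";")
  members_sorted <- vapply(members, function(mm) paste(sort(mm), collapse = ";"), "")
  hit <- members_sorted %in% planted
  expect_true(any(hit))
  # nodes mixing the two planted groups (other than the root, which is
  # trivially present in every replicate) are spurious structure
  straddles <- vapply(members, function(mm) {
    g <- tab$true_group[match(mm, vars$species_name)]
    length(unique(g)) > 1 && length(mm) < nrow(vars)
  }, TRUE)
  if (any(straddles)) {
    expect_gte(min(au$support$au[hit]), max(au$support$au[straddles]))
  }
  expect_gte(min(au$support$au[hit]), 0.9)
})
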