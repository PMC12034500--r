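# Independent oracles and small fixtures shared across tests. Everything
# here is deliberately written from first principles (formulas, brute force)
# rather than reusing the package's internals.

# Brute-force Ward agglomeration by the Lance-Williams update on squared
# distances (the ward.D2 convention); lowest-index pair breaks ties.
brute_force_ward <- function(d) {
  dm <- as.matrix(d)^2
  n <- nrow(dm)
  sizes <- rep(1, n)
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1)
  sets <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (b <= a) next
        i <- active[a]; j <- active[b]
        if (dm[i, j] < bestd - 1e-12) { bestd <- dm[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- sqrt(bestd)
    merged <- sort(c(members[[i]], members[[j]]))
    sets[[step]] <- merged
    # Lance-Williams ward update for every remaining cluster
    for (k in active) {
      if (k == i || k == j) next
      dm[i, k] <- dm[k, i] <-
        ((sizes[i] + sizes[k]) * dm[i, k] + (sizes[j] + sizes[k]) * dm[j, k] -
           sizes[k] * dm[i, j]) / (sizes[i] + sizes[j] + sizes[k])
    }
    sizes[i] <- sizes[i] + sizes[j]
    members[[i]] <- merged
    active <- setdiff(active, j)
  }
  list(heights = heights,
       set_keys = vapply(sets, paste, "", collapse = ","))
}

# Gower distance from the definition, row pair by row pair.
naive_gower <- function(df, kinds) {
  n <- nrow(df)
  out <- matrix(0, n, n)
  rngs <- lapply(df, function(col) if (is.numeric(col)) diff(range(col, na.rm = TRUE)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0; w <- 0
      for (v in seq_along(df)) {
        xi <- df[[v]][i]; xj <- df[[v]][j]
        if (is.na(xi) || is.na(xj)) next
        s <- s + if (kinds[v] == "numeric") abs(xi - xj) / rngs[[v]] else
          as.numeric(xi != xj)
        w <- w + 1
      }
      out[i, j] <- s / w
    }
  }
  out
}

# Rand index between two hard partitions.
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  agree <- same_a == same_b
  (sum(agree[upper.tri(agree)])) / choose(n, 2)
}

# Toy two-species attribute table with hand-computable components.
toy_two_species <- function() {
  tibble::tibble(
    species_name = c("sp A", "sp B"),
    genus = c("Zamia", "Dioon"),
    iucn_category = c("CR", "VU"),
    endemic = c(TRUE, FALSE),
    nom059_category = c("P", "A"),
    n_localities = c(2L, 10L),
    eoo_km2 = c(100, 400),
    pct_area_in_region = c(50, 25),
    pct_habitat_loss = c(80, 20),
    pct_outside_pa = c(90, 40),
    n_municipalities = c(1L, 5L)
  )
}

# A tiny valid species table writer for IO tests.
write_species_csv <- function(tab, path = tempfile(fileext = ".csv")) {
  readr::write_csv(tab, path)
  path
}
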