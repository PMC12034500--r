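#' Ward clustering of a distance matrix
#'
#' Agglomerates by the Lance-Williams Ward update. The default `"ward.D2"`
#' variant operates on squared dissimilarities (heights are in the original
#' distance metric); `"ward.D"` is the legacy variant that applies the
#' update to the raw dissimilarities.
#'
#' @param d A `dist` object (e.g. from [gower_distance()]).
#' @param variant `"ward.D2"` (default) or `"ward.D"`.
#' @return An `hclust` tree.
#' @export
ward_linkage <- function(d, variant = c("ward.D2", "ward.D")) {
  variant <- match.arg(variant)
  if (!inherits(d, "dist")) stop_validation("ward_linkage expects a 'dist' object")
  if (attr(d, "Size") < 2) stop_validation("clustering needs >= 2 objects")
  if (anyNA(d)) stop_validation("distance matrix contains missing entries")
  stats::hclust(d, method = variant)
}

#' Cut a dendrogram into k groups
#'
#' @param tree An `hclust` tree.
#' @param k Number of groups, `1 <= k <= n`.
#' @return Named integer vector of cluster labels.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1 || k > n) stop_validation("k must be between 1 and %d", n)
  stats::cutree(tree, k = k)
}

# Member sets of the n-1 internal nodes of an hclust tree, each encoded as
# a sorted integer vector of leaf indices and a collapsed key string.
hclust_node_sets <- function(tree) {
  n <- length(tree$order)
  sets <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    mem <- integer(0)
    for (j in 1:2) {
      v <- tree$merge[i, j]
      mem <- c(mem, if (v < 0) -v else sets[[v]])
    }
    sets[[i]] <- sort(mem)
  }
  sets
}

node_keys <- function(sets) {
  vapply(sets, paste, "", collapse = ",")
}

#' Multiscale bootstrap AU support for Gower/Ward clusters
#'
#' Assesses the stability of every internal node of a Gower + Ward
#' dendrogram by multiscale bootstrap: the variables (columns) of the data
#' table are resampled with replacement to `ceiling(m * r)` columns at each
#' scale `r`, the tree is rebuilt, and `BP(r)` is the fraction of replicate
#' trees containing the node's exact member set. The normal-theory fit
#' `qnorm(1 - BP(r)) = v * sqrt(r) + c / sqrt(r)` (weighted least squares
#' with binomial weights over scales where `0 < BP < 1`) yields the
#' approximately unbiased support `AU = 1 - pnorm(v - c)`, which corrects
#' the ordinary bootstrap probability's bias. The regression uses the
#' *achieved* scales `ceiling(m * r) / m`, which matters when few variables
#' are resampled. Hit rates within Monte-Carlo resolution of 0 or 1 (3/B)
#' carry no information about the curve and are excluded; nodes recovered
#' in essentially every replicate are saturated at AU = 1 (0 symmetrically).
#'
#' @param data Mixed-type tibble of the clustered variables (rows =
#'   species); a `species_name` column becomes the labels.
#' @param kinds Optional variable kinds, as in [gower_distance()].
#' @param scales Resampling scales `r`; default `seq(0.5, 1.4, by = 0.1)`.
#' @param B Bootstrap replicates per scale (the study-scale default is
#'   5000; 1000 is adequate for routine runs).
#' @param seed Integer seed for the resampling RNG.
#' @param variant Ward variant, see [ward_linkage()].
#' @return A list of class `cpi_au` with the original `tree`, a `support`
#'   tibble (node, member key, `au`, `bp`, fitted `v`, `c`, flag), the `bp`
#'   matrix by scale, and the call parameters.
#' @export
multiscale_bootstrap_au <- function(data, kinds = NULL,
                                    scales = seq(0.5, 1.4, by = 0.1),
                                    B = 1000, seed = 1,
                                    variant = c("ward.D2", "ward.D")) {
  variant <- match.arg(variant)
  labels <- if ("species_name" %in% names(data)) {
    as.character(data$species_name)
  } else rownames(data)
  vars_data <- if ("species_name" %in% names(data)) {
    data[, setdiff(names(data), "species_name"), drop = FALSE]
  } else data
  n <- nrow(vars_data)
  m <- ncol(vars_data)
  if (m < 2) stop_validation("multiscale bootstrap needs >= 2 variables")
  parts <- gower_parts(vars_data, kinds)
  d0 <- combine_gower_parts(parts, n = n, labels = labels)
  tree <- ward_linkage(d0, variant)
  sets <- hclust_node_sets(tree)
  keys <- node_keys(sets)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  # achieved scales: with few variables the realized subsample size
  # ceiling(m * r) can sit well off the nominal r, and the z(r) regression
  # must use the scale actually resampled
  m_per_scale <- pmax(2L, as.integer(ceiling(m * scales)))
  scales_achieved <- m_per_scale / m
  bp <- matrix(0, nrow = length(keys), ncol = length(scales),
               dimnames = list(NULL, sprintf("r=%g", scales)))
  for (s in seq_along(scales)) {
    m_s <- m_per_scale[s]
    hits <- numeric(length(keys))
    for (b in seq_len(B)) {
      idx <- sample.int(m, m_s, replace = TRUE)
      w <- tabulate(idx, nbins = m)
      db <- combine_gower_parts(parts, weights = w, n = n)
      if (anyNA(db)) next
      tb <- stats::hclust(db, method = variant)
      kb <- node_keys(hclust_node_sets(tb))
      hits <- hits + (keys %in% kb)
    }
    bp[, s] <- hits / B
  }

  fit <- au_from_bp(bp, scales_achieved, B)
  support <- tibble::tibble(
    node = seq_along(keys),
    members = vapply(sets, function(sx) paste(labels[sx], collapse = ";"), ""),
    n_members = lengths(sets),
    bp = bp[, which.min(abs(scales_achieved - 1))],
    au = fit$au, v = fit$v, c = fit$c, flag = fit$flag
  )
  structure(list(tree = tree, support = support, bp_by_scale = bp,
                 scales = scales, scales_achieved = scales_achieved,
                 B = B, seed = seed, variant = variant),
            class = "cpi_au")
}

# Fit the multiscale model to a BP-by-scale matrix. Exposed internally so
# the analytic cases (BP identically 1, 0 or 0.5) are testable without
# resampling.
au_from_bp <- function(bp, scales, B) {
  k <- nrow(bp)
  au <- numeric(k); v <- rep(NA_real_, k); cc <- rep(NA_real_, k)
  flag <- character(k)
  sq <- sqrt(scales)
  # hit counts within `edge` of 0 or B say nothing about the z(r) curve:
  # the normal quantile is dominated by the 1/B resolution there
  edge <- min(3 / B, 0.5)
  near1 <- which.min(abs(scales - 1))
  for (i in seq_len(k)) {
    p <- bp[i, ]
    usable <- p >= edge & p <= 1 - edge
    if (stats::median(p) >= 1 - edge && p[near1] >= 1 - edge) {
      au[i] <- 1; flag[i] <- "saturated"; next
    }
    if (stats::median(p) <= edge && p[near1] <= edge) {
      au[i] <- 0; flag[i] <- "never-recovered"; next
    }
    if (sum(usable) < 2) {
      # degenerate mixture of 0/1 scales: fall back to the scale-1 BP
      au[i] <- p[which.min(abs(scales - 1))]
      flag[i] <- "insufficient-scales"
      next
    }
    z <- stats::qnorm(1 - p[usable])
    X <- cbind(sq[usable], 1 / sq[usable])
    w <- B * stats::dnorm(z)^2 / (p[usable] * (1 - p[usable]))
    XtW <- t(X * w)
    beta <- solve(XtW %*% X, XtW %*% z)
    v[i] <- beta[1]; cc[i] <- beta[2]
    au[i] <- 1 - stats::pnorm(beta[1] - beta[2])
    flag[i] <- "fitted"
  }
  list(au = au, v = v, c = cc, flag = flag)
}

#' @export
print.cpi_au <- function(x, ...) {
  cat(sprintf("Gower/Ward (%s) clustering with multiscale-bootstrap AU support\n",
              x$variant))
  cat(sprintf("  %d leaves, %d internal nodes, B = %d per scale, %d scales\n",
              length(x$tree$order), nrow(x$support), x$B, length(x$scales)))
  hi <- x$support[x$support$au >= 0.95, ]
  cat(sprintf("  nodes with AU >= 0.95: %d\n", nrow(hi)))
  invisible(x)
}

#' @rdname multiscale_bootstrap_au
#' @param x A `cpi_au` object.
#' @param ... Unused.
#' @method tidy cpi_au
#' @export
tidy.cpi_au <- function(x, ...) x$support

#' Retain clusters with high AU support
#'
#' @param au A [multiscale_bootstrap_au()] result.
#' @param threshold Minimum AU (the conventional cut is 0.95).
#' @return The `support` rows with `au >= threshold`, largest first.
#' @export
au_retained_clusters <- function(au, threshold = 0.95) {
  stopifnot(inherits(au, "cpi_au"))
  out <- au$support[au$support$au >= threshold, ]
  out[order(-out$n_members), ]
}
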