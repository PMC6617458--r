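#' @title Community-level tests: Bray-Curtis, PERMANOVA, dispersion homogeneity
#' @name diffstats_multivariate
#' @description
#' Whole-community treatment effects are assessed on Bray-Curtis distances
#' between samples with a permutational multivariate ANOVA (pseudo-F with a
#' permutation or exhaustive-relabeling p-value), preceded by a test of
#' multivariate dispersion homogeneity (distances to group centroids in
#' principal-coordinate space).
NULL

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Bray-Curtis distances between samples
#'
#' Computed on per-sample relative abundances:
#' `d(u, v) = sum(|u - v|) / sum(u + v)`, in `[0, 1]`.
#'
#' @param table Count (or abundance) table, features x samples.
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(table) {
  cm <- count_matrix(table)
  rel <- sweep(cm$counts, 2L, colSums(cm$counts), "/")
  n <- ncol(rel)
  d <- matrix(0, n, n, dimnames = list(colnames(rel), colnames(rel)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sum(rel[, i] + rel[, j])
    d[i, j] <- d[j, i] <- if (s == 0) 0 else
      sum(abs(rel[, i] - rel[, j])) / s
  }
  stats::as.dist(d)
}

permanova_F <- function(d2, groups) {
  n <- nrow(d2)
  g <- length(unique(groups))
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (lev in unique(groups)) {
    idx <- which(groups == lev)
    if (length(idx) > 1) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  (ss_between / (g - 1)) / (ss_within / (n - g))
}

#' PERMANOVA on a distance matrix
#'
#' The pseudo-F statistic partitions the sum of squared distances into
#' between- and within-group components. If the number of distinct
#' relabelings (for two groups, `choose(n, n1)`) is at most
#' `exhaustive_limit`, all are enumerated and the p-value is the exact
#' fraction of relabelings with `F >= F_obs`; otherwise `n_perm` random
#' permutations are drawn and `p = (#{F_perm >= F_obs} + 1) / (n_perm + 1)`
#' (the observed labeling included).
#'
#' @param dist A `dist` or symmetric distance matrix.
#' @param groups Group labels per sample (>= 2 per group).
#' @param n_perm Permutations in sampled mode (default 9999).
#' @param exhaustive_limit Maximum relabelings for exhaustive mode.
#' @param seed Seed for sampled mode (local to the call).
#' @return Object of class `permanova`: `pseudo_F`, `p_value`, `mode`
#'   (`"exhaustive"`/`"sampled"`), `n_perm`, `df`.
#' @export
permanova <- function(dist, groups, n_perm = 9999L,
                      exhaustive_limit = 10000L, seed = NULL) {
  d <- as.matrix(dist)
  groups <- as.character(groups)
  n <- nrow(d)
  stopifnot(length(groups) == n)
  if (any(table(groups) < 2L)) abort("every group needs >= 2 samples")
  d2 <- d^2
  f_obs <- permanova_F(d2, groups)
  levs <- unique(groups)
  n_distinct <- exp(lgamma(n + 1) - sum(lgamma(table(groups) + 1)))
  if (length(levs) == 2L && n_distinct <= exhaustive_limit) {
    n1 <- sum(groups == levs[1])
    combos <- utils::combn(n, n1)
    f_perm <- apply(combos, 2L, function(idx) {
      lab <- rep(levs[2], n)
      lab[idx] <- levs[1]
      permanova_F(d2, lab)
    })
    p <- mean(f_perm >= f_obs - 1e-12)
    mode <- "exhaustive"
    nper <- ncol(combos)
  } else {
    f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      permanova_F(d2, sample(groups)), 1.0))
    p <- (sum(f_perm >= f_obs - 1e-12) + 1) / (n_perm + 1)
    mode <- "sampled"
    nper <- n_perm
  }
  structure(list(pseudo_F = f_obs, p_value = p, mode = mode, n_perm = nper,
                 df = c(between = length(levs) - 1L,
                        within = n - length(levs))),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, p = %.4g (%s, %d relabelings)\n",
              x$pseudo_F, x$p_value, x$mode, x$n_perm))
  invisible(x)
}

#' @export
tidy.permanova <- function(x, ...) {
  tibble(term = "group", df = x$df[["between"]], statistic = x$pseudo_F,
         p.value = x$p_value)
}

#' @export
glance.permanova <- function(x, ...) {
  tibble(pseudo_F = x$pseudo_F, p.value = x$p_value, mode = x$mode,
         n_perm = x$n_perm)
}

#' Multivariate dispersion homogeneity test
#'
#' Samples are embedded by principal-coordinate analysis of the distance
#' matrix (negative eigenvalues truncated at zero), each sample's distance
#' to its own group centroid is computed, and group differences in those
#' distances are tested by a permutation F-test.
#'
#' @inheritParams permanova
#' @param n_perm Number of label permutations (default 999).
#' @return Object of class `dispersion_homogeneity`: `F_stat`, `p_value`,
#'   `distances` (tibble `sample_id`, `group`, `dist_to_centroid`).
#' @export
dispersion_homogeneity <- function(dist, groups, n_perm = 999L,
                                   seed = NULL) {
  d <- as.matrix(dist)
  groups <- as.character(groups)
  n <- nrow(d)
  # PCoA via double centering
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  coords <- eig$vectors %*% diag(sqrt(lambda), n)
  dists <- numeric(n)
  for (lev in unique(groups)) {
    idx <- which(groups == lev)
    cen <- colMeans(coords[idx, , drop = FALSE])
    dists[idx] <- sqrt(rowSums(sweep(coords[idx, , drop = FALSE], 2L,
                                     cen)^2))
  }
  f_stat <- anova_F(dists, groups)
  f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    anova_F(dists, sample(groups)), 1.0))
  p <- (sum(f_perm >= f_stat - 1e-12) + 1) / (n_perm + 1)
  structure(list(F_stat = f_stat, p_value = p,
                 distances = tibble(sample_id = rownames(d) %||%
                                      paste0("s", seq_len(n)),
                                    group = groups,
                                    dist_to_centroid = dists)),
            class = "dispersion_homogeneity")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

anova_F <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  # all distances (numerically) equal: nothing to test
  if (stats::sd(values) < 1e-9 * (abs(grand) + 1)) return(0)
  levs <- unique(groups)
  ss_b <- sum(vapply(levs, function(l)
    sum(groups == l) * (mean(values[groups == l]) - grand)^2, 1.0))
  ss_w <- sum(vapply(levs, function(l)
    sum((values[groups == l] - mean(values[groups == l]))^2), 1.0))
  df_b <- length(levs) - 1L
  df_w <- length(values) - length(levs)
  if (ss_w < 1e-300 && ss_b < 1e-300) return(0)
  if (ss_w < 1e-300) return(Inf)
  (ss_b / df_b) / (ss_w / df_w)
}

#' @export
print.dispersion_homogeneity <- function(x, ...) {
  cat(sprintf("Dispersion homogeneity: F = %.4g, p = %.4g\n",
              x$F_stat, x$p_value))
  invisible(x)
}

#' @export
tidy.dispersion_homogeneity <- function(x, ...) x$distances

#' @export
glance.dispersion_homogeneity <- function(x, ...) {
  tibble(F_stat = x$F_stat, p.value = x$p_value)
}
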