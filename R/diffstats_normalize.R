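#' @title Count-table filtering and normalization
#' @name diffstats_normalize
#' @description
#' Count tables are wide tibbles: one feature-id column (the first column;
#' any further non-numeric columns are carried as annotation) and one
#' numeric column per sample. Library sizes default to column sums.
NULL

count_matrix <- function(table, lib_sizes = NULL) {
  table <- as_tibble(table)
  num <- vapply(table, is.numeric, TRUE)
  num[1L] <- FALSE # first column is always the feature id
  # taxon tables carry taxid + name annotation before the sample columns
  if ("name" %in% names(table)) num[names(table) == "name"] <- FALSE
  if ("taxid" %in% names(table)) num[names(table) == "taxid"] <- FALSE
  m <- as.matrix(table[, num, drop = FALSE])
  rownames(m) <- as.character(table[[1L]])
  if (is.null(lib_sizes)) lib_sizes <- colSums(m)
  if (is.null(names(lib_sizes))) names(lib_sizes) <- colnames(m)
  if (any(lib_sizes <= 0)) abort("zero library size")
  list(counts = m, lib_sizes = lib_sizes[colnames(m)], annot = table[, !num,
       drop = FALSE])
}

#' Abundance filter: counts per million in enough samples
#'
#' A feature is kept iff its CPM (`count / library_size * 1e6`) reaches
#' `min_cpm` in at least `min_samples` samples — the filter used to strip
#' sequencing errors and technical artefacts before testing.
#'
#' @param table Count table (see [diffstats_normalize]).
#' @param min_cpm CPM threshold (default 4, boundary inclusive).
#' @param min_samples Number of samples required at threshold (default 4).
#' @param lib_sizes Optional named library sizes; default column sums.
#' @return The kept rows, with attribute `n_removed`.
#' @export
cpm_filter <- function(table, min_cpm = 4, min_samples = 4L,
                       lib_sizes = NULL) {
  cm <- count_matrix(table, lib_sizes)
  cpm <- sweep(cm$counts, 2L, cm$lib_sizes, "/") * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  out <- table[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "library_sizes") <- cm$lib_sizes
  out
}

#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' The reference sample is the one whose 75th-percentile CPM is closest to
#' the mean across samples. For each sample, features with a zero count in
#' either the sample or the reference are excluded; the remaining
#' log2-ratios (M-values) are doubly trimmed (`trim_M` on M, `trim_A` on
#' average log intensity) and combined by a precision-weighted mean
#' (inverse binomial-variance weights); the factor is 2 to that mean.
#' Factors are rescaled to geometric mean 1.
#'
#' @param table Count table.
#' @param trim_M,trim_A Two-sided trim fractions (defaults 0.30 / 0.05).
#' @param lib_sizes Optional library sizes.
#' @return Tibble `sample_id`, `lib_size`, `norm_factor`,
#'   `effective_lib_size` (= lib_size * norm_factor).
#' @export
tmm_factors <- function(table, trim_M = 0.30, trim_A = 0.05,
                        lib_sizes = NULL) {
  cm <- count_matrix(table, lib_sizes)
  y <- cm$counts
  n <- ncol(y)
  libs <- cm$lib_sizes
  if (n == 1L) {
    return(tibble(sample_id = colnames(y), lib_size = unname(libs),
                  norm_factor = 1, effective_lib_size = unname(libs)))
  }
  q75 <- apply(sweep(y, 2L, libs, "/"), 2L, quantile, probs = 0.75)
  ref <- which.min(abs(q75 - mean(q75)))
  f <- vapply(seq_len(n), function(j) {
    tmm_pair(y[, j], y[, ref], libs[j], libs[ref], trim_M, trim_A)
  }, 1.0)
  f <- f / exp(mean(log(f)))
  tibble(sample_id = colnames(y), lib_size = unname(libs),
         norm_factor = unname(f),
         effective_lib_size = unname(libs * f))
}

tmm_pair <- function(obs, ref, n_obs, n_ref, trim_M, trim_A) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(M) & is.finite(A) & w > 0
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  if (!length(M)) return(1)
  if (max(abs(M)) < 1e-6) return(1) # pure depth difference
  nk <- length(M)
  loM <- floor(nk * trim_M) + 1; hiM <- nk + 1 - loM
  loA <- floor(nk * trim_A) + 1; hiA <- nk + 1 - loA
  rM <- rank(M)
  rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  2 ^ (sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

#' Benjamini-Hochberg step-up false discovery rates
#'
#' @param p_values Numeric vector of p-values.
#' @return FDR-adjusted values in the input order.
#' @export
bh_adjust <- function(p_values) {
  m <- length(p_values)
  if (!m) return(numeric())
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p_values[o]))[ro]
}
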