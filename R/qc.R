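# Screen quality control: replicate-plate correlation matrices, siRNA
# reproducibility against a randomised null, and the Z' factor.

zscore_rows_by_feature <- function(m) {
  # z-score each feature (column) across the wells of one plate
  mu <- colMeans(m, na.rm = TRUE)
  sig <- apply(m, 2, sd, na.rm = TRUE)
  sig[!is.finite(sig) | sig == 0] <- NA
  sweep(sweep(m, 2, mu), 2, sig, "/")
}

#' Replicate-plate correlation matrix
#'
#' Well-averaged feature vectors are z-score normalised within each plate;
#' the Pearson correlation is then computed between every well of plate A
#' and every well of plate B. The diagonal holds the replicate (same-well)
#' correlations, the off-diagonal the null, and a Welch two-sample t-test
#' compares the two distributions. Wells with constant feature vectors are
#' excluded with a warning.
#'
#' @param plate_a,plate_b numeric matrices/data.frames (wells x features),
#'   same well order and feature set.
#' @return list: `matrix` (wells x wells correlations), `diagonal`,
#'   `off_diagonal`, `p_value`, `t_test`.
#' @export
replicate_correlation <- function(plate_a, plate_b) {
  A <- as.matrix(plate_a)
  B <- as.matrix(plate_b)
  stopifnot(all(dim(A) == dim(B)))
  Az <- zscore_rows_by_feature(A)
  Bz <- zscore_rows_by_feature(B)
  const <- apply(Az, 1, function(r) sd(r, na.rm = TRUE) == 0) |
    apply(Bz, 1, function(r) sd(r, na.rm = TRUE) == 0)
  const[is.na(const)] <- TRUE
  if (any(const)) {
    warning(sum(const), " well(s) with constant feature vectors excluded")
    Az <- Az[!const, , drop = FALSE]
    Bz <- Bz[!const, , drop = FALSE]
  }
  cm <- cor(t(Az), t(Bz), use = "pairwise.complete.obs")
  dg <- diag(cm)
  off <- cm[row(cm) != col(cm)]
  tt <- t.test(dg, off)   # Welch two-sample
  list(matrix = cm, diagonal = dg, off_diagonal = off,
       p_value = tt$p.value, t_test = tt)
}

#' siRNA reproducibility distributions
#'
#' Positive distribution: Pearson correlations between the z-scored feature
#' vectors of technical-replicate wells of the same siRNA. Null: the same
#' computation after permuting whole feature vectors across wells (preserving
#' within-vector covariance), seeded. Reports the median and the adjusted
#' Fisher-Pearson skewness of both distributions.
#'
#' @param table data.frame with a `sirna` column and numeric feature columns.
#' @param features feature column names.
#' @param seed seed for the null permutation.
#' @return list: `positive`, `null` (correlation vectors), `median_positive`,
#'   `median_null`, `skewness_positive`, `skewness_null`, `p_value`,
#'   `n_skipped` (siRNAs without replicates).
#' @export
sirna_reproducibility <- function(table, features, seed = 1L) {
  stopifnot("sirna" %in% names(table), all(features %in% names(table)))
  M <- zscore_rows_by_feature(as.matrix(table[, features, drop = FALSE]))
  pair_cors <- function(groups) {
    out <- numeric(0)
    for (g in unique(groups)) {
      i <- which(groups == g)
      if (length(i) < 2) next
      cm <- cor(t(M[i, , drop = FALSE]), use = "pairwise.complete.obs")
      out <- c(out, cm[upper.tri(cm)])
    }
    out
  }
  groups <- as.character(table$sirna)
  n_rep <- table(groups)
  n_skipped <- sum(n_rep < 2)
  if (n_skipped) {
    warning(n_skipped, " siRNA(s) without technical replicates skipped")
  }
  pos <- pair_cors(groups)
  if (!length(pos)) warning("no siRNA has >= 2 replicates: empty positive distribution")
  set.seed(seed)
  null <- pair_cors(sample(groups))   # vectors permuted across well labels
  tt <- if (length(pos) > 2 && length(null) > 2) t.test(pos, null) else NULL
  list(positive = pos, null = null,
       median_positive = if (length(pos)) median(pos) else NA_real_,
       median_null = if (length(null)) median(null) else NA_real_,
       skewness_positive = skewness_fp(pos),
       skewness_null = skewness_fp(null),
       p_value = if (!is.null(tt)) tt$p.value else NA_real_,
       n_skipped = n_skipped)
}

#' Z-prime factor
#'
#' `Z' = 1 - 3 * (sd_pos + sd_neg) / |mean_pos - mean_neg|`, the standard
#' dynamic-range statistic for screening assays: above 0.3 is acceptable,
#' 0.5-1.0 desirable. Invariant to affine transformations applied to both
#' arms. Identical control means give `NA` with a diagnostic attribute.
#'
#' @param positive,negative numeric vectors of control well values (>= 3
#'   wells per arm).
#' @return numeric Z' value with attributes `band` ("desirable",
#'   "acceptable" or "failing") and `n`.
#' @export
zprime <- function(positive, negative) {
  positive <- positive[is.finite(positive)]
  negative <- negative[is.finite(negative)]
  if (length(positive) < 3 || length(negative) < 3) {
    stop("need at least 3 wells per control arm")
  }
  dmu <- abs(mean(positive) - mean(negative))
  if (dmu == 0) {
    out <- NA_real_
    attr(out, "band") <- "undefined: control means are identical"
    return(out)
  }
  z <- 1 - 3 * (sd(positive) + sd(negative)) / dmu
  attr(z, "band") <- if (z >= 0.5) "desirable" else if (z > 0.3) {
    "acceptable"
  } else "failing"
  attr(z, "n") <- c(positive = length(positive), negative = length(negative))
  z
}
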