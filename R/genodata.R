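#' Standardize genotype codes
#'
#' Centers and scales a vector of genotype indicator codes to sample mean 0
#' and sample variance 1, z = (z0 - mean(z0)) / sd(z0), using the n - 1
#' denominator sample standard deviation.  With this convention the sum of
#' squared deviations of z is n - 1, so for a single-marker regression
#' var(alpha_hat) = sigma^2 / (n - 1) and the corrected heritability equals
#' the adjusted R-squared exactly (see [r2Family()]).
#'
#' Missing codes are mean-imputed (on the raw scale) before standardization.
#'
#' @param raw_codes numeric vector, typically \{+1, 0, -1\}; length >= 3.
#' @param id marker name used in error messages.
#' @return numeric vector with mean 0 and sample variance 1.
#' @examples
#' z <- standardizeGenotypes(c(1, 0, -1, 0))
#' c(mean(z), var(z))
#' @export
standardizeGenotypes <- function(raw_codes, id = "marker") {
  raw_codes <- as.numeric(raw_codes)
  if (length(raw_codes) < 3L)
    stop("need at least 3 individuals to standardize marker '", id, "'")
  if (anyNA(raw_codes))
    raw_codes[is.na(raw_codes)] <- mean(raw_codes, na.rm = TRUE)
  s <- stats::sd(raw_codes)
  if (!is.finite(s) || s == 0)
    stop("marker '", id, "' is monomorphic: cannot standardize")
  (raw_codes - mean(raw_codes)) / s
}

#' Genotype-frequency moments of the indicator variable
#'
#' Under Hardy-Weinberg equilibrium with allele frequency p for A1, the
#' \{+1, 0, -1\} indicator Z has genotype frequencies P = p^2, H = 2pq,
#' Q = q^2, mean p - q, and variance 2pq.  The classical (fixed-model) QTL
#' variance for a substitution effect alpha is 2pq alpha^2.
#'
#' @param p frequency of allele A1, in [0, 1].
#' @param alpha optional substitution effect; when supplied the classical
#'   QTL variance 2pq alpha^2 is included in the result.
#' @return named list: `mean` (p - q), `variance` (2pq), frequencies
#'   `P`, `H`, `Q`, and `qtl_variance` when `alpha` is given.
#' @examples
#' genotypeMoments(0.5)           # mean 0, variance 0.5
#' genotypeMoments(0.5, alpha = 1)$qtl_variance
#' @export
genotypeMoments <- function(p, alpha = NULL) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  q <- 1 - p
  out <- list(mean = p - q, variance = 2 * p * q,
              P = p^2, H = 2 * p * q, Q = q^2)
  if (!is.null(alpha)) out$qtl_variance <- 2 * p * q * alpha^2
  out
}

#' Marker-inferred kinship matrix
#'
#' Computes K from an n x m marker matrix: columns are standardized to mean
#' 0 / sample variance 1, K = M M' is formed from the standardized matrix,
#' and K is rescaled so that tr(K) = n.  Monomorphic columns are dropped
#' with a warning.
#'
#' @param marker_matrix numeric n x m matrix of genotype codes (rows =
#'   individuals); NAs mean-imputed per column.
#' @return a normalized [KinshipMatrix-class] with trace n.
#' @examples
#' set.seed(1)
#' M <- matrix(sample(c(-1, 0, 1), 40, replace = TRUE), nrow = 8)
#' K <- kinshipFromMarkers(M)
#' sum(diag(K))   # 8
#' @export
kinshipFromMarkers <- function(marker_matrix) {
  M <- as.matrix(marker_matrix)
  if (nrow(M) < 2L) stop("kinship needs at least 2 individuals")
  if (ncol(M) < 1L) stop("kinship needs at least 1 marker")
  keep <- logical(ncol(M))
  Z <- matrix(0, nrow(M), ncol(M))
  for (j in seq_len(ncol(M))) {
    x <- M[, j]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    s <- stats::sd(x)
    if (is.finite(s) && s > 0) {
      keep[j] <- TRUE
      Z[, j] <- (x - mean(x)) / s
    }
  }
  if (!any(keep)) stop("all markers are monomorphic")
  if (any(!keep))
    warning(sum(!keep), " monomorphic marker(s) dropped from kinship")
  Z <- Z[, keep, drop = FALSE]
  K <- tcrossprod(Z)
  K <- K * (nrow(M) / sum(diag(K)))
  kinshipMatrix(K, normalized = TRUE)
}

#' Normalize a kinship matrix to trace n
#'
#' Rescales a relationship matrix by n / tr(K) so that its trace equals the
#' sample size, the convention that puts the polygenic variance on the
#' residual-variance scale.
#'
#' @param K matrix or [KinshipMatrix-class].
#' @return a normalized [KinshipMatrix-class].
#' @export
normalizeKinship <- function(K) {
  K <- as.matrix(K)
  tr <- sum(diag(K))
  if (tr <= 0) stop("kinship trace must be positive")
  kinshipMatrix(K * (nrow(K) / tr), normalized = TRUE)
}

#' Full-sib numerator relationship matrix
#'
#' Block-diagonal additive relationship matrix for unrelated full-sib
#' families: within a family the additive relationship is 1/2, across
#' families 0, and the diagonal is 1 (no inbreeding), so the trace equals
#' the total sample size n_families * m_sibs.
#'
#' @param n_families number of families (>= 1).
#' @param m_sibs full siblings per family (>= 1).
#' @return a normalized [KinshipMatrix-class] of size
#'   (n_families * m_sibs)^2.
#' @examples
#' fullsibNumeratorMatrix(1, 2)   # matrix(c(1, .5, .5, 1), 2)
#' @export
fullsibNumeratorMatrix <- function(n_families, m_sibs) {
  stopifnot(n_families >= 1, m_sibs >= 1)
  block <- matrix(0.5, m_sibs, m_sibs)
  diag(block) <- 1
  n <- n_families * m_sibs
  A <- matrix(0, n, n)
  for (f in seq_len(n_families)) {
    idx <- ((f - 1) * m_sibs + 1):(f * m_sibs)
    A[idx, idx] <- block
  }
  kinshipMatrix(A, normalized = TRUE)
}
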