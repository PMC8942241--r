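#' Moment estimate of the QTL variance
#'
#' The squared fixed-model effect estimate minus its squared standard
#' error, sigma_alpha^2 = alpha_hat^2 - s^2.  Squaring an unbiased effect
#' estimate inflates the variance by the estimation error
#' (E[alpha_hat^2] = alpha^2 + s^2); subtracting s^2 removes that bias.
#' The untruncated form is unbiased; truncated at zero it coincides with
#' the REML estimate from the random-QTL model.
#'
#' @param alpha_hat fixed-model QTL effect estimate (standardized marker).
#' @param s_alpha its standard error (>= 0).
#' @param truncate if TRUE return max(alpha_hat^2 - s^2, 0).
#' @return numeric estimate (possibly negative when `truncate = FALSE`).
#' @examples
#' momentQTLVariance(0.5278, 0.1122)   # 0.2660
#' @export
momentQTLVariance <- function(alpha_hat, s_alpha, truncate = FALSE) {
  stopifnot(all(s_alpha >= 0))
  v <- alpha_hat^2 - s_alpha^2
  if (truncate) pmax(v, 0) else v
}

#' Naive squared-effect estimate of the QTL variance
#'
#' alpha_hat^2 on the standardized scale, or sigma_z2 * alpha_hat^2 when
#' the marker was not standardized (sigma_z2 = 2pq under Hardy-Weinberg).
#' Biased upward by the squared estimation error of alpha_hat.
#'
#' @param alpha_hat QTL effect estimate.
#' @param sigma_z2 variance of the genotype indicator (default 1,
#'   standardized coding).
#' @return numeric estimate.
#' @export
naiveQTLVariance <- function(alpha_hat, sigma_z2 = 1) {
  sigma_z2 * alpha_hat^2
}

#' QTL heritability from variance components
#'
#' Proportion of the phenotypic variance contributed by the locus,
#' sigma_QTL^2 / (sigma_QTL^2 + sigma_xi^2 + sigma^2).  A negative QTL
#' variance (possible for the untruncated moment estimate) is clipped at
#' zero before forming the ratio.
#'
#' @param sigma_qtl2 QTL variance estimate.
#' @param sigma_xi2 polygenic variance (0 if no polygene in the model).
#' @param sigma2 residual variance.
#' @return heritability in [0, 1].
#' @examples
#' qtlHeritability(0.2660, 3.5054, 0.3842)   # 0.06401
#' @export
qtlHeritability <- function(sigma_qtl2, sigma_xi2, sigma2) {
  sigma_qtl2 <- max(sigma_qtl2, 0)
  denom <- sigma_qtl2 + sigma_xi2 + sigma2
  if (!is.finite(denom) || denom <= 0)
    stop("total variance must be positive")
  sigma_qtl2 / denom
}

#' Delta-method standard error of the QTL heritability
#'
#' First-order Taylor propagation of the covariance of the REML variance
#' components to the ratio h2 = X/Y with X = sigma_alpha^2 (contrast
#' L_X = (1,0,0)) and Y = sigma_alpha^2 + sigma_xi^2 + sigma^2 (contrast
#' L_Y = (1,1,1)):
#'   var(h2) ~ (X/Y)^2 [ var(X)/X^2 - 2 cov(X,Y)/(XY) + var(Y)/Y^2 ].
#'
#' @param theta_hat length-3 vector (sigma_alpha^2, sigma_xi^2, sigma^2) or
#'   a [VarianceComponents-class].
#' @param theta_cov 3 x 3 symmetric covariance matrix of theta_hat.
#' @return the standard error sqrt(var(h2)).
#' @examples
#' C <- matrix(c(0.15520, 0.00036, -0.00020,
#'               0.00036, 0.28840, -0.02950,
#'              -0.00020, -0.02950, 0.00881), 3, 3)
#' deltaSEHeritability(c(0.2660, 3.5038, 0.3845), C)   # ~0.0891
#' @export
deltaSEHeritability <- function(theta_hat, theta_cov) {
  if (is(theta_hat, "VarianceComponents")) theta_hat <- thetaVector(theta_hat)
  theta_hat <- as.numeric(theta_hat)
  theta_cov <- as.matrix(theta_cov)
  stopifnot(length(theta_hat) == 3L, all(dim(theta_cov) == 3L))
  if (max(abs(theta_cov - t(theta_cov))) > 1e-8)
    stop("theta_cov must be symmetric")
  L_X <- c(1, 0, 0)
  L_Y <- c(1, 1, 1)
  X <- sum(L_X * theta_hat)
  Y <- sum(L_Y * theta_hat)
  if (Y <= 0) stop("total variance must be positive")
  vX <- drop(L_X %*% theta_cov %*% L_X)
  vY <- drop(L_Y %*% theta_cov %*% L_Y)
  cXY <- drop(L_X %*% theta_cov %*% L_Y)
  vh <- (X / Y)^2 * (vX / X^2 - 2 * cXY / (X * Y) + vY / Y^2)
  if (vh < 0)
    stop("negative delta-method variance: covariance input is not valid ",
         "at these component values")
  sqrt(vh)
}

#' Pseudo R-squared from a likelihood ratio statistic
#'
#' 1 - exp(-LRT/n), a likelihood-based goodness-of-fit proxy for the
#' proportion of variance explained by the QTL term.  It sits between the
#' corrected and the naive heritability on typical data.
#'
#' @param lrt likelihood ratio test statistic (>= 0).
#' @param n sample size (>= 1).
#' @return value in [0, 1).
#' @examples
#' pseudoR2(18.7, 278)   # 0.065054
#' @export
pseudoR2 <- function(lrt, n) {
  stopifnot(lrt >= 0, n >= 1)
  1 - exp(-lrt / n)
}

#' R-squared, adjusted R-squared and the corrected heritability
#'
#' For the single-marker regression y = mu + z alpha + e with standardized
#' z (no polygene), the regression and residual sums of squares are
#' (n-1) alpha_hat^2 and (n-2) sigma2_hat, giving
#'   R2     = (n-1) alpha_hat^2 / ((n-1) alpha_hat^2 + (n-2) sigma2_hat)
#'   R2_adj = 1 - (1 - R2)(n-1)/(n-2).
#' Because s^2 = sigma2_hat/(n-1) under this design, the moment-corrected
#' heritability (alpha_hat^2 - s^2) / (alpha_hat^2 - s^2 + sigma2_hat)
#' equals the adjusted R-squared identically, while R2 strictly exceeds it
#' whenever sigma2_hat > 0.
#'
#' @param alpha_hat OLS effect estimate of the standardized marker.
#' @param sigma2_hat residual variance estimate (n - 2 denominator).
#' @param n sample size (>= 3).
#' @return named list: `R2`, `adjusted_R2`, `corrected_h2`.
#' @export
r2Family <- function(alpha_hat, sigma2_hat, n) {
  if (n <= 2) stop("n must be at least 3")
  stopifnot(sigma2_hat >= 0)
  ssreg <- (n - 1) * alpha_hat^2
  ssres <- (n - 2) * sigma2_hat
  R2 <- ssreg / (ssreg + ssres)
  adj <- 1 - (1 - R2) * (n - 1) / (n - 2)
  s2 <- sigma2_hat / (n - 1)
  mm <- alpha_hat^2 - s2
  h2 <- mm / (mm + sigma2_hat)
  stopifnot(abs(adj - h2) <= 1e-12)
  if (sigma2_hat > 0) stopifnot(R2 > h2)
  list(R2 = R2, adjusted_R2 = adj, corrected_h2 = h2)
}

#' Multi-level (randomized fixed model) moment variance estimate
#'
#' Generalization of the moment estimator to a random effect with k levels
#' estimated as fixed coefficients: the variance is
#' (1/k) [ sum_k alpha_hat_k^2 - tr(var(alpha_hat | alpha)) ].  With k = 1
#' it reduces to [momentQTLVariance()].  Useful e.g. for the four epistatic
#' effect levels of a locus pair sharing one variance.
#'
#' @param alpha_hat numeric vector of k estimated levels.
#' @param alpha_cov k x k error covariance matrix of the estimates.
#' @return numeric variance estimate (untruncated).
#' @examples
#' momentVarianceMultilevel(0.5278, matrix(0.1122^2))   # 0.2660
#' @export
momentVarianceMultilevel <- function(alpha_hat, alpha_cov) {
  alpha_hat <- as.numeric(alpha_hat)
  alpha_cov <- as.matrix(alpha_cov)
  k <- length(alpha_hat)
  if (!all(dim(alpha_cov) == k))
    stop("alpha_cov must be ", k, " x ", k)
  if (max(abs(alpha_cov - t(alpha_cov))) > 1e-8)
    stop("alpha_cov must be symmetric")
  (sum(alpha_hat^2) - sum(diag(alpha_cov))) / k
}

#' LD-partitioned multi-locus QTL variances
#'
#' For k loci with effects alpha and genotype covariance matrix C (linkage
#' disequilibrium in the off-diagonals), the fixed-model variance
#' attributable to locus k is C_kk alpha_k^2 + sum_{k' != k} C_kk' alpha_k
#' alpha_k', and the per-locus terms sum to the total genetic variance
#' alpha' C alpha.  Per-locus terms can be negative under antagonistic LD
#' and are reported as-is.  Under the random-effect treatment with
#' standardized genotypes each locus contributes alpha_k^2 regardless of
#' LD, and the total is sum alpha_k^2.
#'
#' @param effects numeric vector of k locus effects.
#' @param z_cov k x k genotype covariance matrix (ignored for
#'   `model = "random"` beyond dimension checks).
#' @param model `"fixed"` or `"random"`.
#' @return named list: `per_locus` (length k) and `total`.
#' @export
ldPartitionedVariance <- function(effects, z_cov, model = c("fixed", "random")) {
  model <- match.arg(model)
  effects <- as.numeric(effects)
  z_cov <- as.matrix(z_cov)
  k <- length(effects)
  if (!all(dim(z_cov) == k)) stop("z_cov must be ", k, " x ", k)
  if (max(abs(z_cov - t(z_cov))) > 1e-8) stop("z_cov must be symmetric")
  if (model == "random") {
    per <- effects^2
    return(list(per_locus = per, total = sum(per)))
  }
  per <- vapply(seq_len(k), function(i) {
    z_cov[i, i] * effects[i]^2 +
      sum(z_cov[i, -i] * effects[i] * effects[-i])
  }, numeric(1))
  list(per_locus = per, total = drop(effects %*% z_cov %*% effects))
}
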