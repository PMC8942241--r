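## REML machinery for the QTL mixed models
##
## Fixed-QTL model:  y = X beta + z alpha + xi + e, alpha a fixed coefficient,
##                   V = A sigma_xi^2 + I sigma^2      (theta = 2 components)
## Random-QTL model: y = X beta + z alpha + xi + e, alpha ~ N(0, sigma_alpha^2),
##                   V = zz' sigma_alpha^2 + A sigma_xi^2 + I sigma^2
##
## The restricted log-likelihood (natural-log convention, no additive
## constant) is
##   L(theta) = -1/2 ln|V| - 1/2 ln|X'V^-1 X| - 1/2 (y - X bhat)' V^-1 (y - X bhat)
## with bhat the GLS estimate at theta.  The residual variance is profiled
## out analytically, so two-component fits reduce to a one-dimensional
## search over log(lambda_xi) on the spectrum of the kinship matrix and
## three-component fits to a two-dimensional Nelder-Mead over
## (log lambda_alpha, log lambda_xi) followed by coordinate refinement.
## Log-scale parameters guarantee positivity; zero boundaries are handled
## by an explicit refit with the component removed.

MAXIT <- 200L
RELTOL <- 1e-10

# resolve a marker argument to its standardized codes
markerZ <- function(marker) {
  if (is(marker, "GenotypeVector")) return(standardized(marker))
  z <- as.numeric(marker)
  if (length(z) >= 3 && abs(mean(z)) < 1e-8 && abs(stats::var(z) - 1) < 1e-8)
    return(z)
  standardizeGenotypes(z)
}

# fixed design: intercept + covariates (+ marker column when append_z)
buildDesign <- function(n, covariates = NULL, z = NULL) {
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    stopifnot(nrow(covariates) == n)
    X <- cbind(X, covariates)
  }
  if (!is.null(z)) X <- cbind(X, marker = z)
  if (qr(X)$rank < ncol(X))
    stop("fixed design is rank deficient (collinear columns)")
  X
}

checkKinship <- function(kinship, n) {
  if (is.null(kinship)) return(NULL)
  if (!is(kinship, "KinshipMatrix")) kinship <- kinshipMatrix(as.matrix(kinship))
  if (nrow(kinship) != n)
    stop("kinship dimension ", nrow(kinship), " does not match n = ", n)
  A <- kinship@.Data
  if (max(abs(A - diag(n))) < 1e-8)
    stop("kinship matrix is the identity: polygenic and residual variances ",
         "are not identifiable")
  A
}

# restricted log-likelihood at explicit theta, V = sum theta_i Vlist_i
remlLogLik <- function(y, X, Vlist, theta) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (i in seq_along(Vlist)) V <- V + theta[i] * Vlist[[i]]
  R <- chol(V)
  logdetV <- 2 * sum(log(diag(R)))
  Vi_y <- backsolve(R, backsolve(R, y, transpose = TRUE))
  Vi_X <- backsolve(R, backsolve(R, X, transpose = TRUE))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(Vi_X, y))
  r <- y - X %*% beta
  quad <- sum(r * backsolve(R, backsolve(R, r, transpose = TRUE)))
  -0.5 * (logdetV + determinant(XtViX, logarithm = TRUE)$modulus[1] + quad)
}

# diagonal-H fast path (two-component fits on the kinship spectrum)
profiledPiecesDiag <- function(y, X, w) {
  n <- length(y); p <- ncol(X)
  Xw <- X / w
  XtHiX <- crossprod(X, Xw)
  Xty <- crossprod(Xw, y)
  beta <- solve(XtHiX, Xty)
  rss <- sum(y^2 / w) - sum(Xty * beta)
  sigma2 <- max(rss / (n - p), .Machine$double.eps)
  ll <- -0.5 * ((n - p) * log(sigma2) + sum(log(w)) +
                determinant(XtHiX, logarithm = TRUE)$modulus[1] + (n - p))
  list(loglik = ll, sigma2 = sigma2, beta = drop(beta), XtHiX = XtHiX)
}

# profiled REML pieces for V = sigma2 * H: returns loglik, sigma2, beta, XtHiX
profiledPieces <- function(y, X, H) {
  n <- length(y); p <- ncol(X)
  R <- chol(H)
  logdetH <- 2 * sum(log(diag(R)))
  Hi_y <- backsolve(R, backsolve(R, y, transpose = TRUE))
  Hi_X <- backsolve(R, backsolve(R, X, transpose = TRUE))
  XtHiX <- crossprod(X, Hi_X)
  beta <- solve(XtHiX, crossprod(Hi_X, y))
  rss <- sum(y * Hi_y) - sum(crossprod(X, Hi_y) * beta)
  sigma2 <- max(rss / (n - p), .Machine$double.eps)
  ll <- -0.5 * ((n - p) * log(sigma2) + logdetH +
                determinant(XtHiX, logarithm = TRUE)$modulus[1] + (n - p))
  list(loglik = ll, sigma2 = sigma2, beta = drop(beta), XtHiX = XtHiX)
}

# expected (Fisher) information I_ij = 1/2 tr(P Vi P Vj) and its inverse
fisherCov <- function(y, X, Vlist, theta) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (i in seq_along(Vlist)) V <- V + theta[i] * Vlist[[i]]
  Vi <- chol2inv(chol(V))
  ViX <- Vi %*% X
  P <- Vi - ViX %*% solve(crossprod(X, ViX), t(ViX))
  k <- length(Vlist)
  PV <- lapply(Vlist, function(Vi_) P %*% Vi_)
  info <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    info[i, j] <- info[j, i] <- 0.5 * sum(PV[[i]] * t(PV[[j]]))
  }
  solve(info)
}

#' REML fit of the fixed-QTL mixed model
#'
#' Fits y = X beta + z alpha + xi + e with the standardized marker z
#' appended to the fixed design and, when a kinship matrix is supplied, a
#' polygenic component xi ~ N(0, A sigma_xi^2).  The polygenic and residual
#' variances are estimated by REML (one-dimensional search on the kinship
#' spectrum); alpha_hat is the GLS coefficient of z at the REML variance
#' estimates and s_alpha its standard error from (X'V^-1 X)^-1.  Without a
#' kinship matrix the fit reduces to ordinary least squares with the REML
#' (n - p denominator) residual variance.
#'
#' @param y numeric trait vector.
#' @param marker a [GenotypeVector-class] or numeric codes (standardized
#'   internally if needed).
#' @param covariates optional numeric matrix of fixed covariates (no
#'   intercept column; one is added).
#' @param kinship optional [KinshipMatrix-class] (or plain matrix).
#' @return a [FixedQTLFit-class].
#' @examples
#' sim <- simulateF2SingleMarker(n = 120, h2 = 0.2, seed = 1)
#' fit <- remlFitFixedQTL(sim$y, sim$genotype)
#' qtlEffect(fit)
#' @export
remlFitFixedQTL <- function(y, marker, covariates = NULL, kinship = NULL) {
  y <- as.numeric(y)
  z <- markerZ(marker)
  stopifnot(length(z) == length(y))
  X <- buildDesign(length(y), covariates, z)
  fit <- remlVarianceFit(y, X, checkKinship(kinship, length(y)))
  p <- ncol(X)
  alpha <- unname(fit$beta[p])
  s <- sqrt(fit$beta_cov[p, p])
  w <- waldTest(alpha, s)
  new("FixedQTLFit", beta_hat = fit$beta, alpha_hat = alpha, s_alpha = s,
      components = varianceComponents(sigma_xi2 = fit$sigma_xi2,
                                      sigma2 = fit$sigma2),
      restricted_loglik = fit$loglik, wald = w[["W"]],
      p_value = w[["p_value"]], iterations = fit$iterations,
      converged = fit$converged)
}

#' REML fit of the null model (no QTL term)
#'
#' Fits y = X beta + xi + e (or y = X beta + e without kinship); its
#' restricted log-likelihood is the reference for the likelihood ratio test
#' against the fixed-QTL fit.
#'
#' @inheritParams remlFitFixedQTL
#' @return list with `components` (a [VarianceComponents-class]) and
#'   `restricted_loglik`.
#' @export
remlFitNull <- function(y, covariates = NULL, kinship = NULL) {
  y <- as.numeric(y)
  X <- buildDesign(length(y), covariates)
  fit <- remlVarianceFit(y, X, checkKinship(kinship, length(y)))
  list(components = varianceComponents(sigma_xi2 = fit$sigma_xi2,
                                       sigma2 = fit$sigma2),
       restricted_loglik = fit$loglik, converged = fit$converged)
}

# shared engine: REML of V = A sigma_xi2 + I sigma2 (or I sigma2 alone)
remlVarianceFit <- function(y, X, A) {
  n <- length(y); p <- ncol(X)
  if (is.null(A)) {
    qrX <- qr(X)
    beta <- qr.coef(qrX, y)
    r <- y - X %*% beta
    sigma2 <- sum(r^2) / (n - p)
    XtX <- crossprod(X)
    ll <- -0.5 * ((n - p) * log(sigma2) +
                  determinant(XtX, logarithm = TRUE)$modulus[1] + (n - p))
    return(list(beta = beta, beta_cov = chol2inv(qr.R(qrX)) * sigma2,
                sigma_xi2 = NA_real_, sigma2 = sigma2, loglik = ll,
                iterations = 0L, converged = TRUE))
  }
  eg <- eigen(A, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, y)
  Xt <- crossprod(eg$vectors, X)
  nll <- function(loglam) {
    w <- 1 + exp(loglam) * d
    -profiledPiecesDiag(yt, Xt, w)$loglik
  }
  ## coarse grid then Brent: the profiled likelihood can be multimodal in
  ## pathological cases, and the grid also covers the lambda -> 0 boundary
  grid <- seq(-18, 12, by = 1.5)
  vals <- vapply(grid, nll, numeric(1))
  i0 <- which.min(vals)
  lo <- grid[max(1L, i0 - 1L)]; hi <- grid[min(length(grid), i0 + 1L)]
  opt <- stats::optimize(nll, c(lo, hi), tol = 1e-10)
  lam <- exp(opt$minimum)
  if (opt$minimum <= grid[1] + 1e-6) lam <- 0   # boundary: no polygenic signal
  w <- 1 + lam * d
  pieces <- profiledPiecesDiag(yt, Xt, w)
  sigma2 <- pieces$sigma2
  list(beta = stats::setNames(pieces$beta, colnames(X)),
       beta_cov = solve(pieces$XtHiX) * sigma2,
       sigma_xi2 = lam * sigma2, sigma2 = sigma2,
       loglik = pieces$loglik,
       iterations = length(grid) + 20L, converged = TRUE)
}

#' REML fit of the random-QTL model
#'
#' Fits the random model in which the QTL effect is a draw from
#' N(0, sigma_alpha^2), so the QTL variance is estimated directly as a
#' variance component: V = zz' sigma_alpha^2 + A sigma_xi^2 + I sigma^2
#' (the kinship term is dropped when `kinship` is NULL).  The fixed design
#' excludes the marker.  The residual variance is profiled analytically and
#' the remaining ratio(s) maximized on the log scale; a solution at the
#' sigma_alpha^2 = 0 boundary is detected by refitting without the QTL
#' component and comparing restricted likelihoods, and is reported with
#' `boundary = TRUE` and NA covariance entries for the pinned component.
#' The asymptotic covariance of theta_hat is the inverse expected (Fisher)
#' information 1/2 tr(P V_i P V_j) at the optimum.
#'
#' @inheritParams remlFitFixedQTL
#' @return a [RandomQTLFit-class]; `thetaCov()` is a 3 x 3 named matrix
#'   with NA rows for components not in the model or pinned at zero.
#' @examples
#' sim <- simulateF2SingleMarker(n = 120, h2 = 0.2, seed = 1)
#' fit <- remlFitRandomQTL(sim$y, sim$genotype)
#' thetaVector(varComponents(fit))
#' @export
remlFitRandomQTL <- function(y, marker, covariates = NULL, kinship = NULL) {
  y <- as.numeric(y)
  z <- markerZ(marker)
  stopifnot(length(z) == length(y))
  n <- length(y)
  X <- buildDesign(n, covariates)
  A <- checkKinship(kinship, n)
  Zt <- tcrossprod(z)

  labs <- c("sigma_alpha2", "sigma_xi2", "sigma2")
  cov3 <- matrix(NA_real_, 3, 3, dimnames = list(labs, labs))

  ## starting values from the fixed-model fit (moment estimate seeds lambda_alpha)
  fixed <- remlFitFixedQTL(y, z, covariates, kinship)
  fth <- thetaVector(varComponents(fixed))
  mm <- momentQTLVariance(qtlEffect(fixed), qtlEffectSE(fixed), truncate = TRUE)
  la0 <- log(max(mm / fth["sigma2"], 1e-3))

  if (is.null(A)) {
    nll <- function(loglam) {
      -profiledPieces(y, X, diag(n) + exp(loglam) * Zt)$loglik
    }
    grid <- c(la0, seq(-16, 8, by = 2))
    vals <- vapply(grid, nll, numeric(1))
    i0 <- which.min(vals)
    opt <- stats::optimize(nll, c(grid[i0] - 2, grid[i0] + 2), tol = 1e-10)
    la <- opt$minimum
    pieces <- profiledPieces(y, X, diag(n) + exp(la) * Zt)
    sigma2 <- pieces$sigma2
    sa2 <- exp(la) * sigma2
    null <- remlVarianceFit(y, X, NULL)
    boundary <- FALSE
    loglik <- pieces$loglik
    iter <- length(grid) + 20L
    if (sa2 < 1e-8 * sigma2 || null$loglik >= loglik - 1e-10) {
      boundary <- TRUE
      sa2 <- 0
      sigma2 <- null$sigma2
      loglik <- null$loglik
    }
    theta <- c(sa2, NA_real_, sigma2)
    if (!boundary) {
      cv <- fisherCov(y, X, list(Zt, diag(n)), c(sa2, sigma2))
      cov3[c(1, 3), c(1, 3)] <- cv
    } else {
      cv <- fisherCov(y, X, list(diag(n)), sigma2)
      cov3[3, 3] <- cv
    }
    return(new("RandomQTLFit",
               components = varianceComponents(theta[1], theta[2], theta[3]),
               theta_cov = cov3, restricted_loglik = loglik,
               boundary = boundary, iterations = iter, converged = TRUE))
  }

  nll <- function(par) {
    H <- diag(n) + exp(par[1]) * Zt + exp(par[2]) * A
    -profiledPieces(y, X, H)$loglik
  }
  lx0 <- log(max(fth["sigma_xi2"] / fth["sigma2"], 1e-3, na.rm = TRUE))
  opt <- stats::optim(c(la0, lx0), nll, method = "Nelder-Mead",
                      control = list(reltol = RELTOL, maxit = 500L))
  ## coordinate-wise 1-D refinement to tighten Nelder-Mead's loose optimum
  par <- opt$par
  for (pass in 1:3) {
    o1 <- stats::optimize(function(u) nll(c(u, par[2])),
                          c(par[1] - 1, par[1] + 1), tol = 1e-11)
    par[1] <- o1$minimum
    o2 <- stats::optimize(function(u) nll(c(par[1], u)),
                          c(par[2] - 1, par[2] + 1), tol = 1e-11)
    par[2] <- o2$minimum
  }
  H <- diag(n) + exp(par[1]) * Zt + exp(par[2]) * A
  pieces <- profiledPieces(y, X, H)
  sigma2 <- pieces$sigma2
  sa2 <- exp(par[1]) * sigma2
  sx2 <- exp(par[2]) * sigma2
  loglik <- pieces$loglik
  iter <- opt$counts[["function"]]
  converged <- opt$convergence == 0L

  ## boundary check at sigma_alpha^2 = 0: two-component refit without z
  null <- remlVarianceFit(y, X, A)
  boundary <- FALSE
  if (sa2 < 1e-8 * sigma2 || null$loglik >= loglik - 1e-10) {
    boundary <- TRUE
    sa2 <- 0
    sx2 <- null$sigma_xi2
    sigma2 <- null$sigma2
    loglik <- null$loglik
  }
  theta <- c(sa2, sx2, sigma2)
  if (!boundary) {
    cv <- fisherCov(y, X, list(Zt, A, diag(n)), theta)
    cov3[, ] <- cv
  } else {
    free <- c(2, 3)
    cv <- fisherCov(y, X, list(A, diag(n)), theta[free])
    cov3[free, free] <- cv
  }
  new("RandomQTLFit",
      components = varianceComponents(theta[1], theta[2], theta[3]),
      theta_cov = cov3, restricted_loglik = loglik, boundary = boundary,
      iterations = iter, converged = converged)
}

#' Wald test of a QTL effect
#'
#' W = (alpha_hat / s_alpha)^2 referred to chi-square with 1 df.
#'
#' @param alpha_hat effect estimate.
#' @param s_alpha its standard error (> 0).
#' @return named numeric c(W, p_value).
#' @examples
#' waldTest(0.5278, 0.1122)
#' @export
waldTest <- function(alpha_hat, s_alpha) {
  stopifnot(s_alpha > 0)
  W <- unname((alpha_hat / s_alpha)^2)
  c(W = W, p_value = stats::pchisq(W, df = 1, lower.tail = FALSE))
}

#' Bonferroni-corrected Wald threshold
#'
#' Chi-square(1) quantile at probability 1 - alpha / n_tests: the
#' genome-wide significance threshold for the Wald statistic after a
#' Bonferroni correction over the number of (real) markers tested.
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error rate, in (0, 1].
#' @return threshold on the Wald-statistic scale.
#' @examples
#' bonferroniWaldThreshold(193, 0.05)   # 13.34533
#' @export
bonferroniWaldThreshold <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1, alpha > 0, alpha <= 1)
  stats::qchisq(1 - alpha / n_tests, df = 1)
}

#' Likelihood ratio test statistic
#'
#' LRT = -2 (L0 - L1) for nested fits, floored at zero.  Both
#' log-likelihoods must come from the same (restricted) convention.
#'
#' @param loglik_null restricted log-likelihood of the null model.
#' @param loglik_alt restricted log-likelihood of the model with the QTL.
#' @return non-negative LRT value.
#' @examples
#' likelihoodRatioTest(-464.4, -455.05)   # 18.7
#' @export
likelihoodRatioTest <- function(loglik_null, loglik_alt) {
  if (loglik_alt < loglik_null - 1e-6)
    stop("alternative log-likelihood below the null: models are not nested ",
         "or a fit failed to converge")
  max(0, -2 * (loglik_null - loglik_alt))
}
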