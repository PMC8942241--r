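#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Genotype indicator variable for one locus
#'
#' Per-individual marker codes for a biallelic locus: the raw codes
#' (+1 for A1A1, 0 for A1A2, -1 for A2A2) together with the standardized
#' indicator z = (z0 - mean(z0)) / sd(z0) used in all model fits.  With the
#' standardized coding the QTL variance equals the squared substitution
#' effect, which is what makes the moment correction a pure function of the
#' effect estimate and its standard error.
#'
#' @slot raw integer vector of codes in \{+1, 0, -1\} (missing values are
#'   mean-imputed before standardization by the constructor).
#' @slot standardized numeric vector with sample mean 0 and sample
#'   variance 1 (n - 1 denominator).
#' @slot id character scalar, marker name.
#'
#' @seealso [genotypeVector()], [standardizeGenotypes()]
#' @exportClass GenotypeVector
setClass("GenotypeVector",
  representation(raw = "integer", standardized = "numeric", id = "character"))

setValidity("GenotypeVector", function(object) {
  msg <- character()
  if (!all(object@raw %in% c(-1L, 0L, 1L)))
    msg <- c(msg, "raw codes must be in {+1, 0, -1}")
  if (length(unique(object@raw)) < 2L)
    msg <- c(msg, sprintf("marker '%s' is monomorphic", object@id))
  if (length(object@raw) != length(object@standardized))
    msg <- c(msg, "raw and standardized lengths differ")
  z <- object@standardized
  if (length(z) >= 3L) {
    if (abs(mean(z)) > 1e-10)
      msg <- c(msg, "standardized codes must have mean 0")
    if (abs(stats::var(z) - 1) > 1e-10)
      msg <- c(msg, "standardized codes must have sample variance 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeVector
#'
#' Validates the raw codes, mean-imputes missing values (with a message),
#' and standardizes to mean 0 / sample variance 1.
#'
#' @param raw numeric or integer vector of codes in \{+1, 0, -1\}; NAs allowed.
#' @param id marker name used in error messages.
#' @return A [GenotypeVector-class] object.
#' @examples
#' g <- genotypeVector(c(1, 0, -1, 0, 1))
#' mean(standardized(g))   # 0
#' @export
genotypeVector <- function(raw, id = "marker") {
  if (anyNA(raw)) {
    message(sprintf("marker '%s': %d missing genotype(s) mean-imputed",
                    id, sum(is.na(raw))))
  }
  z <- standardizeGenotypes(raw, id = id)
  raw_filled <- raw
  raw_filled[is.na(raw_filled)] <- round(mean(raw, na.rm = TRUE))
  new("GenotypeVector", raw = as.integer(raw_filled), standardized = z,
      id = as.character(id))
}

#' @describeIn GenotypeVector-class standardized codes
#' @param object,x a `GenotypeVector`
#' @export
standardized <- function(x) {
  stopifnot(is(x, "GenotypeVector"))
  x@standardized
}

#' @describeIn GenotypeVector-class raw \{+1,0,-1\} codes
#' @export
rawCodes <- function(x) {
  stopifnot(is(x, "GenotypeVector"))
  x@raw
}

setMethod("length", "GenotypeVector", function(x) length(x@raw))

setMethod("show", "GenotypeVector", function(object) {
  tab <- table(factor(object@raw, levels = c(1L, 0L, -1L)))
  cat(sprintf("GenotypeVector '%s': n = %d (A1A1: %d, A1A2: %d, A2A2: %d)\n",
              object@id, length(object@raw), tab[["1"]], tab[["0"]],
              tab[["-1"]]))
})

#' Additive relationship (kinship) matrix
#'
#' An n x n symmetric positive-semidefinite matrix of additive genetic
#' relationships, either a pedigree numerator matrix A or a marker-inferred
#' kinship K.  When `normalized` is TRUE the trace equals the sample size,
#' the convention under which the polygenic variance component is on the
#' same scale as the residual variance.
#'
#' @slot .Data numeric matrix.
#' @slot normalized logical flag; TRUE asserts tr(K) = n.
#' @seealso [kinshipFromMarkers()], [fullsibNumeratorMatrix()]
#' @exportClass KinshipMatrix
setClass("KinshipMatrix", contains = "matrix",
  representation(normalized = "logical"))

setValidity("KinshipMatrix", function(object) {
  K <- object@.Data
  msg <- character()
  if (nrow(K) != ncol(K)) return("kinship matrix must be square")
  if (max(abs(K - t(K))) > 1e-10)
    msg <- c(msg, "kinship matrix must be symmetric")
  if (nrow(K) <= 1000) {   # full spectrum is cheap at fitting-scale n
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev)))
      msg <- c(msg, "kinship matrix must be positive semidefinite")
  }
  if (isTRUE(object@normalized) &&
      abs(sum(diag(K)) - nrow(K)) > 1e-8)
    msg <- c(msg, "normalized kinship must have trace equal to n")
  if (length(msg)) msg else TRUE
})

kinshipMatrix <- function(values, normalized = FALSE) {
  values <- as.matrix(values)
  values <- (values + t(values)) / 2
  new("KinshipMatrix", values, normalized = normalized)
}

setMethod("show", "KinshipMatrix", function(object) {
  cat(sprintf("KinshipMatrix: %d x %d, trace = %.4f%s\n",
              nrow(object), ncol(object), sum(diag(object@.Data)),
              if (isTRUE(object@normalized)) " (normalized)" else ""))
})

#' Is a kinship matrix trace-normalized?
#' @param x a [KinshipMatrix-class]
#' @return logical
#' @export
isNormalized <- function(x) {
  stopifnot(is(x, "KinshipMatrix"))
  isTRUE(x@normalized)
}

#' Variance components of the QTL mixed model
#'
#' The parameter vector theta = (sigma_alpha^2, sigma_xi^2, sigma^2): QTL
#' variance, polygenic variance and residual variance.  Fixed-QTL fits carry
#' no sigma_alpha^2 (NA); models without a polygene carry no sigma_xi^2 (NA).
#' Ratio forms lambda_alpha = sigma_alpha^2 / sigma^2 and
#' lambda_xi = sigma_xi^2 / sigma^2 are available through [lambdaRatios()].
#'
#' @slot sigma_alpha2 QTL variance (NA when the QTL effect is fixed).
#' @slot sigma_xi2 polygenic variance (NA when no kinship term is fitted).
#' @slot sigma2 residual variance, > 0.
#' @exportClass VarianceComponents
setClass("VarianceComponents",
  representation(sigma_alpha2 = "numeric", sigma_xi2 = "numeric",
                 sigma2 = "numeric"))

setValidity("VarianceComponents", function(object) {
  msg <- character()
  for (s in c("sigma_alpha2", "sigma_xi2")) {
    v <- slot(object, s)
    if (!is.na(v) && v < 0) msg <- c(msg, paste(s, "must be >= 0"))
  }
  if (is.na(object@sigma2) || object@sigma2 <= 0)
    msg <- c(msg, "sigma2 must be > 0")
  if (length(msg)) msg else TRUE
})

varianceComponents <- function(sigma_alpha2 = NA_real_, sigma_xi2 = NA_real_,
                               sigma2) {
  new("VarianceComponents", sigma_alpha2 = as.numeric(sigma_alpha2),
      sigma_xi2 = as.numeric(sigma_xi2), sigma2 = as.numeric(sigma2))
}

#' @describeIn VarianceComponents-class named vector
#'   c(sigma_alpha2, sigma_xi2, sigma2)
#' @param x a `VarianceComponents`
#' @export
thetaVector <- function(x) {
  stopifnot(is(x, "VarianceComponents"))
  c(sigma_alpha2 = x@sigma_alpha2, sigma_xi2 = x@sigma_xi2,
    sigma2 = x@sigma2)
}

#' @describeIn VarianceComponents-class variance ratios
#'   lambda_alpha = sigma_alpha^2/sigma^2 and lambda_xi = sigma_xi^2/sigma^2
#' @export
lambdaRatios <- function(x) {
  stopifnot(is(x, "VarianceComponents"))
  c(lambda_alpha = x@sigma_alpha2 / x@sigma2,
    lambda_xi = x@sigma_xi2 / x@sigma2)
}

setMethod("show", "VarianceComponents", function(object) {
  v <- thetaVector(object)
  cat("VarianceComponents:\n")
  print(round(v, 6))
})

#' Fixed-QTL mixed-model fit
#'
#' Result of fitting y = X beta + z alpha + xi + e with the QTL effect alpha
#' as a fixed coefficient (the standardized marker appended to the fixed
#' design) and REML estimation of the polygenic and residual variances.
#' Carries the moment estimate of the QTL variance alpha_hat^2 - s^2 and the
#' corrected / naive heritabilities derived from it.
#'
#' @slot beta_hat named numeric, GLS fixed-effect estimates (last = alpha).
#' @slot alpha_hat QTL effect estimate.
#' @slot s_alpha its standard error sqrt(var(alpha_hat | alpha)).
#' @slot components [VarianceComponents-class] (sigma_xi^2, sigma^2 only).
#' @slot restricted_loglik restricted log-likelihood at the optimum.
#' @slot wald Wald statistic (alpha_hat / s_alpha)^2.
#' @slot p_value chi-square(1) upper-tail p.
#' @slot iterations optimizer evaluation count.
#' @slot converged logical.
#' @exportClass FixedQTLFit
setClass("FixedQTLFit",
  representation(beta_hat = "numeric", alpha_hat = "numeric",
                 s_alpha = "numeric", components = "VarianceComponents",
                 restricted_loglik = "numeric", wald = "numeric",
                 p_value = "numeric", iterations = "numeric",
                 converged = "logical"))

setValidity("FixedQTLFit", function(object) {
  msg <- character()
  if (object@s_alpha <= 0) msg <- c(msg, "s_alpha must be > 0")
  if (abs(object@wald - (object@alpha_hat / object@s_alpha)^2) > 1e-10)
    msg <- c(msg, "wald must equal (alpha_hat/s_alpha)^2")
  if (length(msg)) msg else TRUE
})

#' Random-QTL mixed-model fit
#'
#' Result of the random-model REML fit with variance
#' V = zz' sigma_alpha^2 + A sigma_xi^2 + I sigma^2: the QTL effect is a
#' random draw from N(0, sigma_alpha^2) and its variance is estimated
#' directly as a component, which is what removes the squared-effect bias.
#'
#' @slot components [VarianceComponents-class], full theta.
#' @slot theta_cov asymptotic covariance of theta_hat (inverse Fisher
#'   information); rows/cols of components pinned at the zero boundary are NA.
#' @slot restricted_loglik restricted log-likelihood at the optimum.
#' @slot boundary logical, TRUE when sigma_alpha^2 was pinned at 0.
#' @slot iterations optimizer evaluation count.
#' @slot converged logical.
#' @exportClass RandomQTLFit
setClass("RandomQTLFit",
  representation(components = "VarianceComponents",
                 theta_cov = "matrix", restricted_loglik = "numeric",
                 boundary = "logical", iterations = "numeric",
                 converged = "logical"))

setValidity("RandomQTLFit", function(object) {
  C <- object@theta_cov
  msg <- character()
  ok <- is.finite(C)
  if (any(abs(C[ok & t(ok)] - t(C)[ok & t(ok)]) > 1e-8))
    msg <- c(msg, "theta_cov must be symmetric")
  d <- diag(C)
  if (any(d[is.finite(d)] < 0))
    msg <- c(msg, "theta_cov diagonal must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn FixedQTLFit-class variance components of a fit
#' @param object,fit a fit object
#' @export
setGeneric("varComponents", function(object) standardGeneric("varComponents"))
setMethod("varComponents", "FixedQTLFit", function(object) object@components)
setMethod("varComponents", "RandomQTLFit", function(object) object@components)

#' @describeIn FixedQTLFit-class restricted log-likelihood of a fit
#' @export
setGeneric("restrictedLogLik",
           function(object) standardGeneric("restrictedLogLik"))
setMethod("restrictedLogLik", "FixedQTLFit",
          function(object) object@restricted_loglik)
setMethod("restrictedLogLik", "RandomQTLFit",
          function(object) object@restricted_loglik)

#' @describeIn FixedQTLFit-class QTL effect estimate alpha_hat
#' @export
qtlEffect <- function(fit) {
  stopifnot(is(fit, "FixedQTLFit"))
  fit@alpha_hat
}

#' @describeIn FixedQTLFit-class standard error of alpha_hat
#' @export
qtlEffectSE <- function(fit) {
  stopifnot(is(fit, "FixedQTLFit"))
  fit@s_alpha
}

#' @describeIn RandomQTLFit-class asymptotic covariance of theta_hat
#' @export
thetaCov <- function(fit) {
  stopifnot(is(fit, "RandomQTLFit"))
  fit@theta_cov
}

setMethod("show", "FixedQTLFit", function(object) {
  cat("Fixed-QTL mixed-model fit (REML)\n")
  cat(sprintf("  alpha_hat = %.4f (s = %.4f), W = %.4f, p = %.4g\n",
              object@alpha_hat, object@s_alpha, object@wald, object@p_value))
  th <- thetaVector(object@components)
  cat(sprintf("  sigma_xi2 = %s, sigma2 = %.4f\n",
              if (is.na(th[2])) "--" else sprintf("%.4f", th[2]), th[3]))
  cat(sprintf("  moment sigma_QTL2 = %.4f, restricted logL = %.4f\n",
              momentQTLVariance(object@alpha_hat, object@s_alpha),
              object@restricted_loglik))
})

setMethod("show", "RandomQTLFit", function(object) {
  cat("Random-QTL mixed-model fit (REML)\n")
  th <- thetaVector(object@components)
  se <- sqrt(diag(object@theta_cov))
  lab <- c("sigma_alpha2", "sigma_xi2", "sigma2")
  for (i in seq_along(th)) {
    if (is.na(th[i])) next
    cat(sprintf("  %-12s = %.4f (SE %s)\n", lab[i], th[i],
                if (is.finite(se[i])) sprintf("%.4f", se[i]) else "--"))
  }
  if (object@boundary) cat("  sigma_alpha2 pinned at the zero boundary\n")
  cat(sprintf("  restricted logL = %.4f\n", object@restricted_loglik))
})
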