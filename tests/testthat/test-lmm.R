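test_that("fixed fit without kinship reduces to closed-form OLS", {
  set.seed(21)
  sim <- simulateF2SingleMarker(n = 60, h2 = 0.15)
  z <- standardized(sim$genotype)
  fit <- remlFitFixedQTL(sim$y, sim$genotype)
  ora <- olsOracle(sim$y, cbind(1, z))
  expect_equal(qtlEffect(fit), unname(ora$beta[2]), tolerance = 1e-10)
  expect_equal(qtlEffectSE(fit), unname(ora$se[2]), tolerance = 1e-10)
  expect_equal(thetaVector(varComponents(fit))[["sigma2"]], ora$sigma2,
               tolerance = 1e-10)
  # with standardized z, s^2 = sigma2_hat / (n - 1)
  expect_equal(qtlEffectSE(fit)^2, ora$sigma2 / 59, tolerance = 1e-10)
})

test_that("covariates enter the fixed design and collinearity errors", {
  set.seed(22)
  sim <- simulateF2SingleMarker(n = 80, h2 = 0.1)
  sex <- rep(c(1, 0), 40)
  fit <- remlFitFixedQTL(sim$y, sim$genotype, covariates = cbind(sex = sex))
  ora <- olsOracle(sim$y, cbind(1, sex, standardized(sim$genotype)))
  expect_equal(qtlEffect(fit), unname(ora$beta[3]), tolerance = 1e-10)
  expect_error(
    remlFitFixedQTL(sim$y, sim$genotype,
                    covariates = cbind(a = sex, b = 2 * sex)),
    "rank deficient")
  expect_error(
    remlFitFixedQTL(sim$y, sim$genotype,
                    covariates = cbind(standardized(sim$genotype))),
    "rank deficient")
})

test_that("two-component REML recovers simulated full-sib variances", {
  set.seed(23)
  reps <- 200
  est <- t(replicate(reps, {
    sim <- simulateFullsibPolygenic(50, 5, h2 = 0.1)
    fit <- remlFitFixedQTL(sim$y, sim$genotype, kinship = sim$kinship)
    thetaVector(varComponents(fit))[c("sigma_xi2", "sigma2")]
  }))
  for (j in 1:2) {
    mc_se <- sd(est[, j]) / sqrt(reps)
    expect_lt(abs(mean(est[, j]) - 10), 3 * mc_se)
  }
})

test_that("null fit nests under the alternative and LRT behaves", {
  set.seed(24)
  sim <- simulateFullsibPolygenic(10, 5, h2 = 0.15)
  fit <- remlFitFixedQTL(sim$y, sim$genotype, kinship = sim$kinship)
  null <- remlFitNull(sim$y, kinship = sim$kinship)
  expect_lte(null$restricted_loglik, restrictedLogLik(fit) + 1e-6)
  lrt <- likelihoodRatioTest(null$restricted_loglik, restrictedLogLik(fit))
  expect_gte(lrt, 0)
  expect_equal(likelihoodRatioTest(-464.4, -455.05), 18.7, tolerance = 1e-10)
  expect_equal(likelihoodRatioTest(-10, -10), 0)
  expect_error(likelihoodRatioTest(-5, -10), "nested")
  # OLS limit: residual variance of pure noise about its sample variance
  y <- rnorm(100)
  n0 <- remlFitNull(y)
  expect_equal(thetaVector(n0$components)[["sigma2"]], var(y),
               tolerance = 1e-10)
})

test_that("Wald test and Bonferroni threshold match independent references", {
  expect_equal(waldTest(0, 0.2), c(W = 0, p_value = 1))
  w <- waldTest(0.5278, 0.1122)
  expect_equal(w[["W"]], (0.5278 / 0.1122)^2, tolerance = 1e-12)
  expect_equal(bonferroniWaldThreshold(1, 1), 0)
  expect_equal(bonferroniWaldThreshold(193, 0.05), 13.34533,
               tolerance = 1e-6)
  # independent root-find of the chi-square CDF
  root <- uniroot(function(x) pchisq(x, 1) - 0.95, c(0, 50),
                  tol = 1e-12)$root
  expect_equal(bonferroniWaldThreshold(1, 0.05), root, tolerance = 1e-8)
})

test_that("random-model REML equals the truncated moment estimate without a polygene", {
  set.seed(25)
  agree <- replicate(30, {
    sim <- simulateF2SingleMarker(n = 50, h2 = 0.1)
    f <- remlFitFixedQTL(sim$y, sim$genotype)
    r <- remlFitRandomQTL(sim$y, sim$genotype)
    mm <- momentQTLVariance(qtlEffect(f), qtlEffectSE(f), truncate = TRUE)
    abs(mm - thetaVector(varComponents(r))[["sigma_alpha2"]])
  })
  expect_gte(mean(agree <= 1e-4), 0.95)
})

test_that("random-model optimum satisfies the moment stationarity identity", {
  # at the random fit's own (sigma_xi2, sigma2) the REML QTL variance is
  # exactly the untruncated moment value of the GLS effect estimate
  set.seed(26)
  sim <- simulateFullsibPolygenic(10, 5, h2 = 0.15)
  r <- remlFitRandomQTL(sim$y, sim$genotype, kinship = sim$kinship)
  th <- thetaVector(varComponents(r))
  expect_false(r@boundary)
  V2 <- plainMatrix(sim$kinship) * th[["sigma_xi2"]] + diag(50) * th[["sigma2"]]
  X <- cbind(1, standardized(sim$genotype))
  Vi <- solve(V2)
  XtViX <- crossprod(X, Vi %*% X)
  b <- solve(XtViX, crossprod(X, Vi %*% sim$y))
  s2 <- solve(XtViX)[2, 2]
  expect_equal(th[["sigma_alpha2"]], drop(b[2]^2 - s2), tolerance = 1e-4)
})

test_that("restricted likelihood is a local maximum at the REML solution", {
  set.seed(27)
  sim <- simulateFullsibPolygenic(10, 5, h2 = 0.2)
  r <- remlFitRandomQTL(sim$y, sim$genotype, kinship = sim$kinship)
  th <- thetaVector(varComponents(r))
  X <- matrix(1, 50, 1)
  Vl <- list(tcrossprod(standardized(sim$genotype)),
             plainMatrix(sim$kinship), diag(50))
  L0 <- qtlvar:::remlLogLik(sim$y, X, Vl, th)
  expect_equal(L0, restrictedLogLik(r), tolerance = 1e-8)
  for (i in 1:3) for (d in c(-1e-3, 1e-3)) {
    tp <- th
    tp[i] <- tp[i] * (1 + d)
    if (any(tp < 0)) next
    expect_lte(qtlvar:::remlLogLik(sim$y, X, Vl, tp), L0 + 1e-10)
  }
})

test_that("Fisher covariance agrees with a finite-difference Hessian", {
  set.seed(28)
  sim <- simulateFullsibPolygenic(10, 5, h2 = 0.2)
  r <- remlFitRandomQTL(sim$y, sim$genotype, kinship = sim$kinship)
  expect_false(r@boundary)
  th <- thetaVector(varComponents(r))
  X <- matrix(1, 50, 1)
  Vl <- list(tcrossprod(standardized(sim$genotype)),
             plainMatrix(sim$kinship), diag(50))
  H <- fdHessian(function(t) qtlvar:::remlLogLik(sim$y, X, Vl, t), th,
                 eps = 1e-3)
  obs_cov <- solve(-H)
  C <- thetaCov(r)
  # expected vs observed information: agree within 5% relative on the scale
  # of the largest entry
  expect_lt(max(abs(C - obs_cov)) / max(abs(obs_cov)), 0.05)
  expect_equal(C, t(C), tolerance = 1e-8)
  expect_true(all(diag(C) >= 0))
})

test_that("boundary solutions pin the QTL variance at zero with NA covariance", {
  set.seed(31)
  found <- FALSE
  for (i in 1:20) {
    sim <- simulateF2SingleMarker(n = 40, h2 = 0)
    r <- remlFitRandomQTL(sim$y, sim$genotype)
    if (r@boundary) {
      found <- TRUE
      expect_identical(thetaVector(varComponents(r))[["sigma_alpha2"]], 0)
      expect_true(all(is.na(thetaCov(r)[1, ])))
      break
    }
  }
  expect_true(found)
})

test_that("identity kinship is flagged as non-identifiable", {
  set.seed(32)
  sim <- simulateF2SingleMarker(n = 30, h2 = 0.1)
  A <- fullsibNumeratorMatrix(30, 1)   # singleton families: A = I
  expect_error(remlFitFixedQTL(sim$y, sim$genotype, kinship = A),
               "identifiable")
})
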