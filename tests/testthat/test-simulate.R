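test_that("effect grid follows alpha^2 = (background) h2 / (1 - h2)", {
  grid <- vapply(c(0.05, 0.10, 0.15, 0.20),
                 function(h) effectFromHeritability(h, 10, 10)$alpha2,
                 numeric(1))
  expect_equal(grid, c(1.0526, 2.2222, 3.5294, 5.0000), tolerance = 1e-4)
  expect_equal(effectFromHeritability(0, 10, 10)$alpha2, 0)
  expect_equal(effectFromHeritability(0.1, 0, 20)$alpha2, 20 / 9,
               tolerance = 1e-12)
  expect_error(effectFromHeritability(1, 10, 10), "below 1")
})

test_that("simulations are reproducible under a fixed seed", {
  a <- simulateF2SingleMarker(50, 0.1, seed = 99)
  b <- simulateF2SingleMarker(50, 0.1, seed = 99)
  expect_identical(rawCodes(a$genotype), rawCodes(b$genotype))
  expect_equal(a$y, b$y, tolerance = 1e-12)
  c1 <- simulateFullsibPolygenic(6, 4, 0.1, seed = 100)
  c2 <- simulateFullsibPolygenic(6, 4, 0.1, seed = 100)
  expect_identical(rawCodes(c1$genotype), rawCodes(c2$genotype))
  expect_equal(c1$y, c2$y, tolerance = 1e-12)
})

test_that("F2 generator hits the target heritability at large n", {
  sim <- simulateF2SingleMarker(1e5, 0.1, seed = 5)
  z <- standardized(sim$genotype)
  sample_h2 <- var(z * sim$alpha) / var(sim$y)
  expect_lt(abs(sample_h2 - 0.1), 0.01)
  # genotype frequencies near 1:2:1
  tab <- table(rawCodes(sim$genotype)) / 1e5
  expect_equal(unname(tab[c("-1", "0", "1")]), c(0.25, 0.5, 0.25),
               tolerance = 0.01, ignore_attr = TRUE)
})

test_that("null-heritability F2 data show no marker-trait correlation", {
  set.seed(51)
  cors <- replicate(500, {
    sim <- simulateF2SingleMarker(30, 0)
    cor(sim$y, standardized(sim$genotype))
  })
  expect_lt(abs(mean(cors)), 3 * sd(cors) / sqrt(500))
})

test_that("full-sib generator induces within-family covariance sigma_xi2 / 2", {
  sim <- simulateFullsibPolygenic(2000, 2, h2 = 0, sigma_xi2 = 10,
                                  sigma2 = 10, seed = 52)
  y1 <- sim$y[seq(1, 4000, by = 2)]
  y2 <- sim$y[seq(2, 4000, by = 2)]
  cv <- cov(y1, y2)
  # empirical covariance of sib pairs ~ sigma_xi2 / 2 = 5
  mc_se <- sqrt(var(y1 * y2) / 2000)
  expect_lt(abs(cv - 5), 3 * mc_se)
  expect_equal(dim(sim$kinship), c(4000L, 4000L))
})

test_that("degenerate full-sib design matches the F2 marginal moments", {
  # sigma_xi2 = 0: same marginal variance structure as the single-marker
  # generator
  sim <- simulateFullsibPolygenic(200, 5, h2 = 0.1, sigma_xi2 = 0,
                                  sigma2 = 20, mu = 10, seed = 53)
  expect_equal(sim$alpha2, effectFromHeritability(0.1, 0, 20)$alpha2)
  expect_lt(abs(var(sim$y) - (sim$alpha2 + 20)) / (sim$alpha2 + 20), 0.15)
  s2 <- simulateFullsibPolygenic(10, 5, 0.1, seed = 54)
  expect_length(s2$y, 50)
  expect_equal(sum(diag(s2$kinship)), 50)
})

test_that("bias experiment reproduces the squared-method inflation at h2 = 0", {
  d <- simulationDesign("f2_single_marker", n = 50, h2_grid = 0,
                        n_replicates = 200, seed = 55)
  e <- runBiasExperiment(d)
  s <- e$summary
  # naive = moment + s^2 per replicate, so the null-mean naive estimate is
  # about the mean squared standard error (> 0)
  expect_equal(s$mean_naive - s$mean_moment, s$mean_s2, tolerance = 1e-10)
  expect_gt(s$mean_naive, 0)
  mc_se <- s$mc_se_moment
  expect_lt(abs(s$mean_moment), 3 * mc_se)
  expect_true(all(e$replicates$moment_trunc >= 0))
  expect_equal(nrow(e$replicates), 200)
})

test_that("naive bias shrinks with sample size", {
  d25 <- simulationDesign("f2_single_marker", n = 25, h2_grid = 0.1,
                          n_replicates = 500, seed = 56)
  d250 <- simulationDesign("f2_single_marker", n = 250, h2_grid = 0.1,
                           n_replicates = 500, seed = 57)
  b25 <- runBiasExperiment(d25)$summary
  b250 <- runBiasExperiment(d250)$summary
  bias25 <- b25$mean_naive - b25$alpha2_true
  bias250 <- b250$mean_naive - b250$alpha2_true
  expect_gt(bias25, bias250)
  expect_gt(bias25, 0)
  expect_gt(bias250, 0)
})

test_that("equivalence experiment pairs are non-negative and flagged", {
  d <- simulationDesign("fullsib_polygenic", n_families = 10, m_sibs = 5,
                        h2_grid = 0.15, n_replicates = 30, seed = 58)
  eq <- runEquivalenceExperiment(d)
  expect_true(all(eq$pairs$moment_trunc >= 0))
  expect_true(all(eq$pairs$reml >= 0))
  expect_true(is.finite(eq$agreement$fraction_agree))
  expect_equal(nrow(eq$pairs), 30)
})

test_that("experiment tables round-trip to TSV", {
  d <- simulationDesign("f2_single_marker", n = 30, h2_grid = c(0, 0.2),
                        n_replicates = 5, seed = 59)
  e <- runBiasExperiment(d)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeExperimentTSV(e, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 10)
  expect_equal(back$moment, e$replicates$moment, tolerance = 1e-6)
})
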