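test_that("pseudo-marker expected codes match the enumeration oracle", {
  for (gL in c(-1, 0, 1)) for (gR in c(-1, 0, 1)) {
    expect_equal(qtlvar:::expectedF2Code(gL, gR, 5, 5),
                 f2CodeOracle(gL, gR, 5, 5), tolerance = 1e-12)
    expect_equal(qtlvar:::expectedF2Code(gL, gR, 3, 12),
                 f2CodeOracle(gL, gR, 3, 12), tolerance = 1e-12)
  }
  # zero distance to the left flank: expected code equals the observed code
  for (g in c(-1, 0, 1))
    expect_equal(qtlvar:::expectedF2Code(g, 0, 1e-9, 10), g,
                 tolerance = 1e-6)
  # midpoint between two +1 flanks stays below +1 (hidden heterozygotes)
  mid <- qtlvar:::expectedF2Code(1, 1, 5, 5)
  expect_true(mid > 0 && mid < 1)
})

test_that("pseudo-marker insertion follows the cM grid", {
  set.seed(71)
  n <- 30
  geno <- replicate(3, sample(c(1, 0, -1), n, replace = TRUE,
                              prob = c(0.25, 0.5, 0.25)))
  colnames(geno) <- c("mA", "mB", "mC")
  map <- data.frame(marker = colnames(geno), chromosome = 1,
                    position = c(0, 10, 25))
  aug <- imputePseudoMarkers(geno, map, step_cM = 5)
  # 10 cM interval at step 5 -> 1 insertion; 15 cM -> 2 insertions
  expect_equal(sum(aug$map$is_pseudo), 3)
  expect_equal(nrow(aug$map), 6)
  expect_equal(ncol(aug$geno), 6)
  expect_equal(aug$map$position,
               sort(c(0, 10, 25, 5, 15, 20)))
  # real markers pass through untouched
  expect_equal(aug$geno[, "mB"], geno[, "mB"])
  # pseudo codes bounded by the code range
  pseudo <- aug$geno[, aug$map$is_pseudo]
  expect_true(all(pseudo >= -1 & pseudo <= 1))
})

test_that("single-marker chromosomes get no insertions, with a warning", {
  geno <- cbind(mA = c(1, 0, -1, 0, 1, -1))
  map <- data.frame(marker = "mA", chromosome = 3, position = 12)
  expect_warning(aug <- imputePseudoMarkers(geno, map, 5), "single marker")
  expect_equal(nrow(aug$map), 1)
  expect_false(aug$map$is_pseudo)
})

test_that("interval-mapping scan localizes a simulated causal marker", {
  set.seed(72)
  hits <- replicate(50, {
    tabs <- simulatePanel(n = 200, m = 20, causal = 7, h2 = 0.3)
    rows <- genomeScan(tabs, model = "fixed", method = "interval")
    which.max(rows$wald) == 7
  })
  expect_gte(mean(hits), 0.9)
})

test_that("scan rows carry coherent statistics and attributes", {
  set.seed(73)
  tabs <- simulatePanel(n = 120, m = 8, causal = 3, h2 = 0.25)
  rows <- genomeScan(tabs, model = "random", method = "interval",
                     pseudo_step = 5)
  # 8 markers 10 cM apart -> 7 intervals x 1 pseudo marker each
  expect_equal(nrow(rows), 8 + 7)
  expect_equal(attr(rows, "n_real_markers"), 8)
  expect_equal(attr(rows, "threshold"), bonferroniWaldThreshold(8, 0.05))
  ok <- rows[rows$converged, ]
  expect_true(all(ok$wald >= 0))
  expect_true(all(ok$sigma_qtl2_moment >= 0))
  expect_true(all(ok$h2_corrected >= 0 & ok$h2_corrected <= 1))
  # naive heritability dominates the corrected one at every position
  expect_true(all(ok$h2_naive >= ok$h2_corrected - 1e-10))
  # random-model variance present
  expect_true(any(is.finite(ok$sigma_alpha2_reml)))
})

test_that("polygenic mapping shrinks the Wald profile on average", {
  set.seed(74)
  nfam <- 30; m <- 4
  sim <- simulateFullsibPolygenic(nfam, m, h2 = 0.15, sigma_xi2 = 10,
                                  sigma2 = 10)
  n <- nfam * m
  panel <- replicate(10, sample(c(1, 0, -1), n, replace = TRUE,
                                prob = c(0.25, 0.5, 0.25)))
  panel[, 4] <- rawCodes(sim$genotype)
  colnames(panel) <- paste0("m", 1:10)
  tabs <- list(trait = sim$y, covariates = NULL, genotypes = panel,
               kinship = sim$kinship,
               map = data.frame(marker = colnames(panel), chromosome = 1,
                                position = 10 * (1:10)))
  rows_im <- genomeScan(tabs, model = "fixed", method = "interval")
  rows_pg <- genomeScan(tabs, model = "fixed", method = "polygenic")
  expect_gte(mean(rows_im$wald, na.rm = TRUE),
             mean(rows_pg$wald, na.rm = TRUE))
})

test_that("scan summary reports Bonferroni calls and relative bias", {
  # arithmetic on the heritability pairs reported for the mouse peaks
  rows <- data.frame(marker = c("c2peak", "c18peak"), chromosome = c(2, 18),
                     position = c(50, 30), is_pseudo = TRUE,
                     alpha_hat = c(1, 1), s_alpha = c(0.3, 0.4),
                     wald = c(17.72, 9.73), p_value = c(2.6e-5, 1.8e-3),
                     sigma_qtl2_moment = c(1, 1),
                     sigma_alpha2_reml = NA_real_,
                     h2_corrected = c(0.1333, 0.1153),
                     h2_naive = c(0.1401, 0.1271), converged = TRUE)
  rep_ <- summarizeScan(rows, n_real_markers = 193, alpha = 0.05)
  expect_equal(rep_$threshold, 13.34533, tolerance = 1e-5)
  expect_equal(rep_$rows$significant, c(TRUE, FALSE))
  expect_equal(rep_$rows$relative_bias, c(0.0514, 0.1021), tolerance = 1e-2)
  expect_equal(rep_$peak$marker, "c2peak")
  # zero bias when the two heritabilities coincide
  rows$h2_naive <- rows$h2_corrected
  expect_equal(summarizeScan(rows, 193)$rows$relative_bias, c(0, 0))
})
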