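#' QTL effect implied by a heritability
#'
#' Solves h2 = alpha^2 / (alpha^2 + sigma_xi^2 + sigma^2) for the squared
#' effect: alpha^2 = (sigma_xi^2 + sigma^2) * h2 / (1 - h2).  With the
#' background variance fixed at 20 (the replicated-experiment setting),
#' h2 = 0.05, 0.10, 0.15, 0.20 give alpha^2 = 1.0526, 2.2222, 3.5294, 5.
#'
#' @param h2 QTL heritability in [0, 1).
#' @param sigma_xi2 polygenic variance (0 for the single-marker design).
#' @param sigma2 residual variance.
#' @return named list: `alpha2` and its positive root `alpha`.
#' @examples
#' effectFromHeritability(0.05, 10, 10)$alpha2   # 1.0526
#' @export
effectFromHeritability <- function(h2, sigma_xi2 = 0, sigma2) {
  stopifnot(h2 >= 0, sigma_xi2 >= 0, sigma2 >= 0)
  if (h2 >= 1) stop("h2 must be below 1")
  a2 <- (sigma_xi2 + sigma2) * h2 / (1 - h2)
  list(alpha2 = a2, alpha = sqrt(a2))
}

# draw {+1,0,-1} F2 codes (1:2:1), redrawing monomorphic samples
drawF2Codes <- function(n, max_attempts = 100L) {
  for (i in seq_len(max_attempts)) {
    raw <- sample(c(1L, 0L, -1L), n, replace = TRUE,
                  prob = c(0.25, 0.5, 0.25))
    if (length(unique(raw)) >= 2L) {
      if (i > 1L) message("monomorphic draw redrawn (", i - 1L, "x)")
      return(raw)
    }
  }
  stop("could not draw a polymorphic marker in ", max_attempts, " attempts")
}

#' Simulate an F2 population with a single QTL
#'
#' Genotypes are drawn from the 1:2:1 F2 segregation with codes
#' \{+1, 0, -1\}, standardized per replicate with sample moments, and the
#' trait is y = mu + z alpha + e with e ~ N(0, sigma^2) and
#' alpha^2 = sigma^2 h2 / (1 - h2) (no polygenic background).
#'
#' @param n sample size (>= 3).
#' @param h2 true QTL heritability in [0, 1).
#' @param mu population mean (default 10).
#' @param sigma2 residual variance (default 20).
#' @param seed optional integer seed; NULL draws from the current stream.
#' @return list: `y`, `genotype` ([GenotypeVector-class]), `alpha` (true
#'   effect), `alpha2`, `h2`.
#' @examples
#' sim <- simulateF2SingleMarker(100, 0.1, seed = 7)
#' var(sim$y)
#' @export
simulateF2SingleMarker <- function(n, h2, mu = 10, sigma2 = 20, seed = NULL) {
  stopifnot(n >= 3)
  if (!is.null(seed)) set.seed(seed)
  alpha <- effectFromHeritability(h2, 0, sigma2)$alpha
  g <- genotypeVector(drawF2Codes(n), id = "simQTL")
  y <- mu + standardized(g) * alpha + stats::rnorm(n, 0, sqrt(sigma2))
  list(y = y, genotype = g, alpha = alpha, alpha2 = alpha^2, h2 = h2)
}

#' Simulate full-sib families with a QTL and a polygenic background
#'
#' Families of m full siblings share an additive relationship of 1/2
#' ([fullsibNumeratorMatrix()]).  The polygenic value of individual j in
#' family f is xi_fj = u_f + w_fj with u_f ~ N(0, sigma_xi^2/2) shared
#' within the family and w_fj ~ N(0, sigma_xi^2/2) individual, so
#' var(xi) = sigma_xi^2 and cov within family = sigma_xi^2/2 = A_jk
#' sigma_xi^2.  QTL genotypes segregate 1:2:1 independently per individual
#' and the trait is y = mu + z alpha + xi + e with
#' alpha^2 = (sigma_xi^2 + sigma^2) h2 / (1 - h2).
#'
#' @param n_families number of families.
#' @param m_sibs siblings per family (n = n_families * m_sibs >= 3).
#' @param h2 true QTL heritability in [0, 1).
#' @param sigma_xi2 polygenic variance (default 10).
#' @param sigma2 residual variance (default 10).
#' @param mu population mean (default 0).
#' @param seed optional integer seed.
#' @return list: `y`, `genotype`, `kinship` ([KinshipMatrix-class]),
#'   `alpha`, `alpha2`, `h2`.
#' @examples
#' sim <- simulateFullsibPolygenic(10, 5, 0.1, seed = 7)
#' sum(diag(sim$kinship))   # 50
#' @export
simulateFullsibPolygenic <- function(n_families, m_sibs, h2, sigma_xi2 = 10,
                                     sigma2 = 10, mu = 0, seed = NULL) {
  n <- n_families * m_sibs
  stopifnot(n >= 3)
  if (!is.null(seed)) set.seed(seed)
  alpha <- effectFromHeritability(h2, sigma_xi2, sigma2)$alpha
  A <- fullsibNumeratorMatrix(n_families, m_sibs)
  g <- genotypeVector(drawF2Codes(n), id = "simQTL")
  u <- rep(stats::rnorm(n_families, 0, sqrt(sigma_xi2 / 2)), each = m_sibs)
  w <- stats::rnorm(n, 0, sqrt(sigma_xi2 / 2))
  y <- mu + standardized(g) * alpha + u + w +
    stats::rnorm(n, 0, sqrt(sigma2))
  list(y = y, genotype = g, kinship = A, alpha = alpha, alpha2 = alpha^2,
       h2 = h2)
}

#' Design of a replicated bias/equivalence experiment
#'
#' @param population `"f2_single_marker"` or `"fullsib_polygenic"`.
#' @param n sample size (f2 design); ignored for full-sib.
#' @param n_families,m_sibs full-sib design dimensions.
#' @param h2_grid vector of true heritabilities in [0, 1).
#' @param mu population mean (default 10 for f2, 0 for full-sib).
#' @param sigma_xi2 polygenic variance (full-sib design).
#' @param sigma2 residual variance.
#' @param n_replicates replicates per grid point.
#' @param seed integer seed for the whole experiment.
#' @return list of class `"SimulationDesign"`.
#' @export
simulationDesign <- function(population = c("f2_single_marker",
                                            "fullsib_polygenic"),
                             n = 100, n_families = 10, m_sibs = 5,
                             h2_grid = c(0.05, 0.10, 0.15, 0.20),
                             mu = NULL, sigma_xi2 = 10, sigma2 = NULL,
                             n_replicates = 500, seed = 1) {
  population <- match.arg(population)
  if (is.null(sigma2))
    sigma2 <- if (population == "f2_single_marker") 20 else 10
  if (is.null(mu))
    mu <- if (population == "f2_single_marker") 10 else 0
  stopifnot(all(h2_grid >= 0), all(h2_grid < 1), sigma2 >= 0,
            n_replicates >= 1)
  structure(list(population = population, n = n, n_families = n_families,
                 m_sibs = m_sibs, h2_grid = h2_grid, mu = mu,
                 sigma_xi2 = if (population == "fullsib_polygenic")
                   sigma_xi2 else 0,
                 sigma2 = sigma2, n_replicates = n_replicates, seed = seed),
            class = "SimulationDesign")
}

# one replicate: simulate, fit fixed + random models, return one row
replicateRow <- function(design, h2) {
  if (design$population == "f2_single_marker") {
    sim <- simulateF2SingleMarker(design$n, h2, design$mu, design$sigma2)
    kin <- NULL
  } else {
    sim <- simulateFullsibPolygenic(design$n_families, design$m_sibs, h2,
                                    design$sigma_xi2, design$sigma2,
                                    design$mu)
    kin <- sim$kinship
  }
  row <- data.frame(h2_true = h2, alpha2_true = sim$alpha2,
                    naive = NA_real_, moment = NA_real_,
                    moment_trunc = NA_real_, reml = NA_real_,
                    s2 = NA_real_, sigma2_hat = NA_real_,
                    sigma_xi2_hat = NA_real_,
                    reml_boundary = NA, converged = FALSE)
  fit <- try(remlFitFixedQTL(sim$y, sim$genotype, kinship = kin),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(row)
  rfit <- try(remlFitRandomQTL(sim$y, sim$genotype, kinship = kin),
              silent = TRUE)
  if (inherits(rfit, "try-error")) return(row)
  a <- qtlEffect(fit); s <- qtlEffectSE(fit)
  th <- thetaVector(varComponents(fit))
  row$naive <- naiveQTLVariance(a)
  row$moment <- momentQTLVariance(a, s)
  row$moment_trunc <- momentQTLVariance(a, s, truncate = TRUE)
  row$reml <- thetaVector(varComponents(rfit))[["sigma_alpha2"]]
  row$s2 <- s^2
  row$sigma2_hat <- th[["sigma2"]]
  row$sigma_xi2_hat <- th[["sigma_xi2"]]
  row$reml_boundary <- rfit@boundary
  row$converged <- fit@converged && rfit@converged
  row
}

#' Replicated bias experiment for the QTL variance estimators
#'
#' For each heritability on the design grid, simulates `n_replicates`
#' populations and estimates the QTL variance by the naive squared-effect
#' method, the moment method (with and without zero truncation) and the
#' random-model REML.  Non-converged replicates are flagged and excluded
#' from the aggregated means.  Aggregated heritabilities follow the
#' average-then-ratio convention: the mean variance estimate over
#' replicates is divided by (mean variance + background variances).
#'
#' @param design a `simulationDesign()` object.
#' @return list of class `"BiasExperiment"`: `replicates` (one row per
#'   replicate x grid point), `summary` (one row per grid point with mean
#'   estimates, Monte-Carlo standard errors and aggregated heritabilities),
#'   `design`.
#' @export
runBiasExperiment <- function(design) {
  stopifnot(inherits(design, "SimulationDesign"))
  set.seed(design$seed)
  rows <- do.call(rbind, lapply(design$h2_grid, function(h2) {
    reps <- do.call(rbind, lapply(seq_len(design$n_replicates),
                                  function(r) replicateRow(design, h2)))
    reps$replicate <- seq_len(design$n_replicates)
    reps
  }))
  agg <- do.call(rbind, lapply(split(rows, rows$h2_true), function(d) {
    ok <- d[d$converged, , drop = FALSE]
    bg <- design$sigma_xi2 + design$sigma2
    msd <- function(x) stats::sd(x) / sqrt(length(x))
    data.frame(h2_true = d$h2_true[1], alpha2_true = d$alpha2_true[1],
               n_used = nrow(ok), n_failed = nrow(d) - nrow(ok),
               mean_naive = mean(ok$naive), mean_moment = mean(ok$moment),
               mean_moment_trunc = mean(ok$moment_trunc),
               mean_reml = mean(ok$reml), mean_s2 = mean(ok$s2),
               mc_se_naive = msd(ok$naive), mc_se_moment = msd(ok$moment),
               mc_se_reml = msd(ok$reml),
               h2_naive = mean(ok$naive) / (mean(ok$naive) + bg),
               h2_moment = max(mean(ok$moment), 0) /
                 (max(mean(ok$moment), 0) + bg),
               h2_reml = mean(ok$reml) / (mean(ok$reml) + bg))
  }))
  rownames(agg) <- NULL
  structure(list(replicates = rows, summary = agg, design = design),
            class = "BiasExperiment")
}

#' Fixed-vs-random model equivalence experiment
#'
#' Replicated full-sib simulations comparing the zero-truncated moment
#' estimate (fixed model) with the REML estimate (random model) of the QTL
#' variance.  The two coincide except for occasional local-convergence
#' deviations of the three-component REML fit.
#'
#' @param design a `simulationDesign()` with `population =
#'   "fullsib_polygenic"`.
#' @param tol agreement tolerance on the variance scale (default 1e-4).
#' @return list of class `"EquivalenceExperiment"`: `pairs` (per-replicate
#'   truncated-moment and REML estimates with boundary flags),
#'   `agreement` (per grid point, fraction of pairs within `tol`),
#'   `design`.
#' @export
runEquivalenceExperiment <- function(design, tol = 1e-4) {
  stopifnot(inherits(design, "SimulationDesign"),
            design$population == "fullsib_polygenic")
  exp <- runBiasExperiment(design)
  pairs <- exp$replicates[, c("h2_true", "replicate", "moment_trunc",
                              "reml", "reml_boundary", "converged")]
  pairs$agree <- abs(pairs$moment_trunc - pairs$reml) <= tol
  ok <- pairs[pairs$converged, , drop = FALSE]
  agreement <- do.call(rbind, lapply(split(ok, ok$h2_true), function(d) {
    data.frame(h2_true = d$h2_true[1], n = nrow(d),
               fraction_agree = mean(d$agree))
  }))
  rownames(agreement) <- NULL
  structure(list(pairs = pairs, agreement = agreement, design = design),
            class = "EquivalenceExperiment")
}

#' @export
print.BiasExperiment <- function(x, ...) {
  cat("Replicated QTL-variance bias experiment (",
      x$design$population, ")\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}

#' @export
print.EquivalenceExperiment <- function(x, ...) {
  cat("Fixed (truncated moment) vs random (REML) equivalence\n")
  print(x$agreement, digits = 4)
  invisible(x)
}

#' Write experiment replicates to TSV
#' @param experiment a `BiasExperiment` or `EquivalenceExperiment`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeExperimentTSV <- function(experiment, path) {
  tab <- if (inherits(experiment, "EquivalenceExperiment"))
    experiment$pairs else experiment$replicates
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
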