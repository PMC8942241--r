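## Genome-scan driver: per-marker fixed/random QTL fits, interval or
## polygenic mapping, pseudo-marker insertion, Bonferroni Wald threshold.

# Haldane map function: cM distance -> recombination fraction
haldaneR <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

# gamete transition probability between adjacent loci (alleles 0/1)
gameteT <- function(a, b, r) ifelse(a == b, 1 - r, r)

# conditional expectation of the {+1,0,-1} code at a position between two
# flanking F2 markers, given the flanking genotypes.  The F2 individual is
# two independent gametes, each a two-state Markov chain along the
# chromosome with Haldane recombination fractions; phase is summed out by
# enumerating ordered haplotype pairs consistent with the observed
# (unordered) flanking genotypes.  NA flanks are marginalized.
expectedF2Code <- function(gL, gR, dL_cM, dR_cM) {
  rL <- haldaneR(dL_cM)
  rR <- haldaneR(dR_cM)
  cntL <- if (is.na(gL)) NA_integer_ else as.integer(gL + 1)  # A1 count
  cntR <- if (is.na(gR)) NA_integer_ else as.integer(gR + 1)
  pQ <- numeric(3)  # P(A1 count at Q = 0,1,2 | flanks)
  for (a1 in 0:1) for (q1 in 0:1) for (b1 in 0:1) {
    p1 <- 0.5 * gameteT(a1, q1, rL) * gameteT(q1, b1, rR)
    for (a2 in 0:1) for (q2 in 0:1) for (b2 in 0:1) {
      if (!is.na(cntL) && a1 + a2 != cntL) next
      if (!is.na(cntR) && b1 + b2 != cntR) next
      p2 <- 0.5 * gameteT(a2, q2, rL) * gameteT(q2, b2, rR)
      pQ[q1 + q2 + 1] <- pQ[q1 + q2 + 1] + p1 * p2
    }
  }
  pQ <- pQ / sum(pQ)
  pQ[3] - pQ[1]   # E[Z] = P(+1) - P(-1)
}

#' Insert pseudo markers on a cM grid
#'
#' Adds pseudo-marker positions every `step_cM` inside each marker
#' interval and fills their genotype values with the conditional
#' expectation of the \{+1, 0, -1\} F2 code given the flanking observed
#' genotypes under a Haldane map (Haley-Knott expected codes).  Real
#' markers pass through unchanged.  Chromosomes with a single marker get
#' no insertions (with a warning).
#'
#' @param geno n x m numeric matrix of raw \{+1, 0, -1\} codes, columns
#'   named as in `map$marker`.
#' @param map data.frame with columns `marker`, `chromosome`, `position`
#'   (cM), sorted within chromosome.
#' @param step_cM grid step in centimorgans (default 5).
#' @return list: `geno` (n x (m + inserted) matrix of codes, pseudo columns
#'   fractional), `map` (augmented, with `is_pseudo` flag, sorted by
#'   chromosome then position).
#' @export
imputePseudoMarkers <- function(geno, map, step_cM = 5) {
  geno <- as.matrix(geno)
  stopifnot(ncol(geno) == nrow(map), step_cM > 0)
  if (is.null(colnames(geno))) colnames(geno) <- map$marker
  map <- map[order(map$chromosome, map$position), , drop = FALSE]
  out_cols <- list(); out_map <- list()
  for (chr in unique(map$chromosome)) {
    cm <- map[map$chromosome == chr, , drop = FALSE]
    if (nrow(cm) < 2L) {
      warning("chromosome ", chr, " has a single marker: no insertions")
      out_cols[[length(out_cols) + 1L]] <-
        geno[, cm$marker, drop = FALSE]
      cm$is_pseudo <- FALSE
      out_map[[length(out_map) + 1L]] <- cm
      next
    }
    for (i in seq_len(nrow(cm) - 1L)) {
      mL <- cm[i, ]; mR <- cm[i + 1L, ]
      out_cols[[length(out_cols) + 1L]] <-
        geno[, mL$marker, drop = FALSE]
      out_map[[length(out_map) + 1L]] <-
        cbind(mL, is_pseudo = FALSE)
      pos <- seq(mL$position + step_cM, mR$position - 1e-9, by = step_cM)
      for (p in pos) {
        gL <- geno[, mL$marker]; gR <- geno[, mR$marker]
        key <- paste(gL, gR)
        vals <- vapply(unique(key), function(k) {
          pair <- strsplit(k, " ")[[1]]
          expectedF2Code(suppressWarnings(as.numeric(pair[1])),
                         suppressWarnings(as.numeric(pair[2])),
                         p - mL$position, mR$position - p)
        }, numeric(1))
        col <- matrix(vals[key], ncol = 1)
        nm <- sprintf("%s_c%s_%gcM", "pseudo", chr, p)
        colnames(col) <- nm
        out_cols[[length(out_cols) + 1L]] <- col
        out_map[[length(out_map) + 1L]] <-
          data.frame(marker = nm, chromosome = chr, position = p,
                     is_pseudo = TRUE)
      }
    }
    last <- cm[nrow(cm), ]
    out_cols[[length(out_cols) + 1L]] <- geno[, last$marker, drop = FALSE]
    out_map[[length(out_map) + 1L]] <- cbind(last, is_pseudo = FALSE)
  }
  keep <- c("marker", "chromosome", "position", "is_pseudo")
  map_out <- do.call(rbind, lapply(out_map, function(d) d[, keep]))
  rownames(map_out) <- NULL
  list(geno = do.call(cbind, out_cols), map = map_out)
}

#' Genome scan for QTL variance and heritability
#'
#' Scans every marker position with a single-locus mixed model.  Under
#' `model = "fixed"` the standardized marker enters the fixed design and
#' the QTL variance is the zero-truncated moment estimate; under
#' `model = "random"` the marker is an additional variance component
#' estimated by REML, with the Wald test taken from the companion fixed
#' fit.  `method = "interval"` omits the polygenic term;
#' `method = "polygenic"` includes xi ~ N(0, A sigma_xi^2) with the
#' supplied kinship.  The Bonferroni Wald threshold is computed over real
#' markers only (pseudo markers are tested but not counted).
#'
#' @param tables list as returned by [readQTLTables()]: `trait`,
#'   `covariates`, `genotypes` (list of [GenotypeVector-class] or an
#'   n x m code matrix), `kinship`, `map`.
#' @param model `"fixed"` or `"random"`.
#' @param method `"interval"` (no polygene) or `"polygenic"` (kinship
#'   required).
#' @param pseudo_step optional cM step: insert Haley-Knott pseudo markers
#'   before scanning (requires `tables$map`).
#' @param alpha family-wise error rate for the threshold (default 0.05).
#' @return data.frame with one row per scanned position: `marker`,
#'   `chromosome`, `position`, `is_pseudo`, `alpha_hat`, `s_alpha`, `wald`,
#'   `p_value`, `sigma_qtl2_moment`, `sigma_alpha2_reml`, `h2_corrected`,
#'   `h2_naive`, `converged`; attributes `threshold` and `n_real_markers`.
#' @export
genomeScan <- function(tables, model = c("fixed", "random"),
                       method = c("interval", "polygenic"),
                       pseudo_step = NULL, alpha = 0.05) {
  model <- match.arg(model)
  method <- match.arg(method)
  y <- tables$trait
  covariates <- tables$covariates
  kinship <- if (method == "polygenic") {
    if (is.null(tables$kinship))
      stop("polygenic mapping requires a kinship matrix")
    tables$kinship
  } else NULL

  geno <- tables$genotypes
  if (is.list(geno) && !is.matrix(geno))
    geno <- vapply(geno, rawCodes, numeric(length(y)))
  geno <- as.matrix(geno)
  map <- tables$map
  if (is.null(map)) {
    map <- data.frame(marker = colnames(geno),
                      chromosome = 1L,
                      position = seq_len(ncol(geno)))
  }
  if (!is.null(pseudo_step)) {
    aug <- imputePseudoMarkers(geno, map, pseudo_step)
    geno <- aug$geno
    map <- aug$map
  }
  if (is.null(map$is_pseudo)) map$is_pseudo <- FALSE
  n_real <- sum(!map$is_pseudo)

  rows <- lapply(seq_len(nrow(map)), function(i) {
    row <- data.frame(marker = map$marker[i],
                      chromosome = map$chromosome[i],
                      position = map$position[i],
                      is_pseudo = map$is_pseudo[i],
                      alpha_hat = NA_real_, s_alpha = NA_real_,
                      wald = NA_real_, p_value = NA_real_,
                      sigma_qtl2_moment = NA_real_,
                      sigma_alpha2_reml = NA_real_,
                      h2_corrected = NA_real_, h2_naive = NA_real_,
                      converged = FALSE)
    res <- try({
      zraw <- geno[, map$marker[i]]
      fit <- remlFitFixedQTL(y, standardizeGenotypes(zraw, map$marker[i]),
                             covariates, kinship)
      th <- thetaVector(varComponents(fit))
      bg <- sum(th[c("sigma_xi2", "sigma2")], na.rm = TRUE)
      a <- qtlEffect(fit); s <- qtlEffectSE(fit)
      row$alpha_hat <- a
      row$s_alpha <- s
      row$wald <- fit@wald
      row$p_value <- fit@p_value
      mm <- momentQTLVariance(a, s, truncate = TRUE)
      row$sigma_qtl2_moment <- mm
      row$h2_naive <- qtlHeritability(naiveQTLVariance(a),
                                      sum(th["sigma_xi2"], na.rm = TRUE),
                                      th[["sigma2"]])
      if (model == "random") {
        rfit <- remlFitRandomQTL(y, standardizeGenotypes(zraw),
                                 covariates, kinship)
        rth <- thetaVector(varComponents(rfit))
        row$sigma_alpha2_reml <- rth[["sigma_alpha2"]]
        row$h2_corrected <- qtlHeritability(
          rth[["sigma_alpha2"]], sum(rth["sigma_xi2"], na.rm = TRUE),
          rth[["sigma2"]])
      } else {
        row$h2_corrected <- qtlHeritability(
          mm, sum(th["sigma_xi2"], na.rm = TRUE), th[["sigma2"]])
      }
      row$converged <- TRUE
      row
    }, silent = TRUE)
    if (inherits(res, "try-error")) row else res
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- bonferroniWaldThreshold(n_real, alpha)
  attr(out, "n_real_markers") <- n_real
  out
}

#' Summarize a genome scan
#'
#' Flags positions exceeding the Bonferroni Wald threshold and reports the
#' per-position relative bias of the naive squared-effect heritability
#' against the corrected heritability,
#' (h2_naive - h2_corrected) / h2_corrected.
#'
#' @param rows data.frame from [genomeScan()].
#' @param n_real_markers Bonferroni denominator (default: the scan's
#'   `n_real_markers` attribute).
#' @param alpha family-wise error rate (default 0.05).
#' @return list: `threshold`, `rows` (augmented with `significant` and
#'   `relative_bias`), `significant` (subset), `peak` (row with maximum
#'   Wald statistic).
#' @export
summarizeScan <- function(rows, n_real_markers = attr(rows, "n_real_markers"),
                          alpha = 0.05) {
  stopifnot(nrow(rows) > 0, !is.null(n_real_markers))
  thr <- bonferroniWaldThreshold(n_real_markers, alpha)
  rows$significant <- !is.na(rows$wald) & rows$wald > thr
  rows$relative_bias <- ifelse(
    is.na(rows$h2_corrected) | rows$h2_corrected <= 0, NA_real_,
    (rows$h2_naive - rows$h2_corrected) / rows$h2_corrected)
  peak <- rows[which.max(rows$wald), , drop = FALSE]
  list(threshold = thr, rows = rows,
       significant = rows[rows$significant, , drop = FALSE], peak = peak)
}
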