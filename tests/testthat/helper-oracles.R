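# Independent oracles, deliberately coded from first principles and kept
# apart from the package's own computation paths.

# closed-form OLS: coefficients, residual variance (n - p denominator, the
# REML convention) and coefficient standard errors via explicit normal
# equations
olsOracle <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX) %*% t(X) %*% y
  r <- y - X %*% beta
  sigma2 <- sum(r^2) / (length(y) - ncol(X))
  list(beta = drop(beta), sigma2 = sigma2,
       se = sqrt(diag(solve(XtX)) * sigma2))
}

# hand-rolled marker kinship: per-column (x - mean)/sd, tcrossprod,
# rescale to trace n
kinshipOracle <- function(M) {
  Z <- apply(M, 2, function(x) (x - mean(x)) / sd(x))
  K <- Z %*% t(Z)
  K * nrow(M) / sum(diag(K))
}

# central finite-difference gradient propagation for the heritability
# ratio h(theta) = theta1 / (theta1 + theta2 + theta3)
deltaOracle <- function(theta, C, eps = 1e-6) {
  h <- function(t) t[1] / sum(t)
  g <- vapply(1:3, function(i) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + eps
    tm[i] <- tm[i] - eps
    (h(tp) - h(tm)) / (2 * eps)
  }, numeric(1))
  sqrt(drop(t(g) %*% C %*% g))
}

# finite-difference Hessian of a scalar function
fdHessian <- function(f, x, eps = 1e-4) {
  k <- length(x)
  H <- matrix(0, k, k)
  for (i in 1:k) for (j in i:k) {
    ei <- ej <- rep(0, k)
    ei[i] <- eps; ej[j] <- eps
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
      (4 * eps^2)
  }
  H
}

# enumeration oracle for the expected F2 code at a position flanked by two
# observed genotypes: iterates over the 3 hidden genotypes using F2
# genotype-to-genotype transition probabilities derived from per-gamete
# Haldane recombination (coded independently of the package's ordered
# haplotype-pair enumeration)
f2CodeOracle <- function(gL, gR, dL, dR) {
  r2f <- function(d) (1 - exp(-2 * d / 100)) / 2
  # genotype transition matrix between two loci at recombination r:
  # rows/cols indexed by A1-allele count 0,1,2; each of the two gametes
  # transmits its allele with switch probability r
  tg <- function(r) {
    g1 <- matrix(c(1 - r, r, r, 1 - r), 2, 2)  # P(allele_to | allele_from)
    Tm <- matrix(0, 3, 3)
    for (c1 in 0:2) for (c2 in 0:2) {
      # unordered genotype c1 -> ordered gamete-allele pairs
      pr <- 0
      for (a in 0:1) for (b in 0:1) {
        if (a + b != c1) next
        w <- if (c1 == 1) 0.5 else 1
        for (ap in 0:1) for (bp in 0:1) {
          if (ap + bp != c2) next
          pr <- pr + w * g1[ap + 1, a + 1] * g1[bp + 1, b + 1]
        }
      }
      Tm[c1 + 1, c2 + 1] <- pr
    }
    Tm
  }
  TL <- tg(r2f(dL))
  TR <- tg(r2f(dR))
  prior <- c(0.25, 0.5, 0.25)
  cl <- gL + 1; cr <- gR + 1   # codes -1/0/1 -> counts 0/1/2
  pq <- numeric(3)
  for (q in 0:2) {
    pq[q + 1] <- prior[cl + 1] * TL[cl + 1, q + 1] * TR[q + 1, cr + 1]
  }
  pq <- pq / sum(pq)
  pq[3] - pq[1]
}

# simulate a small multi-marker F2 panel of unlinked loci with one causal
# marker; returns tables in the genomeScan() input layout
simulatePanel <- function(n, m, causal, h2, sigma2 = 20) {
  geno <- replicate(m, sample(c(1, 0, -1), n, replace = TRUE,
                              prob = c(0.25, 0.5, 0.25)))
  while (any(apply(geno, 2, function(g) length(unique(g)) < 2))) {
    geno <- replicate(m, sample(c(1, 0, -1), n, replace = TRUE,
                                prob = c(0.25, 0.5, 0.25)))
  }
  colnames(geno) <- paste0("m", seq_len(m))
  alpha <- sqrt(sigma2 * h2 / (1 - h2))
  z <- scale(geno[, causal])
  y <- 10 + drop(z) * alpha + rnorm(n, 0, sqrt(sigma2))
  list(trait = y, covariates = NULL, genotypes = geno, kinship = NULL,
       map = data.frame(marker = colnames(geno), chromosome = 1,
                        position = seq_len(m) * 10))
}

# strip the S4 wrapper off a KinshipMatrix for plain-matrix comparisons
plainMatrix <- function(K) K@.Data
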