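# Independent oracles used across the suite.

# Brute-force prospective simulator: draw genotypes from HWE, assign case
# status by Bernoulli(penetrance).  Used as the distributional oracle for
# the retrospective sampler.
prospective_sample <- function(pen, maf1, maf2, n) {
  f1 <- edgesnp::hwe_genotype_freqs(maf1)
  f2 <- edgesnp::hwe_genotype_freqs(maf2)
  g1 <- sample.int(3, n, replace = TRUE, prob = f1) - 1L
  g2 <- sample.int(3, n, replace = TRUE, prob = f2) - 1L
  y <- stats::rbinom(n, 1, pen[cbind(g1 + 1, g2 + 1)])
  data.frame(SNP1 = g1, SNP2 = g2, status = y)
}

# Closed-form OLS oracle for the codominant dummy fit with intercept:
# solves the normal equations directly.
ols_dummy_oracle <- function(g, y) {
  X <- cbind(1, as.numeric(g == 1), as.numeric(g == 2))
  beta <- solve(crossprod(X), crossprod(X, y))
  c(het = beta[2], ha = beta[3])
}

# Newton-Raphson logistic oracle on the 3-cell genotype x status table.
logistic_3cell_oracle <- function(n_by_class, cases_by_class,
                                  maxit = 200, tol = 1e-12) {
  X <- cbind(1, c(0, 1, 0), c(0, 0, 1))
  beta <- rep(0, 3)
  for (i in seq_len(maxit)) {
    eta <- X %*% beta
    mu <- 1 / (1 + exp(-eta))
    W <- as.vector(n_by_class * mu * (1 - mu))
    score <- t(X) %*% (cases_by_class - n_by_class * mu)
    delta <- solve(t(X) %*% (X * W), score)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  c(het = beta[2], ha = beta[3])
}

# Expected retrospective genotype-pair distributions given a penetrance.
retro_distributions <- function(pen, maf1, maf2) {
  f <- outer(edgesnp::hwe_genotype_freqs(maf1),
             edgesnp::hwe_genotype_freqs(maf2))
  pc <- as.vector(f * pen); pk <- as.vector(f * (1 - pen))
  list(cases = pc / sum(pc), controls = pk / sum(pk))
}

# Cross-tabulate a sampled dataset back into 3 x 3 case/control counts.
dataset_counts <- function(d) {
  tab <- function(sub) {
    t <- table(factor(sub$SNP1, 0:2), factor(sub$SNP2, 0:2))
    matrix(as.integer(t), 3, 3)
  }
  list(cases = tab(d[d$status == 1, ]), controls = tab(d[d$status == 0, ]))
}
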