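sim_pair <- function(pen, n = 2000, seed = 1) {
  sample_dataset(pen, sim_config(n_samples = n, seed = seed))
}

test_that("an all-zero interaction column gives LRT statistic 0 and p 1", {
  set.seed(2)
  g1 <- sample(0:2, 400, replace = TRUE, prob = c(.49, .42, .09))
  g2 <- rep(0L, 400)                       # recessive-encoded column is 0
  y <- rbinom(400, 1, 0.3)
  r <- lrt_interaction(g1, g2, y, scheme = "recessive")
  expect_equal(r$lrt_stat, 0)
  expect_equal(r$lrt_p, 1)
  expect_equal(r$lrt_df, 0)
})

test_that("the LRT is non-negative and codominant adds exactly 4 parameters", {
  pen <- penetrance_interaction("ADD", "DOM", 0.1, 1.2)
  for (seed in 1:10) {
    d <- sim_pair(pen, 1500, seed)
    for (sc in c("additive", "dominant", "recessive")) {
      r <- lrt_interaction(d$SNP1, d$SNP2, d$status, scheme = sc)
      expect_gte(2 * (r$full$ll - r$reduced$ll), -1e-8)
      expect_equal(r$lrt_df, 1)
    }
    r <- lrt_interaction(d$SNP1, d$SNP2, d$status, scheme = "codominant")
    expect_equal(r$full$rank - r$reduced$rank, 4)
    expect_equal(r$lrt_df, 4)
    expect_gte(r$lrt_stat, 0)
  }
})

test_that("EDGE with fixed alpha reproduces the traditional encodings exactly", {
  pen <- penetrance_interaction("SUP", "SUB", 0.1, 1.3)
  fixed <- list(additive = 0.5, dominant = 1, recessive = 0)
  for (seed in 1:5) {
    d <- sim_pair(pen, 2000, seed)
    for (sc in names(fixed)) {
      a <- fixed[[sc]]
      r1 <- lrt_interaction(d$SNP1, d$SNP2, d$status, scheme = sc)
      r2 <- lrt_interaction(d$SNP1, d$SNP2, d$status, scheme = "edge",
                            alpha1 = a, alpha2 = a)
      # agreement to at least 10 significant digits
      expect_equal(r2$lrt_p, r1$lrt_p, tolerance = 1e-10)
      expect_equal(r2$lrt_stat, r1$lrt_stat, tolerance = 1e-10)
    }
  }
})

test_that("null LRT statistics follow their chi-square reference", {
  pen <- matrix(0.15, 3, 3)
  seeds <- replicate_seeds(55, 400)
  stats1 <- numeric(0); stats4 <- numeric(0)
  for (s in seeds) {
    d <- sim_pair(pen, 1000, s)
    r1 <- lrt_interaction(d$SNP1, d$SNP2, d$status, scheme = "additive")
    r4 <- lrt_interaction(d$SNP1, d$SNP2, d$status, scheme = "codominant")
    stats1 <- c(stats1, r1$lrt_stat)
    stats4 <- c(stats4, r4$lrt_stat)
  }
  expect_gt(stats::ks.test(stats1, stats::pchisq, df = 1)$p.value, 0.001)
  expect_gt(stats::ks.test(stats4, stats::pchisq, df = 4)$p.value, 0.001)
})

test_that("the EDGE pipeline estimates alpha before testing and flags failures", {
  pen <- penetrance_interaction("ADD", "ADD", 0.1, 1.4)
  d <- sim_pair(pen, 2000, 9)
  r <- edge_interaction_pipeline(d$SNP1, d$SNP2, d$status)
  expect_true(r$converged)
  a1 <- estimate_alpha(d$SNP1, d$status)
  a2 <- estimate_alpha(d$SNP2, d$status)
  ref <- lrt_interaction(d$SNP1, d$SNP2, d$status, scheme = "edge",
                         alpha1 = a1, alpha2 = a2)
  expect_equal(r$lrt_p, ref$lrt_p)
  expect_equal(r$alpha1, a1$alpha)
  # degenerate SNP2 (no homozygous-alternate class): flagged, no error
  g2 <- pmin(d$SNP2, 1L)
  r2 <- edge_interaction_pipeline(d$SNP1, g2, d$status)
  expect_false(r2$converged)
  expect_true(is.na(r2$lrt_p))
})

test_that("perfect separation is flagged as non-convergence, not an error", {
  g <- rep(0:2, each = 30)
  y <- as.integer(g >= 1)
  f <- fit_single_snp(g, y, scheme = "dominant")
  expect_false(f$converged)
  expect_true(is.na(f$lrt_p))
})

test_that("single-SNP Wald p-values are uniform under the null", {
  seeds <- replicate_seeds(123, 300)
  p <- vapply(seeds, function(s) {
    set.seed(s)
    g <- sample(0:2, 600, replace = TRUE, prob = c(.49, .42, .09))
    y <- rbinom(600, 1, 0.3)
    f <- fit_single_snp(g, y, scheme = "additive")
    unname(f$wald_p[grep("^Var1", names(f$wald_p))[1]])
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.001)
})

test_that("the designed-for encoding outscores the mismatched one", {
  # dominant-simulated SNP: dominant-encoding LRT statistic beats the
  # recessive encoding in nearly all replicates
  pen1 <- penetrance_main_effect("DOM", 0.1, 1.0)
  wins <- 0L
  seeds <- replicate_seeds(7, 60)
  for (s in seeds) {
    d <- sample_dataset(pen1, sim_config(n_samples = 10000, seed = s))
    fd <- fit_single_snp(d$SNP1, d$status, scheme = "dominant")
    fr <- fit_single_snp(d$SNP1, d$status, scheme = "recessive")
    wins <- wins + (fd$lrt_stat >= fr$lrt_stat)
  }
  expect_gte(wins / 60, 0.95)
})

test_that("codominant single-SNP significance is a 2-df LRT", {
  set.seed(17)
  g <- sample(0:2, 500, replace = TRUE, prob = c(.49, .42, .09))
  y <- rbinom(500, 1, 0.1 + 0.15 * (g == 1) + 0.3 * (g == 2))
  f <- fit_single_snp(g, y, scheme = "codominant")
  expect_equal(f$lrt_df, 2)
  expect_lt(f$lrt_p, 0.05)
})

test_that("p-value adjustments follow Bonferroni and BH", {
  expect_equal(adjust_pvalues(1e-5, "bonferroni", n_tests = 5671), 0.05671)
  expect_equal(adjust_pvalues(1, "bonferroni", n_tests = 1e6), 1)
  p <- c(0.001, 0.01, 0.02, 0.5)
  bh <- adjust_pvalues(p, "fdr_bh")
  expect_equal(bh, stats::p.adjust(p, "BH"))
  expect_true(all(diff(bh[order(p)]) >= -1e-15))
  expect_true(all(adjust_pvalues(p, "bonferroni", 4) >= p))
  expect_error(adjust_pvalues(c(0.5, 1.2), "bonferroni"), "is.na")
})

test_that("fits on aggregated count data equal fits on expanded samples", {
  # the study engine fits 18 weighted rows; this must match the public
  # per-sample path exactly
  pen <- penetrance_interaction("SUB", "SUP", 0.1, 1.2)
  d <- sim_pair(pen, 2000, 21)
  cnt <- dataset_counts(d)
  p_counts <- edgesnp:::.pair_pvalues(cnt$cases, cnt$controls,
                                      c("additive", "codominant", "edge"))
  r_add <- lrt_interaction(d$SNP1, d$SNP2, d$status, scheme = "additive")
  r_cod <- lrt_interaction(d$SNP1, d$SNP2, d$status, scheme = "codominant")
  r_edge <- edge_interaction_pipeline(d$SNP1, d$SNP2, d$status)
  expect_equal(unname(p_counts["additive"]), r_add$lrt_p, tolerance = 1e-10)
  expect_equal(unname(p_counts["codominant"]), r_cod$lrt_p,
               tolerance = 1e-10)
  expect_equal(unname(p_counts["edge"]), r_edge$lrt_p, tolerance = 1e-8)
})

test_that("interaction results flatten to the documented schema", {
  pen <- penetrance_interaction("ADD", "DOM", 0.1, 1.2)
  d <- sim_pair(pen, 1000, 4)
  r <- lrt_interaction(d$SNP1, d$SNP2, d$status, scheme = "additive")
  flat <- as.data.frame(r)
  expect_true(all(c("Raw_LRT_pval", "Red_Var1_beta", "Full_Var1_Var2_Pval",
                    "Red_model_Pval", "Full_model_Pval",
                    "Overall_LRT_Pval", "Converged", "Num_nonMissing",
                    "Num_Cases", "N_Iter") %in% names(flat)))
  expect_equal(flat$Raw_LRT_pval, r$lrt_p)
  expect_equal(flat$Converged, 1L)
})

test_that("linear-family interaction LRT works on quantitative traits", {
  pen <- penetrance_interaction("ADD", "ADD", 0.3, 0.5,
                                scale = "penetrance")
  d <- sample_dataset(pen, sim_config(n_samples = 3000, seed = 6,
                                      trait = "quantitative",
                                      noise_sd = 0.3))
  r <- lrt_interaction(d$SNP1, d$SNP2, d$trait, scheme = "additive",
                       family = "linear")
  expect_true(r$converged)
  expect_lt(r$lrt_p, 0.01)
})
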