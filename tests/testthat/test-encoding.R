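test_that("alpha equals the class-mean ratio for the linear family", {
  g <- rep(0:2, c(12, 10, 8))
  y <- rep(c(0.1, 0.3, 0.5), c(12, 10, 8))
  a <- estimate_alpha(g, y, family = "linear")
  expect_equal(a$alpha, (0.3 - 0.1) / (0.5 - 0.1))
  expect_true(a$converged)

  # against the exhaustive least-squares oracle on noisy small instances
  set.seed(42)
  for (i in 1:20) {
    n <- sample(9:30, 1)
    g <- c(0, 1, 2, sample(0:2, n - 3, replace = TRUE))
    y <- rnorm(n)
    a <- estimate_alpha(g, y, family = "linear")
    bo <- ols_dummy_oracle(g, y)
    expect_equal(a$beta_het, unname(bo["het"]), tolerance = 1e-10)
    expect_equal(a$beta_ha, unname(bo["ha"]), tolerance = 1e-10)
    expect_equal(a$alpha, unname(bo["het"] / bo["ha"]), tolerance = 1e-9)
  }
})

test_that("recessive and dominant class-mean patterns give alpha 0 and 1", {
  g <- rep(0:2, each = 10)
  rec <- estimate_alpha(g, rep(c(0.1, 0.1, 0.5), each = 10),
                        family = "linear")
  dom <- estimate_alpha(g, rep(c(0.1, 0.5, 0.5), each = 10),
                        family = "linear")
  expect_equal(rec$alpha, 0)
  expect_equal(dom$alpha, 1)
})

test_that("logistic alpha converges to the log-odds-ratio ratio", {
  # exact class penetrances (0.1, 0.2, 0.4) at large n: alpha must approach
  # log(2.25)/log(6), verified against a Newton-Raphson oracle on the
  # 3-cell table
  n_class <- c(45000, 42000, 9000)
  cases <- round(n_class * c(0.1, 0.2, 0.4))
  g <- rep(rep(0:2, 2), c(cases, n_class - cases))
  y <- rep(c(1, 0), c(sum(cases), sum(n_class - cases)))
  a <- estimate_alpha(g, y, family = "logistic")
  oracle <- logistic_3cell_oracle(n_class, cases)
  expect_equal(a$beta_het, unname(oracle["het"]), tolerance = 1e-6)
  expect_equal(a$beta_ha, unname(oracle["ha"]), tolerance = 1e-6)
  expect_equal(a$alpha, log(2.25) / log(6), tolerance = 1e-6)
})

test_that("alpha is invariant to positive rescaling of the phenotype", {
  set.seed(7)
  g <- sample(0:2, 200, replace = TRUE, prob = c(.49, .42, .09))
  y <- rnorm(200, mean = 0.2 * g)
  a1 <- estimate_alpha(g, y, family = "linear")
  a2 <- estimate_alpha(g, 37.5 * y, family = "linear")
  expect_equal(a1$alpha, a2$alpha, tolerance = 1e-12)
})

test_that("degenerate genotype distributions and undefined alpha are handled", {
  expect_error(estimate_alpha(rep(0:1, 10), rnorm(20), family = "linear"),
               "degenerate genotype distribution")
  # flat phenotype across classes: beta_ha ~ 0 -> alpha undefined
  g <- rep(0:2, each = 20)
  y <- rep(0.5, 60)
  expect_error(estimate_alpha(g, y, family = "linear"),
               "phenotype is constant")
  y <- rep(c(0.2, 0.7, 0.2), each = 20)  # beta_ha exactly 0
  a <- estimate_alpha(g, y, family = "linear")
  expect_false(a$alpha_defined)
  expect_true(is.na(a$alpha))
})

test_that("encoding schemes map genotypes to their design values", {
  g <- c(0, 1, 2, NA)
  expect_equal(encode_genotype(g, "additive"), c(0, 0.5, 1, NA))
  expect_equal(encode_genotype(g, "dominant"), c(0, 1, 1, NA))
  expect_equal(encode_genotype(g, "recessive"), c(0, 0, 1, NA))
  expect_equal(encode_genotype(g, "edge", alpha = 0.25), c(0, 0.25, 1, NA))
  # out-of-range alpha passes through unclamped
  expect_equal(encode_genotype(g, "edge", alpha = -1.39),
               c(0, -1.39, 1, NA))
  cod <- encode_genotype(g, "codominant")
  expect_equal(dim(cod), c(4, 2))
  expect_equal(cod[, "het"], c(0, 1, 0, NA))
  expect_equal(cod[, "ha"], c(0, 0, 1, NA))
  # EDGE with fixed alpha reproduces the single-column schemes
  for (pair in list(c(0.5, "additive"), c(1, "dominant"),
                    c(0, "recessive"))) {
    expect_identical(
      encode_genotype(g, "edge", alpha = as.numeric(pair[1])),
      encode_genotype(g, pair[2]))
  }
  expect_error(encode_genotype(g, "edge"), "alpha")
  expect_error(encode_genotype(c(0, 3), "additive"), "0/1/2")
})

test_that("batch alpha estimation flags degenerate SNPs instead of dropping them", {
  set.seed(11)
  n <- 300
  g1 <- sample(0:2, n, replace = TRUE, prob = c(.5, .4, .1))
  g2 <- sample(0:1, n, replace = TRUE)   # no homozygous-alternate carriers
  g3 <- sample(0:2, n, replace = TRUE, prob = c(.4, .4, .2))
  y <- rbinom(n, 1, 0.2 + 0.1 * g1)
  tab <- estimate_alpha_all(cbind(a = g1, b = g2, c = g3), y)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$Converged[2], 0L)
  expect_match(tab$note[2], "degenerate")
  expect_true(all(is.finite(tab$categ_weight[c(1, 3)])))
  expect_equal(tab$Num_nonMissing, rep(n, 3))
})

test_that("simulated main-effect SNPs recover their heterozygous weight", {
  # simulator round trip at moderate replicate count: ADD and DOM SNPs at
  # 30% MAF should give alpha near 0.5 and 1
  r <- run_alpha_recovery_study(models = c("ADD", "DOM"),
                                n_samples = 10000, n_replicates = 60,
                                seed = 99)
  expect_equal(r$mean[r$model == "ADD"], 0.5, tolerance = 0.03)
  expect_equal(r$mean[r$model == "DOM"], 1.0, tolerance = 0.04)
  expect_equal(r$n_defined, r$n_replicates)
})

test_that("missing genotypes are dropped per SNP (complete-case)", {
  g <- c(NA, rep(0:2, each = 15))
  y <- c(1, rep(c(0.1, 0.3, 0.5), each = 15))
  a <- estimate_alpha(g, y, family = "linear")
  expect_equal(a$n_used, 45)
  expect_equal(a$alpha, 0.5)
})
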