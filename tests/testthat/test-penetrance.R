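test_that("main-effect penetrance vectors follow the model risk fractions", {
  expect_equal(penetrance_main_effect("ADD", 0.1, 0.4, "penetrance"),
               c(0.1, 0.3, 0.5))
  expect_equal(penetrance_main_effect("SUB", 0.1, 0.4, "penetrance"),
               c(0.1, 0.2, 0.5))
  expect_equal(penetrance_main_effect("HET", 0.1, 0.4, "penetrance"),
               c(0.1, 0.5, 0.1))
  expect_error(penetrance_main_effect("ADD", 0.8, 0.4, "penetrance"),
               "outside")
  expect_error(penetrance_main_effect("XYZ", 0.1, 0.1), "unknown")
  # odds scale: log odds linear in the risk vector
  p <- penetrance_main_effect("SUP", 0.1, 1.2, "odds")
  lo <- log(p / (1 - p))
  expect_equal(lo[2] - lo[1], 0.75 * (lo[3] - lo[1]), tolerance = 1e-12)
})

test_that("genotype-based tables match their cell definitions", {
  xor <- penetrance_genotype_based("XOR", 0, 1, "penetrance")
  expect_equal(as.vector(t(xor)), c(1, 0, 1, 0, 1, 0, 1, 0, 1))
  hyp <- penetrance_genotype_based("Hyp", 0, 1, "penetrance")
  expect_equal(hyp["AA", ], c(BB = 0, Bb = 0.5, bb = 1))
  expect_equal(hyp["Aa", "Bb"], 0.5)
  expect_equal(hyp["aa", "bb"], 0)
  hr <- penetrance_genotype_based("HR-HR", 0.05, 0.2, "penetrance")
  expect_equal(hr["AA", "BB"], 0.25)
  expect_equal(sum(hr == 0.05), 8)
  rhyp <- penetrance_genotype_based("RHyp", 0, 1, "penetrance")
  expect_equal(rhyp["AA", "BB"], 1)
  expect_equal(rhyp["aa", "bb"], 1)
})

test_that("two-SNP main-effect tables have no interaction on their scale", {
  # risk scale: direct evaluation of b + s*m1 + s*m2
  p <- penetrance_two_main_effects("ADD", "REC", 0.05, 0.1, "penetrance")
  expect_equal(unname(p[1, ]), c(0.05, 0.05, 0.15))
  expect_equal(unname(p[2, ]), c(0.10, 0.10, 0.20))
  expect_equal(unname(p[3, ]), c(0.15, 0.15, 0.25))
  pd <- penetrance_two_main_effects("DOM", "DOM", 0.1, 0.2, "penetrance")
  expect_equal(sort(unique(as.vector(pd))), c(0.1, 0.3, 0.5))
  # HET on one SNP only: rows replicated across the other SNP
  ph <- penetrance_two_main_effects("HET", NULL, 0.1, 0.3, "penetrance")
  expect_equal(unname(ph[2, ]), rep(0.4, 3))
  expect_equal(unname(ph[1, ]), unname(ph[3, ]))
  # odds scale: the 2x2 log-odds interaction contrast vanishes everywhere
  po <- penetrance_two_main_effects("SUP", "SUB", 0.1, 1.3, "odds")
  lo <- log(po / (1 - po))
  for (i in 2:3) for (j in 2:3) {
    expect_equal(lo[i, j] - lo[i, 1] - lo[1, j] + lo[1, 1], 0,
                 tolerance = 1e-12)
  }
})

test_that("centered interaction tables have exactly constant HWE marginals", {
  models <- enumerate_interaction_models()
  pw <- models[models$type %in% c("pairwise", "het_pairwise"), ]
  for (k in seq_len(nrow(pw))) {
    pen <- penetrance_interaction(pw$model1[k], pw$model2[k],
                                  baseline = 0.3, effect = 0.2,
                                  maf1 = 0.3, maf2 = 0.3,
                                  construction = "centered")
    f1 <- hwe_genotype_freqs(0.3); f2 <- hwe_genotype_freqs(0.3)
    marg1 <- as.vector(pen %*% f2)     # penetrance of g1 averaged over g2
    marg2 <- as.vector(f1 %*% pen)
    expect_lt(max(abs(marg1 - 0.3)), 1e-12)
    expect_lt(max(abs(marg2 - 0.3)), 1e-12)
  }
  # hand computation: ADD x ADD at MAF 0.5, b = 0.2, s = 0.4
  pen <- penetrance_interaction("ADD", "ADD", 0.2, 0.4, 0.5, 0.5,
                                construction = "centered")
  expect_equal(pen[1, 1], 0.3)   # (-0.5)*(-0.5)*0.4 + 0.2
  expect_equal(pen[1, 3], 0.1)
  expect_equal(unname(pen[2, ]), rep(0.2, 3))
  expect_equal(unname(pen[, 2]), rep(0.2, 3))
  # REC x DOM: zero deviation wherever m1 equals its HWE mean
  expect_error(penetrance_interaction("ADD", "ADD", 0.05, 2, 0.3, 0.3,
                                      construction = "centered"),
               "outside")
})

test_that("product interaction tables coincide with their single-cell twins", {
  expect_equal(penetrance_interaction("REC", "REC", 0.1, 0.7,
                                      scale = "penetrance"),
               unname(penetrance_genotype_based("HA-HA", 0.1, 0.7,
                                                "penetrance")),
               ignore_attr = TRUE)
  expect_equal(penetrance_interaction("HET", "HET", 0.1, 0.7,
                                      scale = "penetrance"),
               unname(penetrance_genotype_based("HET-HET", 0.1, 0.7,
                                                "penetrance")),
               ignore_attr = TRUE)
})

test_that("the interaction model catalogue has exactly 29 entries", {
  models <- enumerate_interaction_models()
  expect_equal(nrow(models), 29)
  expect_equal(sum(models$type == "pairwise"), 15)
  expect_equal(sum(models$type == "het_pairwise"), 5)
  expect_equal(sum(models$type == "genotype_based"), 9)
  expect_false(any(duplicated(models$name)))
  # HET-HET appears exactly once, as the genotype-based table
  expect_equal(sum(grepl("HET.HET", models$name)), 1)
  expect_equal(models$type[models$name == "HET-HET"], "genotype_based")
})

test_that("the main-effect catalogue covers one- and two-SNP models plus null", {
  m <- enumerate_main_effect_models()
  expect_equal(sum(m$type == "one_snp"), 6)
  expect_equal(sum(m$type == "two_snp"), 21)
  expect_equal(sum(m$type == "null"), 1)
  expect_false(any(duplicated(m$name)))
})

test_that("max_admissible_effect bounds the penetrance cells", {
  mask <- genotype_based_model("XOR")
  expect_equal(max_admissible_effect(mask, 0.1), 0.9)
  cen <- outer(c(0, 0.5, 1) - 0.3, c(0, 0.5, 1) - 0.3)
  smax <- max_admissible_effect(cen, 0.1)
  pen <- 0.1 + smax * cen
  expect_true(all(pen >= -1e-12 & pen <= 1 + 1e-12))
  expect_error(penetrance_genotype_based("XOR", 0.1, smax * 10,
                                         "penetrance"), "outside")
})

test_that("hwe frequencies are the binomial genotype proportions", {
  f <- hwe_genotype_freqs(0.3)
  expect_equal(unname(f), c(0.49, 0.42, 0.09))
  expect_equal(sum(f), 1)
})
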