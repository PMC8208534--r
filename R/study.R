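## Power / type-I-error simulation study orchestration.
##
## The study runner works on the 3x3x2 genotype-pair x status count tables
## directly: every replicate's regression is fit on at most 18
## frequency-weighted rows, which is likelihood-identical to fitting the
## expanded per-sample data (verified in the test suite) and keeps a
## 29-model x 5-encoding x 1,000-replicate study inside a few minutes.

.G1 <- rep(0:2, 3)
.G2 <- rep(0:2, each = 3)

## alpha from the marginal genotype-class counts of one SNP
#' @noRd
.alpha_from_counts <- function(case9, ctrl9, snp, family = "logistic",
                               tol = 1e-8) {
  if (length(case9) == 3) {                    # single-SNP marginal counts
    nc <- as.vector(case9); nk <- as.vector(ctrl9)
  } else {
    g <- if (snp == 1) .G1 else .G2
    nc <- as.vector(tapply(case9, g, sum))
    nk <- as.vector(tapply(ctrl9, g, sum))
  }
  if (any(nc + nk == 0)) return(NA_real_)
  y <- c(1, 1, 1, 0, 0, 0)
  w <- c(nc, nk)
  gg <- c(0:2, 0:2)
  X <- cbind(1, as.numeric(gg == 1), as.numeric(gg == 2))
  keep <- w > 0
  fit <- .fit_design(X[keep, , drop = FALSE], y[keep], w[keep],
                     family = family, collapse = FALSE)
  bha <- fit$coef[3]
  if (!fit$converged || !is.finite(bha) || abs(bha) < tol) return(NA_real_)
  unname(fit$coef[2] / bha)
}

## interaction LRT p-values for one replicate's count table, all schemes
#' @noRd
.pair_pvalues <- function(case9, ctrl9, schemes, family = "logistic") {
  y <- c(rep(1, 9), rep(0, 9))
  w <- c(as.vector(case9), as.vector(ctrl9))
  keep <- w > 0
  out <- stats::setNames(rep(NA_real_, length(schemes)), schemes)
  for (sc in schemes) {
    if (sc == "edge") {
      a1 <- .alpha_from_counts(case9, ctrl9, 1, family)
      a2 <- .alpha_from_counts(case9, ctrl9, 2, family)
      if (is.na(a1) || is.na(a2)) next
      alpha1 <- a1; alpha2 <- a2
    } else {
      alpha1 <- alpha2 <- NULL
    }
    E1 <- .encode_cols(c(.G1, .G1), sc, alpha1, "Var1")
    E2 <- .encode_cols(c(.G2, .G2), sc, alpha2, "Var2")
    EI <- .interaction_cols(E1, E2)
    one <- rep(1, 18)
    Xr <- cbind(`(Intercept)` = one, E1, E2)
    Xf <- cbind(Xr, EI)
    fr <- .fit_design(Xr[keep, , drop = FALSE], y[keep], w[keep],
                      family = family, collapse = FALSE)
    ff <- .fit_design(Xf[keep, , drop = FALSE], y[keep], w[keep],
                      family = family, collapse = FALSE)
    df <- ff$rank - fr$rank
    if (!fr$converged || !ff$converged) next
    if (df == 0) { out[sc] <- 1; next }
    stat <- max(0, 2 * (ff$ll - fr$ll))
    out[sc] <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  }
  out
}

#' @noRd
.run_study <- function(models, encodings, maf, n_samples, ratio, baseline,
                       effect, scale, construction, n_replicates,
                       alpha_level, seed) {
  grid <- expand.grid(maf = maf, n_samples = n_samples, ratio = ratio,
                      baseline = baseline, effect = effect,
                      KEEP.OUT.ATTRS = FALSE)
  n_cond <- nrow(models) * nrow(grid)
  cond_seeds <- replicate_seeds(seed, n_cond)
  rows <- vector("list", n_cond)
  cond <- 0
  for (m in seq_len(nrow(models))) {
    spec <- models[m, ]
    for (gidx in seq_len(nrow(grid))) {
      cond <- cond + 1
      gp <- grid[gidx, ]
      pen <- build_model_penetrance(spec, baseline = gp$baseline,
                                    effect = gp$effect, scale = scale,
                                    construction = construction,
                                    maf1 = gp$maf, maf2 = gp$maf)
      split <- .case_control_split(gp$n_samples, gp$ratio)
      set.seed(cond_seeds[cond])
      det <- stats::setNames(integer(length(encodings)), encodings)
      flagged <- stats::setNames(integer(length(encodings)), encodings)
      for (r in seq_len(n_replicates)) {
        cnt <- sample_genotype_counts(pen, gp$maf, gp$maf,
                                      split["cases"], split["controls"])
        ps <- .pair_pvalues(cnt$cases, cnt$controls, encodings)
        det <- det + (!is.na(ps) & ps < alpha_level)
        flagged <- flagged + is.na(ps)
      }
      rows[[cond]] <- data.frame(
        model = spec$name, type = spec$type, encoding = encodings,
        maf = gp$maf, n_samples = gp$n_samples, ratio = gp$ratio,
        baseline = gp$baseline, effect = gp$effect,
        n_replicates = n_replicates, n_detected = as.integer(det),
        n_flagged = as.integer(flagged),
        power_or_fpr = as.numeric(det) / n_replicates,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the SNP-SNP interaction power study
#'
#' For every combination of interaction model, encoding and parameter grid
#' point, simulates `n_replicates` case-control datasets and counts the
#' fraction with interaction LRT p below `alpha_level`.  Replicates that
#' fail (non-convergence, undefined alpha) count as non-detections.
#' Deterministic under the master `seed`.
#'
#' @param models model catalogue rows (default: the 29 interaction models
#'   of [enumerate_interaction_models()]).
#' @param encodings encodings to evaluate (default all five).
#' @param maf,n_samples,ratio,baseline,effect parameter values; vectors are
#'   crossed into a grid.  `effect` is on the scale given by `scale`
#'   (default: log odds units).
#' @param scale,construction penetrance construction options (see
#'   [penetrance_interaction()]).
#' @param n_replicates replicates per condition.
#' @param alpha_level nominal significance level of the LRT.
#' @param seed master seed.
#' @return a data.frame, one row per (model, grid point, encoding), with
#'   `n_detected` and `power_or_fpr`.
#' @export
run_power_study <- function(models = enumerate_interaction_models(),
                            encodings = EDGE_SCHEMES,
                            maf = 0.3, n_samples = 2000, ratio = 1,
                            baseline = 0.1, effect = 1.25,
                            scale = c("odds", "penetrance"),
                            construction = c("product", "centered"),
                            n_replicates = 1000, alpha_level = 0.05,
                            seed = 1) {
  scale <- match.arg(scale)
  construction <- match.arg(construction)
  encodings <- match.arg(encodings, EDGE_SCHEMES, several.ok = TRUE)
  .run_study(models, encodings, maf, n_samples, ratio, baseline, effect,
             scale, construction, n_replicates, alpha_level, seed)
}

#' Run the type-I-error (false positive rate) study
#'
#' As [run_power_study()] but over main-effect-only and null models, where
#' every detection is a false positive.  Adds a `bradley_ok` flag marking
#' estimated type-I error inside Bradley's liberal interval
#' (0.025, 0.075) at the 0.05 nominal level.
#'
#' @inheritParams run_power_study
#' @param models main-effect/null catalogue (default
#'   [enumerate_main_effect_models()]).
#' @param effect main-effect size (log odds ratio of the full-risk
#'   genotype class by default).
#' @return a data.frame as in [run_power_study()] plus `bradley_ok`.
#' @export
run_type1_study <- function(models = enumerate_main_effect_models(),
                            encodings = EDGE_SCHEMES,
                            maf = 0.3, n_samples = 2000, ratio = 1,
                            baseline = 0.1, effect = 1.1,
                            scale = c("odds", "penetrance"),
                            n_replicates = 1000, alpha_level = 0.05,
                            seed = 1) {
  scale <- match.arg(scale)
  encodings <- match.arg(encodings, EDGE_SCHEMES, several.ok = TRUE)
  out <- .run_study(models, encodings, maf, n_samples, ratio, baseline,
                    effect, scale, "product", n_replicates, alpha_level,
                    seed)
  out$bradley_ok <- out$power_or_fpr > 0.025 & out$power_or_fpr < 0.075
  out
}

#' Sweep power / type-I error over increasing signal levels
#'
#' Runs the study at each signal level and summarizes, per encoding and
#' level, the average and the maximum power (or false positive rate)
#' across models.  On the `"penetrance"` scale a level is interpreted as a
#' fraction of each model's largest admissible effect
#' ([max_admissible_effect()]); on the `"odds"` scale levels are log-odds
#' effect sizes used directly.
#'
#' @inheritParams run_power_study
#' @param levels increasing signal levels.
#' @return a data.frame with one row per (encoding, level):
#'   `mean_power`, `max_power`, `max_model`.
#' @export
sweep_signal_to_noise <- function(models = enumerate_interaction_models(),
                                  encodings = EDGE_SCHEMES,
                                  levels = seq(0.25, 1.5, by = 0.25),
                                  maf = 0.3, n_samples = 2000, ratio = 1,
                                  baseline = 0.1,
                                  scale = c("odds", "penetrance"),
                                  construction = c("product", "centered"),
                                  n_replicates = 200, alpha_level = 0.05,
                                  seed = 1) {
  scale <- match.arg(scale)
  construction <- match.arg(construction)
  if (is.unsorted(levels, strictly = TRUE)) {
    stop("signal levels must be strictly increasing")
  }
  out <- vector("list", length(levels))
  for (k in seq_along(levels)) {
    lev <- levels[k]
    if (scale == "penetrance") {
      ## per-model effect: fraction of the admissible maximum
      res <- lapply(seq_len(nrow(models)), function(m) {
        spec <- models[m, ]
        mask <- .model_mask(spec, construction, maf[1], maf[1])
        smax <- max_admissible_effect(mask, baseline)
        eff <- if (is.finite(smax)) lev * smax else 0
        .run_study(spec, encodings, maf, n_samples, ratio, baseline,
                   eff, "penetrance", construction, n_replicates,
                   alpha_level, seed + m)
      })
      res <- do.call(rbind, res)
    } else {
      res <- .run_study(models, encodings, maf, n_samples, ratio, baseline,
                        lev, "odds", construction, n_replicates,
                        alpha_level, seed)
    }
    agg <- do.call(rbind, lapply(split(res, res$encoding), function(d) {
      data.frame(encoding = d$encoding[1], level = lev,
                 mean_power = mean(d$power_or_fpr),
                 max_power = max(d$power_or_fpr),
                 max_model = d$model[which.max(d$power_or_fpr)],
                 stringsAsFactors = FALSE)
    }))
    out[[k]] <- agg
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Alpha-recovery simulation study
#'
#' Simulates `n_replicates` single-SNP main-effect datasets per
#' inheritance model, estimates the heterozygous weight alpha on each by
#' the codominant-dummy regression ratio, and reports the distribution
#' mode on a histogram grid of width `bin_width` (bins centered on
#' multiples of the width).  Under the default log-odds effect scale the
#' estimator is unbiased for the simulated heterozygous risk fraction, so
#' the modes are expected at 0 / 0.25 / 0.5 / 0.75 / 1 for
#' REC / SUB / ADD / SUP / DOM.
#'
#' @param models inheritance model names.
#' @param maf,n_samples,ratio,baseline,effect,scale simulation settings;
#'   the default effect (1.5 log-odds units) gives near-complete
#'   single-SNP detection power, concentrating the alpha distribution.
#' @param n_replicates replicate datasets per model.
#' @param bin_width histogram bin width for the mode.
#' @param seed master seed.
#' @return a data.frame with one row per model: `mode`, `mean`, `sd`,
#'   `n_defined` (replicates with a defined alpha).  The raw alpha draws
#'   are attached as `attr(, "alphas")` (a named list).
#' @export
run_alpha_recovery_study <- function(models = c("REC", "SUB", "ADD",
                                                "SUP", "DOM"),
                                     maf = 0.3, n_samples = 2000,
                                     ratio = 1, baseline = 0.1,
                                     effect = 1.5,
                                     scale = c("odds", "penetrance"),
                                     n_replicates = 1000,
                                     bin_width = 0.05, seed = 1) {
  scale <- match.arg(scale)
  split <- .case_control_split(n_samples, ratio)
  seeds <- replicate_seeds(seed, length(models))
  alphas <- vector("list", length(models))
  names(alphas) <- models
  rows <- vector("list", length(models))
  for (m in seq_along(models)) {
    pen <- penetrance_main_effect(models[m], baseline, effect, scale)
    set.seed(seeds[m])
    a <- replicate(n_replicates, {
      cnt <- sample_genotype_counts(pen, maf, NULL,
                                    split["cases"], split["controls"])
      .alpha_from_counts(cnt$cases, cnt$controls, 1)
    })
    alphas[[m]] <- a
    def <- a[!is.na(a)]
    bins <- table(round(def / bin_width))
    mode_bin <- as.numeric(names(bins)[which.max(bins)]) * bin_width
    rows[[m]] <- data.frame(model = models[m], maf = maf,
                            n_samples = n_samples,
                            n_replicates = n_replicates,
                            n_defined = length(def),
                            mode = mode_bin, mean = mean(def),
                            sd = stats::sd(def), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alphas") <- alphas
  out
}

#' One-way ANOVA of power on each simulation parameter
#'
#' For each (model, encoding) cell of a study summary grid, tests each
#' parameter (MAF, sample size, case-control ratio, baseline risk) with a
#' one-way ANOVA of power across that parameter's levels, the other grid
#' dimensions serving as replication.  Parameters with fewer than two
#' levels are skipped with a note.
#'
#' @param summary a study summary from [run_power_study()] with a
#'   multi-level parameter grid.
#' @param parameters columns of `summary` to test.
#' @return data.frame with `model`, `encoding`, `parameter`, `f_statistic`,
#'   `p_value`, `skipped`.
#' @export
anova_parameter_effects <- function(summary,
                                    parameters = c("maf", "n_samples",
                                                   "ratio", "baseline")) {
  cells <- split(summary, list(summary$model, summary$encoding), drop = TRUE)
  rows <- list()
  for (cell in cells) {
    for (par in parameters) {
      lev <- unique(cell[[par]])
      if (length(lev) < 2 || nrow(cell) <= length(lev)) {
        rows[[length(rows) + 1]] <- data.frame(
          model = cell$model[1], encoding = cell$encoding[1],
          parameter = par, f_statistic = NA_real_, p_value = NA_real_,
          skipped = TRUE, stringsAsFactors = FALSE)
        next
      }
      fit <- stats::aov(power_or_fpr ~ factor(cell[[par]]), data = cell)
      tab <- summary(fit)[[1]]
      rows[[length(rows) + 1]] <- data.frame(
        model = cell$model[1], encoding = cell$encoding[1],
        parameter = par, f_statistic = tab$`F value`[1],
        p_value = tab$`Pr(>F)`[1], skipped = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
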