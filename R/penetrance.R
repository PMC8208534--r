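## Penetrance-model builders for the biallelic simulator.
##
## Single-SNP inheritance models assign the heterozygote a fraction w of the
## homozygous-alternate risk: REC 0, SUB 0.25, ADD 0.5, SUP 0.75, DOM 1.
## The HET model gives the heterozygote full risk and both homozygotes none.
## Effects can enter on the penetrance scale, pen = b + s * M, or on the
## log-odds scale, logit(pen) = logit(b) + s * M.  The log-odds scale is the
## default for simulation studies: it is the scale on which the logistic
## codominant regression defines the heterozygous weight, so the estimated
## alpha recovers the simulated risk fraction without scale bias, and a
## log-odds-additive two-SNP table is an exact null of the interaction LRT.

#' Inheritance model risk vectors
#'
#' Returns the per-genotype risk multipliers (homozygous referent,
#' heterozygous, homozygous alternate) for the named single-SNP models.
#'
#' @param name one of `"REC"`, `"SUB"`, `"ADD"`, `"SUP"`, `"DOM"`, `"HET"`,
#'   or `NULL` to return the full named list.
#' @return a numeric 3-vector, or a named list of them.
#' @examples
#' inheritance_model("ADD")  # 0 0.5 1
#' @export
inheritance_model <- function(name = NULL) {
  models <- list(REC = c(0, 0,    1),
                 SUB = c(0, 0.25, 1),
                 ADD = c(0, 0.5,  1),
                 SUP = c(0, 0.75, 1),
                 DOM = c(0, 1,    1),
                 HET = c(0, 1,    0))
  if (is.null(name)) return(models)
  name <- toupper(name)
  if (!name %in% names(models)) {
    stop("unknown inheritance model: ", name)
  }
  models[[name]]
}

#' Genotype-based 3x3 interaction mask tables
#'
#' Cell-wise interaction patterns over the nine two-SNP genotype
#' combinations (rows: SNP1 AA, Aa, aa; columns: SNP2 BB, Bb, bb).  The six
#' single-cell models place all risk in one genotype pair (e.g. `HR-HR` in
#' the double homozygous referent cell), `XOR` alternates risk in a
#' checkerboard, and `Hyp`/`RHyp` are the hyperbolic saddle and its reverse.
#'
#' @param name model name, or `NULL` for the full named list.
#' @return a 3x3 numeric matrix (or named list of them).
#' @export
genotype_based_model <- function(name = NULL) {
  byrow <- function(...) matrix(c(...), 3, 3, byrow = TRUE,
                                dimnames = list(c("AA", "Aa", "aa"),
                                                c("BB", "Bb", "bb")))
  models <- list(
    "HR-HR"   = byrow(1, 0, 0,  0, 0, 0,  0, 0, 0),
    "HR-HET"  = byrow(0, 1, 0,  0, 0, 0,  0, 0, 0),
    "HR-HA"   = byrow(0, 0, 1,  0, 0, 0,  0, 0, 0),
    "HET-HET" = byrow(0, 0, 0,  0, 1, 0,  0, 0, 0),
    "HET-HA"  = byrow(0, 0, 0,  0, 0, 1,  0, 0, 0),
    "HA-HA"   = byrow(0, 0, 0,  0, 0, 0,  0, 0, 1),
    "XOR"     = byrow(1, 0, 1,  0, 1, 0,  1, 0, 1),
    "Hyp"     = byrow(0, 0.5, 1,  0.5, 0.5, 0.5,  1, 0.5, 0),
    "RHyp"    = byrow(1, 0.5, 0,  0.5, 0.5, 0.5,  0, 0.5, 1))
  if (is.null(name)) return(models)
  if (!name %in% names(models)) stop("unknown genotype-based model: ", name)
  models[[name]]
}

#' @noRd
.logit <- function(p) log(p / (1 - p))
#' @noRd
.expit <- function(x) 1 / (1 + exp(-x))

#' Hardy-Weinberg genotype frequencies
#'
#' @param maf minor allele frequency in `[0, 0.5]`.
#' @return frequencies of 0, 1, 2 copies of the minor allele.
#' @export
hwe_genotype_freqs <- function(maf) {
  stopifnot(maf >= 0, maf <= 0.5 + 1e-12)
  c(`0` = (1 - maf)^2, `1` = 2 * maf * (1 - maf), `2` = maf^2)
}

#' @noRd
.apply_scale <- function(mask, baseline, effect, scale) {
  pen <- switch(scale,
    penetrance = baseline + effect * mask,
    odds       = .expit(.logit(baseline) + effect * mask),
    stop("scale must be 'penetrance' or 'odds'"))
  bad <- which(pen < -1e-12 | pen > 1 + 1e-12)
  if (length(bad)) {
    stop("penetrance cell(s) outside [0, 1] at index ",
         paste(bad, collapse = ", "),
         " (baseline = ", baseline, ", effect = ", effect, ")")
  }
  pmin(pmax(pen, 0), 1)
}

#' Single-SNP main-effect penetrance
#'
#' Builds the 3-vector of case probabilities for one SNP under a named
#' inheritance model: on the penetrance scale `b + s * m`, on the log-odds
#' scale `expit(logit(b) + s * m)`, with `m` the model risk vector.
#'
#' @param model inheritance model name (see [inheritance_model()]).
#' @param baseline baseline risk `b` in (0, 1) (the homozygous-referent
#'   penetrance; for HET also the homozygous-alternate penetrance).
#' @param effect effect size `s` (risk increment, or log odds ratio of the
#'   full-risk genotype, depending on `scale`).
#' @param scale `"odds"` (default) or `"penetrance"`.
#' @return numeric 3-vector of penetrances for genotypes 0, 1, 2.
#' @examples
#' penetrance_main_effect("ADD", baseline = 0.1, effect = 0.4,
#'                        scale = "penetrance")  # 0.1 0.3 0.5
#' @export
penetrance_main_effect <- function(model, baseline, effect,
                                   scale = c("odds", "penetrance")) {
  scale <- match.arg(scale)
  m <- if (is.character(model)) inheritance_model(model) else model
  stopifnot(length(m) == 3)
  .apply_scale(m, baseline, effect, scale)
}

#' Two-SNP main-effect-only penetrance table
#'
#' Builds a 3x3 table in which one or both SNPs carry a marginal effect but
#' there is no interaction.  On the default log-odds scale the table is
#' log-odds additive, `logit(pen) = logit(b) + s1*m1(g1) + s2*m2(g2)`, which
#' is an exact null of the interaction likelihood ratio test.  On the
#' penetrance scale the combination is additive on the risk scale,
#' `pen = b + s1*m1(g1) + s2*m2(g2)` (note that a risk-additive table is
#' not log-odds additive, so the logistic interaction LRT is not exactly
#' null under it).
#'
#' @param model1,model2 inheritance model names, or `NULL` for no effect
#'   (at least one must be non-NULL).
#' @param baseline baseline risk.
#' @param effect effect size, recycled to both SNPs; give a length-2 vector
#'   for distinct effects.
#' @param scale `"odds"` (default) or `"penetrance"`.
#' @return 3x3 penetrance matrix (rows SNP1 genotype, columns SNP2).
#' @export
penetrance_two_main_effects <- function(model1, model2 = NULL, baseline,
                                        effect,
                                        scale = c("odds", "penetrance")) {
  scale <- match.arg(scale)
  if (length(model1) == 1 && is.na(model1)) model1 <- NULL
  if (length(model2) == 1 && is.na(model2)) model2 <- NULL
  if (is.null(model1) && is.null(model2)) {
    stop("at least one of model1, model2 must be given")
  }
  effect <- rep_len(effect, 2)
  m1 <- if (is.null(model1)) rep(0, 3) else inheritance_model(model1)
  m2 <- if (is.null(model2)) rep(0, 3) else inheritance_model(model2)
  mask <- outer(effect[1] * m1, rep(1, 3)) + outer(rep(1, 3), effect[2] * m2)
  .apply_scale(mask, baseline, 1, scale)
}

#' Pairwise SNP-SNP interaction penetrance table
#'
#' Builds the 3x3 penetrance for an interaction between two SNPs with named
#' inheritance models.  Two constructions are available:
#'
#' * `"product"` (default): the interaction mask is the outer product
#'   `m1(g1) * m2(g2)` and the model contains no main-effect terms
#'   (pure epistasis in the penetrance-model sense).  Marginal genotype
#'   effects induced by the product itself are retained; they are what
#'   allows the heterozygous weight alpha to be estimated before
#'   interaction testing.  Note `REC x REC` reduces to the `HA-HA`
#'   single-cell table and `HET x HET` to `HET-HET`.
#' * `"centered"`: penetrance-scale construction
#'   `b + s * (m1(g1) - mu1) * (m2(g2) - mu2)` with `mu_i` the
#'   HWE-frequency-weighted mean of `m_i` at `maf_i`.  The HWE-weighted
#'   marginal penetrance is then exactly constant (no marginal association
#'   at the stated MAFs).
#'
#' @param model1,model2 inheritance model names.
#' @param baseline baseline risk.
#' @param effect interaction effect size `s`.
#' @param maf1,maf2 minor allele frequencies (required for `"centered"`).
#' @param construction `"product"` or `"centered"`.
#' @param scale `"odds"` (default) or `"penetrance"`; `"centered"` is
#'   defined on the penetrance scale only.
#' @return 3x3 penetrance matrix.
#' @export
penetrance_interaction <- function(model1, model2, baseline, effect,
                                   maf1 = NULL, maf2 = NULL,
                                   construction = c("product", "centered"),
                                   scale = c("odds", "penetrance")) {
  construction <- match.arg(construction)
  scale <- match.arg(scale)
  m1 <- inheritance_model(model1)
  m2 <- inheritance_model(model2)
  if (construction == "product") {
    return(.apply_scale(outer(m1, m2), baseline, effect, scale))
  }
  if (is.null(maf1) || is.null(maf2)) {
    stop("the centered construction requires maf1 and maf2")
  }
  mu1 <- sum(hwe_genotype_freqs(maf1) * m1)
  mu2 <- sum(hwe_genotype_freqs(maf2) * m2)
  .apply_scale(outer(m1 - mu1, m2 - mu2), baseline, effect, "penetrance")
}

#' Genotype-based interaction penetrance table
#'
#' Applies baseline and effect to one of the cell-wise interaction masks of
#' [genotype_based_model()].
#'
#' @inheritParams penetrance_interaction
#' @param name genotype-based model name (e.g. `"XOR"`, `"Hyp"`, `"HR-HR"`).
#' @return 3x3 penetrance matrix.
#' @examples
#' penetrance_genotype_based("XOR", baseline = 0, effect = 1,
#'                           scale = "penetrance")
#' @export
penetrance_genotype_based <- function(name, baseline, effect,
                                      scale = c("odds", "penetrance")) {
  scale <- match.arg(scale)
  .apply_scale(genotype_based_model(name), baseline, effect, scale)
}

#' Largest admissible penetrance-scale effect
#'
#' For a given interaction mask and baseline, the largest effect `s` such
#' that all cells of `b + s * M` stay inside `[0, 1]`.  Used to express
#' penetrance-scale signal levels as fractions of their admissible maximum.
#'
#' @param mask 3x3 (or 3-vector) model mask.
#' @param baseline baseline risk.
#' @return the maximum effect (possibly `Inf` for an all-zero mask).
#' @export
max_admissible_effect <- function(mask, baseline) {
  up <- mask[mask > 0]
  dn <- mask[mask < 0]
  min(c(Inf,
        if (length(up)) (1 - baseline) / max(up),
        if (length(dn)) baseline / max(-dn)))
}

#' Enumerate the 29 SNP-SNP interaction models
#'
#' The catalogue used by the power study: the 15 unordered pairs of
#' REC/SUB/ADD/SUP/DOM, the 5 pairs of HET with each of those, and the 9
#' genotype-based models.  The pairwise HET x HET combination is not listed
#' separately because its product mask is identical to the genotype-based
#' `HET-HET` table (just as REC x REC coincides with `HA-HA`, which the
#' catalogue keeps in both forms).
#'
#' @return a data.frame with columns `name`, `type` (`"pairwise"`,
#'   `"het_pairwise"` or `"genotype_based"`), `model1`, `model2` (NA for
#'   genotype-based entries); 29 rows.
#' @export
enumerate_interaction_models <- function() {
  base5 <- c("REC", "SUB", "ADD", "SUP", "DOM")
  pw <- t(utils::combn(5, 2))
  pairs <- rbind(cbind(base5[pw[, 1]], base5[pw[, 2]]),
                 cbind(base5, base5))
  ord <- order(match(pairs[, 1], base5), match(pairs[, 2], base5))
  pairs <- pairs[ord, , drop = FALSE]
  het <- cbind("HET", base5)
  gb <- names(genotype_based_model())
  out <- rbind(
    data.frame(name = paste(pairs[, 1], pairs[, 2], sep = "x"),
               type = "pairwise", model1 = pairs[, 1], model2 = pairs[, 2],
               stringsAsFactors = FALSE),
    data.frame(name = paste(het[, 1], het[, 2], sep = "x"),
               type = "het_pairwise", model1 = het[, 1], model2 = het[, 2],
               stringsAsFactors = FALSE),
    data.frame(name = gb, type = "genotype_based",
               model1 = NA_character_, model2 = NA_character_,
               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Enumerate the main-effect-only models for the type-I-error study
#'
#' One-SNP models (each of REC/SUB/ADD/SUP/DOM/HET on SNP1 only) and
#' two-SNP models (all unordered pairs, with replacement, of those six),
#' optionally preceded by the null model (no effect on either SNP).
#'
#' @param include_null prepend the null model row (default `TRUE`).
#' @return data.frame with columns `name`, `type` (`"null"`, `"one_snp"`,
#'   `"two_snp"`), `model1`, `model2`.
#' @export
enumerate_main_effect_models <- function(include_null = TRUE) {
  base6 <- c("REC", "SUB", "ADD", "SUP", "DOM", "HET")
  one <- data.frame(name = paste0(base6, " only"), type = "one_snp",
                    model1 = base6, model2 = NA_character_,
                    stringsAsFactors = FALSE)
  idx <- which(upper.tri(diag(6), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  two <- data.frame(name = paste(base6[idx[, "row"]], base6[idx[, "col"]],
                                 sep = "x"),
                    type = "two_snp",
                    model1 = base6[idx[, "row"]], model2 = base6[idx[, "col"]],
                    stringsAsFactors = FALSE)
  out <- rbind(one, two)
  if (include_null) {
    out <- rbind(data.frame(name = "null", type = "null",
                            model1 = NA_character_, model2 = NA_character_,
                            stringsAsFactors = FALSE), out)
  }
  rownames(out) <- NULL
  out
}

#' Build the penetrance table for a catalogued model row
#'
#' Dispatcher used by the study runners: takes one row of
#' [enumerate_interaction_models()] or [enumerate_main_effect_models()] and
#' returns its penetrance table.
#'
#' @param spec a one-row data.frame (or list) with `name`, `type`,
#'   `model1`, `model2`.
#' @param baseline,effect,scale passed to the specific builder.
#' @param maf1,maf2 needed only for the centered interaction construction.
#' @param construction interaction construction (see
#'   [penetrance_interaction()]).
#' @return 3x3 penetrance matrix (the null model returns a constant table).
#' @export
build_model_penetrance <- function(spec, baseline, effect,
                                   scale = c("odds", "penetrance"),
                                   construction = c("product", "centered"),
                                   maf1 = NULL, maf2 = NULL) {
  scale <- match.arg(scale)
  construction <- match.arg(construction)
  type <- spec$type
  if (type == "null") {
    return(matrix(baseline, 3, 3))
  }
  if (type == "one_snp") {
    p1 <- penetrance_main_effect(spec$model1, baseline, effect, scale)
    return(matrix(p1, 3, 3))
  }
  if (type == "two_snp") {
    return(penetrance_two_main_effects(spec$model1, spec$model2,
                                       baseline, effect, scale))
  }
  if (type == "genotype_based") {
    return(penetrance_genotype_based(spec$name, baseline, effect, scale))
  }
  penetrance_interaction(spec$model1, spec$model2, baseline, effect,
                         maf1 = maf1, maf2 = maf2,
                         construction = construction, scale = scale)
}

## raw model mask (no baseline/effect applied); used for signal-level
## standardization relative to the admissible maximum
#' @noRd
.model_mask <- function(spec, construction = "product",
                        maf1 = NULL, maf2 = NULL) {
  switch(spec$type,
    null = matrix(0, 3, 3),
    one_snp = matrix(inheritance_model(spec$model1), 3, 3),
    two_snp = {
      m1 <- if (is.na(spec$model1)) rep(0, 3) else inheritance_model(spec$model1)
      m2 <- if (is.na(spec$model2)) rep(0, 3) else inheritance_model(spec$model2)
      outer(m1, rep(1, 3)) + outer(rep(1, 3), m2)
    },
    genotype_based = genotype_based_model(spec$name),
    {
      m1 <- inheritance_model(spec$model1)
      m2 <- inheritance_model(spec$model2)
      if (construction == "product") outer(m1, m2)
      else {
        mu1 <- sum(hwe_genotype_freqs(maf1) * m1)
        mu2 <- sum(hwe_genotype_freqs(maf2) * m2)
        outer(m1 - mu1, m2 - mu2)
      }
    })
}
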