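## Full-versus-reduced likelihood ratio testing of SNP-SNP interactions.
##
## For each encoding the reduced model carries both SNPs' main effects (and
## covariates), the full model adds the interaction term(s):
## one product column for the single-column encodings (1 df) and the four
## pairwise products of the dummy columns for codominant (4 df).  EDGE
## plugs the per-SNP alpha estimates in as fixed weights, so its
## interaction test also has 1 df.

#' @noRd
.encode_cols <- function(geno, scheme, alpha, prefix) {
  e <- encode_genotype(geno, scheme, alpha)
  if (is.matrix(e)) {
    colnames(e) <- paste0(prefix, "_", colnames(e))
    e
  } else {
    e <- matrix(e, ncol = 1, dimnames = list(NULL, prefix))
    e
  }
}

#' @noRd
.interaction_cols <- function(E1, E2) {
  out <- matrix(0, nrow(E1), ncol(E1) * ncol(E2))
  nms <- character(ncol(E1) * ncol(E2))
  k <- 0
  for (i in seq_len(ncol(E1))) for (j in seq_len(ncol(E2))) {
    k <- k + 1
    out[, k] <- E1[, i] * E2[, j]
    nms[k] <- paste0(colnames(E1)[i], "x", colnames(E2)[j])
  }
  colnames(out) <- nms
  out
}

#' @noRd
.coef_block <- function(fit, terms) {
  lapply(terms, function(tm) {
    list(beta = unname(fit$coef[tm]), se = unname(fit$se[tm]),
         p = unname(fit$p[tm]))
  })
}

#' Single-SNP association fit
#'
#' Regresses the phenotype on one encoded SNP (plus covariates).  For the
#' single-column encodings the per-term Wald p-value and a 1-df LRT against
#' the covariate-only model are both reported; for codominant the SNP
#' p-value is the 2-df LRT against the covariate-only model.
#'
#' @inheritParams estimate_alpha
#' @param scheme encoding scheme name.
#' @param alpha alpha estimate or numeric weight (EDGE only).
#' @return a list of class `snp_fit`: coefficient table, `lrt_stat`,
#'   `lrt_df`, `lrt_p`, `wald_p` (single-column schemes), log-likelihoods,
#'   `converged`, `n_used`, `n_cases`, `n_iter`.
#' @export
fit_single_snp <- function(geno, pheno, covariates = NULL,
                           scheme = EDGE_SCHEMES, alpha = NULL,
                           family = c("logistic", "linear")) {
  scheme <- match.arg(scheme)
  family <- match.arg(family)
  covmat <- .as_covmat(covariates, length(geno))
  ok <- .complete_rows(geno, pheno, covmat)
  g <- geno[ok]; y <- pheno[ok]
  cv <- if (is.null(covmat)) NULL else covmat[ok, , drop = FALSE]
  E <- .encode_cols(g, scheme, alpha, "Var1")
  X0 <- cbind(`(Intercept)` = rep(1, length(y)), cv)
  X1 <- cbind(X0, E)
  collapse <- is.null(cv)
  fit0 <- .fit_design(X0, y, family = family, collapse = collapse)
  fit1 <- .fit_design(X1, y, family = family, collapse = collapse)
  df <- fit1$rank - fit0$rank
  stat <- max(0, 2 * (fit1$ll - fit0$ll))
  converged <- fit0$converged && fit1$converged
  lrt_p <- if (converged && df > 0) {
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  } else NA_real_
  structure(list(
    scheme = scheme, family = family,
    coef = fit1$coef, se = fit1$se, wald_p = fit1$p,
    lrt_stat = stat, lrt_df = df, lrt_p = lrt_p,
    ll_model = fit1$ll, ll_null = fit0$ll,
    converged = converged, n_used = fit1$n_used,
    n_cases = if (family == "logistic") sum(y == 1) else NA_integer_,
    n_iter = fit1$n_iter), class = "snp_fit")
}

#' SNP-SNP interaction likelihood ratio test
#'
#' Fits the reduced model `Y ~ SNP1 + SNP2 [+ covariates]` and the full
#' model with the interaction term(s) added, under one encoding, and
#' compares them with a chi-square LRT (df = difference in model rank:
#' 1 for single-column encodings, 4 for codominant with all cells
#' populated).  The reported `pseudo_r2` is the increment in McFadden's
#' pseudo-R-squared (share of the intercept-only log-likelihood explained)
#' from the reduced to the full model.
#'
#' @param g1,g2 genotype vectors (minor-allele counts 0/1/2).
#' @param pheno,covariates,family as in [estimate_alpha()].
#' @param scheme encoding scheme used for both SNPs.
#' @param alpha1,alpha2 per-SNP alpha estimates (EDGE only).
#' @return an object of class `interaction_result`; see
#'   [as.data.frame.interaction_result()] for the flat output schema.
#' @export
lrt_interaction <- function(g1, g2, pheno, covariates = NULL,
                            scheme = EDGE_SCHEMES,
                            alpha1 = NULL, alpha2 = NULL,
                            family = c("logistic", "linear")) {
  scheme <- match.arg(scheme)
  family <- match.arg(family)
  covmat <- .as_covmat(covariates, length(g1))
  ok <- .complete_rows(g1, g2, pheno, covmat)
  g1 <- g1[ok]; g2 <- g2[ok]; y <- pheno[ok]
  cv <- if (is.null(covmat)) NULL else covmat[ok, , drop = FALSE]
  E1 <- .encode_cols(g1, scheme, alpha1, "Var1")
  E2 <- .encode_cols(g2, scheme, alpha2, "Var2")
  EI <- .interaction_cols(E1, E2)
  one <- rep(1, length(y))
  collapse <- is.null(cv)
  fit0 <- .fit_design(cbind(`(Intercept)` = one, cv), y,
                      family = family, collapse = collapse)
  fitR <- .fit_design(cbind(`(Intercept)` = one, E1, E2, cv), y,
                      family = family, collapse = collapse)
  fitF <- .fit_design(cbind(`(Intercept)` = one, E1, E2, EI, cv), y,
                      family = family, collapse = collapse)
  df <- fitF$rank - fitR$rank
  stat <- max(0, 2 * (fitF$ll - fitR$ll))
  converged <- fitR$converged && fitF$converged
  lrt_p <- if (!converged) NA_real_
           else if (df == 0) 1          # no parameters added: trivially null
           else stats::pchisq(stat, df = df, lower.tail = FALSE)
  if (converged && df == 0) stat <- 0
  denom <- abs(fit0$ll)
  pseudo_r2 <- if (denom > 0) (fitF$ll - fitR$ll) / denom else NA_real_
  structure(list(
    scheme = scheme, family = family,
    reduced = fitR, full = fitF,
    interaction_terms = colnames(EI),
    lrt_stat = stat, lrt_df = df, lrt_p = lrt_p,
    pseudo_r2 = pseudo_r2,
    red_model_p = if (fitR$converged)
      stats::pchisq(max(0, 2 * (fitR$ll - fit0$ll)),
                    df = max(fitR$rank - fit0$rank, 1),
                    lower.tail = FALSE) else NA_real_,
    full_model_p = if (fitF$converged)
      stats::pchisq(max(0, 2 * (fitF$ll - fit0$ll)),
                    df = max(fitF$rank - fit0$rank, 1),
                    lower.tail = FALSE) else NA_real_,
    converged = converged,
    n_used = fitF$n_used,
    n_cases = if (family == "logistic") sum(y == 1) else NA_integer_,
    n_iter = fitF$n_iter,
    alpha1 = if (inherits(alpha1, "alpha_estimate")) alpha1$alpha else alpha1,
    alpha2 = if (inherits(alpha2, "alpha_estimate")) alpha2$alpha else alpha2),
    class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat("SNP-SNP interaction LRT (", x$scheme, " encoding, ", x$family,
      " family)\n", sep = "")
  cat(sprintf("  LRT statistic %.4f on %d df, p = %.4g\n",
              x$lrt_stat, x$lrt_df, x$lrt_p))
  cat(sprintf("  pseudo-r2 increment %.3g; n = %d; converged: %s\n",
              x$pseudo_r2, x$n_used, x$converged))
  invisible(x)
}

#' EDGE interaction pipeline for one SNP pair
#'
#' Runs the full EDGE procedure on one dataset: estimate alpha per SNP from
#' main-effects-only codominant fits (before any interaction fitting),
#' encode both SNPs with their alphas, then run the interaction LRT.  An
#' undefined alpha on either SNP yields a flagged (non-converged) result
#' rather than an error.
#'
#' @inheritParams lrt_interaction
#' @return an `interaction_result`, with `alpha1`/`alpha2` recorded; when
#'   alpha estimation fails the result carries `converged = FALSE` and a
#'   missing LRT p-value.
#' @export
edge_interaction_pipeline <- function(g1, g2, pheno, covariates = NULL,
                                      family = c("logistic", "linear")) {
  family <- match.arg(family)
  a1 <- tryCatch(estimate_alpha(g1, pheno, covariates, family),
                 error = function(e) NULL)
  a2 <- tryCatch(estimate_alpha(g2, pheno, covariates, family),
                 error = function(e) NULL)
  ok1 <- !is.null(a1) && isTRUE(a1$alpha_defined)
  ok2 <- !is.null(a2) && isTRUE(a2$alpha_defined)
  if (!ok1 || !ok2) {
    return(structure(list(
      scheme = "edge", family = family, reduced = NULL, full = NULL,
      interaction_terms = character(), lrt_stat = NA_real_,
      lrt_df = NA_integer_, lrt_p = NA_real_, pseudo_r2 = NA_real_,
      red_model_p = NA_real_, full_model_p = NA_real_,
      converged = FALSE, n_used = sum(.complete_rows(g1, g2, pheno)),
      n_cases = NA_integer_, n_iter = NA_integer_,
      alpha1 = if (ok1) a1$alpha else NA_real_,
      alpha2 = if (ok2) a2$alpha else NA_real_),
      class = "interaction_result"))
  }
  lrt_interaction(g1, g2, pheno, covariates, scheme = "edge",
                  alpha1 = a1, alpha2 = a2, family = family)
}

#' Multiple-testing adjustment
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param method `"bonferroni"` (`min(1, p * n_tests)`) or `"fdr_bh"`
#'   (Benjamini-Hochberg step-up).
#' @param n_tests number of tests adjusted for; defaults to
#'   `length(pvals)`.
#' @return adjusted p-values.
#' @export
adjust_pvalues <- function(pvals, method = c("bonferroni", "fdr_bh"),
                           n_tests = length(pvals)) {
  method <- match.arg(method)
  stopifnot(all(is.na(pvals) | (pvals >= 0 & pvals <= 1)))
  if (method == "bonferroni") {
    pmin(1, pvals * n_tests)
  } else {
    stats::p.adjust(pvals, method = "BH", n = max(n_tests, length(pvals)))
  }
}

#' Flatten an interaction result to one table row
#'
#' Produces the flat record used by the interaction result writer, with
#' the reduced/full coefficient blocks (`Red_`/`Full_` beta, SE, p per SNP
#' term and `Full_Var1_Var2_*` for the interaction term; for codominant
#' the first dummy column of each block is reported).
#'
#' @param x an `interaction_result`.
#' @param row.names,optional,... standard [as.data.frame()] arguments
#'   (ignored).
#' @return a one-row data.frame.
#' @export
as.data.frame.interaction_result <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  pick <- function(fit, pat) {
    if (is.null(fit)) return(list(beta = NA_real_, se = NA_real_,
                                  p = NA_real_))
    idx <- grep(pat, names(fit$coef))
    if (!length(idx)) return(list(beta = NA_real_, se = NA_real_,
                                  p = NA_real_))
    i <- idx[1]
    list(beta = unname(fit$coef[i]), se = unname(fit$se[i]),
         p = unname(fit$p[i]))
  }
  r1 <- pick(x$reduced, "^Var1"); r2 <- pick(x$reduced, "^Var2")
  f1 <- pick(x$full, "^Var1(_het|_ha)?$"); f2 <- pick(x$full, "^Var2(_het|_ha)?$")
  fi <- pick(x$full, "xVar2")
  data.frame(
    Encoding = x$scheme,
    Num_nonMissing = x$n_used, Num_Cases = x$n_cases,
    N_Iter = x$n_iter, Converged = as.integer(x$converged),
    Raw_LRT_pval = x$lrt_p,
    Red_Var1_Pval = r1$p, Red_Var1_beta = r1$beta, Red_Var1_SE = r1$se,
    Red_Var2_Pval = r2$p, Red_Var2_beta = r2$beta, Red_Var2_SE = r2$se,
    Full_Var1_Pval = f1$p, Full_Var1_beta = f1$beta, Full_Var1_SE = f1$se,
    Full_Var2_Pval = f2$p, Full_Var2_beta = f2$beta, Full_Var2_SE = f2$se,
    Full_Var1_Var2_Pval = fi$p, Full_Var1_Var2_beta = fi$beta,
    Full_Var1_Var2_SE = fi$se,
    Red_model_Pval = x$red_model_p, Full_model_Pval = x$full_model_p,
    Overall_LRT_Pval = x$lrt_p,
    pseudo_r2 = x$pseudo_r2,
    alpha1 = if (is.null(x$alpha1)) NA_real_ else x$alpha1,
    alpha2 = if (is.null(x$alpha2)) NA_real_ else x$alpha2,
    stringsAsFactors = FALSE)
}

#' Run a single-encoding GWAS over a genotype matrix
#'
#' Applies [fit_single_snp()] to every SNP; for EDGE, alpha is estimated
#' per SNP first.  Rows for SNPs that fail preconditions are flagged, not
#' dropped.
#'
#' @param genotypes a [genotype_matrix()] or samples x SNPs 0/1/2 matrix.
#' @param pheno,covariates,family as in [estimate_alpha()].
#' @param scheme encoding scheme.
#' @param adjust_n number of tests used for the adjusted p-values
#'   (defaults to the number of SNPs).
#' @return data.frame with columns `Var1_ID`, `Var1_Pos`, `Var1_MAF`,
#'   `Num_nonMissing`, `Num_Cases`, `N_Iter`, `Converged`, `Raw_LRT_pval`,
#'   `Var1_Pval`, `Var1_beta`, `Overall_LRT_Pval`,
#'   `Overall_Pval_adj_Bonferroni`, `Overall_Pval_adj_FDR`.
#' @export
run_gwas <- function(genotypes, pheno, covariates = NULL,
                     scheme = EDGE_SCHEMES,
                     family = c("logistic", "linear"), adjust_n = NULL) {
  scheme <- match.arg(scheme)
  family <- match.arg(family)
  gm <- as_genotype_matrix(genotypes)
  n_snp <- ncol(gm$geno)
  rows <- vector("list", n_snp)
  for (j in seq_len(n_snp)) {
    g <- gm$geno[, j]
    info <- gm$snps[j, ]
    pos <- if (is.na(info$chrom)) NA_character_ else
      paste0(info$chrom, ":", info$pos)
    fit <- tryCatch({
      alpha <- if (scheme == "edge") {
        estimate_alpha(g, pheno, covariates, family)
      } else NULL
      fit_single_snp(g, pheno, covariates, scheme, alpha, family)
    }, error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      rows[[j]] <- data.frame(
        Var1_ID = info$id, Var1_Pos = pos, Var1_MAF = info$maf,
        Num_nonMissing = sum(!is.na(g)), Num_Cases = NA_integer_,
        N_Iter = NA_integer_, Converged = 0L, Raw_LRT_pval = NA_real_,
        Var1_Pval = NA_real_, Var1_beta = NA_real_,
        Overall_LRT_Pval = NA_real_, note = fit, stringsAsFactors = FALSE)
    } else {
      i <- grep("^Var1", names(fit$coef))[1]
      rows[[j]] <- data.frame(
        Var1_ID = info$id, Var1_Pos = pos, Var1_MAF = info$maf,
        Num_nonMissing = fit$n_used, Num_Cases = fit$n_cases,
        N_Iter = fit$n_iter, Converged = as.integer(fit$converged),
        Raw_LRT_pval = fit$lrt_p,
        Var1_Pval = unname(fit$wald_p[i]), Var1_beta = unname(fit$coef[i]),
        Overall_LRT_Pval = fit$lrt_p, note = "", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_tests <- if (is.null(adjust_n)) nrow(out) else adjust_n
  out$Overall_Pval_adj_Bonferroni <-
    adjust_pvalues(out$Overall_LRT_Pval, "bonferroni", n_tests)
  out$Overall_Pval_adj_FDR <-
    adjust_pvalues(out$Overall_LRT_Pval, "fdr_bh", n_tests)
  out
}

#' Interaction scan over candidate SNP pairs
#'
#' Runs [lrt_interaction()] (or the EDGE pipeline) for each pair under one
#' encoding and assembles the flat result table, including Bonferroni and
#' Benjamini-Hochberg adjusted LRT p-values over the scanned pairs.
#'
#' @param genotypes a [genotype_matrix()].
#' @param pairs data.frame with columns `snp1`, `snp2` (SNP ids), e.g. from
#'   [select_candidate_pairs()].
#' @param pheno,covariates,family as in [estimate_alpha()].
#' @param scheme encoding scheme.
#' @param adjust_n number of tests for the adjustment (defaults to
#'   `nrow(pairs)`).
#' @return data.frame, one row per pair, with SNP metadata, the flattened
#'   fit record and `Overall_Pval_adj_Bonferroni`/`Overall_Pval_adj_FDR`.
#' @export
run_interaction_scan <- function(genotypes, pairs, pheno, covariates = NULL,
                                 scheme = EDGE_SCHEMES,
                                 family = c("logistic", "linear"),
                                 adjust_n = NULL) {
  scheme <- match.arg(scheme)
  family <- match.arg(family)
  gm <- as_genotype_matrix(genotypes)
  idx <- function(id) {
    i <- match(id, gm$snps$id)
    if (is.na(i)) stop("SNP not found in genotype matrix: ", id)
    i
  }
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i1 <- idx(pairs$snp1[k]); i2 <- idx(pairs$snp2[k])
    g1 <- gm$geno[, i1]; g2 <- gm$geno[, i2]
    res <- if (scheme == "edge") {
      edge_interaction_pipeline(g1, g2, pheno, covariates, family)
    } else {
      tryCatch(lrt_interaction(g1, g2, pheno, covariates, scheme,
                               family = family),
               error = function(e) NULL)
    }
    meta <- data.frame(
      Var1_ID = gm$snps$id[i1],
      Var1_Pos = paste0(gm$snps$chrom[i1], ":", gm$snps$pos[i1]),
      Var1_MAF = gm$snps$maf[i1],
      Var2_ID = gm$snps$id[i2],
      Var2_Pos = paste0(gm$snps$chrom[i2], ":", gm$snps$pos[i2]),
      Var2_MAF = gm$snps$maf[i2], stringsAsFactors = FALSE)
    if (is.null(res)) {
      flat <- as.data.frame.interaction_result(structure(list(
        scheme = scheme, family = family, reduced = NULL, full = NULL,
        lrt_stat = NA_real_, lrt_df = NA_integer_, lrt_p = NA_real_,
        pseudo_r2 = NA_real_, red_model_p = NA_real_,
        full_model_p = NA_real_, converged = FALSE,
        n_used = NA_integer_, n_cases = NA_integer_, n_iter = NA_integer_,
        alpha1 = NULL, alpha2 = NULL), class = "interaction_result"))
    } else {
      flat <- as.data.frame(res)
    }
    rows[[k]] <- cbind(meta, flat)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_tests <- if (is.null(adjust_n)) nrow(out) else adjust_n
  out$Overall_Pval_adj_Bonferroni <-
    adjust_pvalues(out$Overall_LRT_Pval, "bonferroni", n_tests)
  out$Overall_Pval_adj_FDR <-
    adjust_pvalues(out$Overall_LRT_Pval, "fdr_bh", n_tests)
  out
}

#' Write an interaction result table as TSV
#'
#' @param results output of [run_interaction_scan()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
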