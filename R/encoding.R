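## Elastic data-driven genotype encoding (EDGE).
##
## A codominant (dummy) regression of the phenotype on indicator columns
## for the heterozygous and homozygous-alternate genotype classes gives
## coefficients beta_het and beta_ha measured against the
## homozygous-referent class.  Their ratio alpha = beta_het / beta_ha is
## the heterozygous risk expressed as a fraction of the homozygous
## alternate risk (scaled so the referent class is 0 and the alternate
## class 1).  Alpha is deliberately not clamped: values below 0
## (under-recessive) or above 1 (over-dominant) are legitimate estimates.

#' The five encoding scheme names
#' @export
EDGE_SCHEMES <- c("additive", "dominant", "recessive", "codominant", "edge")

#' @noRd
.het_weight <- function(scheme) {
  switch(scheme, additive = 0.5, dominant = 1, recessive = 0,
         stop("no fixed heterozygous weight for scheme: ", scheme))
}

#' Estimate the EDGE heterozygous weight for one SNP
#'
#' Fits the codominant dummy model
#' `Y ~ beta_het * I(g == 1) + beta_ha * I(g == 2) [+ covariates]` with the
#' homozygous-referent class as baseline (an intercept is included, so both
#' coefficients are deviations -- log odds for the logistic family -- from
#' the referent class) and returns `alpha = beta_het / beta_ha`.
#'
#' @param geno integer vector of minor-allele counts in `{0, 1, 2}`
#'   (`NA` allowed; complete cases are used).
#' @param pheno phenotype vector: 0/1 for `family = "logistic"`, numeric
#'   for `"linear"`.
#' @param covariates optional numeric matrix/data.frame of adjustment
#'   covariates, entered jointly with the dummy terms.
#' @param family `"logistic"` or `"linear"`.
#' @param tol degeneracy tolerance: `|beta_ha|` below this leaves alpha
#'   undefined (`NA`) to avoid division blow-up.
#' @return an object of class `alpha_estimate`: a list with `alpha`,
#'   `beta_het`, `beta_ha`, `se_het`, `se_ha`, `converged`, `n_used`,
#'   `n_iter` and `alpha_defined`.
#' @examples
#' g <- rep(0:2, c(50, 30, 20))
#' y <- c(rnorm(50, 0.1), rnorm(30, 0.3), rnorm(20, 0.5))
#' estimate_alpha(g, y, family = "linear")
#' @export
estimate_alpha <- function(geno, pheno, covariates = NULL,
                           family = c("logistic", "linear"), tol = 1e-8) {
  family <- match.arg(family)
  covmat <- .as_covmat(covariates, length(geno))
  ok <- .complete_rows(geno, pheno, covmat)
  g <- geno[ok]; y <- pheno[ok]
  if (!all(g %in% 0:2)) stop("genotypes must be coded 0/1/2")
  if (length(unique(g)) < 3) {
    stop("degenerate genotype distribution: all three genotype classes ",
         "must be observed")
  }
  if (length(unique(y)) < 2) stop("phenotype is constant")
  X <- cbind(`(Intercept)` = 1, het = as.numeric(g == 1),
             ha = as.numeric(g == 2))
  if (!is.null(covmat)) X <- cbind(X, covmat[ok, , drop = FALSE])
  fit <- .fit_design(X, y, family = family,
                     collapse = is.null(covmat))
  beta_het <- unname(fit$coef["het"])
  beta_ha <- unname(fit$coef["ha"])
  defined <- fit$converged && is.finite(beta_ha) && abs(beta_ha) >= tol
  structure(list(alpha = if (defined) beta_het / beta_ha else NA_real_,
                 beta_het = beta_het, beta_ha = beta_ha,
                 se_het = unname(fit$se["het"]),
                 se_ha = unname(fit$se["ha"]),
                 converged = fit$converged,
                 alpha_defined = defined,
                 n_used = fit$n_used, n_iter = fit$n_iter,
                 family = family),
            class = "alpha_estimate")
}

#' @export
print.alpha_estimate <- function(x, ...) {
  cat("EDGE alpha estimate (", x$family, " family)\n", sep = "")
  cat(sprintf("  alpha     %s\n",
              if (x$alpha_defined) format(x$alpha, digits = 4) else
                "undefined"))
  cat(sprintf("  beta_het  %8.4f (SE %.4f)\n", x$beta_het, x$se_het))
  cat(sprintf("  beta_ha   %8.4f (SE %.4f)\n", x$beta_ha, x$se_ha))
  cat(sprintf("  n = %d, converged: %s\n", x$n_used, x$converged))
  invisible(x)
}

#' Encode a genotype vector under a scheme
#'
#' Maps minor-allele counts `{0, 1, 2}` to numeric design values
#' `{0, w, 1}` with heterozygous weight `w` = 0.5 (additive), 1 (dominant),
#' 0 (recessive) or the estimated alpha (EDGE, passed through unclamped).
#' The codominant scheme returns the two indicator columns instead.
#' Missing genotypes map to missing.
#'
#' @param geno integer vector of minor-allele counts.
#' @param scheme one of `r paste0('"', EDGE_SCHEMES, '"', collapse = ", ")`.
#' @param alpha an [estimate_alpha()] result or a bare numeric weight;
#'   required for `scheme = "edge"`.
#' @return numeric vector, or a 2-column matrix (`het`, `ha`) for
#'   codominant.
#' @examples
#' encode_genotype(c(0, 1, 2), "additive")        # 0 0.5 1
#' encode_genotype(c(0, 1, 2), "edge", alpha = 0.25)
#' @export
encode_genotype <- function(geno, scheme = EDGE_SCHEMES, alpha = NULL) {
  scheme <- match.arg(scheme)
  bad <- !is.na(geno) & !geno %in% 0:2
  if (any(bad)) stop("genotypes must be coded 0/1/2 (or NA)")
  if (scheme == "codominant") {
    return(cbind(het = as.numeric(geno == 1), ha = as.numeric(geno == 2)))
  }
  if (scheme == "edge") {
    if (inherits(alpha, "alpha_estimate")) {
      if (!isTRUE(alpha$alpha_defined)) {
        stop("EDGE encoding requires a defined alpha estimate")
      }
      alpha <- alpha$alpha
    }
    if (is.null(alpha) || !is.finite(alpha)) {
      stop("EDGE encoding requires a supplied, defined alpha")
    }
    w <- alpha
  } else {
    w <- .het_weight(scheme)
  }
  out <- rep(NA_real_, length(geno))
  out[geno == 0] <- 0
  out[geno == 1] <- w
  out[geno == 2] <- 1
  out
}

#' Estimate alpha for every SNP of a genotype matrix
#'
#' Applies [estimate_alpha()] per SNP.  SNPs whose genotype distribution is
#' degenerate (a missing genotype class) or whose fit does not converge are
#' emitted as flagged rows, never dropped.
#'
#' @param genotypes a [genotype_matrix()] or a samples x SNPs numeric
#'   matrix of 0/1/2 dosages.
#' @param pheno,covariates,family as in [estimate_alpha()].
#' @return a data.frame with one row per SNP, mirroring the alpha
#'   ("categ_weight") output sheet: `Var1_ID`, `Var1_Pos`, `Var1_MAF`,
#'   `Num_nonMissing`, `Converged`, `categ_weight` (alpha), `beta_het`,
#'   `beta_ha`, `se_het`, `se_ha`, plus a `note` column for flagged SNPs.
#' @export
estimate_alpha_all <- function(genotypes, pheno, covariates = NULL,
                               family = c("logistic", "linear")) {
  family <- match.arg(family)
  gm <- as_genotype_matrix(genotypes)
  n_snp <- ncol(gm$geno)
  rows <- vector("list", n_snp)
  for (j in seq_len(n_snp)) {
    g <- gm$geno[, j]
    res <- tryCatch(estimate_alpha(g, pheno, covariates, family),
                    error = function(e) conditionMessage(e))
    info <- gm$snps[j, ]
    pos <- if (is.na(info$chrom)) NA_character_ else
      paste0(info$chrom, ":", info$pos)
    if (is.character(res)) {
      rows[[j]] <- data.frame(
        Var1_ID = info$id, Var1_Pos = pos, Var1_MAF = info$maf,
        Num_nonMissing = sum(!is.na(g)), Converged = 0L,
        categ_weight = NA_real_, beta_het = NA_real_, beta_ha = NA_real_,
        se_het = NA_real_, se_ha = NA_real_, note = res,
        stringsAsFactors = FALSE)
    } else {
      rows[[j]] <- data.frame(
        Var1_ID = info$id, Var1_Pos = pos, Var1_MAF = info$maf,
        Num_nonMissing = res$n_used,
        Converged = as.integer(res$converged),
        categ_weight = res$alpha, beta_het = res$beta_het,
        beta_ha = res$beta_ha, se_het = res$se_het, se_ha = res$se_ha,
        note = if (res$alpha_defined) "" else "alpha undefined",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an alpha table as TSV
#'
#' @param alpha_table output of [estimate_alpha_all()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alpha_table <- function(alpha_table, path) {
  utils::write.table(alpha_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
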