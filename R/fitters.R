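## Internal weighted-GLM core shared by the alpha estimator, the single-SNP
## association fits and the interaction LRT engine.  All models are fit on
## explicit design matrices; identical (row, response) combinations are
## collapsed to frequency weights, which leaves coefficients, standard
## errors and log-likelihood differences unchanged but makes genotype-only
## models (at most 18 distinct rows) essentially free to fit.

#' @noRd
.collapse_rows <- function(X, y, w) {
  key <- do.call(paste, c(as.data.frame(cbind(X, y)), sep = "\r"))
  if (length(unique(key)) > 64L) {
    return(list(X = X, y = y, w = w))
  }
  grp <- match(key, unique(key))
  first <- !duplicated(grp)
  list(X = X[first, , drop = FALSE],
       y = y[first],
       w = as.vector(tapply(w, grp, sum))[grp[first]])
}

## log-likelihood with frequency weights.  For the gaussian family the
## weights are interpreted as replicate counts and the MLE variance is used,
## so 2 * (ll1 - ll0) is the usual n*log(RSS0/RSS1) statistic.
#' @noRd
.ll_weighted <- function(y, mu, w, family) {
  if (family == "logistic") {
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
  } else {
    n <- sum(w)
    rss <- sum(w * (y - mu)^2)
    if (rss <= 0) rss <- .Machine$double.eps
    -n / 2 * (log(2 * pi * rss / n) + 1)
  }
}

#' Fit one regression model on an explicit design matrix
#'
#' Returns coefficients, standard errors, per-term Wald p-values, the
#' frequency-weighted log-likelihood, rank, iteration count and a
#' convergence flag.  Rows with any missing value must already be removed.
#'
#' @param X numeric design matrix (including the intercept column).
#' @param y response vector (0/1 for `family = "logistic"`).
#' @param w optional frequency weights (replicate counts).
#' @param family `"logistic"` or `"linear"`.
#' @param maxit,tol IRLS iteration cap and relative log-likelihood tolerance.
#' @noRd
.fit_design <- function(X, y, w = NULL, family = c("logistic", "linear"),
                        maxit = 100L, tol = 1e-8, collapse = TRUE) {
  family <- match.arg(family)
  if (is.null(w)) w <- rep.int(1, length(y))
  if (collapse && is.null(dim(w))) {
    cl <- .collapse_rows(X, y, w)
    X <- cl$X; y <- cl$y; w <- cl$w
  }
  fam <- if (family == "logistic") stats::binomial() else stats::gaussian()
  fit <- suppressWarnings(stats::glm.fit(
    X, y, weights = w, family = fam,
    control = stats::glm.control(epsilon = tol, maxit = maxit)))
  p <- ncol(X)
  rank <- fit$rank
  coefs <- fit$coefficients                      # NA for aliased terms
  piv <- fit$qr$pivot[seq_len(rank)]
  Rmat <- fit$qr$qr[seq_len(rank), seq_len(rank), drop = FALSE]
  cov_unscaled <- tryCatch(chol2inv(Rmat), error = function(e) NULL)
  se <- rep(NA_real_, p)
  if (!is.null(cov_unscaled)) {
    disp <- if (family == "logistic") 1
            else sum(w * fit$residuals^2) / max(sum(w) - rank, 1)
    se[piv] <- sqrt(pmax(diag(cov_unscaled), 0) * disp)
  }
  ll <- .ll_weighted(y, fit$fitted.values, w, family)
  finite_coefs <- coefs[!is.na(coefs)]
  converged <- isTRUE(fit$converged) && !isTRUE(fit$boundary) &&
    all(is.finite(finite_coefs)) &&
    (family == "linear" || max(abs(finite_coefs)) < 20)
  z <- coefs / se
  pvals <- 2 * stats::pnorm(-abs(z))
  names(coefs) <- names(se) <- names(pvals) <- colnames(X)
  list(coef = coefs, se = se, p = pvals, ll = ll, rank = rank,
       n_used = sum(w), n_iter = fit$iter, converged = converged,
       family = family)
}

## Remove rows with missing values across genotype columns, response and
## covariates (per-model listwise deletion); returns index of kept rows.
#' @noRd
.complete_rows <- function(...) {
  parts <- list(...)
  n <- NROW(parts[[1]])
  ok <- rep(TRUE, n)
  for (p in parts) {
    if (is.null(p)) next
    if (is.matrix(p) || is.data.frame(p)) {
      ok <- ok & stats::complete.cases(p)
    } else {
      ok <- ok & !is.na(p)
    }
  }
  ok
}

#' @noRd
.as_covmat <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  cm <- as.matrix(covariates)
  if (nrow(cm) != n) stop("covariates must have one row per sample")
  if (is.null(colnames(cm))) colnames(cm) <- paste0("cov", seq_len(ncol(cm)))
  storage.mode(cm) <- "double"
  cm
}
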