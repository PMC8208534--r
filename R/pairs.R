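## Candidate-pair selection for interaction scans of real datasets: the
## union of each encoding's top-K GWAS hits, expanded to all unordered
## pairs, plus region-window pair expansion for replication analyses.

#' Select candidate SNP pairs from multi-encoding GWAS results
#'
#' Takes the per-encoding GWAS result tables, keeps each encoding's
#' `top_k` SNPs by raw p-value (ties at the boundary p-value are all
#' included, so a list may exceed `top_k`), forms the union U of the
#' selected SNP ids, and returns all `choose(|U|, 2)` unordered pairs.
#'
#' @param gwas_results a single GWAS result data.frame or a (named) list
#'   of them, each with columns `Var1_ID` and `p_col`.
#' @param top_k SNPs kept per encoding (>= 1).
#' @param p_col p-value column used for ranking.
#' @return data.frame with columns `snp1`, `snp2` (lexicographic order
#'   within and across pairs); the union size is attached as
#'   `attr(, "n_union")`.
#' @export
select_candidate_pairs <- function(gwas_results, top_k = 50,
                                   p_col = "Overall_LRT_Pval") {
  stopifnot(top_k >= 1)
  if (is.data.frame(gwas_results)) gwas_results <- list(gwas_results)
  if (!length(gwas_results)) stop("at least one GWAS result table needed")
  selected <- character(0)
  for (res in gwas_results) {
    if (!all(c("Var1_ID", p_col) %in% names(res))) {
      stop("GWAS results need columns Var1_ID and ", p_col)
    }
    res <- res[!is.na(res[[p_col]]), , drop = FALSE]
    ## deterministic ranking: p-value, then SNP id lexicographically
    res <- res[order(res[[p_col]], res$Var1_ID), , drop = FALSE]
    if (nrow(res) <= top_k) {
      selected <- c(selected, res$Var1_ID)
      next
    }
    cut <- res[[p_col]][top_k]
    selected <- c(selected, res$Var1_ID[res[[p_col]] <= cut])
  }
  u <- sort(unique(selected))
  if (length(u) < 2) {
    out <- data.frame(snp1 = character(0), snp2 = character(0),
                      stringsAsFactors = FALSE)
  } else {
    cmb <- utils::combn(u, 2)
    out <- data.frame(snp1 = cmb[1, ], snp2 = cmb[2, ],
                      stringsAsFactors = FALSE)
  }
  attr(out, "n_union") <- length(u)
  out
}

#' Expand a SNP pair to all pairs within a region window
#'
#' Returns every cross pair (s1', s2') such that s1' lies within
#' `window_bp` (inclusive, same chromosome) of the first anchor SNP and
#' s2' within `window_bp` of the second.  Used for region-based
#' replication; the Bonferroni denominator for that analysis is the
#' number of returned pairs.
#'
#' @param snp1,snp2 anchor SNP ids.
#' @param snps SNP metadata data.frame (`id`, `chrom`, `pos`), e.g.
#'   `gm$snps`.
#' @param window_bp window half-width in base pairs (>= 0).
#' @return data.frame with columns `snp1`, `snp2`.
#' @export
region_pairs <- function(snp1, snp2, snps, window_bp = 50000) {
  stopifnot(window_bp >= 0)
  anchor <- function(id) {
    i <- match(id, snps$id)
    if (is.na(i)) stop("anchor SNP not found: ", id)
    snps[i, ]
  }
  a1 <- anchor(snp1); a2 <- anchor(snp2)
  near <- function(a) {
    hit <- !is.na(snps$chrom) & snps$chrom == a$chrom &
      abs(snps$pos - a$pos) <= window_bp
    snps$id[hit]
  }
  s1 <- near(a1); s2 <- near(a2)
  if (!length(s1) || !length(s2)) {
    message("region_pairs: empty window around ",
            if (!length(s1)) snp1 else snp2)
    return(data.frame(snp1 = character(0), snp2 = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- expand.grid(snp1 = s1, snp2 = s2, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out <- out[out$snp1 != out$snp2, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write an analysis configuration (YAML)
#'
#' A light wrapper around YAML with the analysis defaults filled in:
#' encodings, top-K main-effect filter, region window, adjustment method
#' and seed.
#'
#' @param path YAML file path.
#' @return a named list of configuration values.
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(encodings = EDGE_SCHEMES, top_k = 50,
                   window_bp = 50000, adjustment = "bonferroni", seed = 1)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (cfg$top_k < 1) stop("top_k must be >= 1")
  if (cfg$window_bp < 0) stop("window_bp must be >= 0")
  cfg
}

#' @rdname read_analysis_config
#' @param config configuration list to write.
#' @export
write_analysis_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
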