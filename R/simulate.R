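## Case-control dataset simulator for one or two independent biallelic SNPs
## in Hardy-Weinberg equilibrium.  Sampling is retrospective: genotype
## (pairs) are drawn conditional on case/control status, which controls the
## case:control ratio exactly and is equivalent in distribution to
## prospective simulation followed by subsampling to the ratio (the
## prospective sampler is kept in the test suite as an oracle).

#' Simulation configuration
#'
#' Collects the sampling parameters for [sample_dataset()] and
#' [replicate_study()], with the study defaults filled in.
#'
#' @param n_samples total sample size.
#' @param maf minor allele frequency; recycled to both SNPs, or length 2.
#' @param case_control_ratio cases per control (1 is balanced, 1/3 means
#'   one case per three controls).
#' @param baseline baseline risk used when a penetrance must be rebuilt.
#' @param n_replicates number of replicate datasets.
#' @param seed integer master seed, or `NULL` to use the current RNG state.
#' @param trait `"binary"` (case-control) or `"quantitative"`.
#' @param noise_sd residual standard deviation for quantitative traits.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 2000, maf = 0.3, case_control_ratio = 1,
                       baseline = 0.1, n_replicates = 1000, seed = NULL,
                       trait = c("binary", "quantitative"), noise_sd = 1) {
  trait <- match.arg(trait)
  stopifnot(n_samples >= 2, case_control_ratio > 0)
  maf <- rep_len(maf, 2)
  structure(list(n_samples = as.integer(n_samples), maf = maf,
                 case_control_ratio = case_control_ratio,
                 baseline = baseline, n_replicates = as.integer(n_replicates),
                 seed = seed, trait = trait, noise_sd = noise_sd),
            class = "sim_config")
}

#' @noRd
.case_control_split <- function(n, ratio) {
  n_cases <- round(n * ratio / (1 + ratio))
  n_cases <- min(max(n_cases, 1L), n - 1L)
  c(cases = as.integer(n_cases), controls = as.integer(n - n_cases))
}

#' Retrospective genotype-pair counts
#'
#' Draws genotype-pair counts for cases and controls under a penetrance
#' table.  Cases are drawn from `f1(g1) f2(g2) pen(g1,g2) / P(case)` and
#' controls from `f1 f2 (1 - pen) / (1 - P(case))`, with `f` the HWE
#' genotype frequencies.
#'
#' @param pen 3x3 penetrance matrix, or 3-vector for a single SNP.
#' @param maf1,maf2 minor allele frequencies.
#' @param n_cases,n_controls counts to draw.
#' @return a list with `cases` and `controls` count tables shaped like
#'   `pen`, plus the population `prevalence`.
#' @export
sample_genotype_counts <- function(pen, maf1, maf2 = NULL,
                                   n_cases, n_controls) {
  single <- is.null(dim(pen))
  f <- if (single) hwe_genotype_freqs(maf1)
       else outer(hwe_genotype_freqs(maf1), hwe_genotype_freqs(maf2))
  stopifnot(length(f) == length(pen))
  pc <- as.vector(f * pen)
  pk <- as.vector(f * (1 - pen))
  if (n_cases > 0 && sum(pc) <= 0) {
    stop("penetrance is identically 0: requested cases unattainable")
  }
  if (n_controls > 0 && sum(pk) <= 0) {
    stop("penetrance is identically 1: requested controls unattainable")
  }
  shape <- function(x) if (single) x else matrix(x, 3, 3)
  list(cases = shape(stats::rmultinom(1, n_cases, pc)[, 1]),
       controls = shape(stats::rmultinom(1, n_controls, pk)[, 1]),
       prevalence = sum(f * pen))
}

#' @noRd
.expand_counts <- function(counts, single) {
  if (single) {
    g1 <- rep.int(0:2, counts)
    cbind(SNP1 = g1)
  } else {
    idx <- rep.int(seq_len(9), as.vector(counts))
    cbind(SNP1 = (idx - 1) %% 3, SNP2 = (idx - 1) %/% 3)
  }
}

#' Simulate one case-control (or quantitative-trait) dataset
#'
#' @param pen penetrance table: 3-vector (one SNP) or 3x3 matrix (two SNPs).
#'   For a quantitative trait the table is read as the genotype mean.
#' @param config a [sim_config()].
#' @return a data.frame with `sample_id`, `SNP1` (and `SNP2`) minor-allele
#'   counts, and `status` (0/1) or `trait`.
#' @export
sample_dataset <- function(pen, config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  single <- is.null(dim(pen))
  n <- config$n_samples
  if (config$trait == "quantitative") {
    f1 <- hwe_genotype_freqs(config$maf[1])
    g1 <- sample.int(3, n, replace = TRUE, prob = f1) - 1L
    if (single) {
      mu <- pen[g1 + 1]
      d <- data.frame(sample_id = seq_len(n), SNP1 = g1)
    } else {
      f2 <- hwe_genotype_freqs(config$maf[2])
      g2 <- sample.int(3, n, replace = TRUE, prob = f2) - 1L
      mu <- pen[cbind(g1 + 1, g2 + 1)]
      d <- data.frame(sample_id = seq_len(n), SNP1 = g1, SNP2 = g2)
    }
    d$trait <- mu + stats::rnorm(n, sd = config$noise_sd)
    return(d)
  }
  split <- .case_control_split(n, config$case_control_ratio)
  cnt <- sample_genotype_counts(pen, config$maf[1], config$maf[2],
                                split["cases"], split["controls"])
  g <- rbind(.expand_counts(cnt$cases, single),
             .expand_counts(cnt$controls, single))
  status <- rep(c(1L, 0L), split)
  ord <- sample.int(nrow(g))
  d <- data.frame(sample_id = seq_len(nrow(g)), g[ord, , drop = FALSE],
                  status = status[ord])
  rownames(d) <- NULL
  d
}

#' Derive independent replicate seeds from a master seed
#'
#' @param master_seed integer master seed.
#' @param n number of replicate seeds.
#' @return integer vector of `n` seeds in `[1, 2^31 - 1]`.
#' @export
replicate_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max, n)
}

#' Simulate a set of replicate datasets
#'
#' Each replicate gets its own seed derived deterministically from the
#' master seed in `config$seed`, so the study is reproducible and
#' replicates are mutually independent.
#'
#' @inheritParams sample_dataset
#' @return a list of `config$n_replicates` data.frames.
#' @export
replicate_study <- function(pen, config = sim_config()) {
  master <- if (is.null(config$seed)) sample.int(.Machine$integer.max, 1)
            else config$seed
  seeds <- replicate_seeds(master, config$n_replicates)
  lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    sample_dataset(pen, cfg)
  })
}

#' Write a simulated dataset and its manifest
#'
#' The dataset is written as TSV; the manifest (JSON) records the full
#' penetrance table, MAFs, sample sizes and seed so a replicate set is
#' self-describing.
#'
#' @param dataset data.frame from [sample_dataset()].
#' @param path output TSV path.
#' @param pen,config the generating penetrance and configuration; when
#'   given, a manifest is written next to `path` with suffix
#'   `.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, pen = NULL, config = NULL) {
  utils::write.table(dataset, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(pen) || !is.null(config)) {
    manifest <- list(penetrance = pen, config = unclass(config))
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
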