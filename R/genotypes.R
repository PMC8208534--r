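## Genotype matrix container and readers/writers.
##
## Genotypes are stored as a dense samples x SNPs integer matrix of
## minor-allele counts (0/1/2, NA for missing).  Minor-allele orientation
## is recomputed from the data at load time: SNPs whose coded allele
## frequency exceeds 0.5 are flipped (0 <-> 2) so the coded (alternate)
## allele is always the minor allele; an exact 0.5 tie keeps the input's
## ALT allele as coded allele.

#' Construct a genotype matrix
#'
#' @param geno samples x SNPs matrix of allele counts 0/1/2 (NA allowed).
#' @param snps optional SNP metadata data.frame with columns `id`,
#'   `chrom`, `pos` (1-based bp) and optionally `ref`, `alt`; defaults are
#'   derived from column names.
#' @param samples optional sample ids (default: row names or `S1..Sn`).
#' @param orient recompute minor-allele orientation (default `TRUE`).
#' @return an object of class `genotype_matrix`: a list with `geno`,
#'   `snps` (including recomputed `maf` and a `flipped` flag) and
#'   `samples`.
#' @export
genotype_matrix <- function(geno, snps = NULL, samples = NULL,
                            orient = TRUE) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (!all(geno %in% c(0L, 1L, 2L, NA))) {
    stop("genotypes must be coded 0/1/2 or NA")
  }
  if (is.null(samples)) {
    samples <- rownames(geno)
    if (is.null(samples)) samples <- paste0("S", seq_len(nrow(geno)))
  }
  if (is.null(snps)) {
    ids <- colnames(geno)
    if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(geno)))
    snps <- data.frame(id = ids, chrom = NA_character_, pos = NA_integer_,
                       stringsAsFactors = FALSE)
  }
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (!"chrom" %in% names(snps)) snps$chrom <- NA_character_
  if (!"pos" %in% names(snps)) snps$pos <- NA_integer_
  stopifnot(nrow(snps) == ncol(geno), length(samples) == nrow(geno))
  freq <- colMeans(geno, na.rm = TRUE) / 2
  flipped <- rep(FALSE, ncol(geno))
  if (orient) {
    flip <- !is.na(freq) & freq > 0.5
    if (any(flip)) {
      geno[, flip] <- 2L - geno[, flip]
      freq[flip] <- 1 - freq[flip]
      flipped <- flip
    }
  }
  snps$maf <- unname(freq)
  snps$flipped <- unname(flipped)
  rownames(geno) <- samples
  colnames(geno) <- snps$id
  structure(list(geno = geno, snps = snps, samples = samples),
            class = "genotype_matrix")
}

#' Coerce to a genotype matrix
#'
#' @param x a `genotype_matrix` (returned unchanged) or a bare matrix.
#' @param ... passed to [genotype_matrix()].
#' @export
as_genotype_matrix <- function(x, ...) {
  if (inherits(x, "genotype_matrix")) return(x)
  genotype_matrix(x, ...)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "samples x", ncol(x$geno),
      "SNPs\n")
  cat("  MAF range:", paste(signif(range(x$snps$maf, na.rm = TRUE), 3),
                            collapse = " - "), "\n")
  cat("  missing calls:", sum(is.na(x$geno)), "\n")
  invisible(x)
}

#' Read genotypes from TSV, VCF or PLINK bed/bim/fam
#'
#' * `tsv`: a header line of SNP ids, then one row per sample
#'   (`sample_id` first column), values 0/1/2 or NA.
#' * `vcf`: biallelic SNVs; the GT field is converted to ALT-allele
#'   counts.  Multi-allelic records are skipped; the number skipped is
#'   available as `attr(x, "n_skipped")`.
#' * `plink`: binary SNP-major `.bed` plus `.bim`/`.fam` (pass the `.bed`
#'   path or the prefix).
#'
#' All formats return a minor-allele-oriented [genotype_matrix()].
#'
#' @param path input path.
#' @param format `"tsv"`, `"vcf"` or `"plink"` (default: by extension).
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf", "plink")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf"
              else if (grepl("\\.bed$", path) || file.exists(paste0(path, ".bed"))) "plink"
              else "tsv"
  }
  switch(format,
         tsv = .read_genotypes_tsv(path),
         vcf = .read_genotypes_vcf(path),
         plink = read_plink(path))
}

#' @noRd
.read_genotypes_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (!ncol(d) >= 2) stop("genotype TSV needs a sample id column and at ",
                          "least one SNP column: ", path)
  geno <- as.matrix(d[, -1, drop = FALSE])
  rownames(geno) <- as.character(d[[1]])
  genotype_matrix(geno)
}

#' @noRd
.read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = dimnames(vcfR::getFIX(v)))
  multi <- grepl(",", fix[, "ALT"])
  n_skipped <- sum(multi)
  if (n_skipped > 0) {
    warning(n_skipped, " multi-allelic record(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | x %in% c(".", "./.", ".|."), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", x), "/"),
                  function(a) sum(a == "1"), integer(1)))
  }
  geno <- t(apply(gt, 1, count_alt))
  geno <- t(geno)                       # samples x SNPs
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  snps <- data.frame(id = ids, chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  out <- genotype_matrix(geno, snps = snps,
                         samples = colnames(gt))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write genotypes as TSV
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(gm, path) {
  gm <- as_genotype_matrix(gm)
  d <- data.frame(sample_id = gm$samples, gm$geno, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- PLINK binary (.bed/.bim/.fam), SNP-major ----
## 2-bit codes per genotype: 00 = hom alternate (2 copies of allele 1),
## 01 = missing, 10 = het, 11 = hom referent.  Allele 1 in the .bim is the
## coded (alternate) allele.  No R package in the dependency set reads
## .bed, so a minimal reader/writer is implemented here and round-trip
## tested.

#' @noRd
.plink_prefix <- function(path) sub("\\.(bed|bim|fam)$", "", path)

#' Read a PLINK bed/bim/fam fileset
#'
#' @param path the `.bed` path or the fileset prefix.
#' @return a minor-allele-oriented [genotype_matrix()].
#' @export
read_plink <- function(path) {
  prefix <- .plink_prefix(path)
  bed <- paste0(prefix, ".bed")
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos",
                                         "a1", "a2"))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed, "raw", n = 3 + ceiling(n / 4) * m)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK .bed file: ", bed)
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed files supported")
  body <- raw[-(1:3)]
  bpv <- ceiling(n / 4)
  geno <- matrix(NA_integer_, n, m)
  ## decode 2-bit fields: 0b00 -> 2 copies of a1, 0b10 -> 1, 0b11 -> 0,
  ## 0b01 -> missing
  lut <- c(2L, NA_integer_, 1L, 0L)     # codes 0b00, 0b01, 0b10, 0b11
  for (j in seq_len(m)) {
    bytes <- as.integer(body[((j - 1) * bpv + 1):(j * bpv)])
    ## four 2-bit fields per byte, least significant first
    codes <- as.vector(rbind(bytes %% 4L, (bytes %/% 4L) %% 4L,
                             (bytes %/% 16L) %% 4L, bytes %/% 64L))
    geno[, j] <- lut[codes[seq_len(n)] + 1L]
  }
  snps <- data.frame(id = bim$id, chrom = as.character(bim$chrom),
                     pos = as.integer(bim$pos), ref = bim$a2, alt = bim$a1,
                     stringsAsFactors = FALSE)
  genotype_matrix(geno, snps = snps, samples = as.character(fam$V2))
}

#' Write a PLINK bed/bim/fam fileset
#'
#' Writes the matrix SNP-major with allele 1 as the coded allele.
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output prefix (creates `prefix.bed/.bim/.fam`).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(gm, prefix) {
  gm <- as_genotype_matrix(gm)
  n <- nrow(gm$geno); m <- ncol(gm$geno)
  bim <- data.frame(
    chrom = ifelse(is.na(gm$snps$chrom), "0", gm$snps$chrom),
    id = gm$snps$id, cm = 0,
    pos = ifelse(is.na(gm$snps$pos), 0L, gm$snps$pos),
    a1 = if ("alt" %in% names(gm$snps)) gm$snps$alt else "A",
    a2 = if ("ref" %in% names(gm$snps)) gm$snps$ref else "B")
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = gm$samples, iid = gm$samples, pat = 0, mat = 0,
                    sex = 0, phe = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  code <- matrix(1L, n, m)                      # 0b01 missing
  code[which(gm$geno == 2L)] <- 0L
  code[which(gm$geno == 1L)] <- 2L
  code[which(gm$geno == 0L)] <- 3L
  bpv <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- matrix(0L, bpv * 4, m)
  pad[seq_len(n), ] <- code
  packed <- pad[seq(1, 4 * bpv, by = 4), , drop = FALSE] +
    4L * pad[seq(2, 4 * bpv, by = 4), , drop = FALSE] +
    16L * pad[seq(3, 4 * bpv, by = 4), , drop = FALSE] +
    64L * pad[seq(4, 4 * bpv, by = 4), , drop = FALSE]
  writeBin(as.raw(packed), con)
  invisible(prefix)
}
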