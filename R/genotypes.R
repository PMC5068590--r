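#' Construct a genotype dosage matrix
#'
#' Holds a samples x variants matrix of allele-b dosages in \[0, 2\]
#' (fractional values allowed for imputed data, `NA` for missing) together
#' with per-variant metadata. Dosages always count copies of `allele_b`.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `allele_a`, `allele_b`.
#' @param sample_ids character vector of unique sample identifiers.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, sample_ids) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (ncol(dosages) != nrow(variants)) {
    stop("variant metadata length must equal matrix width", call. = FALSE)
  }
  if (nrow(dosages) != length(sample_ids)) {
    stop("sample_ids length must equal matrix height", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique", call. = FALSE)
  if (anyDuplicated(variants$variant_id)) {
    stop("variant ids must be unique", call. = FALSE)
  }
  rng <- range(dosages, na.rm = TRUE)
  if (!all(is.na(dosages)) && (rng[1] < 0 || rng[2] > 2)) {
    stop("dosages must lie in [0, 2] or be NA", call. = FALSE)
  }
  needed <- c("variant_id", "chrom", "pos", "allele_a", "allele_b")
  if (!all(needed %in% names(variants))) {
    stop("variants must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  variants <- as.data.frame(variants)[, needed]
  variants$variant_id <- as.character(variants$variant_id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  dimnames(dosages) <- list(as.character(sample_ids), variants$variant_id)
  structure(
    list(dosages = dosages, variants = variants,
         sample_ids = as.character(sample_ids)),
    class = "genotype_matrix"
  )
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d missing entries)\n",
              nrow(x$dosages), ncol(x$dosages), sum(is.na(x$dosages))))
  invisible(x)
}

#' Allele-b frequencies from non-missing dosages
#'
#' @param gm a `genotype_matrix`.
#' @return Numeric vector of allele-b frequencies (mean dosage / 2), one per
#'   variant; `NaN` where a variant has no non-missing calls.
#' @export
allele_frequencies <- function(gm) {
  colMeans(gm$dosages, na.rm = TRUE) / 2
}

#' Read a genotype dosage matrix
#'
#' Supported formats: `"tsv"` (plain dosage matrix: columns `variant_id`,
#' `chrom`, `pos`, `allele_a`, `allele_b`, then one column per sample, one
#' row per variant); `"vcf"` (plain-text VCF, dosages from the `DS` FORMAT
#' field when present, otherwise counted from `GT`; requires the
#' VariantAnnotation package); `"plink"` (binary .bed/.bim/.fam trio,
#' SNP-major; `path` may be the prefix or the .bed file). Hard calls and
#' fractional imputed dosages are both accepted; missing entries are kept
#' as `NA`, never zero-filled.
#'
#' @param path input path (or PLINK prefix).
#' @param format one of `"tsv"`, `"vcf"`, `"plink"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf", "plink")) {
  format <- match.arg(format)
  switch(format,
    tsv = read_genotypes_tsv(path),
    vcf = read_genotypes_vcf(path),
    plink = read_genotypes_plink(path)
  )
}

read_genotypes_tsv <- function(path) {
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           na.strings = c("NA", "."))
  meta_cols <- c("variant_id", "chrom", "pos", "allele_a", "allele_b")
  if (!all(meta_cols %in% names(raw))) {
    stop("dosage TSV must start with columns ",
         paste(meta_cols, collapse = ", "), call. = FALSE)
  }
  samples <- setdiff(names(raw), meta_cols)
  if (!length(samples)) stop("dosage TSV has no sample columns", call. = FALSE)
  d <- t(as.matrix(raw[, samples, drop = FALSE]))
  genotype_matrix(d, raw[, meta_cols], samples)
}

#' Write a genotype matrix
#'
#' Inverse of [read_genotypes()] for each format. PLINK .bed files store
#' hard calls only, so writing `format = "plink"` errors on fractional
#' dosages. VCF output always carries a `DS` field and a `GT` field
#' (hard-call genotypes where the dosage is integral, `./.` otherwise).
#'
#' @param gm a `genotype_matrix`.
#' @param path output path (PLINK prefix for `format = "plink"`).
#' @param format one of `"tsv"`, `"vcf"`, `"plink"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("tsv", "vcf", "plink")) {
  format <- match.arg(format)
  switch(format,
    tsv = write_genotypes_tsv(gm, path),
    vcf = write_genotypes_vcf(gm, path),
    plink = write_genotypes_plink(gm, path)
  )
  invisible(path)
}

write_genotypes_tsv <- function(gm, path) {
  out <- cbind(gm$variants, as.data.frame(t(gm$dosages)))
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
}

# ---- VCF ------------------------------------------------------------------

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("VCF input requires the VariantAnnotation package", call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  if (any(lengths(alt) != 1)) {
    stop("only biallelic VCF records are supported", call. = FALSE)
  }
  variants <- data.frame(
    variant_id = names(rr),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    allele_a = as.character(VariantAnnotation::ref(vcf)),
    allele_b = as.character(unlist(alt)),
    stringsAsFactors = FALSE
  )
  g <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(g)) {
    d <- t(matrix(as.numeric(g$DS), nrow = nrow(g$DS)))
    samp <- colnames(g$DS)
  } else if ("GT" %in% names(g)) {
    gt <- g$GT
    cnt <- vapply(strsplit(gsub("\\|", "/", as.vector(gt)), "/"),
                  function(a) {
                    if (any(a == ".")) return(NA_real_)
                    sum(a == "1")
                  }, numeric(1))
    d <- t(matrix(cnt, nrow = nrow(gt)))
    samp <- colnames(gt)
  } else {
    stop("VCF has neither DS nor GT genotype fields", call. = FALSE)
  }
  genotype_matrix(d, variants, samp)
}

write_genotypes_vcf <- function(gm, path) {
  n <- nrow(gm$dosages)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t")
  )
  gt_of <- function(d) {
    out <- rep("./.", length(d))
    hard <- !is.na(d) & d == round(d)
    out[hard & d == 0] <- "0/0"
    out[hard & d == 1] <- "0/1"
    out[hard & d == 2] <- "1/1"
    out
  }
  rows <- vapply(seq_len(ncol(gm$dosages)), function(j) {
    d <- gm$dosages[, j]
    ds <- ifelse(is.na(d), ".", formatC(d, format = "g", digits = 8))
    cell <- paste(gt_of(d), ds, sep = ":")
    v <- gm$variants[j, ]
    paste(c(v$chrom, v$pos, v$variant_id, v$allele_a, v$allele_b, ".", ".",
            ".", "GT:DS", cell), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
}

# ---- PLINK binary ---------------------------------------------------------

# .bed is SNP-major: per variant, ceil(n/4) bytes, two bits per sample:
# 00 = homozygous A1, 01 = missing, 10 = heterozygous, 11 = homozygous A2.
# We map A1 -> allele_b so dosage counts A1 copies (the allele PLINK scores).
plink_lut <- function() {
  codes <- c(2, NA, 1, 0)  # indexed by 2-bit value 0..3
  t(vapply(0:255, function(b) {
    codes[c(bitwAnd(b, 3L), bitwAnd(bitwShiftR(b, 2L), 3L),
            bitwAnd(bitwShiftR(b, 4L), 3L), bitwAnd(bitwShiftR(b, 6L), 3L)) + 1L]
  }, numeric(4)))
}

plink_prefix <- function(path) sub("\\.bed$", "", path)

read_genotypes_plink <- function(path) {
  prefix <- plink_prefix(path)
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop("missing PLINK file: ", f, call. = FALSE)
  }
  bim_df <- data.table::fread(bim, header = FALSE, data.table = FALSE)
  names(bim_df) <- c("chrom", "variant_id", "cm", "pos", "a1", "a2")
  fam_df <- data.table::fread(fam, header = FALSE, data.table = FALSE)
  samples <- as.character(fam_df[[2]])
  n <- length(samples)
  m <- nrow(bim_df)
  bpv <- ceiling(n / 4)
  con <- file(bed, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(108L, 27L, 1L))) {
    stop("not a SNP-major PLINK .bed file: ", bed, call. = FALSE)
  }
  bytes <- readBin(con, "raw", bpv * m)
  if (length(bytes) < bpv * m) {
    stop("truncated .bed: sample/variant count mismatch", call. = FALSE)
  }
  lut <- plink_lut()
  idx <- matrix(as.integer(bytes) + 1L, nrow = bpv)
  d <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    vals <- as.vector(t(lut[idx[, j], , drop = FALSE]))
    d[, j] <- vals[seq_len(n)]
  }
  variants <- data.frame(
    variant_id = bim_df$variant_id, chrom = as.character(bim_df$chrom),
    pos = bim_df$pos, allele_a = bim_df$a2, allele_b = bim_df$a1,
    stringsAsFactors = FALSE
  )
  genotype_matrix(d, variants, samples)
}

write_genotypes_plink <- function(gm, prefix) {
  d <- gm$dosages
  if (any(!is.na(d) & d != round(d))) {
    stop("PLINK .bed stores hard calls only; fractional dosages present",
         call. = FALSE)
  }
  n <- nrow(d)
  m <- ncol(d)
  fam <- data.frame(gm$sample_ids, gm$sample_ids, 0, 0, 0, -9)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t",
                     col.names = FALSE)
  bim <- data.frame(gm$variants$chrom, gm$variants$variant_id, 0,
                    gm$variants$pos, gm$variants$allele_b,
                    gm$variants$allele_a)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t",
                     col.names = FALSE)
  code_of <- c(`2` = 0L, `1` = 2L, `0` = 3L)  # dosage -> 2-bit code
  bpv <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(m)) {
    codes <- rep(1L, bpv * 4)  # pad with "missing"
    dj <- d[, j]
    codes[seq_len(n)] <- ifelse(is.na(dj), 1L,
                                code_of[as.character(dj)])
    by4 <- matrix(codes, nrow = 4)
    bytes <- by4[1, ] + bitwShiftL(by4[2, ], 2L) +
      bitwShiftL(by4[3, ], 4L) + bitwShiftL(by4[4, ], 6L)
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}
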