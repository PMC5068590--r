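#' Harmonize summary statistics to a target genotype matrix
#'
#' Restricts summary statistics to variants shared with the target cohort
#' and orients every weight so that it refers to the target's `allele_b`
#' (the allele the dosage counts). For each shared variant: if the summary
#' (effect, other) alleles equal (`allele_b`, `allele_a`) the weight is
#' kept; if they equal (`allele_a`, `allele_b`) it is negated; if they
#' match only after strand complementation, the alleles are complemented
#' first and the same rule applied. Strand-ambiguous variants (A/T, C/G)
#' cannot be resolved by complementation and are dropped by default;
#' variants whose allele pairs match under no rule are dropped with a
#' report.
#'
#' @param ss a [summary_stats()] object.
#' @param gm a [genotype_matrix()].
#' @param drop_ambiguous drop A/T and C/G variants (default `TRUE`).
#' @param match_by `"id"` matches on `variant_id`; `"position"` matches on
#'   (chrom, pos).
#' @return A `summary_stats` object restricted to shared variants, with
#'   `effect_allele`/`other_allele` rewritten to the target orientation and
#'   an attribute `dropped` (data.frame of variant_id + reason).
#' @export
harmonize <- function(ss, gm, drop_ambiguous = TRUE,
                      match_by = c("id", "position")) {
  match_by <- match.arg(match_by)
  if (nrow(ss) == 0 || ncol(gm$dosages) == 0) {
    stop("harmonize requires non-empty inputs", call. = FALSE)
  }
  if (match_by == "id") {
    idx <- match(ss$variant_id, gm$variants$variant_id)
  } else {
    key_ss <- paste(ss$chrom, ss$pos)
    key_gm <- paste(gm$variants$chrom, gm$variants$pos)
    idx <- match(key_ss, key_gm)
  }
  shared <- !is.na(idx)
  if (!any(shared)) {
    stop("no variants shared between summary statistics and genotypes",
         call. = FALSE)
  }
  ss2 <- as.data.frame(ss)[shared, , drop = FALSE]
  tg <- gm$variants[idx[shared], , drop = FALSE]

  reason <- rep(NA_character_, nrow(ss2))
  ea <- ss2$effect_allele
  oa <- ss2$other_allele
  if (drop_ambiguous) {
    reason[is_ambiguous_pair(ea, oa)] <- "strand-ambiguous (A/T or C/G)"
  }

  keep_w <- ea == tg$allele_b & oa == tg$allele_a
  flip_w <- ea == tg$allele_a & oa == tg$allele_b
  cea <- complement(ea)
  coa <- complement(oa)
  keep_c <- cea == tg$allele_b & coa == tg$allele_a
  flip_c <- cea == tg$allele_a & coa == tg$allele_b
  resolvable <- keep_w | flip_w | keep_c | flip_c
  reason[is.na(reason) & !resolvable] <- "allele pair mismatch"

  ok <- is.na(reason)
  dropped <- data.frame(variant_id = ss2$variant_id[!ok],
                        reason = reason[!ok], stringsAsFactors = FALSE)
  if (nrow(dropped)) {
    warning(sprintf("harmonize dropped %d variant(s): %s", nrow(dropped),
                    paste(unique(dropped$reason), collapse = "; ")),
            call. = FALSE)
  }
  if (!any(ok)) {
    stop("no variants left after allele harmonization", call. = FALSE)
  }

  flip <- (flip_w | (!keep_w & flip_c))[ok]
  out <- ss2[ok, , drop = FALSE]
  tg <- tg[ok, , drop = FALSE]
  out$weight <- ifelse(flip, -out$weight, out$weight)
  out$effect_allele <- tg$allele_b
  out$other_allele <- tg$allele_a
  out$variant_id <- tg$variant_id
  out$chrom <- tg$chrom
  out$pos <- tg$pos
  rownames(out) <- NULL
  class(out) <- c("summary_stats", "data.frame")
  attr(out, "dropped") <- dropped
  out
}

#' Filter summary statistics on target-cohort minor allele frequency
#'
#' The minor allele frequency of each variant is computed from non-missing
#' dosages as `mean(dosage)/2`, folded to at most 0.5. Variants strictly
#' below the threshold are removed; a variant equal to the threshold is
#' retained. Variants absent from the genotypes cannot be assessed and are
#' retained with a warning.
#'
#' @param ss a [summary_stats()] object.
#' @param gm a [genotype_matrix()].
#' @param threshold MAF cutoff in (0, 0.5); default 0.01.
#' @return The filtered `summary_stats`.
#' @export
maf_filter <- function(ss, gm, threshold = 0.01) {
  stopifnot(threshold > 0, threshold < 0.5)
  idx <- match(ss$variant_id, gm$variants$variant_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)),
            " variant(s) absent from genotypes; MAF not checked",
            call. = FALSE)
  }
  f <- allele_frequencies(gm)[idx]
  maf <- pmin(f, 1 - f)
  drop <- !is.na(maf) & maf < threshold
  out <- as.data.frame(ss)[!drop, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("summary_stats", "data.frame")
  out
}
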