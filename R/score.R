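#' P-value threshold set for scoring
#'
#' Validates an ordered set of P_T ceilings. The default is the six
#' thresholds commonly used for psychiatric risk profile scores:
#' 1e-5, 1e-4, 0.01, 0.1, 0.3, 0.5.
#'
#' @param thresholds strictly increasing numeric vector with values in
#'   (0, 1].
#' @return The validated numeric vector, classed `threshold_set`.
#' @export
prs_thresholds <- function(thresholds = c(1e-5, 1e-4, 0.01, 0.1, 0.3, 0.5)) {
  thresholds <- as.numeric(thresholds)
  if (any(thresholds <= 0 | thresholds > 1)) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  structure(thresholds, class = "threshold_set")
}

#' Polygenic risk scores at multiple P-value thresholds
#'
#' For each threshold `t`, each sample's score is the sum over variants
#' with `P < t` (strict) of the log odds-ratio weight times the dosage of
#' the effect allele. Missing dosages are mean-imputed at scoring time as
#' twice the target-cohort allele frequency (never stored back).
#' `mode = "average"` divides each sample's score by its number of
#' non-missing contributing alleles (2 x non-missing variants), the
#' behaviour of common scoring tools; the default `"sum"` leaves the plain
#' weighted allele count.
#'
#' @param gm a [genotype_matrix()] containing every `ss` variant.
#' @param ss a [summary_stats()] object, harmonized (and typically
#'   clump-indexed) against `gm`.
#' @param thresholds a [prs_thresholds()] set.
#' @param mode `"sum"` (default) or `"average"`.
#' @return An object of class `score_profile`: list with `sample_ids`,
#'   `scores` (samples x thresholds matrix), `n_variants` (per threshold),
#'   `thresholds` and `mode`.
#' @export
prs_score <- function(gm, ss, thresholds = prs_thresholds(),
                      mode = c("sum", "average")) {
  mode <- match.arg(mode)
  thresholds <- prs_thresholds(thresholds)
  col <- match(ss$variant_id, gm$variants$variant_id)
  if (anyNA(col)) {
    stop("variant(s) missing from genotype matrix: ",
         paste(head(ss$variant_id[is.na(col)], 5), collapse = ", "),
         call. = FALSE)
  }
  d <- gm$dosages[, col, drop = FALSE]
  f <- colMeans(d, na.rm = TRUE) / 2
  miss <- is.na(d)
  dimp <- d
  if (any(miss)) {
    dimp[miss] <- (2 * f[rep(seq_along(f), each = nrow(d))])[miss]
  }
  nT <- length(thresholds)
  scores <- matrix(0, nrow(d), nT,
                   dimnames = list(gm$sample_ids,
                                   paste0("P_T_", thresholds)))
  n_variants <- integer(nT)
  for (k in seq_len(nT)) {
    sel <- ss$pvalue < thresholds[k]
    n_variants[k] <- sum(sel)
    if (!any(sel)) {
      warning("no variants pass threshold ", thresholds[k],
              "; scores set to 0", call. = FALSE)
      next
    }
    s <- as.vector(dimp[, sel, drop = FALSE] %*% ss$weight[sel])
    if (mode == "average") {
      denom <- 2 * rowSums(!miss[, sel, drop = FALSE])
      s <- ifelse(denom > 0, s / denom, 0)
    }
    scores[, k] <- s
  }
  structure(list(sample_ids = gm$sample_ids, scores = scores,
                 n_variants = n_variants,
                 thresholds = as.numeric(thresholds), mode = mode),
            class = "score_profile")
}

#' Z-score a score profile across samples
#'
#' Standardizes each threshold's scores to mean 0 and unit sample variance
#' so that downstream regression coefficients are on the standardized-beta
#' scale. Thresholds with zero variance (e.g. no contributing variants)
#' raise an error naming the threshold unless `na_degenerate = TRUE`, in
#' which case they become `NA` columns.
#'
#' @param sp a `score_profile`.
#' @param na_degenerate replace constant columns by `NA` instead of
#'   erroring.
#' @return The standardized `score_profile`.
#' @export
standardize_scores <- function(sp, na_degenerate = FALSE) {
  if (nrow(sp$scores) < 2) stop("need at least 2 samples", call. = FALSE)
  for (k in seq_len(ncol(sp$scores))) {
    s <- sd(sp$scores[, k])
    if (!is.finite(s) || s == 0) {
      if (na_degenerate) {
        sp$scores[, k] <- NA_real_
        next
      }
      stop("zero score variance at threshold ", sp$thresholds[k],
           call. = FALSE)
    }
    sp$scores[, k] <- (sp$scores[, k] - mean(sp$scores[, k])) / s
  }
  sp
}

#' @export
print.score_profile <- function(x, ...) {
  cat(sprintf("score_profile (%s): %d samples x %d thresholds\n", x$mode,
              nrow(x$scores), length(x$thresholds)))
  cat("  n_variants:", paste(x$n_variants, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.score_profile <- function(x, ...) {
  data.frame(sample_id = x$sample_ids, x$scores, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Write a score profile as TSV plus a sidecar of variant counts
#'
#' @param sp a `score_profile`.
#' @param path output TSV path; the sidecar goes to `<path>.nvar`.
#' @return `path`, invisibly.
#' @export
write_scores <- function(sp, path) {
  data.table::fwrite(as.data.frame(sp), path, sep = "\t", quote = FALSE)
  side <- data.frame(threshold = sp$thresholds, n_variants = sp$n_variants)
  data.table::fwrite(side, paste0(path, ".nvar"), sep = "\t", quote = FALSE)
  invisible(path)
}
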