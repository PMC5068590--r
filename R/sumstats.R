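#' Construct a summary-statistics table
#'
#' A `summary_stats` object is a validated data.frame with one row per
#' variant from a training GWAS, holding the effect allele, the log
#' odds-ratio weight, and the association P-value used for thresholding.
#'
#' @param variant_id character, unique variant identifiers (e.g. rsIDs).
#' @param chrom character or integer chromosome labels.
#' @param pos integer base-pair positions (1-based).
#' @param effect_allele,other_allele single characters among A/C/G/T.
#' @param weight numeric log odds ratios (natural log).
#' @param pvalue numeric association P-values in (0, 1].
#' @return A data.frame of class `summary_stats`.
#' @export
summary_stats <- function(variant_id, chrom, pos, effect_allele,
                          other_allele, weight, pvalue) {
  ss <- data.frame(
    variant_id = as.character(variant_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    weight = as.numeric(weight),
    pvalue = as.numeric(pvalue),
    stringsAsFactors = FALSE
  )
  validate_sumstats(ss)
  class(ss) <- c("summary_stats", "data.frame")
  ss
}

validate_sumstats <- function(ss) {
  if (anyDuplicated(ss$variant_id)) {
    stop("duplicate variant_id in summary statistics", call. = FALSE)
  }
  if (any(ss$pos < 1L, na.rm = TRUE)) stop("pos must be >= 1", call. = FALSE)
  if (any(!ss$effect_allele %in% ACGT) || any(!ss$other_allele %in% ACGT)) {
    stop("alleles must be one of A/C/G/T", call. = FALSE)
  }
  if (any(ss$effect_allele == ss$other_allele)) {
    stop("effect_allele must differ from other_allele", call. = FALSE)
  }
  if (any(!is.finite(ss$weight))) stop("weights must be finite", call. = FALSE)
  if (any(ss$pvalue <= 0 | ss$pvalue > 1)) {
    stop("pvalue must lie in (0, 1]", call. = FALSE)
  }
  invisible(ss)
}

#' Canonical column-name map for summary-statistics files
#'
#' Maps the canonical fields to the column names found in the file.
#' Defaults follow the widely used SNP/CHR/BP/A1/A2/OR/P layout, where A1
#' is the effect allele the odds ratio refers to.
#'
#' @param SNP,CHR,BP,A1,A2,OR,P column names in the file.
#' @return Named character vector usable as the `dialect` argument of
#'   [read_sumstats()].
#' @export
sumstats_dialect <- function(SNP = "SNP", CHR = "CHR", BP = "BP", A1 = "A1",
                             A2 = "A2", OR = "OR", P = "P") {
  c(SNP = SNP, CHR = CHR, BP = BP, A1 = A1, A2 = A2, OR = OR, P = P)
}

#' Read GWAS summary statistics
#'
#' Reads a whitespace- or tab-delimited summary-statistics table, converts
#' odds ratios to natural-log weights, and validates each row. Rows with
#' non-ACGT alleles, non-positive odds ratios, or P-values outside (0, 1]
#' are rejected individually (reported via a warning and retrievable from
#' `attr(x, "rejected")`); a missing required column is a format error.
#'
#' @param path path to the file.
#' @param dialect named map from canonical columns to file columns, see
#'   [sumstats_dialect()].
#' @return A `summary_stats` object with attribute `rejected`, a data.frame
#'   of dropped rows and reasons.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           na.strings = c("NA", "."))
  if (nrow(raw) == 0) {
    stop("summary-statistics file has no records: ", path, call. = FALSE)
  }
  needed <- sumstats_dialect()
  dialect <- c(dialect, needed[setdiff(names(needed), names(dialect))])
  missing_cols <- setdiff(unname(dialect), names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  or <- suppressWarnings(as.numeric(raw[[dialect[["OR"]]]]))
  p <- suppressWarnings(as.numeric(raw[[dialect[["P"]]]]))
  a1 <- toupper(as.character(raw[[dialect[["A1"]]]]))
  a2 <- toupper(as.character(raw[[dialect[["A2"]]]]))

  reason <- rep(NA_character_, nrow(raw))
  reason[!a1 %in% ACGT | !a2 %in% ACGT | a1 == a2] <- "invalid alleles"
  bad_or <- is.na(or) | or <= 0
  reason[is.na(reason) & bad_or] <- "odds ratio not strictly positive"
  bad_p <- is.na(p) | p <= 0 | p > 1
  reason[is.na(reason) & bad_p] <- "P-value outside (0, 1]"
  keep <- is.na(reason)

  rejected <- data.frame(row = which(!keep), reason = reason[!keep],
                         variant_id = as.character(raw[[dialect[["SNP"]]]])[!keep])
  if (nrow(rejected)) {
    warning(sprintf("rejected %d of %d rows (%s)", nrow(rejected), nrow(raw),
                    paste(unique(rejected$reason), collapse = "; ")),
            call. = FALSE)
  }
  if (!any(keep)) stop("no valid summary-statistics rows in ", path,
                       call. = FALSE)
  ss <- summary_stats(
    variant_id = raw[[dialect[["SNP"]]]][keep],
    chrom = raw[[dialect[["CHR"]]]][keep],
    pos = raw[[dialect[["BP"]]]][keep],
    effect_allele = a1[keep],
    other_allele = a2[keep],
    weight = log(or[keep]),
    pvalue = p[keep]
  )
  attr(ss, "rejected") <- rejected
  ss
}

#' Write summary statistics back to the canonical TSV layout
#'
#' @param ss a `summary_stats` object.
#' @param path output path.
#' @param dialect column-name map, see [sumstats_dialect()].
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path, dialect = sumstats_dialect()) {
  out <- data.frame(ss$variant_id, ss$chrom, ss$pos, ss$effect_allele,
                    ss$other_allele, exp(ss$weight), ss$pvalue)
  names(out) <- unname(dialect[c("SNP", "CHR", "BP", "A1", "A2", "OR", "P")])
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
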