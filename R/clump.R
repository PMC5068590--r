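#' Clumping parameters
#'
#' @param r2_threshold squared-correlation cutoff: a variant is removed
#'   when its r^2 with an index variant is strictly greater than this.
#'   Default 0.25.
#' @param window_kb window half-width in kilobases: only variants within
#'   +/- `window_kb` of the index (distance <= `window_kb * 1000` bp) on
#'   the same chromosome are considered. Default 500.
#' @param p1 P-value ceiling for variants to enter clumping at all
#'   (P <= p1); default 1 keeps everything.
#' @return A list of class `clump_params`.
#' @export
clump_params <- function(r2_threshold = 0.25, window_kb = 500, p1 = 1.0) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1, window_kb > 0,
            p1 > 0, p1 <= 1)
  structure(list(r2_threshold = r2_threshold, window_kb = window_kb,
                 p1 = p1), class = "clump_params")
}

#' Squared Pearson correlation between two variants' dosages
#'
#' Computed over samples non-missing for both variants; the linkage
#' disequilibrium measure used by clumping. Sign-free: perfectly
#' anti-correlated dosages give r^2 = 1.
#'
#' @param gm a [genotype_matrix()].
#' @param i,j variant column indices or variant ids.
#' @return r^2 in \[0, 1\].
#' @export
pairwise_r2 <- function(gm, i, j) {
  if (is.character(i)) i <- match(i, gm$variants$variant_id)
  if (is.character(j)) j <- match(j, gm$variants$variant_id)
  x <- gm$dosages[, i]
  y <- gm$dosages[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) {
    stop("fewer than 2 overlapping non-missing samples", call. = FALSE)
  }
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    stop("undefined LD: zero dosage variance", call. = FALSE)
  }
  cor(x[ok], y[ok])^2
}

#' Greedy P-value-ordered LD clumping
#'
#' Variants are visited in order of ascending association P-value (ties
#' broken by chromosome then position). Each variant not already removed
#' becomes an index; every other not-yet-indexed, not-yet-removed variant
#' on the same chromosome within the window whose dosage r^2 with the
#' index strictly exceeds `r2_threshold` (by more than 1e-12, so exact
#' rational ties such as r^2 = 1/4 with hard-call dosages resolve to
#' "keep" regardless of rounding direction) is removed and recorded as
#' clumped by that index. Indexes are never removed by later indexes, so
#' the retained set is the standard greedy clump solution. LD is computed
#' in the target cohort itself; a variant with zero dosage variance is
#' treated as r^2 = 0 with a warning.
#'
#' @param ss a [summary_stats()] object harmonized to `gm` (positions
#'   required).
#' @param gm a [genotype_matrix()] containing every `ss` variant.
#' @param params a [clump_params()] object.
#' @return A list of class `clump_result` with elements `index` (data.frame
#'   of retained variants, their P-values and member counts, in selection
#'   order), `clumped_by` (named character vector: removed variant ->
#'   index variant) and `params`.
#' @export
ld_clump <- function(ss, gm, params = clump_params()) {
  if (nrow(ss) == 0) {
    return(structure(list(index = data.frame(variant_id = character(0),
                                             pvalue = numeric(0),
                                             n_members = integer(0)),
                          clumped_by = character(0), params = params),
                     class = "clump_result"))
  }
  if (anyNA(ss$pos)) stop("clumping requires variant positions", call. = FALSE)
  col <- match(ss$variant_id, gm$variants$variant_id)
  if (anyNA(col)) {
    stop("variant(s) missing from genotype matrix: ",
         paste(head(ss$variant_id[is.na(col)], 5), collapse = ", "),
         call. = FALSE)
  }
  use <- ss$pvalue <= params$p1
  ss <- as.data.frame(ss)[use, , drop = FALSE]
  col <- col[use]
  ord <- order(ss$pvalue, ss$chrom, ss$pos)
  window_bp <- params$window_kb * 1000

  m <- nrow(ss)
  status <- integer(m)  # 0 free, 1 index, 2 removed
  clumped_by <- character(0)
  index_rows <- integer(0)
  n_members <- integer(0)
  d <- gm$dosages
  warned_var <- FALSE

  # complete data: pre-standardize once so each index-vs-candidates LD scan
  # is a single BLAS product; with missing entries fall back to pairwise-
  # complete correlations
  complete <- !anyNA(d[, col, drop = FALSE])
  R <- NULL
  if (complete) {
    z <- scale(d[, col, drop = FALSE])
    z[, attr(z, "scaled:scale") == 0] <- NA_real_
    nsamp <- nrow(z)
    if (m <= 4000) {  # one dgemm for the whole correlation matrix
      R <- crossprod(z) / (nsamp - 1)
    }
  }

  for (k in ord) {
    if (status[k] != 0L) next
    status[k] <- 1L
    index_rows <- c(index_rows, k)
    cand <- which(status == 0L & ss$chrom == ss$chrom[k] &
                    abs(ss$pos - ss$pos[k]) <= window_bp)
    cand <- setdiff(cand, k)
    nm <- 0L
    if (length(cand)) {
      if (!is.null(R)) {
        r <- R[cand, k]
      } else if (complete) {
        r <- as.vector(crossprod(z[, k], z[, cand, drop = FALSE])) /
          (nsamp - 1)
      } else {
        r <- suppressWarnings(
          as.vector(cor(d[, col[k]], d[, col[cand], drop = FALSE],
                        use = "pairwise.complete.obs")))
      }
      if (anyNA(r)) {
        if (!warned_var) {
          warning("zero dosage variance encountered; treating r^2 as 0",
                  call. = FALSE)
          warned_var <- TRUE
        }
        r[is.na(r)] <- 0
      }
      # exceeding the threshold beyond floating-point noise triggers
      # removal; integer dosages can produce exact rational ties (e.g.
      # r^2 = 1/4) that different correlation algorithms round to
      # opposite sides of a strict comparison
      hit <- cand[r^2 > params$r2_threshold + 1e-12]
      if (length(hit)) {
        status[hit] <- 2L
        clumped_by[ss$variant_id[hit]] <- ss$variant_id[k]
        nm <- length(hit)
      }
    }
    n_members <- c(n_members, nm)
  }
  index <- data.frame(variant_id = ss$variant_id[index_rows],
                      chrom = ss$chrom[index_rows],
                      pos = ss$pos[index_rows],
                      pvalue = ss$pvalue[index_rows],
                      n_members = n_members,
                      stringsAsFactors = FALSE)
  structure(list(index = index, clumped_by = clumped_by, params = params),
            class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat(sprintf("clump_result: %d index variants, %d removed (r2 > %g within %g kb)\n",
              nrow(x$index), length(x$clumped_by),
              x$params$r2_threshold, x$params$window_kb))
  invisible(x)
}

#' Plain-text clump report
#'
#' One line per clump: index variant, its P-value, and its removed members,
#' modelled on standard clumped-output tables.
#'
#' @param cr a `clump_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clump_report <- function(cr, path) {
  members <- vapply(cr$index$variant_id, function(id) {
    mem <- names(cr$clumped_by)[cr$clumped_by == id]
    if (length(mem)) paste(mem, collapse = ",") else "NONE"
  }, character(1))
  out <- data.frame(INDEX = cr$index$variant_id, CHR = cr$index$chrom,
                    BP = cr$index$pos, P = cr$index$pvalue,
                    N_MEMBERS = cr$index$n_members, MEMBERS = members)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
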