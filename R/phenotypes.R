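#' Construct a phenotype/covariate table
#'
#' One row per sample with sex (0/1, 1 = female), age in years,
#' intracranial volume (ICV, mm^3), and one column per region of interest
#' (ROI) holding its volume in mm^3 (hemisphere-averaged). Missing volumes
#' are `NA`; present volumes must be positive.
#'
#' @param df data.frame with columns `sample_id`, `sex`, `age`, `icv` and
#'   the ROI columns.
#' @param rois character vector naming the ROI columns.
#' @return A data.frame of class `phenotype_table` with attribute `rois`.
#' @export
phenotype_table <- function(df, rois) {
  needed <- c("sample_id", "sex", "age", "icv")
  if (!all(needed %in% names(df))) {
    stop("phenotype table must have columns ",
         paste(setdiff(needed, names(df)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("sample_id must be unique", call. = FALSE)
  }
  missing_rois <- setdiff(rois, names(df))
  if (length(missing_rois)) {
    stop("ROI column(s) absent: ", paste(missing_rois, collapse = ", "),
         call. = FALSE)
  }
  for (r in rois) {
    v <- df[[r]]
    if (any(!is.na(v) & v <= 0)) {
      stop("non-positive volumes in ROI ", r, call. = FALSE)
    }
  }
  df$sample_id <- as.character(df$sample_id)
  out <- df[, c(needed, rois)]
  attr(out, "rois") <- rois
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Read a phenotype/covariate TSV
#'
#' Expects a header row with `sample_id`, `sex`, `age`, `icv` and ROI
#' columns; `NA` marks missing volumes. Hemisphere-specific column pairs
#' named `<roi>_left` / `<roi>_right` are averaged into a single `<roi>`
#' column at ingestion ((left + right) / 2); if either hemisphere is
#' missing the averaged volume is missing, mirroring per-hemisphere
#' quality-control exclusion.
#'
#' @param path path to the TSV.
#' @param rois optional character vector of ROI columns to keep; default is
#'   every non-covariate column after hemisphere averaging.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path, rois = NULL) {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", "."))
  lefts <- grep("_left$", names(df), value = TRUE)
  for (l in lefts) {
    base <- sub("_left$", "", l)
    r <- paste0(base, "_right")
    if (r %in% names(df)) {
      df[[base]] <- (df[[l]] + df[[r]]) / 2
      df[[l]] <- NULL
      df[[r]] <- NULL
    }
  }
  if (is.null(rois)) {
    rois <- setdiff(names(df), c("sample_id", "sex", "age", "icv"))
  }
  phenotype_table(df, rois)
}

#' Write a phenotype table to TSV
#'
#' @param pt a `phenotype_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pt, path) {
  data.table::fwrite(as.data.frame(pt), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}
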