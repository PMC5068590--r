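#' Read and validate a pipeline configuration file
#'
#' The configuration is a single declarative JSON file; relative input
#' paths are resolved against the directory containing the file. Required
#' keys: `sumstats` (named map training-set -> path), `genotypes`,
#' `genotype_format`, `phenotypes`, `seed`. Everything else defaults to
#' the conventional analysis values (MAF 0.01, clump r^2 0.25 within 500
#' kb, six thresholds 1e-5..0.5, sex + ICV covariates with age for the
#' lateral ventricles, 10000 permutations of nominally significant cells).
#'
#' @param path path to the JSON config.
#' @return A validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  for (key in c("sumstats", "genotypes", "phenotypes", "seed")) {
    if (is.null(cfg[[key]])) stop("config key missing: ", key, call. = FALSE)
  }
  cfg$sumstats <- vapply(cfg$sumstats, resolve, character(1))
  cfg$genotypes <- resolve(cfg$genotypes)
  cfg$phenotypes <- resolve(cfg$phenotypes)
  for (f in c(cfg$sumstats, cfg$genotypes, cfg$phenotypes)) {
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  }
  cfg$genotype_format <- cfg$genotype_format %||% "tsv"
  cfg$maf_threshold <- cfg$maf_threshold %||% 0.01
  cl <- cfg$clump %||% list()
  cfg$clump <- clump_params(cl$r2_threshold %||% 0.25,
                            cl$window_kb %||% 500, cl$p1 %||% 1.0)
  cfg$thresholds <- prs_thresholds(cfg$thresholds %||%
                                     c(1e-5, 1e-4, 0.01, 0.1, 0.3, 0.5))
  cov <- cfg$covariates %||% list()
  cfg$covariates <- covariate_policy(
    always = cov$always %||% c("sex", "icv"),
    age_rois = cov$age_rois %||% "lateral_ventricles")
  cfg$score_mode <- cfg$score_mode %||% "sum"
  cfg$standardize <- cfg$standardize %||% TRUE
  cfg$n_perm <- cfg$n_perm %||% 10000
  cfg$perm_policy <- cfg$perm_policy %||% "significant"
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$match_by <- cfg$match_by %||% "id"
  cfg$drop_ambiguous <- cfg$drop_ambiguous %||% TRUE
  cfg$output_dir <- resolve(cfg$output_dir %||% "results")
  attr(cfg, "config_path") <- normalizePath(path)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full scoring-and-association pipeline
#'
#' Orchestrates ingest -> harmonize -> MAF filter -> clump -> score ->
#' associate -> permute -> report from a single configuration. Writes to
#' the output directory: `report.tsv` (wide table: one row per training
#' set x threshold, a column group per ROI), `report.json` (long
#' records), `stage_counts.tsv` (variants surviving each stage per
#' training set), `clumps_<set>.tsv`, `scores_<set>.tsv`, `pipeline.log`,
#' and `provenance.json` (config hash, seed, package version). The same
#' config and seed give byte-identical reports.
#'
#' @param config a `pipeline_config` or a path to one.
#' @param output_dir optional override of the config's output directory.
#' @return Invisibly, a list with the association `results`, per-set
#'   `stage_counts`, and the output `files`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out_dir <- output_dir %||% config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(...) {
    line <- sprintf(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  log("reading genotypes: %s [%s]", config$genotypes, config$genotype_format)
  gm <- read_genotypes(config$genotypes, config$genotype_format)
  log("  %d samples x %d variants", nrow(gm$dosages), ncol(gm$dosages))
  pheno <- read_phenotypes(config$phenotypes, rois = config$rois)
  rois <- attr(pheno, "rois")
  log("reading phenotypes: %s (%d samples, %d ROIs)", config$phenotypes,
      nrow(pheno), length(rois))

  scores <- list()
  counts <- list()
  for (set in names(config$sumstats)) {
    log("[%s] reading summary statistics: %s", set, config$sumstats[[set]])
    ss <- suppressWarnings(read_sumstats(config$sumstats[[set]]))
    n_read <- nrow(ss)
    ss <- suppressWarnings(harmonize(ss, gm,
                                     drop_ambiguous = config$drop_ambiguous,
                                     match_by = config$match_by))
    n_harm <- nrow(ss)
    ss <- suppressWarnings(maf_filter(ss, gm, config$maf_threshold))
    n_maf <- nrow(ss)
    cr <- ld_clump(ss, gm, config$clump)
    n_index <- nrow(cr$index)
    write_clump_report(cr, file.path(out_dir, paste0("clumps_", set, ".tsv")))
    ss_idx <- ss[ss$variant_id %in% cr$index$variant_id, , drop = FALSE]
    class(ss_idx) <- c("summary_stats", "data.frame")
    sp <- suppressWarnings(prs_score(gm, ss_idx, config$thresholds,
                                     mode = config$score_mode))
    if (isTRUE(config$standardize)) {
      sp <- standardize_scores(sp, na_degenerate = TRUE)
    }
    write_scores(sp, file.path(out_dir, paste0("scores_", set, ".tsv")))
    scores[[set]] <- sp
    counts[[set]] <- data.frame(
      training_set = set, n_read = n_read, n_harmonized = n_harm,
      n_after_maf = n_maf, n_index = n_index,
      n_at_min_threshold = sp$n_variants[1])
    log("[%s] variants: read %d -> harmonized %d -> MAF %d -> index %d",
        set, n_read, n_harm, n_maf, n_index)
  }
  stage_counts <- do.call(rbind, counts)
  data.table::fwrite(stage_counts, file.path(out_dir, "stage_counts.tsv"),
                     sep = "\t", quote = FALSE)

  log("association: %d ROIs x %d sets x %d thresholds (n_perm=%d, %s)",
      length(rois), length(scores), length(config$thresholds),
      config$n_perm, config$perm_policy)
  results <- suppressWarnings(run_association(
    pheno, scores, policy = config$covariates, rois = rois,
    n_perm = config$n_perm, perm_policy = config$perm_policy,
    alpha = config$alpha, seed = config$seed))
  files <- list(
    report_tsv = file.path(out_dir, "report.tsv"),
    report_json = file.path(out_dir, "report.json"),
    stage_counts = file.path(out_dir, "stage_counts.tsv"),
    log = file.path(out_dir, "pipeline.log"),
    provenance = file.path(out_dir, "provenance.json"))
  write_assoc_report(results, files$report_tsv, files$report_json)
  cfg_path <- attr(config, "config_path")
  provenance <- list(
    package = "prsvol",
    version = as.character(packageVersion("prsvol")),
    seed = config$seed,
    config = if (!is.null(cfg_path)) basename(cfg_path) else NA,
    config_md5 = if (!is.null(cfg_path))
      unname(tools::md5sum(cfg_path)) else NA)
  jsonlite::write_json(provenance, files$provenance, auto_unbox = TRUE,
                       pretty = TRUE)
  n_sig <- sum(results$significant, na.rm = TRUE)
  log("done: %d cells, %d significant after permutation", nrow(results),
      n_sig)
  writeLines(log_lines, files$log)
  invisible(list(results = results, stage_counts = stage_counts,
                 scores = scores, files = files))
}

#' Generate a self-contained demo data set and configuration
#'
#' Simulates the whole stated world at cohort scale (by default 274
#' samples, 5000 variants), writes the three input table kinds through
#' the package's own writers (four summary-statistics TSVs, a dosage TSV
#' with 1% missingness, a phenotype TSV), and a ready-to-run
#' `config.json`. The demo uses 1000 permutations per cell to stay quick;
#' the function-level default elsewhere remains 10000.
#'
#' @param dir output directory (created if needed).
#' @param n target-cohort size.
#' @param seed global seed; the architecture and every draw derive from
#'   it.
#' @param arch optional [architecture_spec()] override.
#' @param pheno named list of [pheno_spec()]s (default
#'   [default_pheno_specs()]).
#' @param n_perm permutations written into the demo config.
#' @return Path to the written `config.json`.
#' @export
make_demo <- function(dir, n = 274, seed = 42L,
                      arch = NULL, pheno = default_pheno_specs(),
                      n_perm = 1000) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arch <- arch %||% architecture_spec(seed = seed)
  gm <- sim_genotypes(n, arch, missing_rate = 0.01)
  sumstats <- sim_sumstats(arch)
  pt <- sim_phenotypes(gm, arch, pheno)
  ss_paths <- list()
  for (set in names(sumstats)) {
    p <- paste0("sumstats_", set, ".tsv")
    write_sumstats(sumstats[[set]], file.path(dir, p))
    ss_paths[[set]] <- p
  }
  write_genotypes(gm, file.path(dir, "genotypes.tsv"), "tsv")
  write_phenotypes(pt, file.path(dir, "phenotypes.tsv"))
  cfg <- list(
    sumstats = ss_paths,
    genotypes = "genotypes.tsv",
    genotype_format = "tsv",
    phenotypes = "phenotypes.tsv",
    rois = names(pheno),
    maf_threshold = 0.01,
    clump = list(r2_threshold = 0.25, window_kb = 500, p1 = 1.0),
    thresholds = c(1e-5, 1e-4, 0.01, 0.1, 0.3, 0.5),
    covariates = list(always = c("sex", "icv"),
                      age_rois = "lateral_ventricles"),
    score_mode = "sum",
    standardize = TRUE,
    n_perm = n_perm,
    perm_policy = "significant",
    alpha = 0.05,
    seed = seed,
    output_dir = "results"
  )
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  cfg_path
}
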