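#' Incremental association of a risk score with a phenotype
#'
#' Ordinary least squares of the (z-scored) phenotype on the covariates
#' plus the (z-scored) score, on complete cases. Reports the standardized
#' coefficient of the score, its two-sided t-test P-value, and the
#' incremental variance explained delta-R^2 = R^2(covariates + score) -
#' R^2(covariates only), both R^2 computed on the same complete-case
#' sample so delta-R^2 is never negative.
#'
#' @param y numeric phenotype vector (e.g. an ROI volume).
#' @param g numeric score vector.
#' @param X optional covariate matrix or data.frame (entered raw; an
#'   intercept is always added).
#' @return List with `beta`, `p_nominal`, `delta_r2`, `n_used`, `r2_cov`,
#'   `r2_full`.
#' @export
fit_increment <- function(y, g, X = NULL) {
  n <- length(y)
  if (length(g) != n) stop("y and g lengths differ", call. = FALSE)
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
    if (nrow(X) != n) stop("covariate rows must match y", call. = FALSE)
  }
  cc <- !is.na(y) & !is.na(g)
  if (!is.null(X)) cc <- cc & complete.cases(X)
  n_used <- sum(cc)
  p_cov <- 1L + if (is.null(X)) 0L else ncol(X)
  if (n_used <= p_cov + 3L) {
    stop("too few complete cases (", n_used, ") for ", p_cov + 1,
         " predictors", call. = FALSE)
  }
  yz <- zscore(y[cc])
  gz <- zscore(g[cc])
  C <- cbind(`(Intercept)` = rep(1, n_used),
             if (!is.null(X)) X[cc, , drop = FALSE])
  full <- cbind(C, GRS = gz)
  qr_full <- qr(full)
  if (qr_full$rank < ncol(full)) {
    bad <- colnames(full)[qr_full$pivot[-seq_len(qr_full$rank)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit0 <- lm.fit(C, yz)
  fit1 <- lm.fit(full, yz)
  tss <- sum((yz - mean(yz))^2)
  r2_cov <- 1 - sum(fit0$residuals^2) / tss
  r2_full <- 1 - sum(fit1$residuals^2) / tss
  df <- n_used - ncol(full)
  beta <- fit1$coefficients[["GRS"]]
  # t^2 for the added regressor via the partial-R^2 identity; equals the
  # usual beta/se t-test but immune to QR column pivoting
  t2 <- if (r2_full >= 1) Inf else df * (r2_full - r2_cov) / (1 - r2_full)
  list(beta = beta,
       p_nominal = 2 * pt(-sqrt(max(t2, 0)), df),
       delta_r2 = r2_full - r2_cov,
       n_used = n_used, r2_cov = r2_cov, r2_full = r2_full)
}

#' Permutation P-value for the score term of an incremental regression
#'
#' The score vector is permuted across samples `n_perm` times (phenotype
#' and covariate rows stay paired, preserving their relationship); each
#' permuted regression yields a nominal P-value p*, and the permuted
#' P-value is the count of p* strictly below the observed nominal P,
#' divided by the number of permutations. Internally each refit is
#' evaluated through the partial correlation of the score with the
#' covariate-residualized phenotype, which is a monotone transform of the
#' t statistic at fixed degrees of freedom, so the comparison of p* with
#' the observed p is exact without refitting `lm` per permutation.
#'
#' `method = "freedman_lane"` instead permutes the covariate residuals of
#' the phenotype (Freedman-Lane scheme). `estimator = "add_one"` returns
#' (k+1)/(n_perm+1), which is never exactly zero.
#'
#' @param y,g,X as in [fit_increment()].
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed making the draw reproducible; the caller's RNG
#'   state is restored afterwards.
#' @param method `"score"` (permute g, default) or `"freedman_lane"`.
#' @param estimator `"plain"` (k/N, default) or `"add_one"`.
#' @return The permuted P-value.
#' @export
permutation_p <- function(y, g, X = NULL, n_perm = 10000, seed = NULL,
                          method = c("score", "freedman_lane"),
                          estimator = c("plain", "add_one")) {
  method <- match.arg(method)
  estimator <- match.arg(estimator)
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  cc <- !is.na(y) & !is.na(g)
  if (!is.null(X)) {
    X <- as.matrix(X)
    cc <- cc & complete.cases(X)
  }
  y <- y[cc]
  g <- g[cc]
  n <- length(y)
  C <- cbind(rep(1, n), if (!is.null(X)) X[cc, , drop = FALSE])
  Q <- qr.Q(qr(C))
  ry <- y - Q %*% crossprod(Q, y)          # phenotype residualized on covariates
  rg <- g - Q %*% crossprod(Q, g)
  ss_ry <- sum(ry^2)
  ss_rg <- sum(rg^2)
  if (ss_ry == 0 || ss_rg == 0) {
    stop("zero residual variance; permutation undefined", call. = FALSE)
  }
  r_obs <- sum(ry * g) / sqrt(ss_ry * ss_rg)

  k <- with_seed(seed, {
    perm <- matrix(0L, n, n_perm)
    for (b in seq_len(n_perm)) perm[, b] <- sample.int(n)
    if (method == "score") {
      G <- matrix(g[perm], n, n_perm)
      num <- as.vector(crossprod(G, ry))
      qg <- crossprod(Q, G)
      den2 <- (colSums(G^2) - colSums(qg^2)) * ss_ry
    } else {
      E <- matrix(ry[perm], n, n_perm)     # permuted phenotype residuals
      num <- as.vector(crossprod(E, rg))
      qe <- crossprod(Q, E)
      den2 <- (colSums(E^2) - colSums(qe^2)) * ss_rg
    }
    r_perm <- ifelse(den2 > 0, num / sqrt(den2), 0)
    sum(abs(r_perm) > abs(r_obs))
  })
  if (estimator == "plain") k / n_perm else (k + 1) / (n_perm + 1)
}

#' Covariate policy for ROI regressions
#'
#' Sex and intracranial volume enter every model; age enters only for the
#' ROIs named in `age_rois` (default the lateral ventricles, the one
#' structure whose volume typically correlates with age in young healthy
#' cohorts).
#'
#' @param always covariate columns used for every ROI.
#' @param age_rois ROIs whose models additionally include age.
#' @return A list of class `covariate_policy`.
#' @export
covariate_policy <- function(always = c("sex", "icv"),
                             age_rois = "lateral_ventricles") {
  structure(list(always = always, age_rois = age_rois),
            class = "covariate_policy")
}

covariates_for <- function(pheno, roi, policy) {
  cols <- policy$always
  if (roi %in% policy$age_rois) cols <- c(cols, "age")
  missing_cols <- setdiff(cols, names(pheno))
  if (length(missing_cols)) {
    stop("covariate column(s) absent: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  as.matrix(as.data.frame(pheno)[, cols, drop = FALSE])
}

#' Full ROI x training-set x threshold association table
#'
#' Runs [fit_increment()] for every combination of ROI, training set and
#' P-value threshold, then [permutation_p()] according to `perm_policy`:
#' `"significant"` (default) permutes only cells with nominal P below
#' `alpha`, mirroring post hoc multiple-testing correction of dependent
#' tests; `"all"` permutes every cell; `"none"` skips permutation.
#' Scores are aligned to phenotype rows by sample id.
#'
#' @param pheno a [phenotype_table()].
#' @param scores named list of `score_profile` objects, one per training
#'   set (e.g. `SCZ_BD`, `SCZvsBD`, `SCZ`, `BD`).
#' @param policy a [covariate_policy()].
#' @param rois ROIs to analyse; default all ROIs in `pheno`.
#' @param n_perm permutations per cell (default 10000).
#' @param perm_policy `"significant"`, `"all"` or `"none"`.
#' @param alpha nominal significance level (default 0.05).
#' @param seed global seed; each cell uses a deterministic substream.
#' @return A data.frame of class `assoc_table`, threshold-major within
#'   training set: columns `roi`, `training_set`, `p_t`, `n_snps`, `beta`,
#'   `p_nominal`, `delta_r2`, `p_perm` (`NA` where not permuted),
#'   `n_used`, `significant` (permuted P < alpha, `FALSE` when the cell
#'   was not permuted).
#' @export
run_association <- function(pheno, scores, policy = covariate_policy(),
                            rois = NULL, n_perm = 10000,
                            perm_policy = c("significant", "all", "none"),
                            alpha = 0.05, seed = 1L) {
  perm_policy <- match.arg(perm_policy)
  if (is.null(rois)) rois <- attr(pheno, "rois")
  if (!length(rois)) stop("no ROIs to analyse", call. = FALSE)
  absent <- setdiff(rois, names(pheno))
  if (length(absent)) {
    stop("ROI column(s) absent: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(names(scores)) || any(names(scores) == "")) {
    stop("scores must be a named list of score profiles", call. = FALSE)
  }
  rows <- list()
  for (set in names(scores)) {
    sp <- scores[[set]]
    idx <- match(pheno$sample_id, sp$sample_ids)
    if (all(is.na(idx))) {
      stop("no overlapping samples between phenotypes and scores for ",
           set, call. = FALSE)
    }
    for (k in seq_along(sp$thresholds)) {
      gvec <- sp$scores[idx, k]
      for (roi in rois) {
        yvec <- pheno[[roi]]
        if (all(is.na(yvec))) {
          stop("all volumes missing for ROI ", roi, call. = FALSE)
        }
        X <- covariates_for(pheno, roi, policy)
        if (all(is.na(gvec)) || sd(gvec, na.rm = TRUE) == 0) {
          rows[[length(rows) + 1]] <- data.frame(
            roi = roi, training_set = set, p_t = sp$thresholds[k],
            n_snps = sp$n_variants[k], beta = NA_real_,
            p_nominal = NA_real_, delta_r2 = NA_real_, p_perm = NA_real_,
            n_used = NA_integer_, significant = FALSE)
          next
        }
        fit <- fit_increment(yvec, gvec, X)
        pp <- NA_real_
        if (perm_policy == "all" ||
            (perm_policy == "significant" && fit$p_nominal < alpha)) {
          pp <- permutation_p(
            yvec, gvec, X, n_perm = n_perm,
            seed = substream_seed(seed, paste(set, k, roi)))
        }
        rows[[length(rows) + 1]] <- data.frame(
          roi = roi, training_set = set, p_t = sp$thresholds[k],
          n_snps = sp$n_variants[k], beta = fit$beta,
          p_nominal = fit$p_nominal, delta_r2 = fit$delta_r2,
          p_perm = pp, n_used = fit$n_used,
          significant = !is.na(pp) && pp < alpha)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Write the association report (TSV mirroring the wide table layout, plus
#' machine-readable JSON)
#'
#' The TSV has one row per (training set, threshold) and a column group
#' per ROI (`<roi>.beta`, `<roi>.p`, `<roi>.delta_r2`, `<roi>.p_perm`);
#' the JSON holds the long-format records verbatim.
#'
#' @param results an `assoc_table`.
#' @param tsv_path,json_path output paths (either may be `NULL`).
#' @return Invisibly, the wide data.frame written to the TSV.
#' @export
write_assoc_report <- function(results, tsv_path = NULL, json_path = NULL) {
  rois <- unique(results$roi)
  keys <- unique(results[, c("training_set", "p_t")])
  wide <- keys
  for (roi in rois) {
    sub <- results[results$roi == roi, ]
    i <- match(paste(keys$training_set, keys$p_t),
               paste(sub$training_set, sub$p_t))
    wide[[paste0(roi, ".beta")]] <- round(sub$beta[i], 6)
    wide[[paste0(roi, ".p")]] <- signif(sub$p_nominal[i], 6)
    wide[[paste0(roi, ".delta_r2")]] <- round(sub$delta_r2[i], 6)
    wide[[paste0(roi, ".p_perm")]] <- sub$p_perm[i]
  }
  if (!is.null(tsv_path)) {
    data.table::fwrite(wide, tsv_path, sep = "\t", quote = FALSE, na = "NA")
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(as.data.frame(results), json_path, digits = NA,
                         na = "null", auto_unbox = FALSE)
  }
  invisible(wide)
}
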