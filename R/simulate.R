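#' Cross-disorder genetic architecture specification
#'
#' Describes the simulated world: `m` variants in LD blocks of
#' `block_size` adjacent variants whose haplotypes follow an AR(1) latent
#' Gaussian with correlation `rho`; allele frequencies uniform on
#' `maf_range`; disjoint causal sets for the shared component and for each
#' disorder (at most one causal variant per LD block, so causal signals
#' occupy independent loci); per-causal standardized effects drawn
#' Normal(0, `effect_sd`^2); and training-GWAS estimates with standard
#' error `1/sqrt(2 * n_train_eff * f(1-f))`.
#'
#' Defaults are desk-scale but structured like the real problem: a
#' 274-sample target cohort is scored from 5000 variants in 25-variant
#' blocks, with 40 shared and 60 per-disorder causal variants whose
#' effects are well powered (effect_sd 0.08 against a Wald standard error
#' of roughly 0.005) in a training GWAS of effective size 1e5.
#'
#' @param m variant count.
#' @param block_size variants per LD block.
#' @param rho within-block AR(1) haplotype correlation in \[0, 1).
#' @param maf_range allele-frequency range, within (0.01, 0.5\].
#' @param n_causal_shared,n_causal_A,n_causal_B causal-set sizes
#'   (disjoint; their sum may not exceed the number of blocks).
#' @param effect_sd standard deviation of true log-odds effects.
#' @param n_train_eff effective training-GWAS sample size.
#' @param seed integer seed anchoring the architecture (variant layout,
#'   frequencies, causal sets, true effects).
#' @return A list of class `architecture_spec`.
#' @export
architecture_spec <- function(m = 5000, block_size = 25, rho = 0.8,
                              maf_range = c(0.05, 0.5),
                              n_causal_shared = 40, n_causal_A = 60,
                              n_causal_B = 60, effect_sd = 0.08,
                              n_train_eff = 1e5, seed = 1L) {
  stopifnot(m >= 1, block_size >= 1, rho >= 0, rho < 1,
            length(maf_range) == 2, maf_range[1] > 0.01,
            maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
            n_causal_shared >= 0, n_causal_A >= 0, n_causal_B >= 0,
            effect_sd >= 0, n_train_eff > 0)
  n_blocks <- ceiling(m / block_size)
  total_causal <- n_causal_shared + n_causal_A + n_causal_B
  if (total_causal > n_blocks) {
    stop("causal sets exceed the number of LD blocks (one causal variant ",
         "per block)", call. = FALSE)
  }
  if (total_causal > m) stop("more causal variants than variants", call. = FALSE)
  structure(list(m = m, block_size = block_size, rho = rho,
                 maf_range = maf_range, n_causal_shared = n_causal_shared,
                 n_causal_A = n_causal_A, n_causal_B = n_causal_B,
                 effect_sd = effect_sd, n_train_eff = n_train_eff,
                 seed = as.integer(seed)),
            class = "architecture_spec")
}

# Deterministic layout derived from the architecture seed: variant grid,
# frequencies, causal assignment and true effects.
arch_layout <- function(arch) {
  with_seed(substream_seed(arch$seed, "layout"), {
    m <- arch$m
    blocks <- rep(seq_len(ceiling(m / arch$block_size)),
                  each = arch$block_size)[seq_len(m)]
    maf <- runif(m, arch$maf_range[1], arch$maf_range[2])
    # unambiguous allele pairs only, so strand never blocks harmonization
    pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                   c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
    pick <- sample.int(nrow(pairs), m, replace = TRUE)
    variants <- data.frame(
      variant_id = sprintf("var%05d", seq_len(m)),
      chrom = "1",
      pos = seq_len(m) * 5000L,
      allele_a = pairs[pick, 1],
      allele_b = pairs[pick, 2],
      stringsAsFactors = FALSE
    )
    total <- arch$n_causal_shared + arch$n_causal_A + arch$n_causal_B
    causal_blocks <- sample(max(blocks), total)
    causal_idx <- vapply(causal_blocks, function(b) {
      members <- which(blocks == b)
      members[sample.int(length(members), 1)]
    }, integer(1))
    shared <- causal_idx[seq_len(arch$n_causal_shared)]
    a_spec <- causal_idx[arch$n_causal_shared + seq_len(arch$n_causal_A)]
    b_spec <- causal_idx[arch$n_causal_shared + arch$n_causal_A +
                           seq_len(arch$n_causal_B)]
    b_shared <- b_aspec <- b_bspec <- numeric(m)
    b_shared[shared] <- rnorm(length(shared), 0, arch$effect_sd)
    b_aspec[a_spec] <- rnorm(length(a_spec), 0, arch$effect_sd)
    b_bspec[b_spec] <- rnorm(length(b_spec), 0, arch$effect_sd)
    list(variants = variants, maf = maf, blocks = blocks,
         causal = list(shared = shared, A = a_spec, B = b_spec),
         b_shared = b_shared, b_aspec = b_aspec, b_bspec = b_bspec)
  })
}

#' Simulate LD-blocked genotype dosages
#'
#' Each of the two haplotypes per sample is an AR(1) latent Gaussian
#' within LD blocks (independent across blocks), thresholded at
#' `qnorm(1 - maf)` to give an allele indicator; the dosage is the sum of
#' the two haplotypes. Deterministic given the seed.
#'
#' @param n number of samples (>= 2).
#' @param arch an [architecture_spec()].
#' @param seed seed for the genotype draw; defaults to a substream of the
#'   architecture seed.
#' @param missing_rate fraction of entries masked as missing (default 0).
#' @return A [genotype_matrix()].
#' @export
sim_genotypes <- function(n, arch, seed = NULL, missing_rate = 0) {
  stopifnot(n >= 2, missing_rate >= 0, missing_rate < 1)
  seed <- seed %||% substream_seed(arch$seed, "genotypes")
  lay <- arch_layout(arch)
  m <- arch$m
  d <- with_seed(seed, {
    thr <- qnorm(1 - lay$maf)
    d <- matrix(0, n, m)
    s <- sqrt(1 - arch$rho^2)
    for (b in unique(lay$blocks)) {
      cols <- which(lay$blocks == b)
      z <- matrix(0, 2 * n, length(cols))
      z[, 1] <- rnorm(2 * n)
      if (length(cols) > 1) {
        for (j in 2:length(cols)) {
          z[, j] <- arch$rho * z[, j - 1] + s * rnorm(2 * n)
        }
      }
      h <- sweep(z, 2, thr[cols], ">")
      d[, cols] <- h[seq_len(n), , drop = FALSE] +
        h[n + seq_len(n), , drop = FALSE]
    }
    if (missing_rate > 0) {
      d[runif(n * m) < missing_rate] <- NA_real_
    }
    d
  })
  genotype_matrix(d, lay$variants, sprintf("S%04d", seq_len(n)))
}

#' Simulate the four coupled training summary-statistics sets
#'
#' True per-variant standardized effects follow the shared/specific
#' decomposition `b_A = b_shared + b_Aspec`, `b_B = b_shared + b_Bspec`.
#' The four training sets are: combined cases versus controls with true
#' effect `(b_A + b_B)/2`; case-only contrast with `(b_A - b_B)/2`
#' (shared risk cancels, disorder-specific risk survives at half size);
#' and the two single-disorder scans with `b_A` and `b_B`. Estimates are
#' drawn analytically as `b + Normal(0, se^2)` with
#' `se = 1/sqrt(2 * n_train_eff * f(1-f))`, P-values from the Wald
#' statistic, and the odds-ratio column is `exp(bhat)`. A random half of
#' the variants is emitted with swapped alleles and negated weight, which
#' is statistically identical after harmonization and keeps the allele
#' orientation code honest.
#'
#' @param arch an [architecture_spec()].
#' @param seed seed for the estimate noise; defaults to a substream of the
#'   architecture seed.
#' @param flip_fraction fraction of rows emitted in swapped-allele
#'   orientation (default 0.5).
#' @return Named list of four [summary_stats()] objects (`SCZ_BD`,
#'   `SCZvsBD`, `SCZ`, `BD`) with attribute `true_effects`.
#' @export
sim_sumstats <- function(arch, seed = NULL, flip_fraction = 0.5) {
  seed <- seed %||% substream_seed(arch$seed, "sumstats")
  lay <- arch_layout(arch)
  b_A <- lay$b_shared + lay$b_aspec
  b_B <- lay$b_shared + lay$b_bspec
  truth <- list(SCZ_BD = (b_A + b_B) / 2, SCZvsBD = (b_A - b_B) / 2,
                SCZ = b_A, BD = b_B)
  se <- 1 / sqrt(2 * arch$n_train_eff * lay$maf * (1 - lay$maf))
  out <- with_seed(seed, {
    flip <- runif(arch$m) < flip_fraction
    lapply(truth, function(b) {
      bhat <- b + rnorm(arch$m) * se
      p <- pmin(pmax(2 * pnorm(-abs(bhat) / se), 1e-300), 1)
      ss <- summary_stats(
        variant_id = lay$variants$variant_id,
        chrom = lay$variants$chrom,
        pos = lay$variants$pos,
        effect_allele = ifelse(flip, lay$variants$allele_a,
                               lay$variants$allele_b),
        other_allele = ifelse(flip, lay$variants$allele_b,
                              lay$variants$allele_a),
        weight = ifelse(flip, -bhat, bhat),
        pvalue = p
      )
      ss
    })
  })
  attr(out, "true_effects") <- truth
  out
}

#' Phenotype (ROI volume) generator specification
#'
#' @param coupling which causal set drives the genetic component:
#'   `"null"` (none), `"shared"`, `"A-specific"`, `"B-specific"`.
#' @param target_delta_r2 designed incremental delta-R^2: the genetic
#'   component's share of total phenotype variance, in \[0, 1).
#' @param sign direction of the genetic association (default -1: higher
#'   risk burden, smaller volume).
#' @param intercept baseline volume, mm^3.
#' @param beta_sex,beta_icv,beta_age covariate effects (mm^3 per unit).
#' @param noise_sd residual standard deviation, mm^3.
#' @param missing_rate fraction of volumes masked missing (default 0).
#' @return A list of class `pheno_spec`.
#' @export
pheno_spec <- function(coupling = c("null", "shared", "A-specific",
                                    "B-specific"),
                       target_delta_r2 = 0, sign = -1, intercept = 4000,
                       beta_sex = 0, beta_icv = 0.002, beta_age = 0,
                       noise_sd = 400, missing_rate = 0) {
  coupling <- match.arg(coupling)
  if (target_delta_r2 < 0 || target_delta_r2 >= 1) {
    stop("target_delta_r2 must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(noise_sd > 0, missing_rate >= 0, missing_rate < 1)
  structure(list(coupling = coupling, target_delta_r2 = target_delta_r2,
                 sign = sign, intercept = intercept, beta_sex = beta_sex,
                 beta_icv = beta_icv, beta_age = beta_age,
                 noise_sd = noise_sd, missing_rate = missing_rate),
            class = "pheno_spec")
}

#' Default six-ROI phenotype battery
#'
#' Mirrors the qualitative pattern the pipeline is designed to detect: a
#' globus-pallidus-like structure negatively coupled to the shared genetic
#' component (designed delta-R^2 0.022), an amygdala-like structure
#' negatively coupled to the B-specific (bipolar-like) component
#' (designed delta-R^2 0.020), and four null structures. Intercepts,
#' covariate effects and noise are plausible adult subcortical values in
#' mm^3.
#'
#' @return Named list of [pheno_spec()] objects.
#' @export
default_pheno_specs <- function() {
  list(
    thalamus = pheno_spec("null", intercept = 7500, beta_sex = -120,
                          beta_icv = 0.0030, noise_sd = 700),
    hippocampus = pheno_spec("null", intercept = 4200, beta_sex = -80,
                             beta_icv = 0.0018, noise_sd = 420),
    amygdala = pheno_spec("B-specific", target_delta_r2 = 0.020,
                          intercept = 1700, beta_sex = -50,
                          beta_icv = 0.0008, noise_sd = 180),
    globus_pallidus = pheno_spec("shared", target_delta_r2 = 0.022,
                                 intercept = 1800, beta_sex = -40,
                                 beta_icv = 0.0008, noise_sd = 180),
    caudate = pheno_spec("null", intercept = 3700, beta_sex = -70,
                         beta_icv = 0.0016, noise_sd = 380),
    lateral_ventricles = pheno_spec("null", intercept = 1500,
                                    beta_sex = -150, beta_icv = 0.0040,
                                    beta_age = 40, noise_sd = 1800)
  )
}

#' Simulate ROI volumes with covariates and a designed genetic component
#'
#' Demographics emulate a young healthy imaging-genetics cohort: sex
#' drawn Bernoulli(0.714) (1 = female), age Normal(24.77, 6.86^2) years,
#' ICV Normal around 1.6e6 mm^3 with a sex difference. For each ROI the
#' genetic value `G` is the true-effect-weighted dosage sum over the
#' causal set named by `coupling`, rescaled so that its share of the
#' total phenotype variance equals `target_delta_r2` -- i.e. the designed
#' value is on the same scale as the incremental delta-R^2 the
#' association stage reports (genetic variance over total variance,
#' since the covariates are orthogonal to genotype by construction).
#' The scaled component is then added with the configured sign on top of
#' the covariate structure plus Gaussian noise.
#'
#' @param gm a [genotype_matrix()] simulated from `arch`.
#' @param arch the [architecture_spec()] used for `gm`.
#' @param pheno named list of [pheno_spec()] objects (ROI name -> spec).
#' @param seed seed; defaults to a substream of the architecture seed.
#' @param female_frac,age_mean,age_sd cohort demographics.
#' @return A [phenotype_table()] with attribute `true_genetic` (the list
#'   of scaled genetic values actually injected per ROI).
#' @export
sim_phenotypes <- function(gm, arch, pheno = default_pheno_specs(),
                           seed = NULL, female_frac = 0.714,
                           age_mean = 24.77, age_sd = 6.86) {
  seed <- seed %||% substream_seed(arch$seed, "phenotypes")
  lay <- arch_layout(arch)
  n <- nrow(gm$dosages)
  with_seed(seed, {
    sex <- rbinom(n, 1, female_frac)
    age <- rnorm(n, age_mean, age_sd)
    icv <- 1.6e6 - 1.5e5 * sex + rnorm(n, 0, 1.0e5)
    df <- data.frame(sample_id = gm$sample_ids, sex = sex, age = age,
                     icv = icv, stringsAsFactors = FALSE)
    true_g <- list()
    for (roi in names(pheno)) {
      sp <- pheno[[roi]]
      base <- sp$intercept + sp$beta_sex * sex + sp$beta_icv * icv +
        sp$beta_age * age
      gshift <- 0
      if (sp$coupling != "null" && sp$target_delta_r2 > 0) {
        set <- switch(sp$coupling,
                      shared = list(lay$causal$shared, lay$b_shared),
                      `A-specific` = list(lay$causal$A, lay$b_aspec),
                      `B-specific` = list(lay$causal$B, lay$b_bspec))
        idx <- set[[1]]
        if (!length(idx)) {
          stop("coupling '", sp$coupling, "' has no causal variants in ",
               "this architecture", call. = FALSE)
        }
        dsub <- gm$dosages[, idx, drop = FALSE]
        if (anyNA(dsub)) {  # impute for generation only
          fm <- colMeans(dsub, na.rm = TRUE)
          nas <- which(is.na(dsub), arr.ind = TRUE)
          dsub[nas] <- fm[nas[, 2]]
        }
        G <- as.vector(dsub %*% set[[2]][idx])
        sg <- sd(G)
        if (sg > 0) {
          # scale so the OLS increment delta-R^2 (genetic variance over
          # total phenotype variance, covariates included) hits the target:
          # v_g = t/(1-t) * (v_covariates + v_noise)
          t <- sp$target_delta_r2
          v_rest <- var(base) + sp$noise_sd^2
          cscale <- sqrt(t / (1 - t) * v_rest) / sg
          gshift <- sp$sign * cscale * (G - mean(G))
        }
      }
      v <- base + gshift + rnorm(n, 0, sp$noise_sd)
      v <- pmax(v, 1)  # volumes are physical; guard the extreme tail
      if (sp$missing_rate > 0) v[runif(n) < sp$missing_rate] <- NA_real_
      df[[roi]] <- v
      true_g[[roi]] <- gshift
    }
    pt <- phenotype_table(df, names(pheno))
    attr(pt, "true_genetic") <- true_g
    pt
  })
}
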