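test_that("fit_increment matches the normal-equations oracle on a fixed dataset", {
  # fixed 6-sample dataset with one covariate
  y <- c(3.1, 4.0, 2.2, 5.5, 4.8, 3.3)
  g <- c(0.2, -1.0, 0.8, -0.3, 1.5, 0.0)
  X <- cbind(cov1 = c(10, 12, 9, 15, 14, 11))
  got <- fit_increment(y, g, X)
  want <- oracle_fit(y, g, X)
  expect_equal(got$beta, want$beta, tolerance = 1e-12)
  expect_equal(got$delta_r2, want$delta_r2, tolerance = 1e-12)
  expect_equal(got$n_used, want$n_used)
  # nominal p agrees with lm's t-test
  lm_p <- summary(lm(scale(y) ~ X + scale(g)))$coefficients[3, 4]
  expect_equal(got$p_nominal, lm_p, tolerance = 1e-10)
})

test_that("fit_increment handles the perfect and null extremes", {
  set.seed(10)
  y <- rnorm(50)
  perfect <- fit_increment(y, y)
  expect_equal(perfect$beta, 1)
  expect_equal(perfect$delta_r2, 1)
  expect_lt(perfect$p_nominal, 1e-20)

  n <- 10000
  y2 <- rnorm(n)
  g2 <- rnorm(n)  # independent of y2
  nul <- fit_increment(y2, g2, cbind(x = rnorm(n)))
  expect_lt(nul$delta_r2, 0.001)
})

test_that("delta_r2 is non-negative and obeys the partial-R2 identity", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(30:120, 1)
    X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
    g <- rnorm(n) + 0.3 * X[, 1]
    y <- 0.5 * X[, 1] + 0.2 * g + rnorm(n)
    f <- fit_increment(y, g, X)
    expect_gte(f$delta_r2, 0)
    expect_true(is.finite(f$beta))
    expect_equal(f$delta_r2, f$r2_full - f$r2_cov, tolerance = 1e-12)
  }
  # for uncorrelated (orthogonal) covariates the textbook relation holds
  for (i in 1:10) {
    n <- 4000
    X <- cbind(a = rnorm(n))
    g <- rnorm(n)
    y <- 0.4 * X[, 1] + 0.1 * g + rnorm(n)
    f <- fit_increment(y, g, X)
    expect_equal(f$beta^2, f$delta_r2 / (1 - f$r2_cov), tolerance = 0.02)
  }
})

test_that("complete-case handling drops exactly the missing samples", {
  set.seed(5)
  n <- 60
  y <- rnorm(n); g <- rnorm(n); X <- cbind(a = rnorm(n))
  base <- fit_increment(y, g, X)
  y2 <- y; y2[1:7] <- NA
  expect_equal(fit_increment(y2, g, X)$n_used, base$n_used - 7)
  g2 <- g; g2[8:9] <- NA
  X2 <- X; X2[10, 1] <- NA
  expect_equal(fit_increment(y2, g2, X2)$n_used, n - 10)
})

test_that("degenerate designs error informatively", {
  y <- rnorm(30); g <- rnorm(30)
  X <- cbind(a = rep(2, 30))  # collinear with the intercept
  expect_error(fit_increment(y, g, X), "collinear")
  expect_error(fit_increment(y[1:4], g[1:4]), "complete cases")
})

test_that("permutation_p equals the brute-force lm-refit oracle", {
  set.seed(21)
  n <- 40
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
  g <- rnorm(n)
  y <- 0.3 * g + 0.5 * X[, 1] + rnorm(n)
  for (seed in c(1, 99)) {
    got <- permutation_p(y, g, X, n_perm = 300, seed = seed)
    want <- oracle_perm_p(y, g, X, n_perm = 300, seed = seed)
    expect_equal(got, want)
  }
  # missing data: both paths drop the same complete cases
  y_na <- y; y_na[1:3] <- NA
  expect_equal(permutation_p(y_na, g, X, n_perm = 200, seed = 7),
               oracle_perm_p(y_na, g, X, n_perm = 200, seed = 7))
})

test_that("permutation_p behaves at the extremes and is seed-reproducible", {
  set.seed(31)
  n <- 60
  X <- cbind(a = rnorm(n))
  y <- rnorm(n) + X[, 1]
  # make g exactly orthogonal to the covariate-residualized phenotype
  C <- cbind(1, X)
  ry <- y - C %*% solve(crossprod(C), crossprod(C, y))
  g <- rnorm(n)
  g <- g - as.vector(ry) * sum(g * ry) / sum(ry^2)
  expect_gt(permutation_p(y, g, X, n_perm = 500, seed = 2), 0.95)

  # perfectly collinear score: no permutation can beat it
  y2 <- rnorm(200)
  expect_equal(permutation_p(y2, y2, n_perm = 500, seed = 3), 0)
  expect_equal(permutation_p(y2, y2, n_perm = 500, seed = 3,
                             estimator = "add_one"), 1 / 501)

  g3 <- rnorm(n)
  expect_identical(permutation_p(y, g3, X, n_perm = 400, seed = 5),
                   permutation_p(y, g3, X, n_perm = 400, seed = 5))
  # Freedman-Lane option runs and lands in the same neighbourhood
  pf <- permutation_p(y, g3, X, n_perm = 2000, seed = 5,
                      method = "freedman_lane")
  ps <- permutation_p(y, g3, X, n_perm = 2000, seed = 5)
  expect_lt(abs(pf - ps), 0.1)
})

assoc_fixture <- function(n = 150, seed = 9) {
  arch <- architecture_spec(m = 400, block_size = 10, n_causal_shared = 12,
                            n_causal_A = 12, n_causal_B = 12, seed = seed)
  gm <- sim_genotypes(n, arch)
  pt <- sim_phenotypes(gm, arch, list(
    globus_pallidus = pheno_spec("shared", target_delta_r2 = 0.12,
                                 intercept = 1800, beta_icv = 8e-4,
                                 noise_sd = 180),
    caudate = pheno_spec("null", intercept = 3700, beta_icv = 16e-4,
                         noise_sd = 380),
    lateral_ventricles = pheno_spec("null", intercept = 1500,
                                    beta_age = 40, beta_icv = 40e-4,
                                    noise_sd = 1800)))
  ss <- suppressWarnings(harmonize(sim_sumstats(arch)$SCZ_BD, gm))
  cr <- ld_clump(ss, gm)
  ssi <- ss[ss$variant_id %in% cr$index$variant_id, ]
  class(ssi) <- class(ss)
  sp <- standardize_scores(suppressWarnings(prs_score(gm, ssi)),
                           na_degenerate = TRUE)
  list(pt = pt, sp = sp)
}

test_that("run_association produces one row per cell with the right policies", {
  fx <- assoc_fixture()
  res <- run_association(fx$pt, list(SCZ_BD = fx$sp), n_perm = 200,
                         seed = 4)
  expect_s3_class(res, "assoc_table")
  expect_equal(nrow(res), 6 * 3)  # 6 thresholds x 3 ROIs x 1 set
  expect_true(all(res$delta_r2[!is.na(res$delta_r2)] >= 0))
  # permutations only where nominally significant
  expect_true(all(is.na(res$p_perm[res$p_nominal >= 0.05])))
  expect_true(all(!is.na(res$p_perm[res$p_nominal < 0.05])))
  # cells flagged significant are a subset of nominally significant cells
  expect_true(all(res$p_nominal[res$significant] < 0.05))
  # p_perm granularity is 1/n_perm
  pp <- res$p_perm[!is.na(res$p_perm)]
  expect_true(all(abs(pp * 200 - round(pp * 200)) < 1e-9))

  none <- run_association(fx$pt, list(SCZ_BD = fx$sp), perm_policy = "none",
                          seed = 4)
  expect_true(all(is.na(none$p_perm)))
  alln <- run_association(fx$pt, list(SCZ_BD = fx$sp), perm_policy = "all",
                          n_perm = 50, seed = 4)
  expect_true(all(!is.na(alln$p_perm)))
})

test_that("run_association validates ROIs, missing data, and score alignment", {
  fx <- assoc_fixture(n = 100, seed = 13)
  expect_error(run_association(fx$pt, list(A = fx$sp), rois = "nucleus_x"),
               "nucleus_x")
  pt2 <- fx$pt
  pt2$caudate <- NA_real_
  class(pt2) <- class(fx$pt)
  attr(pt2, "rois") <- attr(fx$pt, "rois")
  expect_error(run_association(pt2, list(A = fx$sp), perm_policy = "none"),
               "caudate")
  expect_error(run_association(fx$pt, list(fx$sp)), "named")

  # shuffled phenotype rows give identical results (alignment by sample id)
  perm <- sample.int(nrow(fx$pt))
  pt3 <- fx$pt[perm, ]
  class(pt3) <- class(fx$pt)
  attr(pt3, "rois") <- attr(fx$pt, "rois")
  r1 <- run_association(fx$pt, list(A = fx$sp), perm_policy = "none")
  r3 <- run_association(pt3, list(A = fx$sp), perm_policy = "none")
  expect_equal(r3$beta, r1$beta, tolerance = 1e-12)
})

test_that("age joins the covariates only for the configured ROIs", {
  fx <- assoc_fixture(n = 120, seed = 23)
  res <- run_association(fx$pt, list(A = fx$sp), perm_policy = "none")
  # recompute one ventricle cell by hand with age included
  g <- fx$sp$scores[match(fx$pt$sample_id, fx$sp$sample_ids), 6]
  withage <- fit_increment(fx$pt$lateral_ventricles, g,
                           as.matrix(fx$pt[, c("sex", "icv", "age")]))
  cell <- res[res$roi == "lateral_ventricles" & res$p_t == 0.5, ]
  expect_equal(cell$beta, withage$beta, tolerance = 1e-12)
  noage <- fit_increment(fx$pt$lateral_ventricles, g,
                         as.matrix(fx$pt[, c("sex", "icv")]))
  expect_false(isTRUE(all.equal(cell$beta, noage$beta)))
})
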