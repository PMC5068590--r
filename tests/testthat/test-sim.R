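test_that("generators are bit-reproducible and replicates are independent", {
  arch <- architecture_spec(m = 150, block_size = 10, n_causal_shared = 5,
                            n_causal_A = 5, n_causal_B = 5, seed = 31)
  g1 <- sim_genotypes(80, arch)
  g2 <- sim_genotypes(80, arch)
  expect_identical(g1$dosages, g2$dosages)
  g3 <- sim_genotypes(80, arch, seed = 999)
  expect_false(identical(g1$dosages, g3$dosages))
  # cross-replicate dosage correlation ~ 0
  cors <- vapply(1:150, function(j) {
    if (sd(g1$dosages[, j]) == 0 || sd(g3$dosages[, j]) == 0) return(0)
    cor(g1$dosages[, j], g3$dosages[, j])
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.03)

  s1 <- sim_sumstats(arch)
  s2 <- sim_sumstats(arch)
  expect_identical(s1$SCZ$weight, s2$SCZ$weight)
  p1 <- sim_phenotypes(g1, arch)
  p2 <- sim_phenotypes(g1, arch)
  expect_identical(p1$globus_pallidus, p2$globus_pallidus)
})

test_that("realized allele frequencies track their targets", {
  arch <- architecture_spec(m = 200, block_size = 10, n_causal_shared = 0,
                            n_causal_A = 0, n_causal_B = 0, seed = 8)
  gm <- sim_genotypes(5000, arch)
  lay <- prsvol:::arch_layout(arch)
  expect_true(all(abs(allele_frequencies(gm) - lay$maf) < 0.05))
})

test_that("rho = 0 gives independent variants; rho > 0 gives within-block LD", {
  arch0 <- architecture_spec(m = 100, block_size = 10, rho = 0,
                             n_causal_shared = 0, n_causal_A = 0,
                             n_causal_B = 0, seed = 4)
  n <- 400
  gm0 <- sim_genotypes(n, arch0)
  cm <- cor(gm0$dosages)^2
  off <- cm[upper.tri(cm)]
  # E[r^2] under independence is ~ 1/n
  expect_lt(mean(off), 2.5 / n)
  expect_gt(mean(off), 0.4 / n)

  arch9 <- architecture_spec(m = 100, block_size = 10, rho = 0.9,
                             n_causal_shared = 0, n_causal_A = 0,
                             n_causal_B = 0, seed = 4)
  gm9 <- sim_genotypes(n, arch9)
  lay <- prsvol:::arch_layout(arch9)
  same_block <- outer(lay$blocks, lay$blocks, "==")
  cm9 <- cor(gm9$dosages)^2
  adj <- cm9[cbind(1:99, 2:100)][lay$blocks[1:99] == lay$blocks[2:100]]
  expect_gt(mean(adj), 0.25)  # adjacent in-block variants strongly linked
})

test_that("null architectures give uniform P-values in all four sets", {
  arch <- architecture_spec(m = 2000, block_size = 10, n_causal_shared = 0,
                            n_causal_A = 0, n_causal_B = 0, seed = 55)
  ssl <- sim_sumstats(arch)
  for (set in names(ssl)) {
    ks <- suppressWarnings(ks.test(ssl[[set]]$pvalue, "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("training estimates are consistent as n_train_eff grows", {
  arch <- architecture_spec(m = 200, block_size = 5, n_causal_shared = 10,
                            n_causal_A = 10, n_causal_B = 10,
                            n_train_eff = 1e7, seed = 12)
  ssl <- sim_sumstats(arch)
  truth <- attr(ssl, "true_effects")
  lay <- prsvol:::arch_layout(arch)
  causal <- unlist(lay$causal)
  for (set in names(ssl)) {
    # undo the deliberate allele flip before comparing to truth
    w <- ssl[[set]]$weight
    flip <- ssl[[set]]$effect_allele == lay$variants$allele_a
    w[flip] <- -w[flip]
    expect_true(all(abs(w[causal] - truth[[set]][causal]) < 0.01))
  }
})

test_that("the four sets obey the shared/specific effect algebra", {
  arch <- architecture_spec(m = 100, block_size = 5, n_causal_shared = 6,
                            n_causal_A = 6, n_causal_B = 6, seed = 19)
  ssl <- sim_sumstats(arch)
  truth <- attr(ssl, "true_effects")
  lay <- prsvol:::arch_layout(arch)
  a_only <- lay$causal$A
  expect_equal(truth$SCZvsBD[a_only], truth$SCZ[a_only] / 2)
  expect_equal(truth$SCZ_BD[a_only], truth$SCZ[a_only] / 2)
  b_only <- lay$causal$B
  expect_equal(truth$SCZvsBD[b_only], -truth$BD[b_only] / 2)
  shared <- lay$causal$shared
  expect_equal(truth$SCZvsBD[shared], rep(0, length(shared)))
  expect_equal(truth$SCZ_BD[shared], truth$SCZ[shared])
})

test_that("cohort demographics match the design at n = 274", {
  arch <- architecture_spec(m = 60, block_size = 10, n_causal_shared = 2,
                            n_causal_A = 2, n_causal_B = 2, seed = 3)
  gm <- sim_genotypes(274, arch)
  pt <- sim_phenotypes(gm, arch)
  expect_lt(abs(mean(pt$sex) - 0.714), 0.09)
  expect_lt(abs(mean(pt$age) - 24.77), 1.4)
  expect_lt(abs(sd(pt$age) - 6.86), 1.4)
  expect_true(all(attr(pt, "rois") %in% names(pt)))
  expect_true(all(pt$icv > 0))
})

test_that("designed delta-R2 is recovered by the true causal score", {
  arch <- architecture_spec(m = 300, block_size = 10, n_causal_shared = 20,
                            n_causal_A = 5, n_causal_B = 5, seed = 101)
  lay <- prsvol:::arch_layout(arch)
  gm <- sim_genotypes(8000, arch, seed = 555)
  pt <- sim_phenotypes(gm, arch, list(
    globus_pallidus = pheno_spec("shared", target_delta_r2 = 0.02,
                                 intercept = 1800, beta_sex = -40,
                                 beta_icv = 8e-4, noise_sd = 180),
    caudate = pheno_spec("null", intercept = 3700, beta_icv = 16e-4,
                         noise_sd = 380)), seed = 556)
  g_true <- as.vector(gm$dosages[, lay$causal$shared] %*%
                        lay$b_shared[lay$causal$shared])
  X <- as.matrix(as.data.frame(pt)[, c("sex", "icv")])
  f <- fit_increment(pt$globus_pallidus, g_true, X)
  expect_lt(abs(f$delta_r2 - 0.02), 0.01)
  f0 <- fit_increment(pt$caudate, g_true, X)
  expect_lt(f0$delta_r2, 0.004)
})

test_that("spec constructors validate their domains", {
  expect_error(architecture_spec(m = 100, block_size = 10, rho = 1), "rho")
  expect_error(architecture_spec(m = 20, block_size = 10,
                                 n_causal_shared = 30), "blocks")
  expect_error(pheno_spec("shared", target_delta_r2 = 1), "target_delta_r2")
  expect_error(prs_thresholds(c(0.5, 0.1)), "increasing")
  expect_error(clump_params(r2_threshold = 0), "r2_threshold")
})
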