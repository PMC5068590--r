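make_gm <- function(d, pos = seq_len(ncol(d)) * 1000L, chrom = "1") {
  m <- ncol(d)
  variants <- data.frame(variant_id = paste0("v", seq_len(m)),
                         chrom = rep(chrom, length.out = m), pos = pos,
                         allele_a = "A", allele_b = "G")
  genotype_matrix(d, variants, paste0("s", seq_len(nrow(d))))
}

make_ss <- function(gm, pvalue, weight = 0.1) {
  summary_stats(gm$variants$variant_id, gm$variants$chrom, gm$variants$pos,
                gm$variants$allele_b, gm$variants$allele_a,
                rep(weight, length.out = ncol(gm$dosages)), pvalue)
}

test_that("pairwise_r2 matches hand Pearson arithmetic and is sign-free", {
  gm <- make_gm(cbind(c(0, 2, 0, 2), c(0, 2, 0, 2), c(2, 0, 2, 0),
                      c(0, 1, 2, 0), c(0, 1, 1, 0)))
  expect_equal(pairwise_r2(gm, 1, 2), 1)
  expect_equal(pairwise_r2(gm, 1, 3), 1)  # r = -1, r^2 = 1

  # hand covariance/variance arithmetic for (0,1,2,0) vs (0,1,1,0)
  x <- c(0, 1, 2, 0); y <- c(0, 1, 1, 0)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  hand <- sxy^2 / (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pairwise_r2(gm, 4, 5), hand)
  expect_equal(pairwise_r2(gm, "v4", "v5"), hand)
})

test_that("pairwise_r2 uses pairwise-complete samples and flags degeneracy", {
  gm <- make_gm(cbind(c(0, 1, 2, NA), c(0, 1, 2, 2), c(1, 1, 1, 1),
                      c(NA, NA, NA, 0)))
  expect_equal(pairwise_r2(gm, 1, 2), 1)  # overlap (0,1,2) vs (0,1,2)
  expect_error(pairwise_r2(gm, 2, 3), "zero dosage variance")
  expect_error(pairwise_r2(gm, 1, 4), "overlapping")
})

test_that("ld_clump keeps independent variants and prunes perfect LD by P", {
  set.seed(42)
  d <- matrix(rbinom(100 * 3, 2, 0.4), 100, 3)
  gm <- make_gm(d)  # independent draws: r^2 well below 0.25
  ss <- make_ss(gm, pvalue = c(0.01, 0.02, 0.03))
  res <- ld_clump(ss, gm)
  expect_equal(nrow(res$index), 3L)
  expect_length(res$clumped_by, 0)

  x <- rbinom(50, 2, 0.5)
  gm2 <- make_gm(cbind(x, x), pos = c(100000L, 110000L))  # 10 kb apart
  ss2 <- make_ss(gm2, pvalue = c(1e-4, 1e-8))
  res2 <- ld_clump(ss2, gm2)
  expect_equal(res2$index$variant_id, "v2")  # the 1e-8 variant wins
  expect_equal(unname(res2$clumped_by["v1"]), "v2")
  expect_equal(res2$index$n_members, 1L)

  # outside the window nothing is pruned regardless of LD
  gm3 <- make_gm(cbind(x, x), pos = c(1L, 600001L))
  res3 <- ld_clump(make_ss(gm3, c(1e-4, 1e-8)), gm3)
  expect_equal(nrow(res3$index), 2L)

  expect_equal(nrow(ld_clump(ss[0, ], gm)$index), 0L)
})

test_that("greedy clumping matches the exhaustive re-scan oracle", {
  for (seed in 1:60) {
    inst <- random_clump_instance(seed, n = 40, max_m = 120)
    got <- suppressWarnings(ld_clump(inst$ss, inst$gm, inst$params))
    want <- suppressWarnings(oracle_clump(inst$ss, inst$gm, inst$params))
    expect_identical(got$index$variant_id, want$index,
                     label = paste("index set, seed", seed))
    by_name <- function(x) if (length(x)) x[order(names(x))] else character(0)
    expect_identical(by_name(got$clumped_by), by_name(want$clumped_by),
                     label = paste("clump assignment, seed", seed))
  }
})

test_that("clump output is invariant to input row order", {
  inst <- random_clump_instance(999, n = 40, max_m = 100)
  base <- suppressWarnings(ld_clump(inst$ss, inst$gm, inst$params))
  set.seed(1)
  perm <- sample.int(nrow(inst$ss))
  ss_shuf <- inst$ss[perm, ]
  class(ss_shuf) <- class(inst$ss)
  shuf <- suppressWarnings(ld_clump(ss_shuf, inst$gm, inst$params))
  expect_identical(shuf$index$variant_id, base$index$variant_id)
})

test_that("raising the r2 threshold never shrinks the index set, and removed
           variants really violate window/threshold against their index", {
  for (seed in c(7, 21, 77)) {
    inst <- random_clump_instance(seed, n = 40, max_m = 120)
    sizes <- vapply(c(0.1, 0.3, 0.6, 0.9), function(r2) {
      p <- clump_params(r2, inst$params$window_kb, inst$params$p1)
      nrow(suppressWarnings(ld_clump(inst$ss, inst$gm, p))$index)
    }, numeric(1))
    expect_true(all(diff(sizes) >= 0))

    res <- suppressWarnings(ld_clump(inst$ss, inst$gm, inst$params))
    expect_length(intersect(res$index$variant_id, names(res$clumped_by)), 0)
    expect_setequal(c(res$index$variant_id, names(res$clumped_by)),
                    inst$ss$variant_id[inst$ss$pvalue <= inst$params$p1])
    for (v in names(res$clumped_by)) {
      idx <- res$clumped_by[[v]]
      i <- match(v, inst$ss$variant_id)
      j <- match(idx, inst$ss$variant_id)
      expect_equal(inst$ss$chrom[i], inst$ss$chrom[j])
      expect_lte(abs(inst$ss$pos[i] - inst$ss$pos[j]),
                 inst$params$window_kb * 1000)
      r2 <- suppressWarnings(tryCatch(pairwise_r2(inst$gm, v, idx),
                                      error = function(e) 0))
      expect_gt(r2, inst$params$r2_threshold)
    }
  }
})
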