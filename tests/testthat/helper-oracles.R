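# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths (lm/solve/explicit loops instead of
# lm.fit/vectorized scans).

# Exhaustive clumping reference: after every index selection, re-scan the
# full remaining list for window/r2 hits.
oracle_clump <- function(ss, gm, params) {
  ss <- as.data.frame(ss)
  ss <- ss[ss$pvalue <= params$p1, , drop = FALSE]
  remaining <- seq_len(nrow(ss))
  index <- character(0)
  clumped_by <- character(0)
  window_bp <- params$window_kb * 1000
  col_of <- match(ss$variant_id, gm$variants$variant_id)
  while (length(remaining)) {
    o <- order(ss$pvalue[remaining], ss$chrom[remaining], ss$pos[remaining])
    k <- remaining[o[1]]
    index <- c(index, ss$variant_id[k])
    remaining <- setdiff(remaining, k)
    hits <- integer(0)
    for (j in remaining) {
      if (ss$chrom[j] != ss$chrom[k]) next
      if (abs(ss$pos[j] - ss$pos[k]) > window_bp) next
      x <- gm$dosages[, col_of[k]]
      y <- gm$dosages[, col_of[j]]
      ok <- !is.na(x) & !is.na(y)
      r2 <- if (sum(ok) < 2 || sd(x[ok]) == 0 || sd(y[ok]) == 0) 0
            else cor(x[ok], y[ok])^2
      # same tie-guard as the contract: exceed the threshold beyond fp noise
      if (r2 > params$r2_threshold + 1e-12) hits <- c(hits, j)
    }
    if (length(hits)) {
      clumped_by[ss$variant_id[hits]] <- ss$variant_id[k]
      remaining <- setdiff(remaining, hits)
    }
  }
  list(index = index, clumped_by = clumped_by)
}

# Normal-equations OLS oracle for the incremental fit.
oracle_fit <- function(y, g, X = NULL) {
  cc <- !is.na(y) & !is.na(g)
  if (!is.null(X)) cc <- cc & complete.cases(as.matrix(X))
  y <- y[cc]; g <- g[cc]
  yz <- (y - mean(y)) / sd(y)
  gz <- (g - mean(g)) / sd(g)
  C <- cbind(1, if (!is.null(X)) as.matrix(X)[cc, , drop = FALSE])
  M <- cbind(C, gz)
  b_full <- solve(t(M) %*% M, t(M) %*% yz)
  b_cov <- solve(t(C) %*% C, t(C) %*% yz)
  rss <- function(A, b) sum((yz - A %*% b)^2)
  tss <- sum((yz - mean(yz))^2)
  r2f <- 1 - rss(M, b_full) / tss
  r2c <- 1 - rss(C, b_cov) / tss
  list(beta = b_full[length(b_full)], delta_r2 = r2f - r2c,
       n_used = length(y))
}

# Brute-force permutation p-value: refit lm() per permutation and compare
# nominal p-values, exactly as defined.
oracle_perm_p <- function(y, g, X = NULL, n_perm, seed) {
  cc <- !is.na(y) & !is.na(g)
  if (!is.null(X)) cc <- cc & complete.cases(as.matrix(X))
  y <- y[cc]; g <- g[cc]
  X <- if (is.null(X)) NULL else as.matrix(X)[cc, , drop = FALSE]
  pval_of <- function(gg) {
    dat <- data.frame(y = y, g = gg)
    form <- if (is.null(X)) y ~ g else y ~ X + g
    summary(lm(form, data = dat))$coefficients["g", 4]
  }
  p_obs <- pval_of(g)
  set.seed(seed)
  k <- 0
  for (b in seq_len(n_perm)) {
    p_star <- pval_of(g[sample.int(length(g))])
    if (p_star < p_obs) k <- k + 1
  }
  k / n_perm
}

# Random clumping instance: LD-blocked dosages with randomized positions,
# chromosomes, P-values and window, so the greedy path is stressed.
random_clump_instance <- function(seed, n = 50, max_m = 200) {
  set.seed(seed)
  m <- sample(10:max_m, 1)
  arch <- architecture_spec(
    m = m, block_size = sample(c(3, 5, 10, 25), 1),
    rho = runif(1, 0, 0.95), maf_range = c(0.1, 0.5),
    n_causal_shared = 0, n_causal_A = 0, n_causal_B = 0,
    seed = sample.int(1e6, 1))
  gm <- sim_genotypes(n, arch, seed = sample.int(1e6, 1))
  ss <- summary_stats(
    variant_id = gm$variants$variant_id,
    chrom = sample(c("1", "2"), m, replace = TRUE),
    pos = sort(sample.int(5e5, m)),
    effect_allele = gm$variants$allele_b,
    other_allele = gm$variants$allele_a,
    weight = rnorm(m, 0, 0.1),
    pvalue = runif(m)
  )
  params <- clump_params(
    r2_threshold = sample(c(0.1, 0.25, 0.5, 0.8), 1),
    window_kb = sample(c(10, 50, 100, 500), 1),
    p1 = sample(c(0.8, 1), 1))
  list(ss = ss, gm = gm, params = params)
}

# Small deterministic genotype fixture used across io tests.
tiny_gm <- function() {
  d <- rbind(c(0, 2, 1, NA),
             c(1, 1, 0.5, 2),
             c(2, 0, 1.2, 0),
             c(0, NA, 2, 1))
  variants <- data.frame(
    variant_id = c("v1", "v2", "v3", "v4"),
    chrom = c("1", "1", "2", "2"),
    pos = c(1000L, 2000L, 1000L, 5000L),
    allele_a = c("A", "G", "C", "T"),
    allele_b = c("G", "A", "T", "C"),
    stringsAsFactors = FALSE)
  genotype_matrix(d, variants, c("s1", "s2", "s3", "s4"))
}
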