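---
title: "Methods: polygenic risk scoring against subcortical volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic risk scoring against subcortical volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A recurring question in psychiatric imaging genetics is whether the brain
structural differences seen in patients with schizophrenia (SCZ) and
bipolar disorder (BD) are driven by genetic liability or are secondary to
illness and treatment. One way to address it is to score *healthy*
individuals for common-variant risk and ask whether the score predicts
regional brain volumes. Because the two disorders overlap substantially
in their common genetic architecture, four training scans are
informative: the combined case-versus-control scan (shared plus specific
risk), the case-versus-case scan (specific risk only, shared risk
cancels), and the two single-disorder scans.

`prsvol` implements that full analysis as a reusable pipeline: summary
statistics are harmonized to target-cohort dosages, frequency-filtered,
LD-clumped, summed into log-odds-weighted scores at a ladder of P-value
thresholds, and regressed against hemisphere-averaged region-of-interest
(ROI) volumes after covariates, with permutation-based significance and
a Fisher-z power calculator. A synthetic-data generator reproduces the
statistical structure the analysis assumes, so every stage is testable
without access to individual-level cohort data.

## The scoring model

For sample $i$ and threshold $P_T$, the risk score is

$$ S_i(P_T) = \sum_{j\,:\,P_j < P_T} \hat\beta_j \, d_{ij}, $$

where $\hat\beta_j = \log \mathrm{OR}_j$ is the training log odds ratio
oriented to the dosage allele and $d_{ij} \in [0,2]$ the imputed dosage.
Choices that matter:

* **Threshold comparison is strict** (`P < P_T`), and the default ladder
  is $\{10^{-5}, 10^{-4}, 0.01, 0.1, 0.3, 0.5\}$.
* **MAF filtering is strict** (`MAF < 0.01` removed, computed in the
  target cohort from non-missing dosages, folded to $\le 0.5$).
* **Missing dosages are mean-imputed ($2f_j$) at scoring time only**;
  the stored matrix keeps its `NA`s. This matches standard scoring-tool
  behaviour and keeps expectations unbiased.
* **Sum versus average.** The default is the plain weighted sum (the
  wording most descriptions use); `mode = "average"` divides by each
  sample's non-missing allele count, the default of the common
  command-line scorer. With complete data the two differ only by the
  constant $2m_{P_T}$.
* **Harmonization.** Weights are re-oriented to the target's counted
  allele (kept when aligned, negated when swapped, strand-complemented
  first when necessary). A/T and C/G pairs are unresolvable by
  complementation and are dropped by default; frequency-based rescue is
  deliberately out of scope. Matching is by variant id, with a
  `(chrom, pos)` option.

## Clumping

Greedy P-value-ordered clumping with the conventional parameters:
`r2_threshold = 0.25` (removal requires $r^2$ *strictly greater*),
`window_kb = 500` interpreted as $\pm 500$ kb around the index, LD
estimated in the target cohort itself on pairwise-complete dosages. Ties
in P break by chromosome then position so the result is deterministic.
A variant with zero dosage variance has undefined LD and is treated as
$r^2 = 0$ with a warning rather than an error, since such variants
cannot shadow anything. The greedy single pass is equivalent to the
re-scan formulation (an index, once chosen, is never removed); the test
suite checks exact equivalence against an independent exhaustive
implementation on hundreds of randomized instances. For complete
dosage matrices of moderate width the implementation computes the full
correlation matrix in one BLAS call; otherwise it falls back to
per-index pairwise-complete correlations.

## Association and permutation

Each (ROI, training set, threshold) cell is an OLS fit of the z-scored
volume on covariates plus the z-scored score. Sex and intracranial
volume enter every model; age enters only for ROIs configured in the
covariate policy (default: lateral ventricles), reflecting the usual
situation in young healthy cohorts where age correlates with little
else. z-scoring volume and score makes the reported $\beta$ a
standardized coefficient, consistent with reported effect magnitudes
where $\Delta R^2 \approx \beta^2$; covariates enter raw. $\Delta R^2$
is `R2(full) - R2(covariates)` on the same complete-case sample, hence
never negative. Complete cases are taken per cell, so per-ROI
missingness (a segmentation QC reality) costs only that ROI's rows.

The permutation test shuffles the *score* across samples, keeping
volume and covariates paired — the exchangeable quantity under the null
"score unrelated to volume given covariates" — and the permuted p is
the plain fraction of permuted refits with nominal $p^* < p_{obs}$
(granularity $1/n_{perm}$, may be exactly 0). A Freedman–Lane
residual-permutation variant and a $(k+1)/(N+1)$ estimator are provided
but off by default. Internally each refit is evaluated through the
partial correlation of the permuted score with the covariate-residualized
volume, a monotone transform of the t statistic at fixed degrees of
freedom; this makes the count identical to brute-force `lm` refitting
(verified against exactly that oracle) at a fraction of the cost. By
default only cells with nominal $p < 0.05$ are permuted, mirroring post
hoc correction of dependent tests; `perm_policy = "all"` permutes every
cell.

## Power

The correlation power calculator uses the Fisher z approximation,
$n = ((z_{1-\alpha} + z_{power}) / \operatorname{atanh} r)^2 + 3$,
**one-sided by default and rounded to nearest**: that convention is the
one that reproduces the published benchmark of $n = 717$ at $r = 0.1$,
$\alpha = 0.05$, power $0.85$ (web calculators rarely state their
conventions; ours is recorded as an inference, and the two-sided option
is a flag away). `corr_power()` is its inverse and is validated against
bivariate-normal simulation.

## The synthetic world

The generator is a calibration device, not a reconstruction of any real
GWAS. Its stated world:

* **Genotypes.** Two haplotypes per sample; each haplotype is a latent
  AR(1) Gaussian (correlation `rho = 0.8`) within LD blocks
  (`block_size` adjacent variants, independent across blocks),
  thresholded at $\Phi^{-1}(1 - f_j)$, frequencies uniform on
  $[0.05, 0.5]$. This yields blocky LD with realistic decay inside
  blocks and exact independence between loci — enough structure to make
  clumping non-trivial, far simpler than real human LD maps (a stated
  non-goal).
* **Effects.** Disjoint causal sets (shared, A-specific, B-specific),
  at most one causal variant per LD block so causal loci are
  independent. True standardized effects are
  $b_A = b_{sh} + b_{Asp}$, $b_B = b_{sh} + b_{Bsp}$; the four training
  sets see $(b_A + b_B)/2$, $(b_A - b_B)/2$, $b_A$, $b_B$ — the
  transparent algebra that makes shared risk cancel in the case-case
  contrast. Training estimates are drawn analytically,
  $\hat b = b + N(0, se^2)$ with $se = 1/\sqrt{2 n_{eff} f (1-f)}$,
  rather than by simulating a case-control cohort and fitting logistic
  models: same first-order structure, orders of magnitude faster. Half
  the emitted rows have swapped alleles and negated weights, so the
  harmonization path is always exercised.
* **Training power (a calibrated choice).** The defaults
  `effect_sd = 0.08`, `n_train_eff = 1e5` put causal variants at a Wald
  standard error of roughly $0.005$, i.e. genuinely well powered in the
  training scans. This is deliberate: the qualitative property the
  generator must exhibit — the combined-set score out-predicting either
  single-disorder score for a shared-coupled phenotype — only holds
  when training noise does not swamp the shared/specific contrast. An
  earlier, weaker parameterization (`effect_sd = 0.04`,
  `n_train_eff = 5e4`) left the pattern winning only ~75–90% of
  replicates; the power analysis behind the revision is part of the
  design, and the acceptance thresholds were not touched. More specific
  than shared causal loci (defaults 60/60 vs 40) sharpen the same
  contrast: specific loci dilute a single-disorder score fully but
  enter the combined score at half weight. For replicate-based property
  checks the architecture (causal sets and true effects) is treated as
  the *fixed* stated world and replicates redraw cohorts, training noise
  and phenotype noise over it; redrawing a small causal set each
  replicate makes the shared:specific variance ratio itself fluctuate by
  tens of percent, which tests the luck of tiny architectures rather
  than the pipeline.
* **Phenotypes.** Sex $\sim$ Bernoulli(0.714 female), age
  $\sim N(24.77, 6.86^2)$ years, ICV $\sim N$(1.6e6 − 1.5e5·female,
  1e5$^2$) mm³ — a young, mostly female healthy cohort. Each ROI is
  intercept + sex/ICV(+age) effects + a scaled genetic value + Gaussian
  noise, with plausible mm³ magnitudes. The genetic value is the
  true-effect dosage sum over the causal set selected by `coupling`,
  scaled so that its share of *total* variance equals
  `target_delta_r2` — the same scale as the $\Delta R^2$ the
  association stage reports (an earlier draft scaled against
  post-covariate variance only, which biased recovered $\Delta R^2$ low
  by the factor $1 - R^2_{cov}$; the regression is the arbiter of the
  designed value). Default coupling sign is negative (higher burden,
  smaller volume), matching the direction of the motivating findings.
  The default battery couples a globus-pallidus-like ROI to the shared
  component ($\Delta R^2 = 0.022$) and an amygdala-like ROI to the
  B-specific component ($0.020$), with four null structures.

What a green test does **not** establish: realism of human LD,
population structure, imputation uncertainty, case-control ascertainment
effects, or the real cohort's effect sizes — the published
cohort-specific estimates require the original genotypes and scans and
are design targets only.

## Numerical and runtime choices

* Seeds: one global seed expands into deterministic per-stage substreams
  (`substream_seed`), so adding permutations to one cell never perturbs
  another stage; the full pipeline is byte-identical across runs with
  the same config and seed.
* Degenerate score columns (no variants passing a sparse threshold, or
  zero variance) become `NA` cells in the report rather than aborting
  the run; `standardize_scores()` errors by default and degrades only
  when asked.
* Acceptance-scale simulations keep every stated sample size, replicate
  count and tolerance, but use desk-scale variant counts (300–1500
  instead of 5000) where the estimand does not depend on panel width;
  noted in the tests themselves.
* The pipeline config is JSON (no YAML parser among the supported
  dependencies); structure is unchanged.

## Known limitations

Single-ancestry, single-build world; no genotype QC, imputation or
liftover (inputs are assumed clean, as in the upstream workflow);
case-case and combined scans are simulated with independent noise
rather than the partially shared controls of real consortium data;
the permutation scheme's exchangeability argument assumes the score is
independent of covariates under the null, which the Freedman–Lane
option relaxes.
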