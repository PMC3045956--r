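---
title: "Reference-gene stability for whole-blood RT-qPCR: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability for whole-blood RT-qPCR: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Quantitative RT-PCR expresses a target gene's abundance relative to one or
more *reference* (housekeeping) genes, on the assumption that the reference
genes are stably expressed across all samples. In whole blood that
assumption is fragile: the measured RNA pool is a mixture over leukocyte
populations, so anything that shifts the leukocyte count or composition —
disease, surgery, inflammation — can move a "stable" gene's
quantification cycle (Cq). `refstab` implements the two standard stability
criteria (geNorm and a model-based, NormFinder-style estimator), the
covariate diagnostics needed to understand *why* they disagree, and a
synthetic cohort generator that reproduces the design of a canine
whole-blood panel (9 candidate genes, 263 dogs in four disease groups) so
every estimator can be tested against known ground truth.

## From Cq to relative quantities

A well's Cq is the PCR cycle at which fluorescence crosses threshold; one
cycle corresponds to a factor E, the amplification efficiency (E = 2 at
100% efficiency). Technical duplicates are averaged on the Cq scale at load
time, matching instrument-software convention. Relative quantities are

$$ q_{gs} = E_g^{\,\mathrm{Cq^{min}_g} - \mathrm{Cq}_{gs}}, $$

anchored at each gene's lowest observed Cq so that $0 < q \le 1$ with a
per-gene maximum of exactly 1. The anchor is arbitrary — every downstream
statistic is invariant to per-gene rescaling (equivalently, additive Cq
shifts) — and the minimum-Cq convention simply keeps quantities in a
readable range. When no efficiency file is supplied E defaults to 2, since
assay-validated efficiencies cluster near 100% (the loader warns outside
the 93.9–106.7% band and refuses values outside [1.5, 2.2]).
`efficiency_from_slope()` converts a standard-curve slope via
$E = 10^{-1/\mathrm{slope}}$.

Missing wells are kept as missing at load and handled per analysis:
stability computations drop incomplete samples (complete-case) with a
logged count, because imputing Cq values would bias the standard deviations
those methods rank by.

## geNorm: pairwise-ratio stability

For genes $j, k$ the log-ratio $A_{jk,s} = \log_2(q_{js}/q_{ks})$ is
constant over samples $s$ exactly when the two genes move together. geNorm
scores

$$ V_{jk} = \mathrm{sd}_s(A_{jk,s}), \qquad
   M_j = \frac{1}{n-1}\sum_{k \ne j} V_{jk}, $$

with the sample (n−1) standard deviation, and iteratively removes the gene
with the highest M, recomputing M on the remainder until two genes are
left. Those two are reported as a jointly most-stable *pair*: a pairwise
measure cannot order them. Ties on the maximal M (exact ties arise in
symmetric constructed data) remove the lexicographically larger gene id, so
output is deterministic.

Normalization factors are per-sample geometric means of the selected
genes' quantities. The pairwise variation between sequential factors,

$$ V_{n/n+1} = \mathrm{sd}_s\!\left(\log_2 \frac{NF_n(s)}{NF_{n+1}(s)}\right), $$

measures what the (n+1)-th ranked gene adds; the conventional reading is
that the smallest $n$ with $V_{n/n+1} < 0.15$ genes suffice. The
`optimal_gene_count()` rule implements exactly that. Note that published
analyses sometimes read the plot as "one more gene than the first
sub-cutoff n"; the two conventions differ by one and the V-series is always
reported alongside the chosen n so readers can apply either.

A known blind spot, and the reason a second criterion exists: co-regulated
genes (for instance several ribosomal-protein genes) have small mutual V by
construction and can dominate a geNorm ranking even when they all shift
together between experimental groups.

## Model-based stability (NormFinder-style)

Expression on the log2-quantity scale is modelled additively,

$$ x_{igj} = \alpha_i + c_{gj} + d_{ig} + \varepsilon_{igj}, \qquad
   \varepsilon_{igj} \sim N(0, \sigma^2_{ig}), $$

for gene $i = 1..I$, group $g = 1..G$, sample $j$: a gene level, a
per-sample effect (template amount), a gene-by-group interaction $d_{ig}$ —
the systematic intergroup deviation a poor reference gene shows — and
intragroup noise. Identifiability is imposed by construction:
$\sum_i d_{ig} = 0$ within each group and $\sum_g \hat d_{ig} = 0$ per gene
(double-centering).

The estimator proceeds in moments:

1. Sample-center: $z_{igj} = x_{igj} - \bar x_{\cdot gj}$ removes $c_{gj}$
   exactly, which is why stability values are invariant to per-sample
   scaling of quantities.
2. Group means of $z$, row-centered across groups, give $\hat d_{ig}$.
3. Centering couples the genes: with $s^2_{ig}$ the within-group variance
   of $z$, $E[s^2_{ig}] = \sigma^2_{ig}(1 - 2/I) + \sum_k \sigma^2_{kg}/I^2$.
   Solving the resulting linear system yields the bias-corrected
   $$ \hat\sigma^2_{ig} = \frac{I}{I-2}\left(s^2_{ig} -
      \frac{T_g}{I(I-1)}\right), \qquad T_g = \sum_k s^2_{kg}, $$
   which is exactly unbiased (the correction is linear in the observed
   $T_g$). This is also why at least 3 genes are required. Estimates are
   floored at $10^{-12}$ so degenerate noise-free inputs stay defined.
4. The variance of true deviations is estimated by moments,
   $$ \hat\gamma = \max\!\left(0,\; \frac{\sum_{ig} \hat d_{ig}^2}{(I-1)(G-1)}
      - \overline{\hat\sigma^2_{ig}/n_g}\right), $$
   with $(I-1)(G-1)$ degrees of freedom reflecting the rank of the
   double-centered deviation matrix; negative moment estimates clip to 0.
5. Deviations are shrunk empirically-Bayes style,
   $\tilde d_{ig} = \hat d_{ig}\,\hat\gamma/(\hat\gamma + \hat\sigma^2_{ig}/n_g)$,
   and the stability value combines shrunken deviation magnitude with the
   posterior spread:
   $$ \rho_i = \frac{1}{G} \sum_g \left[\, |\tilde d_{ig}| +
      \sqrt{\frac{\hat\gamma\,(\hat\sigma^2_{ig}/n_g)}{\hat\gamma +
      \hat\sigma^2_{ig}/n_g}} \right]. $$
   With a single group $\rho_i = \hat\sigma_i$. Lower is more stable.

The best *pair* averages two genes: $\hat d$ averages and $\hat\sigma^2$
quarters, so genes with opposite deviations cancel — the property that
makes the pair search worthwhile. Pair stability is undefined without at
least two groups.

When $\hat\gamma = 0$ — intergroup deviations indistinguishable from noise —
every $\rho_i$ is 0 and the ranking is deliberately uninformative rather
than noise-driven. This happens on the package's own default synthetic
cohort under the *disease* grouping: the slope-induced group deviations are
small against the moment penalty, which is dominated by the healthy group's
n = 6. The leukocyte-quartile grouping separates counts far more sharply
and yields $\hat\gamma > 0$ with the low-slope genes ranked on top. The
pipeline reports a Spearman concordance between the geNorm and model-based
rankings per grouping, with NA where a ranking is degenerate.

Validation is by parameter recovery (injected $\sigma^2_{ig}$, $d_{ig}$ of
realistic magnitude recovered across seeded replicates), not by numeric
identity with any closed-source implementation.

## Covariate diagnostics

- **Disease-group ANOVA** (`anova_by_group`): one-way fixed-effects ANOVA
  of Cq on first samples, with optional all-pairs Welch t-tests under Holm
  correction.
- **Leukocytosis dichotomy** (`wbc_dichotomous_compare`): Cq of dogs with a
  leukocyte count inside the canine reference range (4.5–14.6 × 10⁹/l)
  versus dogs above 30 × 10⁹/l, a clinically relevant leukocytosis; counts
  between the strata are excluded by definition. The Welch (unequal
  variance) form is used because the high-count stratum is visibly more
  dispersed; on balanced equal-variance data it coincides with the pooled
  test. Holm correction is applied across the gene panel by
  `wbc_panel_compare`.
- **Leukocyte-count slope** (`wbc_slope_lmm`): Cq regressed on ln(count),
  either OLS on first samples or a random-intercept model over all samples,
  $Cq = \beta_0 + \beta_1 \ln W + u_{dog} + \varepsilon$. The mixed model is
  fitted by REML with the variance ratio $\lambda = \tau^2/\sigma^2$
  profiled by one-dimensional bounded search on the log scale
  ($\lambda \in [10^{-8}, 10^4]$); for each candidate the GLS solve reduces
  to OLS after per-dog partial centering
  $y^* = y - \theta_d \bar y_d$, $\theta_d = 1 - 1/\sqrt{1 + m_d \lambda}$.
  A random-intercept model needs nothing more general, the profile is
  unimodal on tested instances (verified by grid scan), and the fit matches
  `lme4::lmer` to ~6 decimals in the test suite. When every dog has one
  sample the profile is flat in $\lambda$ and the fit snaps to the lower
  boundary, reproducing OLS. Results are reported per unit ln(count) and
  per tenfold increase; the conversion is exactly $\ln 10$.
- **Sampling-occasion LRT** (`sample_number_lrt`): fixed-effects fits of
  `Cq ~ dog` against `Cq ~ dog + sample_number`, compared by
  $N \ln(RSS_0/RSS_1)$ on a chi-square with (occasion levels − 1) df. This
  reference is asymptotic in the *residual* degrees of freedom, and the dog
  factor absorbs one df per dog, so the test is anticonservative in designs
  with few samples per dog: an exact F-distribution calculation gives a
  true size of ~0.15 at 20 dogs × 3 samples, falling to ~0.075 for long
  balanced series, and never reaching the nominal 0.05. The calibration
  check in the test suite therefore uses 40 dogs × 30 occasions (exact size
  0.075), and the analysis scripts flag the caveat when the statistic is
  applied to sparse repeat designs.

Significance is read at α = 0.05 throughout. `holm_adjust` wraps the
standard step-down procedure (sort ascending, multiply $p_{(k)}$ by
$m - k + 1$, enforce monotonicity, cap at 1) with input validation.

## The synthetic cohort generator

No raw Cq data at this design scale are publicly available, so the
generator is a first-class module: it draws cohorts with the statistical
structure the analyses assume, and exports the realized latent effects so
recovery tests have ground truth.

The default configuration (`canine_blood_config()`) encodes:

- **Design**: 263 dogs in groups A/B/C/D = 6/85/107/65 (healthy,
  post-surgical, internal disease, hematologic disease), with the observed
  repeated-sampling pattern (99 second, 34 third, 13 fourth samples,
  distributed per group; the extra samples go to the first dogs of each
  group so the design is deterministic given the configuration).
- **Genes**: the 9-gene canine panel (RPS19, RPL8, RPS5, GUSB, B2M, HNRNPH,
  HPRT, GAPDH, SRPR) with published normal-count baseline Cq, dispersion,
  and Cq change per tenfold leukocyte increase (from +1.28 for B2M to
  −0.87 for HPRT).
- **Leukocyte counts**: lognormal per group. The location is the printed
  group median; the log-scale spread is set so the *expected range of n
  draws* matches the printed group min–max, using the Blom order-statistic
  approximation (the expected half-range of n standard normals is
  ≈ Φ⁻¹((n − 0.375)/(n + 0.25))). Only medians and ranges are published,
  and a range is an order statistic — calibrating to it without the
  adjustment would badly overstate the spread for the large groups.
- **Cq model**:
  $Cq_{is} = \beta_i + d_{ig} + b_i \log_{10}(W_s/10) + u_d + c_s +
  \varepsilon_{is}$ with per-dog intercept $u_d$ (τ = 0.3 Cq by default — a
  documented guess, since within-dog correlation is not published; it is
  varied in tests), per-sample shift $c_s$ (0.1 Cq, a modest
  template-amount effect), and per-gene residual noise at the published
  dispersions. Baselines are referenced at W = 10 × 10⁹/l, a typical normal
  count, so they equal the expected Cq of a normal-count dog.
- **Group offsets** default to zero; `b2m_group_effect = TRUE` adds the one
  documented group-specific contrast (0.51 Cq between groups B and D on
  B2M, split ±0.255; the sign convention is arbitrary since only the
  magnitude is published).
- Optional technical duplicates (two wells averaged at load) and missing
  wells at a configurable rate. Generation is bit-exact for a fixed
  (configuration, seed) and leaves the caller's RNG stream untouched.

What the generator deliberately does **not** emulate: co-regulation between
genes (residuals are independent across genes, so geNorm's vulnerability to
co-regulated ribosomal genes is *not* reproduced — on synthetic data geNorm
has no co-regulated pair to latch onto, and its optimal-n lands higher than
in co-regulated real panels), breed or sex structure (carried as metadata
only), leukocyte *composition* as opposed to count, and time trends within
a hospitalization. Passing recovery tests on this generator therefore
demonstrates estimator correctness under the stated model, not robustness
to those real-data features.

## Numerical and scale choices

Problem sizes in the test suite and acceptance checks are chosen to give
tight Monte-Carlo error at interactive runtimes: 100 random panels for the
geNorm oracle comparison (agreement to 1e-10), 200 seeded replicates for
stability-ranking recovery, 1000 replicates for variance-estimator bias
(<5% at n = 50/group) and for null calibration, and 100 cohorts of 263 dogs
for slope recovery. The REML profile search uses `optimize` with tolerance
1e-9 on the log-ratio scale; the variance floor is 1e-12; exact ties in the
geNorm exclusion are broken lexicographically. Report JSON is written at
full precision with deterministic field order, so identical inputs and seed
give byte-identical bundles.

## A worked session

```{r example}
cfg <- canine_blood_config()
coh <- generate_cohort(cfg, seed = 42)
first <- select_first_samples(coh$dataset)
q <- relative_quantities(first$cq, first$efficiencies)

g <- genorm(q)
g$best_pair
g$optimal_n

nf <- normfinder_stability(q, wbc_quartile_groups(first))
head(sort(nf$stability), 3)

s <- wbc_slope_lmm(coh$dataset, "B2M")
c(estimate = s$beta_per_tenfold, injected = 1.28)
```

## Known limitations

- The model-based stability estimator is a reconstruction of the cited
  model class (additive model, moment estimators, empirical-Bayes
  shrinkage); it is validated by parameter recovery, and its numeric values
  are not expected to match any specific third-party implementation
  digit-for-digit.
- $\hat\gamma = 0$ collapses the model-based ranking to a tie by design;
  use a sharper stratification (e.g. leukocyte quartiles) when group
  deviations are weak relative to small-group noise.
- The sampling-occasion LRT's chi-square reference is anticonservative for
  sparse repeated sampling (see above); treat marginal p-values there with
  caution.
- The quartile stratification uses type-7 sample quantiles of first-sample
  leukocyte counts; published analyses rarely state their binning, so exact
  bin-for-bin agreement with external results is not guaranteed.
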