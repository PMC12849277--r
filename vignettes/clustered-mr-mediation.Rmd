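---
title: "Clustered Mendelian randomisation with two-step protein mediation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustered Mendelian randomisation with two-step protein mediation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrclustmed)
```

## The problem

A single exposure — here, the motivating case is body-mass index and its
relation to breast cancer risk — can be raised by genetic variants acting
through quite different biological pathways, and those pathways need not
affect a downstream disease in the same direction. A conventional
two-sample Mendelian randomisation (MR) analysis pools every instrument
into one causal estimate and treats heterogeneity as a nuisance. This
package instead treats heterogeneity as signal, in two stages:

1. **Clustering.** Per-variant Wald ratios of a disease outcome on the
   exposure are soft-clustered into groups with shared causal slopes,
   plus an explicit null group (no outcome effect) and a junk group
   (outliers), and each cluster gets its own inverse-variance weighted
   (IVW) MR estimate.
2. **Mediation.** For each cluster, a molecular (protein) panel is
   screened for mediators by two-step MR: cluster-scaled exposure →
   protein (one-sample Wald MR with cluster-specific allele scores in a
   split cohort), and protein → outcome (two-sample IVW MR with
   cis-anchored instruments). Candidates passing a double FDR screen get
   product-of-coefficients mediation estimates with delta-method SEs,
   Monte Carlo confidence intervals, signed proportions mediated, and
   between-cluster contrast tests.

## The mixture model

For variant $j$ with Wald ratio $\hat\theta_j = \hat\beta_{out,j} /
\hat\beta_{exp,j}$ and standard error $\sigma_j$ (treated as known), the
likelihood has $K + 2$ components:

* substantive cluster $k$: $\hat\theta_j \sim N(\mu_k, \sigma_j^2)$,
* null: $\hat\theta_j \sim N(0, \sigma_j^2)$,
* junk: $\hat\theta_j \sim U(\min\hat\theta - R,\; \max\hat\theta + R)$,
  with $R$ the observed ratio range, i.e. a flat density over three
  times the observed spread.

EM alternates responsibilities (E) with precision-weighted cluster means
and mean responsibilities (M); iteration stops when the log-likelihood
improves by less than $10^{-8}$ or after 5,000 iterations. The
log-likelihood is non-decreasing by construction and the fitted means
are reported sorted ascending, which removes label-switching ambiguity.
$K$ is chosen by BIC $= -2\log L + (2K+1)\log n$ over $K = 0..K_{max}$,
each $K$ refitted from `n_restarts` seeded initialisations spread over
the ratio range (an even grid, jittered per restart). The grid-plus-
jitter initialisation deliberately depends on the data only through the
ratio range, so model selection is invariant to input row order.

Two numerical caveats are worth knowing. First, the junk density is
*sharper* than the per-variant Gaussians whenever the observed ratio
spread is small relative to the $\sigma_j$; junk then absorbs everything.
This is a degenerate configuration (it means there is nothing to
cluster), not a practical concern at GWAS scale, but synthetic inputs
should keep within-cluster dispersion consistent with the $\sigma_j$.
Second, if all ratios coincide the junk interval would be empty; it
falls back to a unit-width interval.

Assignment takes the fitted model's responsibilities, labels each
variant by its largest one, and calls the label *confident* when that
probability reaches `prob_threshold` (default 0.8). Substantive clusters
retaining fewer than `min_cluster_size` (default 4) confident members
are dissolved, their members relabelled to the next-best surviving
component; probability vectors are untouched, so they still sum to one.

## Per-cluster MR and the winner's curse

Each surviving cluster (and the null) is summarised by fixed-effect IVW
over the Wald ratios of its *confident members*, with Cochran's Q
attached, plus the unweighted mean of member ratios. This mirrors how
the field reports clustered MR, but it inherits a known pathology:
membership is decided by the same noisy ratios being pooled, so members
near a decision boundary are censored and the confident-member IVW is
biased *away* from the adjacent component. In our reference simulation
(below) the middle cluster generates at $-0.61$ and its confident-member
IVW averages near $-0.75$, a bias of roughly twice the IVW standard
error — the same signature visible in published clustered-MR tables,
where per-cluster IVW magnitudes systematically exceed the corresponding
cluster means. The EM means themselves carry no such truncation and are
the better estimate of the cluster locations; the package reports both,
and the acceptance report writes both. Any downstream replication in an
independent cohort (the one-sample score MR below) should therefore be
expected to shrink relative to the confident-member IVW.

## Instrument processing

* **Harmonisation** aligns the outcome record to the exposure's allele
  pair: identical orientation kept, swapped pair sign-flipped (eaf
  reflected), complementary-strand pair complemented first. Palindromic
  variants (A/T, G/C) cannot be disambiguated by alleles; they are kept
  only when both allele frequencies are outside the ambiguity band
  [0.42, 0.58] *and* on the same side of 0.5 after alignment, else
  dropped. The band edge 0.42 follows common two-sample MR practice. We
  chose to drop (rather than strand-flip) concordantly-informative pairs
  on opposite sides of 0.5: that configuration is evidence of a strand
  mix-up, but resolving it by frequency alone is exactly the inference
  the ambiguity band exists to distrust.
* **Clumping** is greedy index-variant selection: smallest p first
  (ties by chromosome, then position), removing variants on the same
  chromosome within ±`window_kb` (closed interval, 500 kb default) with
  $r^2 \ge$ 0.001 against the index. Without an LD matrix the distance
  rule alone applies, and the function says so loudly — distance-only
  clumping under-prunes shared haplotypes.
* **Steiger filtering** keeps a variant only if it explains
  significantly more variance in the exposure than in the outcome:
  pseudo-$r^2 = Z^2/(Z^2+n)$ per trait, one-sided Fisher-z test at
  $\alpha = 0.05$ with variance $1/(n_{exp}-3) + 1/(n_{out}-3)$. The
  pseudo-$r^2$ is computed on the observed scale; a liability-scale
  conversion for binary outcomes is deliberately out of scope, which
  matters when interpreting the filter for case-enriched outcome GWAS
  (see the generator notes below).

## Scores and one-sample MR

Cluster-specific weighted allele scores use the exposure effect sizes of
the cluster's confident members as weights; a weight expressed on the
opposite allele is sign-flipped with the dosage reflected, so scores are
invariant to allele bookkeeping. The exposure is rank-based inverse
normal transformed (Blom offset 3/8, average ranks on ties) before the
score-exposure regression, matching the convention of the GWAS the
weights come from. Associations are ordinary least squares and
maximum-likelihood logistic regression (IRLS, relative convergence
$10^{-10}$, observed-information SEs); the one-sample Wald ratio divides
the score-outcome log-OR by the score-exposure slope with a first-order
SE. The mediation step-1 driver *asserts* that the individuals providing
protein levels are disjoint from those providing the score-exposure
estimate — the two-sample-within-one-cohort discipline.

## Mediation inference

With $\hat\beta_1$ (cluster-scaled exposure → protein) and $\hat\beta_2$
(protein → outcome):

* mediated effect $\hat\beta_1\hat\beta_2$ with delta-method SE
  $\sqrt{\hat\beta_1^2\hat\sigma_2^2 + \hat\beta_2^2\hat\sigma_1^2}$;
* Monte Carlo CI from the empirical quantiles of $b_1^* b_2^*$,
  $b_i^* \sim N(\hat\beta_i, \hat\sigma_i^2)$ independently ($10^6$
  draws by default, seed recorded; the product distribution is skewed
  near the significance boundary, where the normal approximation is
  least trustworthy);
* proportion mediated = mediated / cluster total effect, stored
  *signed* (negative means the mediator works against the cluster's
  total effect) and reported as magnitude with direction. Because the
  outcome effect is an odds ratio, proportions are covariate-set
  dependent approximations (non-collapsibility), and the package treats
  them as ratio arithmetic only;
* between-cluster contrasts exploit that $\hat\beta_2$ is shared across
  clusters for a given protein, so the difference of mediated effects
  factorises as $\hat\beta_{diff}\hat\beta_2$ with
  $\hat\beta_{diff} = \hat\beta_{1,A} - \hat\beta_{1,B}$,
  $\hat\sigma_{diff} = (\hat\sigma_{1,A}^2 + \hat\sigma_{1,B}^2)^{1/2}$
  and contrast SE
  $(\hat\beta_{diff}^2\hat\sigma_2^2 + \hat\beta_2^2\hat\sigma_{diff}^2)^{1/2}$.
  The Sobel-style $z$ divides the contrast by that SE; a Monte Carlo CI
  for the contrast is drawn from the same product construction.
  Contrasts are computed for every cluster pair of each candidate
  protein, using all clusters' step-1 estimates (a cluster need not
  itself be a candidate to enter a contrast).

Screening applies Benjamini–Hochberg FDR within each cluster across the
panel for step 1 (the per-cluster reading of "differentially affected
proteins per cluster"; a pooled-family toggle exists) and across the
panel for step 2; a (cluster, protein) pair is a candidate when both
q-values are below 0.05. Step-2 instruments must number at least three
independent variants at $p < 1.7\times10^{-11}$ with at least one cis
(within ±1 Mb of the gene interval; the window is configurable because
"cis-regulatory" has no universal definition), reusing the same clumping
rule as the exposure — the most defensible single convention absent a
stated alternative.

## The synthetic-data generator

The generator exists so that every stage is testable without restricted
cohort or consortium data. Its defaults are the reference scenario the
package is calibrated against:

| quantity | default | rationale |
|---|---|---|
| substantive clusters | 24 / 73 / 7 variants at ratio means 0.98 / −0.61 / −1.74 | the reference cluster structure the package is calibrated against |
| null mass | 360 variants | likewise |
| exposure GWAS | two sub-studies, n = 266,130 and 322,154, fixed-effect meta-analysed | consortium-scale exposure GWAS |
| outcome GWAS | n = 247,173, binary, case fraction 0.085 | consortium-scale disease GWAS; see below for the case fraction |
| per-variant exposure effects | &#124;β&#124; ~ U(0.02, 0.08) SD, random signs; EAF ~ U(0.1, 0.9) | every generated variant is then genome-wide significant (min Z ≈ 6.5) at these sample sizes, consistent with the premise that the clustered set is the clumped significant instruments |
| cohort | n = 194,682, prevalence 8.5%, molecular sub-sample fraction 0.107 | study-sized; the split mirrors the proteomics sub-cohort |
| protein panel | 2,922 proteins; 5 cis instruments each at n = 54,219 | panel- and pQTL-sized |

Sampling noise per variant is the standard GWAS approximation
$se^2 = 1/(2nf(1-f))$ for the variance-1 quantitative exposure. For the
binary outcome the effects are log odds ratios and the variance carries
the binomial factor: $se^2 = 1/(2nf(1-f)\,\phi(1-\phi))$ with case
fraction $\phi$. The default $\phi = 0.085$ emulates a population-
register disease GWAS at the cohort's prevalence. This choice is
load-bearing: with a quantitative-scale outcome (or a 50:50
case-control $\phi$), observed-scale Steiger filtering removes most
variants whose |ratio| approaches or exceeds 1 — variance explained in
the outcome overtakes the exposure's — and the high-magnitude clusters
cannot survive to clustering at all. Under the population-register
design, Steiger retains essentially all variants, reproducing the
near-complete retention such analyses report in practice (where a
liability-scale variance-explained estimator serves the same
purpose).

Genotypes are Binomial(2, f) dosages in linkage equilibrium (protein
loci carry explicit identity LD matrices so instrument clumping treats
them as independent); the cohort outcome is Bernoulli on a logistic
liability whose intercept is bisected to the target prevalence.
Features of real data the generator does **not** emulate: LD structure
(so clumping is exercised by distance and synthetic matrices only),
population stratification, assortative mating, winner's-curse-selected
weights, and case-control ascertainment within the cohort. Passing
tests therefore demonstrate the estimators' internal correctness and
calibration under the stated design, not robustness to those
real-data complications.

In the pipeline drivers the Wald SEs default to the second-order form
$\sqrt{\sigma_{out}^2 + \theta^2\sigma_{exp}^2}/|\beta_{exp}|$: with the
outcome GWAS roughly 40% the size of the exposure GWAS and ratios up to
|1.74|, the exposure-noise term contributes up to half the ratio
variance, so first-order SEs would be anti-conservative both in the EM
(which takes the $\sigma_j$ as known) and in the cluster IVW CIs. The
plain `wald_ratio()` function keeps the first-order convention as its
default.

## Problem sizes and reproducibility

Calibration studies shipped with the package run at: 50 replicates of
the full 464-variant part-1 pipeline with 10 restarts over $K \le 4$
(model selection is stable under far fewer restarts than the
30-restart function default, because the mixture is one-dimensional
with quantile-spread initialisation); 100 pure-null replicates of 100
variants; 500 Monte Carlo CI replicates at $10^4$ draws; 20 screening
replicates of the full 2,922-protein panel. Every random quantity
descends from a single integer seed, and re-running any driver with the
same configuration reproduces its outputs exactly. Part-1 and part-2
drivers can write their tables alongside a JSON model card / run report
carrying the seed and every threshold.

The same pipeline applies unchanged to real summary statistics in the
canonical column dialect (rsid, chr, pos, ea, oa, eaf, beta, se, p, n);
reproducing published per-cluster estimates from the public consortium
files is possible where those files are available, with the caveats that
clustering is seed- and hyperparameter-sensitive and that a real LD
matrix should be supplied for clumping.

## Known limitations

* Fixed-effect IVW throughout (a multiplicative random-effects toggle
  exists but is off by default, matching the fixed-effect meta-analysis
  convention of the motivating design).
* No weighted-median / mode / MR-PRESSO sensitivity estimators, no
  multivariable MR, no counterfactual mediation decompositions.
* Observed-scale Steiger only; liability-scale conversion out of scope.
* The confident-member cluster IVW is winner's-curse biased by
  construction (see above); use the EM means where an unbiased location
  estimate is needed.
* Proportions mediated through an odds-ratio outcome are approximate
  and covariate-set dependent (non-collapsibility).
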