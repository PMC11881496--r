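---
title: "Annotation-aware genomic prediction with gsannot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-aware genomic prediction with gsannot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Routine genomic evaluation in livestock predicts an animal's additive
genetic merit (its genomic estimated breeding value, GEBV) from a
medium-density genotyping array. Imputed whole-genome sequence data puts
the causative variants themselves into the marker set, and functional
annotation — coding consequences, eQTL catalogues, open-chromatin and
chromatin-state maps — says which variants are *likely* to be causative.
`gsannot` implements the model suite needed to ask whether either kind of
information improves prediction: annotation-agnostic baselines (GBLUP,
BayesCπ, BayesR, BSLMM), annotation-aware extensions (MGFBLUP,
BayesRR-RC), marker-panel pre-selection (functional panels, LD pruning,
array proxies), and a forward cross-validation layer with bootstrap
inference. A block-haplotype simulator generates cohorts with the same
statistical structure, so the entire analysis runs end to end without any
proprietary data.

## Models

**GBLUP.** Phenotypes (pre-corrected trait deviations) are modelled as
$y = 1\mu + g + e$ with $g \sim N(0, G\sigma^2_g)$ and
$e \sim N(0, I\sigma^2_e)$. The genomic relationship matrix $G$ comes in
two codings with different implied architectures:

* *centered* (`GBLUP-C`): $G = ZZ'/\sum_j 2f_j(1-f_j)$, where column $j$
  of $Z$ is the dosage minus $2f_j$ — effect sizes independent of allele
  frequency, so common variants carry most of the genetic variance;
* *standardized* (`GBLUP-S`): $G = XX'/M$ with columns further divided by
  $\sqrt{2f_j(1-f_j)}$ — every marker contributes equally, so rare
  alleles have larger effects.

Allele frequencies are always estimated once from the full supplied
matrix (reference and target combined), because prediction requires the
same centering constants on both sides of the split.

**MGFBLUP.** One polygenic term per annotation group ("genomic
feature"): $y = 1\mu + \sum_s g_s + e$, $g_s \sim N(0, G_s\sigma^2_s)$,
with $G_s$ built from the group's markers only. Because per-group
centered GRMs keep their normalizing constants, the weighted sum of group
GRMs reproduces the all-marker GRM exactly — a structural identity the
tests assert at $10^{-10}$. The fit is capped at 8 GRMs; beyond that REML
becomes unstable (flat directions, null variances).

**REML.** Variance components maximize the restricted likelihood with an
intercept as the only fixed effect. Updates are average-information steps
with step-halving, falling back to an EM step when the AI proposal fails
to improve the likelihood. Convergence requires
$|\Delta \log L| < 10^{-6}$ and relative parameter changes below
$10^{-4}$, within 200 iterations. Variances are floored at
$10^{-8}\,\mathrm{var}(y)$; a component pinned to the floor for three
consecutive iterations is reported as 0 (null group variances do occur in
practice). A near-singular AI matrix — e.g. a GRM proportional to the
identity, which makes $\sigma^2_g$ and $\sigma^2_e$ inseparable — raises
a `flat_likelihood` flag instead of pretending to converge. With a single
GRM the solver works in the GRM eigenbasis, making every iteration
$O(n)$ after one decomposition.

**Heritability partition.** For any annotation-aware fit, group $s$
explains $100\,\sigma^2_s/\sum_t \sigma^2_t$ percent of the genetic
variance, and its *enrichment* is that share divided by the group's share
of the variants. Enrichment above 1 means larger-than-average per-variant
effects. These two identities ($\sum_s \%h^2_s = 100$,
$\sum_s p_s\,\mathrm{enr}_s = 1$) hold by construction and are asserted.

**Bayesian samplers** (Gibbs, implemented in C++ for throughput, seeded
through R's RNG so chains are bit-reproducible):

* *BayesCπ*: spike at zero with probability $\pi$ plus one Gaussian slab;
  $\pi$ has a uniform prior via beta conjugacy, the slab and residual
  variances have weak scaled-inverse-$\chi^2$ priors ($\nu = 4$, scales
  splitting $\mathrm{var}(y)$ in half).
* *BayesR / BayesRR-RC*: spike plus three Gaussians with variances
  $10^{-4}, 10^{-3}, 10^{-2}$ times the group variance $\sigma^2_s$;
  BayesRR-RC gives every annotation group its own Dirichlet(1) mixture
  proportions and its own $\sigma^2_s$; BayesR is the single-group case.
  Defined on standardized genotypes (centered is available as an
  option). 5000 iterations with 2000 burn-in by default.
* *BSLMM*: every marker contributes through a polygenic term
  $u \sim N(0, G\sigma^2_{poly})$ and a sparse subset carries additional
  effects. The chain works in the GRM eigenbasis, which makes the
  polygenic conditionals independent. The two variances use conjugate
  updates; $\pi$ uses random-walk Metropolis on $\log\pi$ with a
  log-uniform prior on $[1/M, 1]$. (A Metropolis update for the variance
  ratios, as in the reference implementation, is equivalent in the limit;
  the conjugate form mixes faster at desk scale and samples the same
  posterior.) Disabling the sparse component reduces the model exactly to
  GBLUP, which the tests verify as a prediction correlation above 0.99.

Marker updates run in fixed ascending order (reproducibility); residuals
are maintained incrementally so one iteration costs $O(nM)$.

## Annotation and panels

Each marker belongs to exactly one group, resolved by expected impact:
coding > eQTL > regulatory (ATAC/epigenetic evidence) > exon-associated >
intronic > intergenic (fallback). FAN1 splits regulatory variants by
evidence (both / epigenetic-only / ATAC-only); FAN2 splits eQTL and
regulatory variants by tissue, with muscle taking precedence when both
muscle and non-muscle intervals overlap (the tissue split exists to
isolate muscle evidence, so muscle wins ties). LDMS crosses three MAF
bins — $(0.01, 0.05]$, $(0.05, 0.10]$, $(0.10, 0.50]$, closed on the
right since the bin notation is ambiguous — with four LD-score quartiles
(nearest-rank boundaries, ties to the lower quartile: deterministic).
LDMS × FAN1 yields 96 groups, empty cells retained at size zero.

A variant overlaps an interval when its 1-based position lies inside it;
indels are judged by start position. BED input is converted from 0-based
half-open on read.

Panels: FUN1 = coding ∪ eQTL ∪ regulatory (either catalogue) ∪ MMD array
markers; FUN2 and FUN3 restrict the regulatory catalogue to ATAC-seq or
epigenetic evidence respectively (hence FUN2, FUN3 ⊆ FUN1); LD panels
prune greedily left-to-right at $r^2$ thresholds 0.99–0.80 within a 1 Mb
window (the earlier marker is kept — deterministic, and the window
default matches the LD-score window; neither is dictated by the source
methods, which name no algorithm); ARRAY is a commercial-array id list.
Array memberships pass through the same QC filters as everything else.

## Evaluation

The reference/target split is by birth date; individuals born *on* the
cutoff go to the target set ("born before" read strictly). Reliability is
$\mathrm{cor}(GEBV, y)^2 / h^2$. The $h^2$ in the denominator is
configurable: on synthetic data the realized simulated $h^2$ is used
(the natural choice when truth is known); a reference-set REML estimate
under the baseline model is available for real data. Bootstrap
comparisons resample target individuals with replacement — one shared
index vector per replicate across all method columns, the paired design
implied by a single GEBV table — and declare a difference significant
when one method is higher in ≥ 97.5% of resamples. Dispersion bias is the
OLS slope of trait deviations on predictions (1 = correctly scaled).
Cumulative-PIP regions sum PIPs over a fixed, non-overlapping 1 Mb grid
(a sliding window would double-count mass; the fixed grid makes the
brute-force oracle exact). The overall muscling score combines the four
linear scores with weights 1, 1, 2, 2, normalized by the weight sum so it
stays on the score scale.

## The synthetic cohort generator

`sim_config()` defaults describe the conditions the analysis assumes:

* **LD**: founder-haplotype pools per 25 kb block (30 haplotypes; a
  Markov copying process with rate 0.95 along markers gives tunable
  within-block $r^2$; blocks recombine freely, so cross-block LD is
  negligible). A coalescent simulator would be more realistic but is out
  of scope: pruning, LD scores and GRM behavior only need block-wise LD.
* **MAF**: block frequencies from a rare-skewed Beta(0.5, 1) rescaled to
  $[0.01, 0.5]$; realized MAF below the 0.01 floor triggers a redraw
  (imputed sequence data is filtered at this floor).
* **Annotation**: multinomial FAN1 categories with genome-wide
  proportions 0.37 / 0.28 / 7.58 / 3.83 / 2.96 / 6.49 / 26.54 / 51.94
  percent; 21.4% of eQTLs and 5% of epigenetic intervals flagged as
  muscle. Interval tracks are collapsed to the tagged positions (narrow
  enough never to cover a neighbor) — interval *logic* is exercised by
  dedicated unit fixtures instead.
* **Arrays**: MAF-weighted draws; 1% of markers on the MMD proxy and
  7.7% on the commercial-array proxy. The study-scale MMD fraction
  (0.33% of 11.3M) would leave a degenerate handful of markers at desk
  scale M, so 1% was fixed once as the desk-scale equivalent.
* **Effects**: per-group spike-plus-mixture (component probabilities
  0.994 / 0.0045 / 0.001 / 0.0005, relative variances
  $10^{-4}/10^{-3}/10^{-2}$), rescaled so realized group variance shares
  match `prop × enrichment` (normalized; a raw share above 1 errors as
  infeasible). Default enrichments put strong weight on coding (16×) and
  eQTL (20×) variants and depletion on intergenic ones (0.43×).
* **Heritability**: default 0.4 per trait — a realistic value for
  muscular-development linear scores in beef cattle; the source material
  does not state trait heritabilities. Noise is scaled against the
  *realized* genetic variance, so $h^2$ is exact in expectation
  conditional on the genotypes. Four score traits share 70% of their
  causal markers; the overall score is their weighted combination.
* **Dates**: uniform over 2010-03-01 – 2020-12-31 with cutoff
  2019-01-01, putting ≈ 18.4% of individuals in the target set (matching
  a 13,461 / 3,047 reference/target split).

What passing tests on this generator do **not** show: realistic
recombination and allele-age structure, array genotyping error,
imputation error (dosages are exact), overlap structure between real
annotation tracks, or selection-induced mean trends across birth years.
Conclusions about *relative* method behavior transfer; absolute
reliabilities do not.

## Numerical choices

* Missing dosages are mean-imputed per marker before any computation;
  fractional dosages are hard-called only for the HWE test (plain 1-df
  chi-square, no continuity correction; monomorphic markers return p = 1
  with a flag).
* GRMs must be symmetric to $10^{-10}$ and PSD to $-10^{-8}$ on the
  smallest eigenvalue; the BLUP solver refuses reciprocal condition
  numbers below $10^{-14}$ and reports them.
* $r^2$ values are clipped to $[0, 1]$; LD scores include the self term,
  so every score is ≥ 1.
* Prior scales for the samplers split $\mathrm{var}(y)$ evenly between
  genetic and residual halves; these are weak ($\nu = 4$) and wash out
  quickly.
* Per-cell seeds in `run_experiment()` are derived from the master seed
  and the cell's (panel, model) name, so report cells are invariant to
  the order panels and models are listed.

## Known limitations

* Under a null phenotype, the BayesR mixture's small-variance components
  are nearly exchangeable with the spike (Bayes factors ≈ 1), so
  component *labels* wander and the "medium/large effect" counts are not
  driven to zero even though the carried variance and $h^2$ are. Counts
  are only meaningful when real signal sets the genetic-variance scale.
* Published eQTL enrichment values cannot be reproduced from the
  published counts and heritability shares (unlike every other
  category); eQTL rows are therefore excluded from the reference
  arithmetic checks.
* Multi-allelic variants, sex chromosomes, phasing, imputation and
  pedigree relationships are out of scope.

## Problem sizes used in the checks

The test suite runs cohorts of 50–2000 individuals and 200–5000 markers;
heritability recovery uses 20 replicates at n = 2000, M = 5000; sampler
recovery checks use chains of 700–6000 iterations; bootstrap calibration
uses 200 cohorts at 2000 resamples each. These sizes were chosen so each
statistical assertion has enough replication for its stated tolerance
while the whole suite stays desk-scale.

## A minimal session

```{r example}
library(gsannot)

dat <- simulate_dataset(sim_config(n_individuals = 1000, n_markers = 5000,
                                   h2 = 0.5, seed = 1))
geno <- filter_markers(dat$geno)
split <- split_by_date(dat$pheno, "2019-01-01")

G <- compute_grm(geno, "centered")
ph <- dplyr::transmute(dat$pheno[dat$pheno$sample_id %in% split$reference, ],
                       sample_id, value = shoulder)
fit <- reml_fit(ph, subset_grm(G, split$reference))
glance(fit)

pred <- blup_predict(ph, G, fit, split$target)
yt <- setNames(dat$pheno$shoulder, dat$pheno$sample_id)[split$target]
reliability(pred$gebv, yt, dat$truth$shoulder$true_h2_realized)
```
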