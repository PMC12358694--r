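---
title: "Diversity-area scaling of microbiome cohorts with darscaling"
author: "darscaling authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity-area scaling of microbiome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darscaling)
```

## The model

The species-area relationship describes how richness grows as more area is
surveyed. Its diversity-area extension replaces richness with Hill numbers,

$$ {}^qD = \Big(\sum_{i=1}^S p_i^q\Big)^{1/(1-q)}, $$

where $p_i$ is the relative abundance of taxon $i$ and the order $q \ge 0$
controls how strongly abundant taxa are weighted: $q=0$ is richness, $q=1$
the limit $\exp(-\sum_i p_i \ln p_i)$ (exponential Shannon entropy), $q=2$
the inverse Simpson concentration. Taxa with $p_i = 0$ are excluded from
the sum at every order, so $^0D$ counts only taxa actually present. The
$q = 1$ limit is substituted analytically whenever $|q - 1| < 10^{-9}$;
no numerical limit-taking is performed.

For cohorts of individual microbiome samples, one sample is one unit of
"area": pooling the raw counts of $A$ samples gives the accrued community
at area $A$, and its Hill diversity traces an accumulation curve $D(A)$,
$A = 1..n$. Pooling raw counts (rather than averaging per-sample
diversities, or reducing to presence/absence) is the convention used
throughout: accrued diversity is the diversity of one pooled community,
and Hill numbers only see the normalized abundances, so raw versus
pre-normalized pooled counts are equivalent.

Two models are fitted to each curve on its log-linear transform by
ordinary least squares:

* power law (PL): $D = c A^z$, i.e. $\ln D = \ln c + z \ln A$;
* power law with exponential cutoff (PLEC):
  $D = c A^z e^{dA}$, i.e. $\ln D = \ln c + z \ln A + dA$,

with $z$ the diversity scaling exponent, $c$ the diversity of the first
area unit, and $d$ a taper-off parameter, typically negative, that lets
accumulation saturate. The reported goodness of fit $R$ is the Pearson
correlation between observed and fitted $\ln D$ (equivalently
$\sqrt{R^2}$ of the regression; for PLEC this is the multiple-correlation
analogue), and the p-value is the overall regression F-test. The F-test
is identical to the slope t-test for PL and is the natural joint test for
PLEC; this choice is a package design decision where either convention
was defensible.

### Permutation averaging

The sequence in which samples are pooled affects the fitted parameters —
most visibly $c$. `permutedFit()` therefore repeats the fit over
`nPermutations` (default 100) uniformly random sample orderings and
averages $z$, $c$, $d$, $R$ and $p$ over the *successful* fits, reporting
the success count $N$ alongside. A fit is successful when it is
non-degenerate, significant at $p < 0.05$, and — for PLEC — has $d < 0$:
a non-negative taper-off puts the curve's maximum at a negative area, so
such fits carry no usable saturation information. Failed fits are
excluded from the averages rather than zero-filled, which is why the
means are reported together with $N$. Parameters are averaged on their
natural scale (in particular $c$ is not averaged as $\ln c$). Degenerate
curves (zero variance in $\ln D$, e.g. identical replicate samples) are
flagged, counted as failures, and never raised as errors inside the
permutation loop.

### The four profiles

From the averaged parameters, `buildProfiles()` derives, at each $q$ of
a grid (default $\{0,1,2,3\}$):

* **DAR profile** — the exponent series $z(q)$ itself;
* **PDO profile** — pairwise diversity overlap $g = 2 - 2^z$, the
  expected shared fraction of diversity between two adjacent equal-size
  areas; $z=1 \Rightarrow g=0$ (no overlap), $z=0 \Rightarrow g=1$
  (complete overlap). $g$ always uses the PL exponent, from which the
  formula is derived; the PLEC exponent is never fed to it.
* **MAD profile** — maximal accrued diversity
  $D_{\max} = c\,(-z/d)^z e^{-z}$, the maximum of the PLEC curve,
  attained at $A_{\max} = -z/d$ areas; interpreted as the cohort's
  potential total diversity at that order.
* **LGD profile** — the local-to-global ratio
  $\mathrm{LGD}\% = 100\,c_{\mathrm{PL}} / D_{\max}$, the share of the
  cohort-wide diversity carried by a single area unit. The numerator is
  the PL $c$ (the model whose $c$ is defined as first-unit diversity);
  the denominator is the PLEC-derived $D_{\max}$.

$A_{\max}$ is reported as a real number of samples; rounding to whole
samples is presentation only. When a model has no successful fits at
some $q$, or the averaged PLEC parameters admit no interior maximum, the
dependent cells are `NA` with a warning rather than an error.

## Group comparison

`compareGroups()` tests whether a DAR parameter differs between two
sample groups with a randomization test: the observed statistic is the
difference of the permutation-averaged parameter, and the null is built
by permuting group labels over the pooled samples (preserving group
sizes) and recomputing the difference each iteration. The two-sided
p-value uses the add-one correction
$p = (1 + \#\{|\delta_{null}| \ge |\delta_{obs}|\})/(1 + B)$, so $p > 0$
always. Label permutation (rather than a bootstrap with replacement) is
the standard exchangeability-based randomization test and is what is
implemented. Iterations in which the parameter is undefined (no
successful fits in one relabeled group) are skipped and counted. The
computation is canonicalized over the sorted pair of labels, so swapping
the two group arguments under the same seed returns the identical
p-value.

`innerPermutations` (orderings per fit inside each iteration, default
10) is a speed/accuracy knob: each of the $B$ iterations refits both
groups, so the full default of 100 orderings per fit is reserved for
final runs.

## The synthetic cohort generator

Real cohorts are sequencing-derived OTU tables; the generator emulates
the statistical structure the DAR analysis responds to, so the whole
pipeline is testable without downloads:

* a **global species pool** (default 600 species, matching the scale of
  cohort-level species totals in multi-study tissue microbiome data);
* **heavy-tailed abundances**: pool relative abundances are lognormal
  (default meanlog 0, sdlog 1.5, a standard microbial species-abundance
  shape); `abundanceSdlog = 0` gives a perfectly even pool;
* **core/satellite occupancy**: a `coreFraction` of the pool is present
  in every sample; each satellite species draws an occupancy probability
  from Beta(0.5, 1.5) (mean 0.25, mass near zero — many sporadic, few
  near-core satellites) and per-sample presence by Bernoulli draws.
  `coreFraction` is the interpretable overlap knob: raising it increases
  inter-individual overlap and drives the fitted $z$ down (and $g$ up);
* **finite sequencing depth**: per sample, reads (default 2000) are
  drawn multinomially from the renormalized abundances of the species
  present;
* a **disjoint mode** partitioning the pool evenly with no sharing — the
  no-overlap limit in which richness accumulates linearly and fitted
  $z \to 1$.

The defaults above are the generator's fixed study conditions, chosen
once on these ecological grounds. What the generator does *not* emulate:
taxonomic misassignment, contamination, batch effects between studies,
primer/platform heterogeneity, or any spatial structure within a
subject. Passing tests on synthetic cohorts therefore demonstrate that
the estimators recover known structure under the stated sampling model,
not that any particular biological cohort satisfies that model.

```{r limits}
shared <- generateCohort(syntheticConfig(nSamples = 20, coreFraction = 1,
                                         abundanceSdlog = 0), seed = 101)
permutedFit(shared, q = 0, model = "PL", nPermutations = 50, seed = 102)

disjoint <- generateCohort(syntheticConfig(nSamples = 20, disjoint = TRUE),
                           seed = 103)
permutedFit(disjoint, q = 0, model = "PL", nPermutations = 50, seed = 104)
```

## Numerical choices and degenerate inputs

* Natural logarithms throughout the log-linear transforms.
* The $q=1$ Hill limit is used whenever $|q-1| < 10^{-9}$.
* Abundance vectors must sum to 1 within $10^{-9}$; zero-abundance taxa
  are retained harmlessly.
* Zero-read samples are dropped with a warning at table construction
  (public OTU tables commonly contain them); negative or fractional
  counts are errors.
* A flat accumulation curve or rank-deficient design yields a flagged
  degenerate fit, not an exception; `fitPL` needs $\ge 3$ points and
  `fitPLEC` $\ge 4$.
* $D_{\max}$ with $z = 0$ returns $c$ (the curve is monotone decreasing
  in $A$ beyond its flat power part); $d \ge 0$ is an error for
  $A_{\max}$/$D_{\max}$ since no interior maximum exists.
* All randomness flows from explicit seeds; library calls restore the
  caller's RNG state, and `runDesign()` derives and logs one child seed
  per task from its master seed.

## Problem sizes

The test suite exercises the estimators at desk scale: cohorts of 15-40
samples against pools of 100-600 species, 100 sample orderings for
single fits, and 50 label-permutation iterations over 50 simulated
cohort pairs for the calibration study, with 20 replicate seeds for the
positive-control power check. These sizes were chosen as the smallest at
which the asymptotic behaviour of the estimators is already visible.

## Known limitations

* The analysis is compositional at heart: only relative abundances enter
  the Hill numbers, so depth differences between samples act through
  detection (presence) rather than through scale.
* No rarefaction or coverage standardization is performed; if samples
  differ strongly in depth, richness-order results ($q = 0$) inherit the
  usual detection bias.
* Phylogenetic and functional diversity variants, and beta-diversity
  matrices, are out of scope.
* The scaling parameters summarize community-level structure only; they
  carry no information about which taxa drive the overlap or saturation.
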