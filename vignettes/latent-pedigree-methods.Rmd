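---
title: "Methods: kinship estimation and latent-pedigree model selection for ancient DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinship estimation and latent-pedigree model selection for ancient DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynastikin)
```

# Scope

`dynastikin` answers a question that recurs in archaeogenetics: two
individuals from related but distinct burial contexts share a
second-degree autosomal relationship and a mitochondrial haplotype — which
*pedigree* connects them? Genotype data alone cannot separate an uncle from
a maternal grandfather (both imply r = 1/4 and, under the right latent
relatives, an mtDNA match). What can separate them is chronology: burial
date ranges, osteological ages at death, and demographic priors on the ages
at which women and men have children. The package implements the full chain
from pseudo-haploid genotype matrices to posterior weights over a catalogue
of candidate pedigrees, plus the supporting statistics used in such studies
(sex determination from X/Y coverage, a sex-biased-admixture Z score,
runs-of-homozygosity consanguinity summaries, IBD degree envelopes, and
exact Wilcoxon rank-sum tests).

# The kinship layer

## Pairwise mismatch rate

For low-coverage ancient DNA the standard genotype representation is
pseudo-haploid: one sequencing read per site is drawn at random and the
individual is recorded as carrying that single allele. For two individuals
with calls at `n` shared sites, the pairwise mismatch rate (PMR) is the
fraction of sites at which the calls differ. Two unrelated individuals
mismatch at a baseline `p0` determined by the panel's heterozygosity; a
pair with relatedness coefficient `r` mismatches at

```
E[PMR] = p0 * (1 - r/2),
```

so an identical pair (or duplicate library) sits at `p0/2`, first degree at
`3/4 p0`, second at `7/8 p0`, third at `15/16 p0`. `degree_posterior()`
turns an observed PMR into posterior class probabilities with a Normal
likelihood at each class mean (binomial SE) and a uniform prior over the
five classes — uniform because no class prior is available a priori, and
configurable for cohorts where one is.

The baseline `p0` is not printed in typical reports and must be estimated:
`baseline_rate()` takes the median PMR over pairs, classifies every pair
against that provisional baseline, drops pairs classified second degree or
closer, and returns the median of the rest. Third-degree calls are *not*
dropped: at typical SE the third-degree and unrelated class means are a few
SE apart, and excluding borderline pairs would bias the median upward.

## Sex determination and the sex-bias Z

`determine_sex()` normalizes per-site X and Y coverage by autosomal
coverage. Expectations are (1, 0) for XX and (0.5, 0.5) for XY. Since only
the expectations are canonical, the decision rule uses symmetric acceptance
boxes (XX iff x &gt; 0.8 and y &lt; 0.1; XY iff 0.35 &lt; x &lt; 0.65 and
y &gt; 0.3; otherwise `unknown`), exposed as arguments rather than
constants.

`sex_bias_z()` implements `Z = (p_A - p_X) / sqrt(sigma_A^2 + sigma_X^2)`
for an ancestry proportion estimated on the autosomes and on the X
chromosome. Negative Z means the tested ancestry is enriched on X, i.e.
female-biased admixture. Note that recomputing a Z from *rounded* printed
proportions can differ in the second decimal from the value computed on
unrounded estimates; the worked example in the test suite documents one
such case (0.94 from rounded inputs where 0.93 was printed).

# The pedigree model space

The catalogue (`inst/extdata/pedigree_catalogue.json`) declares 11
topologies linking two focal individuals A and B, covering every
first- and second-degree connection compatible with both being male:
uncle, maternal grandfather, double first cousins, paternal grandfather,
maternal half-siblings, father, full siblings, and the four
direction-reversed variants. The catalogue is data, not code: other focal
pairs reuse the machinery by substitution of ids (or an alternative
catalogue file).

Each model carries two link sets:

* **kinship links** — the full parentage (including latent spouses needed to
  make, e.g., an uncle a *full* sibling of the mother). From these,
  `kinship_coefficients()` computes the kinship coefficient phi by the
  standard recursion and derives `r = 2 phi`, `k2` from the parental
  cross-kinships, `k1 = 4 phi - 2 k2`. The double-first-cousin model is the
  one catalogued topology with `k2 > 0` (9/16, 6/16, 1/16); it is grouped
  with the second-degree models by its `r = 1/4`. The double-first-cousin
  topology assumes both connecting sibling pairs are full siblings — the
  standard reading of that label.
* **the chronological chain** — one generative parent link per dated node:
  the connecting path, maternal where the topology implies it, paternal
  where the path itself is paternal. Redundant spouse links (a latent
  father whose age prior is wide and uninformative) deliberately do not
  constrain the chronology; they would double the dimension of the latent
  space for almost no information.

`matrilineal_path()` reports whether both focal individuals reach a shared
matriline through unbroken mother links — the condition for an obligate
mtDNA match. Models 1, 3, 5, 7 and 8 are matrilineal; the grandfather and
father models are not, and can only show a match through background
haplotype sharing.

# The chronological engine

## Generative model

For a pedigree model with chain nodes `c_1 (root), c_2, ...`:

* root birth year `b_root ~ Uniform(W)`, where the window `W` spans from
  `min(burial lo) - 110 - 2 * 60` to `max(burial hi)` and is *shared by all
  models*, so its width cancels in the posterior weights;
* each child's birth is `b_parent + age`, with `age` drawn from the
  maternal or paternal age-at-birth prior;
* each observed individual's age at death is uniform on its osteological
  interval;
* the burial year `birth + age` must fall inside the archaeological
  interval — a pure indicator. An interval-width normalization would be
  equivalent (the same constant multiplies every model) and is omitted so
  that the marginal likelihood tends to 1 as the observation intervals
  widen.

`joint_density()` is the product of these terms; `marginal_likelihood()`
integrates the indicators over the prior by direct Monte Carlo (fraction of
prior-predictive draws that satisfy every burial constraint), with a
binomial MC standard error. Direct prior integration was chosen over
harmonic-mean-style estimators from posterior samples: the latent space is
at most six-dimensional, the prior is proper and bounded, and the direct
estimator is unbiased with a computable SE. The MCMC sampler exists to
deliver the posterior marginals (birth dates, burial dates, mothers' birth
dates), not the marginal likelihood.

## Age-at-birth priors

The supports follow the demographic literature: maternal ages in
[13, 50], paternal in [15, 60] years. Within those supports the package
uses truncated normals — maternal N(26, 7), paternal N(32, 9) — peaking in
the twenties / early thirties, the package's own calibration choice where
only the supports are externally fixed. All four numbers are arguments of
`chrono_priors()` and of the pipeline config; analyses that depend on them
should say so.

## MCMC

`sample_posterior()` runs random-walk Metropolis-within-Gibbs: one sweep
per iteration over all coordinates plus one joint translation proposal of
all birth years (the slow mode when burial intervals are wide relative to
age priors). Proposal scales adapt per coordinate during burn-in (discarded,
default 25%) toward a 20-40% acceptance rate and are frozen afterwards.
Chains start from a deterministic greedy feasible state (each birth placed
as close to the value implied by interval midpoints as the link supports
allow), falling back to prior rejection; at least two chains are required
and split-chain R-hat above 1.05 triggers a warning. The sampler is
validated against `rejection_sample()`, which draws exact independent
posterior samples from the generative prior — feasible because the
acceptance probability equals the model's marginal likelihood, which for
realistic configurations is around 1-5%.

Degenerate inputs: exactly zero-width burial intervals have probability
zero under the continuous generative prior and cannot be conditioned on;
the sampler supports intervals of any positive width and the test suite
verifies collapse onto the implied point as widths tend to zero.

## Evidence combination

For each model `m` the posterior weight is

```
w_m  proportional to  prior_m * M_m * G_m * T_m
```

with `M_m` the chronological marginal likelihood, `G_m` the Normal kinship
evidence of the focal PMR at `p0 (1 - r_m / 2)`, and `T_m` the mtDNA term:
1 for a match under a matrilineal model, `f_background` for a match under a
non-matrilineal one (complements if no match). The default
`f_background = 0.01` reflects a shared haplotype individualized by private
mutations; because the ratio between matrilineal and non-matrilineal models
is linear in `f`, this is the single most influential tunable of the
pipeline and lives in the config. Bayes factors are reported relative to
the maximum-weight model. Weights are invariant to rescaling any evidence
vector by a positive constant; setting `f_background = 1` and a flat `G`
reduces the ranking to pure chronology.

# The synthetic-data layer

Every stage is testable without real data, but the generators state a
simplified world:

* `gene_drop()` uses unlinked sites (founders at Hardy-Weinberg from
  per-site frequencies drawn Uniform(0.05, 0.5), mimicking an ascertained
  capture panel). Marginal sharing statistics (PMR, realized k
  coefficients) are exact in this world; linkage disequilibrium, reference
  bias, and damage-driven error structure of real aDNA are not emulated.
* `pseudo_haploidize()` draws one allele per site, flips with a constant
  error rate and drops calls with a constant missing rate — no
  coverage-correlated missingness.
* `simulate_recombination()` places crossovers as a Poisson process (1 per
  100 cM, no interference) and tracks founder-chromosome origin, giving
  exact RoH and IBD segments for the simulated pedigree; there is no
  background (population-level) relatedness, so simulated unrelated pairs
  share exactly nothing. Degree envelopes built from it
  (`ibd_reference()`) therefore understate the sharing noise of real
  cohorts at the low end.
* `simulate_chronology()` draws from the same generative prior the engine
  integrates over; recovery tests run on it are internal-consistency
  checks, not evidence that real archaeological intervals are well
  calibrated.

A green test against these generators establishes correctness of the
estimators *in the stated world* — unbiasedness of gene-dropped k
recovery, the PMR class means, f x L autozygosity — and nothing about
upstream artefacts the out-of-scope tools (read processing, imputation,
IBD calling) may introduce.

# Numerical choices and degenerate inputs

* Exact Wilcoxon rank-sum p-values are computed by the partition-count
  recurrence in double precision (exact for the subset counts arising at
  cohort sizes; the DP refuses tables beyond 1e6 cells). Two-sided p
  doubles the smaller inclusive tail and caps at 1, matching standard
  software. Tied data are rejected: the exact null is undefined under ties
  and the package deliberately omits the normal approximation.
* Segment tables are half-open `[start, end)` in cM so lengths add without
  end corrections; abutting segments merge.
* Calendar years are astronomical (1 BCE = 0), converted exactly once at
  parse time.
* The consanguinity call (`roh_profile()`) uses total RoH at or above 4 cM
  against a 150 cM cut: the expected total for first-cousin parents is
  `L/16`, about 222 cM on the default 3545 cM map, and 150 cM separates
  that regime from background relatedness. The cut is configuration.
* `degree_from_ibd()` treats an observed sum of exactly 0 as
  "unrelated/beyond simulated range" even when a distant degree's envelope
  reaches 0, since zero sharing carries no positive evidence of
  relatedness.

# Known limitations

* The catalogue covers two-individual connections only; no joint inference
  over three or more focal individuals.
* Chronological evidence enters through one generative chain per model;
  topologies whose extra links carry real chronological information (none
  of the catalogued 11 do, materially) would need chain extensions.
* The marginal-likelihood estimator degrades when observation intervals are
  extremely narrow (the indicator acceptance rate underflows); in that
  regime rerun with more draws or widen the intervals to their honest
  uncertainty.
* Headline posterior weights depend on the burial/age intervals, the
  maternal-age prior and `f_background`; the package ships defaults stated
  once in this vignette's terms, and the acceptance suite documents the
  weights they produce rather than tuning them to published values.
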