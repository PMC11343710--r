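# dynastikin

Kinship, consanguinity and latent-pedigree inference for low-coverage
ancient-DNA cohorts.

## The problem

Archaeogenetic studies of burial communities routinely establish *that* two
individuals are related — a pairwise mismatch rate placing them at second
degree, a shared mitochondrial haplotype — but genotypes alone cannot say
*how*: an uncle, a maternal grandfather, double first cousins and maternal
half-siblings all imply relatedness r = 1/4, and several of them also force
an mtDNA match. What breaks the tie is chronology: archaeological
burial-date intervals, osteological age-at-death estimates, and demographic
priors on ages of motherhood and fatherhood. `dynastikin` formalizes that
argument as Bayesian model selection over a catalogue of candidate
pedigrees, for the kind of question raised by the Early Iron Age "princely"
burials of southwestern Germany: did status pass from a man to his sister's
son?

## The model

For each candidate pedigree *m* connecting focal individuals A and B, with
latent relatives (mothers, sisters, daughters) as needed:

- latent birth years follow a generative chain — a root birth uniform on a
  shared window, then child birth = parent birth + an age-at-birth drawn
  from truncated-normal maternal (support 13–50 yr) or paternal (15–60 yr)
  priors;
- each observed individual's age at death is uniform on its osteological
  interval, and the implied burial year (birth + age) must fall in the
  archaeological interval;
- the chronological marginal likelihood M_m is the probability of those
  burial constraints under the prior, estimated by direct Monte Carlo;
- kinship evidence G_m is the Normal likelihood of the observed pairwise
  mismatch rate at the model's expectation p0(1 − r_m/2);
- mtDNA evidence T_m is 1 for a haplotype match under a matrilineally
  connected pedigree, the background frequency f otherwise.

Posterior weights are w_m ∝ π_m · M_m · G_m · T_m, with Bayes factors
relative to the top model, and MCMC delivers posterior marginals for the
birth and burial dates of observed and latent family members.

Around this core the package implements the supporting statistics of such
studies: EIGENSTRAT pseudo-haploid I/O, pairwise mismatch rates with
Bayesian degree classification, X/Y-coverage sex determination, the
sex-biased-admixture Z score (p_A − p_X)/√(σ_A² + σ_X²),
runs-of-homozygosity consanguinity summaries (first-cousin parents expected
at L/16 ≈ 222 cM), IBD degree envelopes from a Poisson-recombination
simulator, and exact two-sided Wilcoxon rank-sum tests by dynamic
programming. A synthetic-data module (gene dropping, pseudo-haploidization,
segment simulation, matrilineal haplotype transmission, chronological
observation generators) makes every stage testable without any download.

## Worked example

Two male central burials: HOC001 (buried 540–520 BCE, died aged 40–50) and
APG001 (510–480 BCE, died 25–35), same mtDNA haplotype, pairwise mismatch
rate 0.21 against a cohort baseline p0 = 0.24 (second-degree expectation
0.875 × 0.24 = 0.21).

```r
library(dynastikin)

meta <- tempfile(fileext = ".tsv")
write_metadata(list(
  individual("HOC001", sex = "XY", burial_lo = -539, burial_hi = -519,
             age_lo = 40, age_hi = 50, mt_haplotype = "J1b1a1"),
  individual("APG001", sex = "XY", burial_lo = -509, burial_hi = -479,
             age_lo = 25, age_hi = 35, mt_haplotype = "J1b1a1")), meta)

cfg <- tempfile(fileext = ".yaml")
writeLines(c(
  "seed: 1", "n_draws: 100000", "n_chains: 4", "n_iter: 20000",
  "p0: 0.24", "f_background: 0.01",
  "pmr:", "  rate: 0.21", "  se: 0.003", "  n_overlap: 100000",
  paste("metadata:", meta),
  "focal: [HOC001, APG001]", "figures: false"), cfg)

report <- run_full_analysis(cfg)
report$model_posterior[1:5, c("model_id", "label", "weight", "bayes_factor")]
```

prints (weights rounded)

```
  model_id label                                        weight bayes_factor
1        1 HOC001 is the uncle of APG001                0.9233       1
2        3 HOC001 and APG001 are double first cousins   0.0352       0.0381
3        2 HOC001 is the maternal grandfather of APG001 0.0231       0.0251
4        4 HOC001 is the paternal grandfather of APG001 0.0168       0.0182
5        5 HOC001 and APG001 are maternal half-siblings 0.0015       0.00166
```

The avuncular pedigree — HOC001's full sister is APG001's mother — carries
92% of the posterior: it is the only second-degree topology that explains
the mtDNA match through an unbroken female line *and* tolerates the ~50-year
gap between the implied birth dates. The grandfather models fit the
chronology even better (higher M_m) but must buy the haplotype match at the
background frequency f = 0.01. First-degree models are excluded by the
mismatch rate; reversed-direction models by the burial order.

The latent summaries date the unobserved family members, e.g. the shared
mother's birth (posterior median −593, 90% CI [−605, −582]) and the latent
sister's (−563 [−574, −550]):

```
      parameter  median    lo90    hi90
1           b:M -592.67 -604.78 -581.87
3           b:S -562.58 -574.40 -549.78
7 burial:HOC001 -524.83 -535.78 -519.47
8 burial:APG001 -502.55 -508.44 -488.55
```

Standalone statistics:

```r
wilcoxon_exact_p(6, 10, 23)           # W = 23, two-sided P = 0.4923
sex_bias_z(0.55, 0.011, 0.835, 0.099) # Z = -2.86: female-biased admixture
roh_profile(read_segments("roh.tsv"), "MBG004")  # consanguinity class
```

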