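---
title: "Oral–stool community coalescence: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oral-stool community coalescence: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

coalesceR implements a longitudinal analysis of microbial community
coalescence between the oral cavity and the gut in patients undergoing
induction chemotherapy for acute leukemia. This vignette is the package's own
account of the science it encodes: the models and their assumptions, the
tunable parameters and why their defaults are what they are, what the
synthetic cohort generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## The analysis in one paragraph

Oral and gut communities of healthy people are compositionally distinct.
Under intensive chemotherapy and broad-spectrum antibiotics, the gut can
become permissive to typically oral taxa, and in a subset of patients the two
communities merge ("coalescence"). The pipeline quantifies this with
phylogenetic beta diversity: for each patient, the minimum weighted UniFrac
distance over *all* longitudinal oral × stool sample pairs measures the
closest the two sites ever came. Patients whose minimum falls in the bottom
quartile of the cohort are classified as coalesced. The classification is
validated against shared-vs-unique OTU trajectories and concordant genus
domination, characterized with random-intercept linear mixed models of
Shannon diversity over time, explained with time-varying Cox models of daily
antibiotic exposure, and linked to infection outcomes with χ² tests and odds
ratios.

## Distances and ordination

* **Bray–Curtis** is computed on raw counts, `1 − 2Σmin(x,y)/(Σx+Σy)`. No
  rarefaction or transformation is applied anywhere in the pipeline — the
  upstream study applied none — but distances operate on relative structure
  (UniFrac works on proportions), so library-size effects are mild. A
  rarefaction hook was deliberately left out rather than off-by-default, to
  keep the surface honest.
* **UniFrac** is computed from first principles by one post-order traversal
  that accumulates, per branch, the proportion of each community descending
  through it. Unweighted UniFrac is the unique observed branch length over
  the total observed branch length; weighted UniFrac is the **normalized**
  variant `Σ l|A−B| / Σ l(A+B)`, chosen so that values are bounded in [0, 1]
  and can be pooled and ranked across patients — which the bottom-quartile
  rule requires.
* **PCoA** is classical metric scaling (Gower double-centring +
  eigendecomposition). Negative eigenvalues, which Bray–Curtis can produce,
  are dropped with a warning rather than corrected; with these data the
  leading axes are far from the negative tail, and a correction would change
  coordinates without changing any downstream decision.
* **PERMANOVA** uses Anderson's pseudo-F computed from squared distances with
  free permutation of sample labels (999 by default, seeded). The permutation
  p is `(1+k)/(1+B)`, which is exact on its grid; an exhaustive mode
  enumerates all `n!` permutations for n ≤ 8 and is used as a test oracle.
  Strata (restricting permutations within patients) are deliberately not the
  default because the headline test pools all samples, but the free
  permutation means p-values for longitudinal data are anti-conservative and
  are read here as descriptive.
* **95% confidence ellipses** on the first two PCoA axes use the group mean,
  the group sample covariance and the χ²₂(0.95) radius. "Overlap" membership
  (a sample inside both sites' ellipses) is one concrete reading of a
  figure-space notion the source material never defined precisely; it is
  labelled as such wherever it is reported.
* **Hierarchical clustering** of the distance matrix uses average linkage
  (UPGMA), a choice the upstream analysis did not name; it is configurable,
  and merge heights are monotone for UPGMA so the three-group cut is stable.

## The coalescence classifier

Per patient, *all* oral × stool pairs are formed regardless of collection
day; patients need at least `min_pairs = 3` pairs ("more than two") to be
eligible. The per-patient minimum distance is ranked ascending and the bottom
quartile — implemented as `rank ≤ floor(n_eligible/4)`, not a numeric
quantile estimator — is called coalesced. With 92 eligible patients this
yields exactly 23, and it avoids the ambiguity among the nine quantile
definitions. Ties in the minimum break by earlier event day, then patient id,
so ranks are always a strict permutation.

The **event day** assigned to a coalesced patient is the *later* collection
day of the minimizing pair: the coalesced state demonstrably exists only once
both samples exist. This matters for the survival analysis, where an event
cannot precede the evidence for it.

The **shared:unique OTU ratio** validation matches each stool sample to the
nearest-day oral sample within ±3 days (stool-anchored; ties toward the
earlier oral day), uses presence = count ≥ 1, and flags pairs with zero
unique OTUs as undefined rather than dividing by zero. **Domination** is a
single genus strictly above 30% of a sample's reads; a genus dominating both
sites of one patient at *any* study day (simultaneity not required — the
source is silent on this) is a concordant domination.

## Longitudinal mixed models

`fit_lmm()` fits `response ~ day * coalesced + (1 | patient)` by REML through
lme4. The random structure is an intercept per patient only — the upstream
models name the patient as the random effect without slopes. Inference on
coefficients is Wald z with no denominator-df correction; the interaction is
additionally tested by a likelihood-ratio comparison of the ML fits with and
without the term. Both are reported because the upstream toolchain's df
method is unknown; parameter recovery, not p-value equality, is the
acceptance surface. A simulation in the test suite confirms the Wald
interaction test holds its 5% size at the cohort scales used here.

## Time-varying Cox models of antibiotic exposure

The risk clock is days since chemotherapy start; patients are at risk from
day 0 until coalescence (event) or censoring at neutrophil recovery or death.
An *antimicrobial therapy day* is any calendar day with any administration of
the drug. Only drugs given to **more than 15%** of the cohort (strict) are
analyzed. Two exposure encodings are fitted univariately per drug:
cumulative therapy days (the per-additional-day effect) and an any-exposure
indicator (once exposed, always exposed).

The covariate convention is that therapy on day *d* increments the covariate
effective at the start of day *d+1*: exposure can never explain an event that
precedes it, which is also how the counting-process construction removes
immortal-time bias. The partial likelihood is maximized by Newton–Raphson
with step-halving; ties use the **Breslow** approximation by default because
events are day-granular and heavily tied (Efron is available). Standard
errors come from the observed information. Degenerate inputs are flagged
rather than fitted: a covariate with no variation inside any risk set returns
a zero log-HR with infinite SE ("no information"), and monotone likelihoods
(perfect separation) are flagged after the estimate walks past ±15.

## The synthetic cohort generator: what it emulates, what it does not

The source study provides no generative model; every distributional choice
below is a stand-in, stated once and not revisited.

* **Structure.** Two body-site communities per patient built from three taxa
  pools (60 oral-specific, 40 shared, 80 gut-specific OTUs on a random
  bifurcating tree with exponential branch lengths). Each site's composition
  is a patient-level Dirichlet draw with concentration 0.03 — set so samples
  reproduce the cohort's reported alpha-diversity scale (median Shannon ~1.8,
  median observed OTUs in the teens-to-twenties) and its frequent >30% genus
  dominations (~90% of coalesced patients show a concordant domination,
  against the reported 87%). Both sites share a common shared-pool profile
  carrying 50% (oral) / 45% (gut) of reads; these masses were set so the
  per-patient minimum weighted UniFrac of non-coalescing patients sits near
  the cohort's reported median (~0.4). All of this is calibration to printed
  summary statistics, not to test outcomes.
* **Sampling.** Twice-weekly (every 3 days) from day 0 until neutrophil
  recovery, drawn uniformly on 18–35 days (bracketing the reported 22-day
  median time to maximal coalescence). Read depth is Poisson around 5000;
  per-sample Dirichlet noise (concentration 50 × target) creates day-to-day
  variation. Death is rare (2%) independent censoring, present only to
  exercise the censoring path.
* **Onset.** A daily Bernoulli event with probability `1 − exp(−h_t)`,
  `log h_t = log h₀ + Σ β_d x_d(t)`, where `x_d(t)` is cumulative therapy
  days of drug *d* before day *t* — *exactly* the covariate the cumulative
  Cox encoding reconstructs, so fits on simulated cohorts estimate the
  generating log hazard ratios. The default β are the study's per-day
  estimates (levofloxacin 0.75, cefepime 1.10, meropenem/metronidazole 1.13,
  linezolid 1.15). The clinical baseline hazard h₀ = 0.006/day makes ~25% of
  patients truly coalesce, matching the reported 23/92. Onset is drawn
  strictly before the censoring day (an onset on the recovery day itself is
  unobservable and would violate the ground-truth invariant).
* **Exposure schedules.** The "clinical" pattern gives every patient
  prophylaxis from day 0 (as in the cohort), switching to a first-line
  empiric agent at a random fever day (70% of patients, day 2–10) with
  probabilistic escalation to later-line agents. The "staggered" pattern
  starts each drug at a uniform random day and runs it to the end; it exists
  for parameter-recovery studies, where the covariate must vary within risk
  sets by construction.
* **Mixing.** After onset the stool target composition is
  `(1−w)·gut + w·oral` with `w = min(0.95, 0.15 × days since onset)`. Rate
  and cap were set so coalesced patients' minimum distances reach the
  reported coalesced median (~0.18) within the reported time scale.
* **Outcomes.** Infection labels are Bernoulli with baseline risks 0.25
  (pre-recovery) and 0.20 (90 days post) for non-coalesced patients —
  plausible for induction-chemotherapy cohorts; the study does not print its
  2×2 cells — with odds multiplied by 4.93 and 2.72 for true coalescers (the
  study's reported odds ratios).
* **Not emulated.** Read-level artifacts (chimeras, contamination),
  taxon-specific antibiotic susceptibility, within-patient compositional
  drift unrelated to coalescence, systematic alpha-diversity decline over
  the treatment course (the full-cohort Shannon trajectories are flat by
  construction; the interaction-recovery study generates trajectories from
  the mixed model directly), strain sharing, hospital transmission, and
  any relationship between diversity and infection other than through the
  coalescence flag. A green end-to-end test therefore establishes that the
  pipeline recovers the generator's coalescence structure — not that the
  generator is a faithful model of real cohorts.

### Recovery-study worlds

The Cox parameter-recovery studies use 2000 patients, follow-up uniform on
25–30 days, a single drug staggered over start days 0–10, and h₀ =
0.004/day (~25% cumulative incidence under the harmful effects; ties stay
sparse enough that the Breslow approximation's attenuation is far below the
Monte-Carlo resolution of 20 seeds). The LMM recovery world generates
directly from the fitted model family: intercept 1.81 (the cohort's median
oral Shannon diversity), day slope −0.01, coalescence main effect −0.3,
interaction −0.017, patient-intercept SD 0.4, residual SD 0.5, a quarter of
patients coalesced, twice-weekly sampling to day 28.

## Numerical choices and degenerate inputs

* Shannon diversity uses the natural log (vegan/phyloseq convention).
* Presence for set operations is count ≥ 1; no detection threshold.
* Samples with zero total counts are dropped with a warning at construction.
* Distance matrices are validated for symmetry (1e-12) and zero diagonal.
* PCoA eigenvalues below `max|λ| × 1e-10` are treated as zero.
* The Newton solver converges on score < 1e-9 or step < 1e-10, with at most
  30 step-halvings per iteration.
* Duplicate (patient, drug, day) exposure rows collapse to one with a
  warning, implementing the therapy-day definition.
* χ² requires positive margins; odds ratios with a zero cell get the 0.5
  continuity correction and a flag.

## Known limitations

* Free-permutation PERMANOVA ignores the repeated-measures structure of the
  pooled sample set; a strata option would be the remedy and is out of scope.
* The Wald z inference in `fit_lmm` is anti-conservative for very small
  cohorts; the size simulation covers the scales used here (≥ 80 patients).
* Weighted UniFrac is quadratic in samples per call; the pipeline therefore
  computes it per patient (the classifier only consumes intra-patient
  blocks) and uses Bray–Curtis for pooled ordination.
* The generator's infection model is deliberately minimal: it encodes the
  reported odds ratios and nothing else, so only direction and rough
  magnitude of the association are recoverable.
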