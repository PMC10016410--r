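---
title: "Methods: z-score subtype-and-stage inference for regional atrophy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: z-score subtype-and-stage inference for regional atrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette describes the statistical model the package implements, the
choices made where the design was genuinely open, what the synthetic cohort
generator does and does not emulate, and the numerical conventions that make
results reproducible. It states no empirical result that the test suite and
the acceptance script do not themselves compute.

## The model

The observation for scan $j$ is a vector $x_j$ of sign-flipped, control-referenced
z-scores over $I$ selected brain regions: larger $x$ means more atrophy. A
**z-score event** is a region crossing one of its thresholds
$z_{i,1} < \dots < z_{i,R_i}$; the grid of all events defines
$E = \sum_i R_i$ model stages beyond stage 0. A **subtype sequence** $S$ is a
permutation of all $E$ events, constrained so a region's lower thresholds
precede its higher ones (atrophy is monotone). A subject at stage $k$ of
subtype $S$ has expected z-scores $g_i(k)$ given by piecewise-linear
interpolation through the anchors $(0, 0)$, $(\mathrm{pos}(e_{i,r}), z_{i,r})$
and $(E + 1, z^{\max}_i)$. The data model is Gaussian around the trajectory,

$$P(x_j \mid S, k) = \prod_i \mathcal{N}\!\left(x_{ji};\, g_i(k),\, \sigma_i\right),$$

with $\sigma_i = 1$ by default (the natural scale for control-referenced
z-scores). Stages carry a uniform prior, so
$P(x_j \mid S) = \frac{1}{E+1}\sum_{k=0}^{E} P(x_j \mid S, k)$, and a
$C$-subtype model is the mixture
$\sum_c f_c\, P(x_j \mid S_c)$ with fractions $f_c$.

Design notes on the model itself:

* **The plateau anchor sits at stage $E + 1$**, not $E$, so it can never
  collide with a biomarker whose last event occupies position $E$; this keeps
  every trajectory single-valued and non-decreasing, which is enforced as a
  hard constraint and checked property-style in the tests.
* **The stage prior is uniform.** It matches the equal-weight stage sum used
  when assigning subjects, and no information about the stage distribution is
  smuggled into the fit.
* **Missing biomarker values are not marginalised**: a scan missing a selected
  region is excluded during preprocessing with a message. Partial-profile
  assignment is a deliberate non-goal of this version.

## Preprocessing

The pipeline order is fixed: combine paired left/right labels (sum), fit the
covariate adjuster on controls only, propagate it to everyone, select
biomarkers by effect size, z-score.

* **Covariate adjustment** fits, per region, ordinary least squares on the
  control scans with age, sex, total intracranial volume, scanner field
  strength and manufacturer; categorical covariates are treatment-coded with
  the most frequent control level as reference (the reference choice only
  relabels coefficients, not the adjusted values). The adjusted volume is the
  residual shifted back to the control reference,
  $v - (\hat v - \overline{\hat v}_{\text{controls}})$, so volumes keep their
  mm³ scale; whether one stores pure residuals or residual-plus-reference
  affects only reporting, since z-scoring removes the offset. Adjustment is
  not idempotent and is applied exactly once.
* **Effect-size selection** uses Cohen's $d$ with the pooled-SD definition,
  computed as controls minus patients on adjusted baseline volumes so atrophy
  gives $d > 0$; regions with $d \ge 0.6$ (moderate-to-large) are kept,
  ordered by descending $d$. Selection is invariant to affine rescaling of a
  region's raw units.
* **Follow-up scans are z-scored with the baseline-fit adjuster and control
  statistics** — the model is frozen before any longitudinal data are seen.

## Fitting

The single-sequence optimiser is greedy coordinate search with random
restarts: from each of `n_starts = 24` random valid permutations, sweep over
events in random order, re-insert each event at the position (compatible with
within-biomarker order) that maximises the stage-marginalised log-likelihood,
and stop when a full sweep brings no improvement. Ties break toward the lowest
position, which makes the search deterministic given the seed. The sweep
objective never decreases; this is asserted in code.

Additional subtypes are introduced hierarchically. To go from $C-1$ to $C$
subtypes, every existing cluster is split: its members (hard-assigned by
maximum responsibility) are randomly bipartitioned, a sequence is fitted to
each half, and the resulting $C$-subtype model is refined by EM
(responsibilities; fraction update; responsibility-weighted greedy sequence
moves) until the log-likelihood gain falls below $10^{-6}$ or 100 iterations.

One subtlety deserves record. A *single* random bipartition of a mixed
cluster is almost always still mixed, so both half-fits converge to the
majority sequence — and an EM started from two identical sequences is at a
symmetric stationary point it can never leave (all responsibilities are
exactly equal). The package therefore attempts `n_split_tries` independent
bipartitions per cluster and fits each half from a *single* random start:
under-restarting the half-fits is intentional, because the resulting
diversity is what occasionally lands a half-fit near the minority pattern,
letting the EM separate the clusters. Each try is scored by a short (5
iteration) EM and only the best try is refined to convergence. If no split
improves the likelihood, the larger model duplicates a sequence with split
fractions, so the fitted likelihood is never below the smaller model's.

**Uncertainty** is estimated by Metropolis–Hastings over orderings with the
fractions held at their maximum-likelihood values (only orderings are
reported as uncertain). Each iteration picks a subtype and an event uniformly,
proposes a uniformly random valid position, and accepts with
$\min(1, L'/L)$ on the full-data likelihood; every retained state contributes
to the positional variance diagrams, whose rows are probability vectors by
construction. Default 100,000 iterations.

**Model selection** uses subject-level ten-fold cross-validation with folds
shared across candidate subtype counts. The criterion is
$\mathrm{CVIC}(C) = -2 \sum_{\text{folds}} \log \hat L_{\text{test}}$; the
paper family this implements names the criterion without printing its
formula, so the deviance-scale definition and the "strong evidence" margin of
6 are package defaults (both configurable). An extra subtype is accepted when
CVIC improves by more than the margin, or when the change is within the
margin but the mean per-fold test log-likelihood still improves; otherwise
the more parsimonious model is kept, and the rule that fired is returned.

## Assignment, longitudinal validation, statistics

The posterior over (subtype, stage) is
$P(c, k \mid x) \propto f_c P(x \mid S_c, k)/(E+1)$, computed in log space
and normalised exactly. The maximum-likelihood subtype is the argmax of the
stage-summed posterior and the stage is the argmax *conditional on that
subtype* (the two-step rule; a joint argmax differs only on scans whose
subtype is already ambiguous, and the conditional form matches assigning a
stage "within" a subtype). The expected stage averages $k$ over every stage
of every subtype. Scans at stage 0 or stage $E$ carry no ordering information
and are flagged not subtypable; they are excluded from subtype-level
statistics but retained in staging plots.

Longitudinal validation freezes the baseline model and assigns all follow-up
scans. Subjects with several follow-ups contribute one pair per consecutive
visit. Subtype stability counts a pair consistent when the subtype is
unchanged or when a stage-0 (normal-appearing) scan has entered a subtype;
progression to the end stage is *not* counted consistent, mirroring the
transition-table convention the report reproduces. Stage progression
classifies pairs with the discrete maximum-likelihood stage, while
progression *rates* use the continuous expected stage divided by the
inter-visit time, averaged within subject before groups are compared with a
Welch t-test.

The post-hoc layer reports Welch (unequal-variance) t-tests — the form that
reproduces published group comparisons from summary statistics — Pearson
chi-square without continuity correction with Bonferroni-adjusted pairwise
row comparisons, the linear model `score ~ subtype + stage + age + sex` on
subtypable scans (subtype indicator coded cortical = 1; direction labels
derive from the coefficient sign and the scale's orientation), a logistic
regression of subtype on covariates whose stage term is the headline check,
an additive two-factor ANOVA of stage on syndrome and subtype with Tukey HSD,
and the 80%-completeness proration rule for partially missing assessments.
Standard fits go through `lm`, `glm`, `aov`, `chisq.test` and `TukeyHSD`;
the package adds the summary-statistic Welch form, which base R does not
expose.

## The synthetic cohort generator

Real MRI data of this kind are not redistributable, so the generator is a
first-class, tested module that emulates the study conditions end-to-end: 290
controls and 426 patients over 20 grey-matter regions; 41 z-score events
(three thresholds for the midbrain, two elsewhere); two latent subtypes with
fractions 0.75/0.25 whose sequences share early brainstem events and diverge
in cortical involvement; syndrome labels enriched ~81–82% for the matching
subtype; follow-up visits 0.91 ± 0.38 years apart with syndrome-dependent
progression of 1.86 (Richardson-like), 1.6 (cortical-variant) and 0.66
(subcortical-variant) stages/year; and clinical scores that worsen linearly
with stage, differ by subtype, and are clipped to their published ranges
(PSPRS 0–100, UPDRS 0–199, SEADL 0–100, MMSE 0–30).

Volumes are produced on the raw mm³ scale by inverting the z-score
construction — `volume = baseline + covariate effects − z · baseline_sd` —
and pushed through the real preprocessing path, so covariate regression,
selection and z-scoring are exercised rather than short-circuited. Stage
increments at follow-up are integer-valued (`round(rate · gap)` plus a
non-negative Poisson jitter, capped at the end stage) because model stages
are discrete and truth must stay comparable to assigned stages.

Generator defaults chosen where the source material is silent, with their
rationale:

* **Trajectory plateau** `z_max` = last threshold + 2: end-stage atrophy
  keeps worsening past the last modelled threshold; a plateau at the last
  threshold would compress the late trajectory into the noise.
* **Noise decomposition.** The total per-scan noise is 1 z-unit, split into a
  persistent subject effect (SD ≈ 0.95) and an independent scan-rescan
  component (SD 0.3). Automated volumetry is highly repeatable (scan–rescan
  coefficients of variation of 1–2%, here ~0.3 of a control SD), while the
  dominant deviation from a subtype trajectory is the subject's own anatomy,
  which persists across visits. Drawing all noise independently per scan
  would misrepresent longitudinal data quality.
* **Baseline stage distribution**: a discretised truncated normal with mean
  0.45 E and SD 0.25 E (≈ 18.5 and 10 at E = 41), the shape of observed
  baseline stage distributions in symptomatic cohorts; a uniform alternative
  overloads the uninformative extremes (stages 0 and E).
* **Syndrome enrichment** is a 2 × 3 matrix P(syndrome | subtype) over
  Richardson, cortical-variant and subcortical-variant labels; three
  syndromes are needed for syndrome-dependent progression rates to be
  expressible, and the defaults preserve the 81%/82% subtype–syndrome match
  proportions.
* The exact default orderings are arbitrary beyond their qualitative design
  (shared brainstem onset, divergent cortical timing) and are defined in one
  place (`default_true_sequences`).

What the generator does **not** emulate: scanner physics and site-specific
image artefacts (covariate effects are exactly linear, so the adjuster's
model is correctly specified by construction); spatial correlation between
neighbouring regions beyond the shared stage; non-Gaussian heavy tails;
informative dropout; and any treatment effect. Passing recovery tests on
these cohorts therefore demonstrates the *machinery* — identifiability at
realistic sizes, noise levels and fractions — not robustness to real-world
model misspecification.

## Numerical conventions and problem sizes

All stochastic functions take explicit seeds and restore the RNG state on
exit; equal seeds give byte-identical outputs, including written CSV/JSON.
Likelihoods are computed in log space with log-sum-exp; the posterior
normalises to 1 within 1e-12. Greedy ties break toward the lowest insertion
position. The likelihood and greedy inner loops are compiled (RcppArmadillo)
and are cross-checked against pure-R brute-force oracles in the tests at
1e-10 or tighter.

The test and acceptance workloads are sized for a single CPU: sequence
recovery uses 10 biomarkers × 300 scans with 24 restarts over 10 seeds;
mixture recovery uses 400 scans with 8 restarts/split tries and subject-level
ten-fold cross-validation over 10 replicates; staging and longitudinal
consistency run the full 716-scan default cohort with the ground-truth model
frozen (fitting a 41-event model afresh per seed would test the same
assignment code at much higher cost); Monte-Carlo checks of the generator use
10,000 subjects. MCMC runs shortened chains (2,000–10,000 iterations) in the
tests; the 100,000-iteration default remains the recommended analysis
setting.

## Limitations

The model assumes a small set of discrete trajectories; a continuum of
progression patterns will be split into pseudo-subtypes. There is no explicit
timescale — stages order events but say nothing about calendar time between
them, so rates are only estimable from longitudinal follow-ups. Fractions are
held fixed during MCMC, so reported uncertainty covers orderings only.
Cross-validation selects the subtype count but is not an external validation;
on small minority subtypes the CVIC is conservative by design.
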