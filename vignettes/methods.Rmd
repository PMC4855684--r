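---
title: "Dyadic permutation regression of resource allocation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dyadic permutation regression of resource allocation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netalloc)
```

## The scientific problem

In a classroom, each adolescent can divide a fixed budget of points (a
modified Dictator Game) among all classmates. The resulting allocation is a
valued, directed network: cell (i, j) of the allocation sociomatrix `Y` is
what i gave to j. The question `netalloc` addresses is how allocation
depends on the social relationships in the same classroom — how strong a
tie i reports toward j, how much j reciprocates that tie, and sender- and
receiver-side attributes such as gender or Machiavellianism — and whether
those dependencies differ between classrooms (year groups).

Dyadic observations are not independent: all of row i shares the sender,
all of column j shares the receiver. Ordinary regression standard errors
are therefore invalid, and every inferential step in this package is built
on actor-level resampling instead: quadratic-assignment permutations for
regression, and the vertex bootstrap for whole-network statistics.

## Data model

**Relationship strength.** Questionnaire items rated by every ego about
every alter are scored into a strength sociomatrix `S` by summing the
strength-component responses and dividing by the maximum possible summed
score. The built-in five-item schema (three yes/no items, a
nature-of-relationship item from −1 *negative relationship* to 4 *best
friend*, and a relative-trust item −1/0/1) has divisor 8, so link weights
span [−0.25, 1]; the six-item schema adds a conflict-resolution item
(−1/0/1) and has divisor 9, spanning [−1/3, 1]. Rows are out-links,
columns in-links. Dyads with no response are missing, never zero — zero
is a meaningful scale point.

**Reciprocation.** `R = t(S) − S`. A positive cell means the alter
reports a stronger tie toward ego than ego reports back. `R` is
antisymmetric by construction, so its off-diagonal total is exactly zero;
this is asserted in the tests to machine precision.

**Attribute matrices.** A per-actor scalar becomes a "giving" matrix by
broadcasting along rows (sender effect) or a "receiving" matrix along
columns (receiver effect).

**Diagonals.** Self-ties are structurally masked (`NA`) everywhere.
Points kept for oneself are a per-actor scalar (`points_to_self`), carried
separately in `group_data` objects, because the regressions model
allocation *to others* only.

**Vectorisation.** All model fitting happens on a dyad design table with
one row per ordered off-diagonal dyad in a fixed row-major order; an
n-actor network contributes n(n−1) rows (23 and 19 actors pool to 848
rows). Rows with any missing value are dropped listwise with a reported
count; the alternative (imputing zeros) would conflate "missing" with
"neutral relationship".

## Density comparison with the vertex bootstrap

The valued density of a network is the mean off-diagonal cell value. To
compare densities across classrooms, `vertex_bootstrap()` resamples actors
(not dyads) with replacement; a resampled pair mapping to two distinct
originals keeps the original cell, and a pair mapping to the same original
(a diagonal collision) is filled by a uniform draw from that actor's own
off-diagonal row and column values. The expected replicate density equals
the observed density (each cell enters exactly two actors' fill pools), a
property the test suite checks at 5000 replicates. The bootstrap SE is
the standard deviation of replicate densities.

`compare_densities()` forms `t = (d1 − d2) / sqrt(se1² + se2²)` with
unpooled bootstrap SEs and **dyad-count degrees of freedom**
`n1(n1−1) + n2(n2−1) − 2` (846 for 23 + 19 actors), the convention for
tie-variable comparisons; `pairwise_density_tests()` runs all C(k, 2)
pairs with a Bonferroni-adjusted threshold `alpha / C(k,2)`.

Default `n_boot` is 1000; seeds are mandatory arguments rather than
optional ones, so every reported SE is reproducible by construction.

## MRQAP with double semipartialing

`mrqap()` regresses the allocation matrix on predictor matrices. Point
estimates are ordinary least squares on the vectorised dyads — they can be
read exactly like regression coefficients — and the test suite verifies
they equal `lm()` on the same table to machine precision. Inference uses
the double-semipartialing (DSP) permutation scheme: for each focal
predictor,

1. residualise the focal predictor on all other predictors (plus
   intercept) over the dyad rows and reshape the residuals into an
   actor-by-actor matrix;
2. apply a random actor relabelling jointly to rows and columns of that
   residual matrix;
3. regress the outcome on the other predictors plus the permuted residual
   and record the focal coefficient;
4. compare the observed coefficient to the accumulated null distribution.

Permuting the *residualised* predictor rather than the raw outcome keeps
the test correctly sized when other predictors have real effects, which is
why DSP is the standard for multi-predictor network regression.
p-values use the exact-test convention `p = (1 + extreme) / (n_perm + 1)`,
so `p ≥ 1/(n_perm+1) > 0` always; identity permutations drawn by chance
are kept, not redrawn. One-tailed p-values are produced only for terms
with a declared directional hypothesis (`hypotheses = c(strength = "+")`),
two-tailed for everything else. The model-level p compares observed R² to
R² under random actor relabellings of the outcome. One RNG stream,
seeded by the mandatory `seed` argument, drives all draws of a fit.

Standardized coefficients are computed as `b · sd(x)/sd(y)` over the dyad
rows, matching z-scored refitting.

## Multigroup MRQAP

`mg_mrqap()` pools several classrooms: common slopes, one freely varying
intercept per class (a fixed-effects-by-class design, reference-coded on
the first group), and optional group-interaction predictors built by
multiplying a predictor's cells by the classroom's scalar group code
(e.g. year group 0/1, or 0/1/2 for a three-level design, which makes the
interaction slope linear in year group). With codes 0/1 the interaction
coefficient is simply the slope difference between the two classrooms.

Inference restricts permutations within classes: in each draw, every
group's outcome matrix is independently relabelled by a random actor
permutation of that group only, and the pooled model is refit. This
within-block outcome permutation respects the nesting of actors in
classes. It is somewhat conservative — with strong true effects of other
predictors, the null spread of a coefficient reflects total outcome
variance rather than residual variance — which is the safe direction for
confirmatory interaction tests. A DSP-within-blocks variant
(`method = "dsp"`) is provided for sensitivity analysis; point estimates
are identical between methods, only p-values differ.

Standardized coefficients are deliberately not reported for multigroup
models: with class fixed effects and pooled blocks of different variance
they have no clean interpretation.

Degenerate cases are treated as errors, not warnings: a group smaller
than three actors, an interaction requested for a predictor not in the
model, and — importantly — identical group codes across all groups, which
make every interaction column collinear with its main effect and signal
miscoded data.

## Backward elimination

`backward_eliminate()` implements the directional stepwise rule: refit,
drop the non-significant term whose **two-tailed** p is closest to 1,
refit, repeat; stop when all remaining droppable terms are significant at
`alpha` under their assigned tail (one-tailed for directional terms). Two
protections apply: a main effect is never dropped while its interaction
term is still in the model, and `forced_keep` terms (a main effect
retained purely so its group interaction can be tested) are never dropped.
The drop criterion stays two-tailed even for directional terms because
"closest to 1" is a statement about evidence against any effect; the
significance gate then uses the directional tail.

Design choices where the procedure was genuinely open:

* p-values are recomputed by a **full permutation refit after every
  drop** (the refit p's are what the elimination footnotes of such models
  report); a smaller `n_perm` can be passed for exploratory passes.
* Each elimination step derives a fresh seed deterministically from the
  master seed, so a trace is exactly reproducible while steps remain
  independent.
* Ties in p (possible at coarse `n_perm`) drop the term **later** in the
  user-specified order, and the trace flags that a tie was broken.

## The synthetic-data generator

No raw classroom data are distributed, so validation runs end-to-end on
synthetic studies with known ground truth (`simulate_study()`).

* **Strength networks.** Each unordered pair receives a bivariate-normal
  latent affinity with correlation `reciprocity_rho` between the two
  directions (default 0.5, typical of adolescent friendship reports).
  Every item response is a monotone discretisation of the same latent
  through fixed category probabilities stored in the schema — roughly
  half of dyads share activities, strong negative ties are rare. Fixed
  thresholds make tests stable; at `rho = 1` the matrix is exactly
  symmetric, and the mapping attenuates the realised weight correlation
  below `rho` (checked, not assumed).
* **Allocations.** `Y = intercept_g + b_S·S + b_R·R + b_RG·R·code_g +`
  attribute effects `+ ε`, with Gaussian `ε` truncated at zero, since
  negative allocations are impossible. Default effect sizes are the
  published scale for such data: intercepts 2.58/2.35 points, strength
  slope 4.82, reciprocation −0.17 with a +2.64 interaction with year
  group, gender-giving −1.18.
* **Noise level.** `noise_sd` defaults to 1.2 points — the largest
  residual scatter at which truncation at zero stays a rare event (under
  5% of cells). This keeps the generating process effectively
  linear-Gaussian, so recovery tests measure the estimator rather than
  censoring artefacts. The trade-off is deliberate: real allocation data
  are zero-inflated and much noisier (observed fits explain ~26–43% of
  variance, versus ~70% here), so passing recovery tests demonstrate
  correctness of the machinery, not robustness to the zero-inflation of
  real Dictator-Game matrices. Even at this noise, truncation leaves a
  measurable ~2–3% downward slope bias, which the long-run recovery test
  quantifies.
* **Budget.** Budget enforcement (100 points per actor, points-to-self =
  budget − row total, with over-budget rows rescaled and counted) is off
  by default because the regression model does not model the constraint.

## Problem sizes and numerical choices

The shipped test suite uses networks of 8–60 actors, permutation counts of
50–2000 and replicate counts of 100–500; these sizes give Monte-Carlo
error comfortably inside every asserted tolerance while keeping the suite
quick. Type-I error of single-predictor MRQAP is checked at n = 20 actors
over 500 null replicates (nominal 0.05, accepted band 0.03–0.07); the
multigroup recovery study uses 200 replicates of a 23 + 19 study at 2000
permutations. The vertex-bootstrap SE is validated against a frozen
100 000-replicate rerun on a deterministic two-block network. All QR
decompositions come from base R; rank deficiency is an error naming the
collinear columns rather than a silent drop.

## Known limitations

* The generator's latent-threshold item model produces no zero-inflation
  and no degree heterogeneity beyond what the latent correlation induces;
  conclusions about real classrooms need the caveats above.
* Within-block outcome permutation (the default multigroup method) is
  conservative when other predictors carry strong effects; use
  `method = "dsp"` to gauge the difference.
* Truncation at zero biases generator-recovered slopes downward by a few
  percent at the default noise; analyses of heavily censored outcomes
  would need a censored-regression formulation, which is out of scope.
* The elimination procedure is purely backward; terms never re-enter.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_study(sim_config(seed = 42))
mg <- mg_mrqap(sim$groups,
               predictors = c("strength", "reciprocation",
                              "gender_giving", "gender_receiving"),
               interactions = "reciprocation",
               n_perm = 2000, seed = 11,
               hypotheses = c(strength = "+", "reciprocation:group" = "+",
                              gender_giving = "-"))
print(mg)
```

The full three-stage workflow — density comparisons, per-group MRQAP with
elimination, multigroup MRQAP with elimination — is `run_study()`; see the
README for a complete run with its printed output.
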