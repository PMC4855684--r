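# netalloc

Dyadic network regression of resource allocation in classroom social
networks.

## The problem

When each member of a classroom divides a fixed budget of points (a
modified Dictator Game) among classmates, the allocations form a valued,
directed network `Y`: cell (i, j) is what actor i gave to actor j. The
scientific questions are dyadic: do adolescents give more to peers toward
whom they report stronger social ties? Do they reward *reciprocation* —
peers who report a stronger tie back than they receive? And do these
dependencies change with age (year group)?

Dyadic observations are non-independent — row i shares a sender, column j
a receiver — so classical standard errors are invalid. `netalloc`
implements the permutation-based toolchain this kind of study needs:

* **Questionnaire scoring** into relationship-strength sociomatrices
  `S` (strength-item sum divided by the maximum possible score; link
  weights in [−0.25, 1] for the five-item schema, [−1/3, 1] for the
  six-item schema), reciprocation matrices `R = Sᵀ − S` (antisymmetric,
  zero total), and attribute giving/receiving matrices.
* **Valued-density comparison** between networks with vertex-bootstrap
  standard errors: `t = (d₁ − d₂)/√(se₁² + se₂²)` with dyad-count degrees
  of freedom `n₁(n₁−1) + n₂(n₂−1) − 2`, and all-pairs testing with
  Bonferroni correction.
* **MRQAP** — multiple regression quadratic assignment procedure — with
  double-semipartialing (DSP) inference: OLS point estimates on the
  vectorised dyads; for each focal predictor its matrix is residualised
  on the others, permuted by random actor relabellings (rows and columns
  jointly), and refit to build the null distribution of the coefficient.
* **Multigroup MRQAP** pooling classrooms with class fixed-effect
  intercepts, group-code interaction predictors (`X × code_g`), and
  permutations restricted within classes.
* **Directional backward elimination**: drop the non-significant term
  with two-tailed p closest to 1, protect main effects while their
  interaction remains, force-retain focal terms, refit p-values by full
  permutation at every step.
* **A synthetic-study generator** with tunable dyadic reciprocity and
  known ground truth, so the entire pipeline is validated end-to-end
  without any external data.

## Worked example

Simulate a two-classroom study (23 + 19 actors, year-group codes 0/1,
strength slope 4.82, reciprocation-by-year-group interaction 2.64) and fit
the pooled multigroup model:

```r
library(netalloc)
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

```
MG_MRQAP fit: 848 dyads (0 dropped), 2000 permutations
R^2 = 0.736, adjusted R^2 = 0.734, model p = 5e-04
Intercepts (reference g1):
intercept:g1 intercept:g2 
       2.559       -0.172 
                term estimate                   p
            strength    4.782  5e-04 (one-tailed)
       reciprocation   -0.309 0.2249 (two-tailed)
       gender_giving   -1.279  5e-04 (one-tailed)
    gender_receiving    0.001 0.9950 (two-tailed)
 reciprocation:group    2.538  5e-04 (one-tailed)
        intercept:g2   -0.172 1.0000 (two-tailed)
```

Reading the output: the 848 rows are the pooled ordered dyads
(23·22 + 19·18). The strength slope 4.78 and the interaction 2.54 recover
the generating values (4.82 and 2.64) within sampling error; the
permutation p of 5e-04 is the floor `1/(n_perm + 1)` at 2000 draws. The
reciprocation main effect is the slope in the code-0 classroom (truth
−0.17, n.s.), and the interaction says the code-1 classroom rewards
reciprocation more per unit of group code. Gender giving −1.28: male
senders allocate fewer points.

Density comparison between the two strength networks:

```r
compare_densities(sim$groups[[1]]$predictors$strength,
                  sim$groups[[2]]$predictors$strength,
                  n_boot = 1000, seed = 3)
```

```
Density 0.3508 vs 0.3198: t(846) = 0.578, p = 0.5636 (two-tailed)
```

The full three-stage workflow (densities → per-group MRQAP + elimination
→ multigroup MRQAP + elimination, with report TSVs and a run log) is
`run_study(sim$groups, ..., seed = 7, out_dir = "report")`.

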