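test_that("simulated strength networks respect schema bounds and reciprocity", {
  sch <- snq_schema("study1")
  # perfect reciprocity: symmetric strength, all-zero reciprocation
  net1 <- simulate_strength_network(10, sch, reciprocity_rho = 1, seed = 1)
  expect_equal(unclass(net1$S), t(unclass(net1$S)))
  expect_true(all(build_reciprocation(net1$S) == 0, na.rm = TRUE))
  # independence: small empirical reciprocity at n = 60
  net0 <- simulate_strength_network(60, sch, reciprocity_rho = 0, seed = 2)
  up <- upper.tri(net0$S)
  r_emp <- cor(unclass(net0$S)[up], t(unclass(net0$S))[up])
  expect_lt(abs(r_emp), 0.1)
  # bounds hold for every generated weight
  for (s in 1:4) {
    net <- simulate_strength_network(15, sch, 0.5, seed = 10 + s)
    expect_true(all(net$S >= -0.25 & net$S <= 1, na.rm = TRUE))
  }
  net2 <- simulate_strength_network(15, snq_schema("study2"), 0.5, seed = 3)
  expect_true(all(net2$S >= -1 / 3 & net2$S <= 1, na.rm = TRUE))
  # responses themselves stay within item ranges (scoring re-validates)
  expect_silent(score_relationship_strength(net2$responses,
                                            snq_schema("study2")))
})

test_that("positive latent correlation carries into scored weights", {
  net <- simulate_strength_network(60, snq_schema("study1"), 0.7, seed = 4)
  up <- upper.tri(net$S)
  r_emp <- cor(unclass(net$S)[up], t(unclass(net$S))[up])
  expect_gt(r_emp, 0.4)  # attenuated by discretisation but clearly positive
})

test_that("allocation generator reproduces the linear model exactly at zero noise", {
  net <- simulate_strength_network(9, snq_schema("study1"), 0.5, seed = 5)
  # intercept-only model: every cell equals the intercept
  a0 <- simulate_allocation(net$S, betas = list(intercept = 2.58),
                            noise_sd = 0, seed = 6)
  expect_true(all(abs(a0$Y - 2.58) < 1e-12, na.rm = TRUE))
  # full model, zero noise: OLS recovers the betas to machine precision
  R <- build_reciprocation(net$S)
  gg <- build_attribute_matrix(setNames(rep(c(0, 1), length.out = 9),
                                        rownames(net$S)), "giving")
  a1 <- simulate_allocation(net$S, R, attr_mats = list(gender_giving = gg),
                            betas = list(intercept = 3, strength = 4.82,
                                         reciprocation = 0.5,
                                         gender_giving = 1.1),
                            noise_sd = 0, seed = 7)
  tab <- vectorize_dyads(list(y = a1$Y, s = net$S, r = R, g = gg))
  f <- ols_dyadic(tab$y, tab[c("s", "r", "g")])
  expect_equal(unname(f$estimates), c(4.82, 0.5, 1.1), tolerance = 1e-9)
  expect_equal(f$intercept, 3, tolerance = 1e-9)
})

test_that("slope estimates are nearly unbiased under default moderate noise", {
  est <- numeric(60)
  for (r in seq_len(60)) {
    net <- simulate_strength_network(25, snq_schema("study1"), 0.5,
                                     seed = 900 + r)
    al <- simulate_allocation(net$S, betas = list(intercept = 2.58,
                                                  strength = 4.82),
                              noise_sd = 1.2, seed = 2900 + r)
    tab <- vectorize_dyads(list(y = al$Y, s = net$S))
    est[r] <- ols_dyadic(tab$y, tab["s"])$estimates["s"]
  }
  expect_lt(abs(mean(est) - 4.82) / 4.82, 0.05)
})

test_that("budget accounting conserves points and flags rescaled rows", {
  net <- simulate_strength_network(8, snq_schema("study1"), 0.5, seed = 8)
  al <- simulate_allocation(net$S, betas = list(intercept = 10,
                                                strength = 5),
                            noise_sd = 1, seed = 9, budget = 100)
  given <- rowSums(al$Y, na.rm = TRUE)
  expect_true(all(given <= 100 + 1e-9))
  expect_true(all(al$points_to_self >= 0))
  expect_equal(unname(given + al$points_to_self), rep(100, 8),
               tolerance = 1e-9)
  expect_gte(al$n_rescaled, 0)
  expect_error(simulate_allocation(net$S, betas = list(intercept = 1),
                                   noise_sd = 0, seed = 1, budget = -5),
               "budget")
})

test_that("study simulation returns coherent groups with a truth record", {
  cfg <- sim_config(seed = 11)
  sim <- simulate_study(cfg)
  expect_length(sim$groups, 2)
  sizes <- vapply(sim$groups, function(g) nrow(g$Y), integer(1))
  expect_equal(sizes, c(23L, 19L))
  expect_equal(sum(sizes * (sizes - 1L)), 848)
  # truth record round-trips the configured betas
  expect_identical(sim$truth$betas, cfg$betas)
  expect_identical(sim$truth$codes, c(0L, 1L))
  # all matrices share actor order within groups; R derived from S
  for (g in sim$groups) {
    expect_identical(rownames(g$Y), g$actors$actor_id)
    expect_equal(unclass(g$predictors$reciprocation),
                 unclass(build_reciprocation(g$predictors$strength)))
    expect_true(all(g$predictors$strength >= -0.25 &
                      g$predictors$strength <= 1, na.rm = TRUE))
  }
  # zero betas and zero noise: all-zero allocations
  cfg0 <- sim_config(betas = list(intercept = 0), noise_sd = 0, seed = 12)
  sim0 <- simulate_study(cfg0)
  expect_true(all(sim0$groups[[1]]$Y == 0, na.rm = TRUE))
  # identical seeds reproduce identical data
  simA <- simulate_study(sim_config(seed = 13))
  simB <- simulate_study(sim_config(seed = 13))
  expect_identical(unclass(simA$groups[[1]]$Y), unclass(simB$groups[[1]]$Y))
})
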