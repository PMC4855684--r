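test_that("interaction matrices scale with the group code", {
  X <- random_dyad_matrix(5, seed = 1)
  expect_true(all(build_interaction_matrix(X, 0) == 0, na.rm = TRUE))
  expect_equal(unclass(build_interaction_matrix(X, 1)), unclass(X))
  expect_equal(unclass(build_interaction_matrix(X, 2)), 2 * unclass(X))
})

test_that("single-group multigroup fit equals single-network MRQAP exactly", {
  sim <- small_study(seed = 201)
  g <- sim$groups[[1]]
  mg <- mg_mrqap(list(g), predictors = names(g$predictors), n_perm = 7,
                 seed = 1)
  sg <- mrqap(g$Y, g$predictors, n_perm = 7, seed = 1)
  expect_identical(mg$terms$estimate, sg$terms$estimate)
  expect_identical(unname(mg$intercepts[1]), sg$intercept)
  expect_identical(mg$r2_adj, sg$r2_adj)
})

test_that("pooled estimates equal lm with per-group intercept dummies", {
  sim <- small_study(seed = 202, n1 = 4L, n2 = 4L)
  gs <- sim$groups
  mg <- mg_mrqap(gs, predictors = c("strength", "reciprocation"),
                 interactions = "reciprocation", n_perm = 5, seed = 1)
  tabs <- lapply(gs, function(g) {
    t <- vectorize_dyads(c(list(y = g$Y), g$predictors[c("strength", "reciprocation")]))
    t$rg <- t$reciprocation * g$group_code
    t$grp <- g$group_id
    t
  })
  tab <- do.call(rbind, tabs)
  ref <- lm(y ~ strength + reciprocation + rg + grp, data = tab)
  tt <- mg$terms
  expect_equal(tt$estimate[tt$term == "strength"],
               unname(coef(ref)["strength"]), tolerance = 1e-10)
  expect_equal(tt$estimate[tt$term == "reciprocation:group"],
               unname(coef(ref)["rg"]), tolerance = 1e-10)
  expect_equal(unname(mg$intercepts[1]), unname(coef(ref)["(Intercept)"]),
               tolerance = 1e-10)
  expect_equal(unname(mg$intercepts["intercept:g2"]),
               unname(coef(ref)["grpg2"]), tolerance = 1e-10)
  expect_equal(mg$r2_adj, summary(ref)$adj.r.squared, tolerance = 1e-10)
})

test_that("all-zero group codes reduce to a common-slope fixed-effects model", {
  sim <- small_study(seed = 203, n1 = 4L, n2 = 4L)
  gs <- sim$groups
  gs[[2]]$group_code <- 0L
  mg <- mg_mrqap(gs, predictors = c("strength", "gender_giving"),
                 n_perm = 5, seed = 1)
  tabs <- lapply(gs, function(g) {
    t <- vectorize_dyads(c(list(y = g$Y),
                           g$predictors[c("strength", "gender_giving")]))
    t$grp <- g$group_id
    t
  })
  tab <- do.call(rbind, tabs)
  ref <- lm(y ~ strength + gender_giving + grp, data = tab)
  expect_equal(mg$terms$estimate[mg$terms$term == "strength"],
               unname(coef(ref)["strength"]), tolerance = 1e-10)
})

test_that("identical group codes make interactions collinear with main effects", {
  sim <- small_study(seed = 204)
  gs <- sim$groups
  gs[[2]]$group_code <- gs[[1]]$group_code  # miscoded groups
  expect_error(
    suppressWarnings(mg_mrqap(gs, predictors = "reciprocation",
                              interactions = "reciprocation",
                              n_perm = 5, seed = 1)),
    "collinear|constant")
})

test_that("pooled estimates are invariant to group order and within-group relabeling", {
  sim <- small_study(seed = 205)
  gs <- sim$groups
  mg1 <- mg_mrqap(gs, predictors = c("strength", "reciprocation"),
                  interactions = "reciprocation", n_perm = 5, seed = 1)
  # relabel actors within group 1
  g1 <- gs[[1]]
  set.seed(3); pi <- sample.int(nrow(g1$Y))
  g1p <- group_data(g1$group_id, g1$actors[pi, ],
                    permute_square(g1$Y, pi),
                    lapply(g1$predictors, permute_square, pi = pi),
                    g1$group_code)
  mg2 <- mg_mrqap(list(g1p, gs[[2]]), predictors = c("strength", "reciprocation"),
                  interactions = "reciprocation", n_perm = 5, seed = 1)
  expect_equal(mg2$terms$estimate, mg1$terms$estimate, tolerance = 1e-10)
  # swap group order: slopes identical (intercept reference changes)
  mg3 <- mg_mrqap(rev(gs), predictors = c("strength", "reciprocation"),
                  interactions = "reciprocation", n_perm = 5, seed = 1)
  keep <- c("strength", "reciprocation", "reciprocation:group")
  expect_equal(mg3$terms$estimate[match(keep, mg3$terms$term)],
               mg1$terms$estimate[match(keep, mg1$terms$term)],
               tolerance = 1e-10)
})

test_that("a planted group-specific reciprocation slope is recovered", {
  # slope 0 in the code-0 group, 2.64 in the code-1 group, low noise
  sim <- small_study(seed = 206, n1 = 23L, n2 = 19L, noise_sd = 0.5,
                     betas = list(reciprocation = 0, recip_x_group = 2.64))
  mg <- mg_mrqap(sim$groups,
                 predictors = c("strength", "reciprocation", "gender_giving"),
                 interactions = "reciprocation", n_perm = 2000, seed = 207,
                 hypotheses = c("reciprocation:group" = "+"))
  tt <- mg$terms
  b_int <- tt$estimate[tt$term == "reciprocation:group"]
  expect_lt(abs(b_int - 2.64) / 2.64, 0.15)
  expect_lt(tt$p_one_tailed[tt$term == "reciprocation:group"], 0.05)
})

test_that("groups smaller than three actors are rejected", {
  sim <- small_study(seed = 208)
  g <- sim$groups[[1]]
  tiny <- group_data("tiny",
                     data.frame(actor_id = c("t1", "t2")),
                     dyad_matrix(matrix(1, 2, 2), actors = c("t1", "t2")),
                     list(strength = dyad_matrix(matrix(.5, 2, 2),
                                                 actors = c("t1", "t2"))),
                     group_code = 1L)
  expect_error(mg_mrqap(list(g, tiny), predictors = "strength",
                        n_perm = 5, seed = 1), "fewer than 3")
  expect_error(mg_mrqap(sim$groups, predictors = "strength",
                        interactions = "reciprocation", n_perm = 5, seed = 1),
               "not in the model")
})

test_that("DSP-within-blocks alternative produces comparable inference", {
  sim <- small_study(seed = 209, n1 = 12L, n2 = 11L)
  mg_y <- mg_mrqap(sim$groups, predictors = c("strength", "reciprocation"),
                   n_perm = 600, seed = 210)
  mg_d <- mg_mrqap(sim$groups, predictors = c("strength", "reciprocation"),
                   n_perm = 600, seed = 210, method = "dsp")
  expect_identical(mg_y$terms$estimate, mg_d$terms$estimate)
  ps_y <- mg_y$terms$p_two_tailed[mg_y$terms$term == "strength"]
  ps_d <- mg_d$terms$p_two_tailed[mg_d$terms$term == "strength"]
  expect_lt(ps_y, 0.05)  # strong true effect detected by both
  expect_lt(ps_d, 0.05)
})
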