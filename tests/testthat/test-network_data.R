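test_that("relationship-strength scoring maps item responses to link weights", {
  sch1 <- snq_schema("study1")
  sch2 <- snq_schema("study2")
  expect_equal(sch1$divisor, 8)
  expect_equal(sch2$divisor, 9)

  # maxima -> 1, minima -> floor, zeros -> 0 (both schemas)
  cases <- list(
    list(sch = sch1, resp = strength_response("a", "b", 1, 1, 1, 4, 1),
         want = 1.0),
    list(sch = sch1, resp = strength_response("a", "b", 0, 0, 0, -1, -1),
         want = -0.25),
    list(sch = sch1, resp = strength_response("a", "b", 0, 0, 0, 0, 0),
         want = 0.0),
    list(sch = sch2,
         resp = strength_response("a", "b", 0, 0, 0, -1, -1, conflict = -1),
         want = -1 / 3),
    list(sch = sch2,
         resp = strength_response("a", "b", 1, 1, 1, 4, 1, conflict = 1),
         want = 1.0))
  for (cs in cases) {
    S <- score_relationship_strength(cs$resp, cs$sch, actors = c("a", "b"))
    expect_equal(S["a", "b"], cs$want)
    expect_true(is.na(S["b", "a"]))  # unanswered dyad is missing, not zero
  }
})

test_that("scoring validates ranges, duplicates and actor coverage", {
  sch <- snq_schema("study1")
  bad <- strength_response("a", "b", 0, 0, 0, 5, 0)
  expect_error(score_relationship_strength(bad, sch), "nature.*a -> b")
  dup <- rbind(strength_response("a", "b", 1, 0, 0, 1, 0),
               strength_response("a", "b", 0, 0, 0, 1, 0))
  expect_error(score_relationship_strength(dup, sch), "duplicate dyad")
  self <- strength_response("a", "a", 1, 0, 0, 1, 0)
  expect_error(score_relationship_strength(self, sch), "self-dyad")
  ok <- strength_response("a", "b", 1, 0, 0, 1, 0)
  expect_error(score_relationship_strength(ok, sch, actors = "a"),
               "not in `actors`")
  S <- score_relationship_strength(ok, sch, actors = c("a", "b", "c"))
  expect_equal(attr(S, "n_missing"), 5L)  # 6 off-diagonal dyads, 1 answered
})

test_that("schema constructor enforces its invariants", {
  items <- data.frame(name = c("i1", "i2"), kind = c("binary", "ordinal"),
                      min = c(0L, -1L), max = c(1L, 2L),
                      strength = c(TRUE, TRUE))
  expect_silent(item_schema(items, divisor = 3))
  expect_error(item_schema(items, divisor = 4), "divisor")
  items$min[1] <- -1L
  expect_error(item_schema(items, divisor = 3), "binary")
})

test_that("reciprocation is the transposed-minus-original strength matrix", {
  S <- dyad_matrix(matrix(c(NA, 1, 0.5, NA), 2, 2, byrow = TRUE))
  R <- build_reciprocation(S)
  expect_equal(R["a1", "a2"], -0.5)
  expect_equal(R["a2", "a1"], 0.5)
  # symmetric strength -> all-zero reciprocation
  Sym <- random_dyad_matrix(6, seed = 1)
  Sym <- dyad_matrix((unclass(Sym) + t(Sym)) / 2)
  expect_true(all(build_reciprocation(Sym) == 0, na.rm = TRUE))
})

test_that("reciprocation matrices are antisymmetric with zero total (property)", {
  for (seed in 1:6) {
    n <- c(3, 5, 11, 20, 35, 50)[seed]
    S <- random_dyad_matrix(n, seed = 100 + seed, kind = "strength")
    R <- build_reciprocation(S)
    expect_equal(unclass(R), -t(unclass(R)))
    expect_equal(sum(R, na.rm = TRUE), 0, tolerance = 1e-12)
    # reciprocation of the transpose is the negation
    expect_equal(unclass(build_reciprocation(dyad_matrix(t(S)))),
                 -unclass(R))
  }
})

test_that("attribute matrices broadcast values across rows or columns", {
  v <- c(a = 0, b = 1, c = 1)
  G <- build_attribute_matrix(v, "giving")
  Rv <- build_attribute_matrix(v, "receiving")
  expect_equal(G["b", "a"], 1)
  expect_equal(G["a", "c"], 0)
  expect_equal(unclass(Rv), t(unclass(G)), ignore_attr = TRUE)  # receiving = giving^T
  Cst <- build_attribute_matrix(c(a = 7, b = 7), "giving")
  expect_true(all(Cst == 7, na.rm = TRUE))          # degenerate constant
  expect_error(build_attribute_matrix(c(z = 1), "giving", actors = c("a", "b")),
               "unknown actor")
})

test_that("dyad vectorization yields n(n-1) rows in a fixed order", {
  S <- random_dyad_matrix(23, seed = 3)
  tab <- vectorize_dyads(list(s = S))
  expect_equal(nrow(tab), 23 * 22)
  expect_equal(tab$ego[1:22], rep("a1", 22))        # row-major ordering
  expect_equal(tab$alter[1:3], c("a2", "a3", "a4"))
  expect_equal(tab$s, S[cbind(match(tab$ego, rownames(S)),
                              match(tab$alter, rownames(S)))])
  expect_equal(nrow(vectorize_dyads(list(x = random_dyad_matrix(2, 1)))), 2)
  # pooled dyad count across two networks
  n_pool <- nrow(tab) + nrow(vectorize_dyads(list(s = random_dyad_matrix(19, 4))))
  expect_equal(n_pool, 848)
  B <- random_dyad_matrix(23, seed = 5)
  rownames(B) <- colnames(B) <- paste0("z", 1:23)
  expect_error(vectorize_dyads(list(a = S, b = B)), "actor order")
})

test_that("adjacency CSV write/read round trip is bit-exact", {
  sch <- snq_schema("study1")
  set.seed(42)
  n <- 7
  resp <- expand.grid(ego = paste0("p", 1:n), alter = paste0("p", 1:n),
                      stringsAsFactors = FALSE)
  resp <- resp[resp$ego != resp$alter, ]
  resp$time_outside <- rbinom(nrow(resp), 1, .5)
  resp$work_with <- rbinom(nrow(resp), 1, .5)
  resp$confide <- rbinom(nrow(resp), 1, .4)
  resp$nature <- sample(-1:4, nrow(resp), TRUE)
  resp$trust <- sample(-1:1, nrow(resp), TRUE)
  S <- score_relationship_strength(resp, sch)
  path <- withr::local_tempfile(fileext = ".csv")
  write_adjacency_csv(S, path)
  S2 <- read_adjacency_csv(path, kind = "strength")
  expect_identical(unclass(S2)[TRUE], unclass(S)[TRUE])
  expect_identical(rownames(S2), rownames(S))
})

test_that("actor relabeling permutes matrices cell-by-cell", {
  M <- random_dyad_matrix(3, seed = 9)
  expect_equal(permute_square(M, 1:3), M)
  pi <- c(3L, 1L, 2L)
  P <- permute_square(M, pi)
  # brute-force oracle
  expect_equal(unclass(P)[TRUE], naive_permute_square(M, pi)[TRUE])
  # explicit hand expansion of a couple of cells
  expect_equal(P[1, 2], M[3, 1])
  expect_equal(P[2, 3], M[1, 2])
  # group property: applying pi then its inverse restores M
  inv <- order(pi)
  expect_equal(permute_square(P, inv), M)
  expect_error(permute_square(M, c(1L, 1L, 2L)), "permutation")
})
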