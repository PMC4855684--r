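# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk.

# A random valued dyadic matrix with standard-normal cells.
random_dyad_matrix <- function(n, seed, kind = "generic") {
  set.seed(seed)
  dyad_matrix(matrix(rnorm(n * n), n, n), kind = kind)
}

# Minimal Study-1-style response row with named item values.
strength_response <- function(ego, alter, time_outside, work_with, confide,
                              nature, trust, conflict = NULL) {
  df <- data.frame(ego = ego, alter = alter, time_outside = time_outside,
                   work_with = work_with, confide = confide, nature = nature,
                   trust = trust, stringsAsFactors = FALSE)
  if (!is.null(conflict)) df$conflict <- conflict
  df
}

# A small two-group simulated study (sizes chosen small for speed).
small_study <- function(seed, n1 = 10L, n2 = 9L, noise_sd = 1.2,
                        betas = NULL, rho = 0.5) {
  cfg <- sim_config(groups = list(list(n = n1, code = 0L),
                                  list(n = n2, code = 1L)),
                    reciprocity_rho = rho,
                    noise_sd = noise_sd, seed = seed)
  if (!is.null(betas)) cfg$betas <- utils::modifyList(cfg$betas, betas)
  simulate_study(cfg)
}

# Naive reference: permute rows and columns of M by pi using explicit loops
# (independent of the vectorised permute_square).
naive_permute_square <- function(M, pi) {
  n <- nrow(M)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) out[i, j] <- M[pi[i], pi[j]]
  out
}

# Naive single-predictor QAP-Y p-value: permute the outcome matrix by actor
# relabelling and compare slopes (independent oracle for the DSP path).
naive_qap_y_p <- function(Y, X, n_perm, seed) {
  set.seed(seed)
  idx <- which(!diag(TRUE, nrow(Y)), arr.ind = TRUE)
  y <- Y[idx]; x <- X[idx]
  b_obs <- stats::coef(stats::lm(y ~ x))[["x"]]
  count <- 0L
  for (p in seq_len(n_perm)) {
    pi <- sample.int(nrow(Y))
    ystar <- Y[pi, pi][idx]
    bstar <- stats::coef(stats::lm(ystar ~ x))[["x"]]
    if (abs(bstar) >= abs(b_obs)) count <- count + 1L
  }
  (1 + count) / (n_perm + 1)
}
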