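#' Valued density of a sociomatrix
#'
#' The mean of the n(n-1) off-diagonal cell values — the natural extension
#' of graph density to valued directed networks.  Missing cells are excluded
#' from the mean; their count is attached as attribute `"n_missing"`.
#'
#' @param M a [dyad_matrix()] or square matrix.
#' @return The mean off-diagonal value (numeric scalar).
#' @export
valued_density <- function(M) {
  M <- as_dyad_matrix(M)
  v <- offdiag_values(M)
  n_miss <- sum(is.na(v))
  if (n_miss == length(v)) stop("all off-diagonal cells are missing")
  structure(mean(v, na.rm = TRUE), n_missing = n_miss)
}

# One vertex-bootstrap replicate: resample actors with replacement and
# rebuild the cell values.  When two sampled positions map to the SAME
# original actor (a diagonal collision), the cell is filled by a uniform
# draw from that actor's own off-diagonal row and column values, following
# the vertex-bootstrap for network-level statistics.
vertex_boot_replicate <- function(M, n) {
  idx <- sample.int(n, n, replace = TRUE)
  B <- M[idx, idx, drop = FALSE]
  coll <- which(outer(idx, idx, "==") & !diag(TRUE, n), arr.ind = TRUE)
  if (nrow(coll)) {
    for (r in seq_len(nrow(coll))) {
      i <- idx[coll[r, 1L]]
      pool <- c(M[i, -i], M[-i, i])
      pool <- pool[!is.na(pool)]
      B[coll[r, 1L], coll[r, 2L]] <-
        if (length(pool)) pool[sample.int(length(pool), 1L)] else NA_real_
    }
  }
  diag(B) <- NA_real_
  mean(B, na.rm = TRUE)
}

#' Vertex-bootstrap standard error of valued network density
#'
#' Whole-network statistics have no classical standard error because dyadic
#' observations are non-independent.  The vertex bootstrap resamples actors
#' (not dyads) with replacement; each replicate network keeps the original
#' cell for every pair of distinct originals and fills diagonal collisions
#' with a random draw from the collided actor's own tie values.  The SE is
#' the standard deviation of the replicate densities.
#'
#' @param M a [dyad_matrix()], n >= 3 actors.
#' @param n_boot number of bootstrap replicates (>= 2; default 1000).
#' @param seed integer seed; results are fully reproducible from it.
#' @param network_id optional label carried into the result.
#' @return List of class `boot_density`: `network_id`, `observed_density`,
#'   `bootstrap_se`, `n_boot`, `seed`, `replicates`.
#' @export
vertex_bootstrap <- function(M, n_boot = 1000L, seed, network_id = NULL) {
  M <- as_dyad_matrix(M)
  n <- nrow(M)
  if (n < 3L) stop("vertex bootstrap needs at least 3 actors")
  if (n_boot < 2L) stop("n_boot must be at least 2")
  if (missing(seed)) stop("`seed` is required for reproducibility")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  reps <- vapply(seq_len(n_boot), function(b) vertex_boot_replicate(M, n),
                 numeric(1L))
  structure(list(network_id = network_id %||% "network",
                 observed_density = as.numeric(valued_density(M)),
                 bootstrap_se = stats::sd(reps),
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 replicates = reps),
            class = "boot_density")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.boot_density <- function(x, ...) {
  cat(sprintf("Valued density of %s: %.4f (vertex-bootstrap SE %.4f, %d replicates)\n",
              x$network_id, x$observed_density, x$bootstrap_se, x$n_boot))
  invisible(x)
}

#' Compare valued densities of two disjoint networks
#'
#' Two-sample t statistic on mean tie value, with per-network
#' vertex-bootstrap standard errors (unpooled) and dyad-count degrees of
#' freedom: `df = n1(n1-1) + n2(n2-1) - 2`, i.e. the number of tie
#' variables across both networks minus 2.
#'
#' @param A,B [dyad_matrix()] objects over disjoint actor sets.
#' @param n_boot bootstrap replicates per network.
#' @param seed integer seed (each network gets a derived sub-seed).
#' @return List of class `density_comparison`: densities, SEs, `t`, `df`,
#'   `p_two_tailed`.
#' @export
compare_densities <- function(A, B, n_boot = 1000L, seed) {
  A <- as_dyad_matrix(A); B <- as_dyad_matrix(B)
  if (length(intersect(actors(A), actors(B)))) {
    stop("networks share actors; density comparison requires disjoint sets")
  }
  if (missing(seed)) stop("`seed` is required")
  seed <- as.integer(seed)
  ba <- vertex_bootstrap(A, n_boot, seed = seed, network_id = "A")
  bb <- vertex_bootstrap(B, n_boot, seed = seed + 1L, network_id = "B")
  nA <- nrow(A); nB <- nrow(B)
  df <- nA * (nA - 1L) + nB * (nB - 1L) - 2L
  se <- sqrt(ba$bootstrap_se^2 + bb$bootstrap_se^2)
  dd <- ba$observed_density - bb$observed_density
  if (se == 0) {
    if (dd == 0) {
      t_stat <- 0; p <- 1
    } else {
      stop("degenerate comparison: zero bootstrap variability but unequal densities")
    }
  } else {
    t_stat <- dd / se
    p <- 2 * stats::pt(-abs(t_stat), df = df)
  }
  structure(list(density_a = ba$observed_density, density_b = bb$observed_density,
                 se_a = ba$bootstrap_se, se_b = bb$bootstrap_se,
                 t = t_stat, df = df, p_two_tailed = p,
                 n_boot = as.integer(n_boot), seed = seed),
            class = "density_comparison")
}

#' @export
print.density_comparison <- function(x, ...) {
  cat(sprintf("Density %.4f vs %.4f: t(%d) = %.3f, p = %.4g (two-tailed)\n",
              x$density_a, x$density_b, x$df, x$t, x$p_two_tailed))
  invisible(x)
}

#' All pairwise density comparisons with Bonferroni correction
#'
#' Tests all C(k,2) unordered pairs of networks and adjusts the
#' significance threshold to `alpha / C(k,2)`.
#'
#' @param networks named list of [dyad_matrix()] objects (disjoint actors).
#' @param n_boot bootstrap replicates per network.
#' @param seed integer seed.
#' @param alpha family-wise significance level (default 0.05).
#' @return Data frame: one row per pair with densities, SEs, `t`, `df`,
#'   `p_two_tailed`, `alpha_adjusted`, `significant`.
#' @export
pairwise_density_tests <- function(networks, n_boot = 1000L, seed,
                                   alpha = 0.05) {
  stopifnot(is.list(networks), length(networks) >= 2L)
  ids <- names(networks)
  if (is.null(ids) || anyDuplicated(ids) || any(ids == "")) {
    stop("`networks` must be a uniquely named list")
  }
  if (missing(seed)) stop("`seed` is required")
  pairs <- utils::combn(length(networks), 2L)
  m <- ncol(pairs)
  alpha_adj <- alpha / m
  rows <- lapply(seq_len(m), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    cmp <- compare_densities(networks[[i]], networks[[j]], n_boot = n_boot,
                             seed = as.integer(seed) + 2L * (k - 1L))
    data.frame(network_a = ids[i], network_b = ids[j],
               density_a = cmp$density_a, density_b = cmp$density_b,
               se_a = cmp$se_a, se_b = cmp$se_b,
               t = cmp$t, df = cmp$df, p_two_tailed = cmp$p_two_tailed,
               alpha_adjusted = alpha_adj,
               significant = cmp$p_two_tailed < alpha_adj,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
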