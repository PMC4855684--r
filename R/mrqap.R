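#' Ordinary least squares on a dyad design table
#'
#' The point-estimation core shared by [mrqap()] and [mg_mrqap()]: plain OLS
#' of a dyad outcome vector on dyad predictor columns.  Coefficients are
#' interpretable exactly as in ordinary regression; only the inference
#' (permutation-based, in the callers) differs.  Standardized estimates are
#' the coefficients of the same regression on z-scored dyad vectors,
#' equivalently `b * sd(x) / sd(y)`.
#'
#' @param y numeric outcome vector (one entry per dyad row).
#' @param X data frame or numeric matrix of predictor columns (no
#'   intercept; one is added).
#' @return List: `intercept`, `estimates` (named), `std_estimates`, `r2`,
#'   `r2_adj`, `n` (rows used), `n_dropped` (incomplete rows removed
#'   listwise), `residuals`, `fitted`, `rows_used` (logical index).
#' @export
ols_dyadic <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  ok <- stats::complete.cases(y, X)
  n_dropped <- sum(!ok)
  y0 <- y[ok]; X0 <- X[ok, , drop = FALSE]
  D <- cbind(`(Intercept)` = 1, X0)
  qd <- qr(D)
  if (qd$rank < ncol(D)) {
    dropped <- colnames(D)[qd$pivot[(qd$rank + 1L):ncol(D)]]
    stop("design is rank deficient; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  N <- length(y0); k <- ncol(X0)
  if (N < k + 2L) stop("too few complete dyads (", N, ") for ", k, " predictors")
  coefs <- qr.coef(qd, y0)
  fitted <- drop(D %*% coefs)
  res <- y0 - fitted
  tss <- sum((y0 - mean(y0))^2)
  if (tss == 0) stop("outcome is constant; R^2 undefined")
  r2 <- 1 - sum(res^2) / tss
  r2_adj <- 1 - (1 - r2) * (N - 1) / (N - k - 1)
  sds <- apply(X0, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant predictor(s): ",
         paste(colnames(X0)[sds == 0], collapse = ", "))
  }
  list(intercept = unname(coefs[1L]),
       estimates = coefs[-1L],
       std_estimates = coefs[-1L] * sds / stats::sd(y0),
       r2 = r2, r2_adj = r2_adj,
       n = N, n_dropped = n_dropped,
       residuals = res, fitted = fitted, rows_used = ok)
}

# Normalise a directional-hypothesis spec (named "+"/"-"/+1/-1) to a named
# numeric vector of signs over `terms`, NA where nondirectional.
normalize_hypotheses <- function(hypotheses, terms) {
  out <- stats::setNames(rep(NA_real_, length(terms)), terms)
  if (is.null(hypotheses) || !length(hypotheses)) return(out)
  nm <- names(hypotheses)
  if (is.null(nm)) stop("`hypotheses` must be named by term")
  unknown <- setdiff(nm, terms)
  if (length(unknown)) stop("hypothesis for unknown term(s): ",
                            paste(unknown, collapse = ", "))
  s <- vapply(hypotheses, function(h) {
    if (is.character(h)) h <- switch(h, "+" = 1, "-" = -1,
                                     stop("hypothesis sign must be '+', '-', 1 or -1"))
    h <- as.numeric(h)
    if (!h %in% c(-1, 1)) stop("hypothesis sign must be +1 or -1")
    h
  }, numeric(1L))
  out[nm] <- s
  out
}

# Permutation-count p-values including the observed statistic:
# p = (1 + #{extreme}) / (n_perm + 1), so p in (0, 1] always.
perm_pvalue <- function(extreme_count, n_perm) {
  (1 + extreme_count) / (n_perm + 1)
}

#' Single-network MRQAP with double-semipartialing permutation inference
#'
#' Regresses a dyadic outcome matrix on dyadic predictor matrices.  Point
#' estimates are ordinary least squares on the vectorised dyads.  Inference
#' respects actor exchangeability via double semipartialing (DSP): for each
#' focal predictor, its matrix is residualised on all other predictors, the
#' residual matrix is permuted by a random actor relabelling (rows and
#' columns jointly), the outcome is regressed on the other predictors plus
#' the permuted residual, and the focal coefficient is recorded.  The
#' observed coefficient is compared against this null distribution.  The
#' model-level p-value compares the observed R^2 against R^2 under random
#' actor relabellings of the outcome matrix.
#'
#' @param Y outcome [dyad_matrix()] (e.g. point allocation).
#' @param predictors named list of [dyad_matrix()] objects sharing `Y`'s
#'   actor order.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed; mandatory, the whole fit is reproducible.
#' @param hypotheses optional named vector of hypothesised signs
#'   (`"+"`/`"-"` or ±1) for directional terms; one-tailed p-values are
#'   reported for these, two-tailed for all terms.
#' @param store_null keep the per-term permutation distributions
#'   (`$null_dist`, an `n_perm` x k matrix)?  Default `FALSE`.
#' @return An object of class `qap_fit`; see [print.qap_fit()].  `$terms`
#'   is a data frame with `term`, `estimate`, `std_estimate`,
#'   `hypothesized_sign`, `p_one_tailed`, `p_two_tailed`.
#' @references Dekker, Krackhardt & Snijders (2007) Psychometrika 72(4):
#'   563-581 (double semipartialing); Krackhardt (1988) Social Networks 10:
#'   359-381.
#' @export
mrqap <- function(Y, predictors, n_perm = 10000L, seed, hypotheses = NULL,
                  store_null = FALSE) {
  Y <- as_dyad_matrix(Y, kind = "allocation")
  stopifnot(is.list(predictors), length(predictors) >= 1L)
  terms <- names(predictors)
  if (is.null(terms) || any(terms == "")) stop("`predictors` must be named")
  if (missing(seed)) stop("`seed` is required for reproducibility")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  tab <- vectorize_dyads(c(list(.y = Y), predictors))
  y <- tab$.y
  X <- as.matrix(tab[terms])
  fit <- ols_dyadic(y, X)
  signs <- normalize_hypotheses(hypotheses, terms)

  n <- nrow(Y)
  idx <- offdiag_index(n)
  ok <- fit$rows_used
  clean <- !anyNA(y) && !anyNA(X)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  k <- length(terms)
  # Residualise each focal predictor on the others (+ intercept) and park the
  # residuals in matrix form for actor-permutation.
  E_mats <- vector("list", k)
  Q_others <- vector("list", k)
  y_res <- vector("list", k)
  for (j in seq_len(k)) {
    others <- cbind(1, X[ok, -j, drop = FALSE])
    qo <- qr(others)
    ej <- X[ok, j] - qr.fitted(qo, X[ok, j])
    ev <- rep(NA_real_, nrow(tab)); ev[ok] <- ej
    E_mats[[j]] <- offdiag_matrix(ev, n)
    Q_others[[j]] <- qr.Q(qo)
    y_res[[j]] <- y[ok] - qr.fitted(qo, y[ok])
  }
  # Full-design pieces for the model-level R^2 null.
  Q_full <- qr.Q(qr(cbind(1, X[ok, , drop = FALSE])))
  Ymat <- unclass(Y)

  null_b <- matrix(NA_real_, n_perm, k, dimnames = list(NULL, terms))
  null_r2 <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    for (j in seq_len(k)) {
      pi_j <- sample.int(n)
      e <- E_mats[[j]][pi_j, pi_j][idx]
      if (clean) {
        num <- sum(e * y_res[[j]])
        den <- sum(e^2) - sum(crossprod(Q_others[[j]], e)^2)
        null_b[p, j] <- if (den > 0) num / den else NA_real_
      } else {
        rows <- ok & !is.na(e)
        D <- cbind(1, X[rows, -j, drop = FALSE], e[rows])
        cf <- tryCatch(qr.coef(qr(D), y[rows]), error = function(err) NULL)
        null_b[p, j] <- if (is.null(cf)) NA_real_ else cf[length(cf)]
      }
    }
    pi_y <- sample.int(n)
    ystar <- Ymat[pi_y, pi_y][idx]
    if (clean) {
      ys <- ystar
      tss <- sum((ys - mean(ys))^2)
      null_r2[p] <- (sum(crossprod(Q_full, ys)^2) - length(ys) * mean(ys)^2) / tss
    } else {
      rows <- ok & !is.na(ystar)
      f2 <- tryCatch(ols_dyadic(ystar[rows], X[rows, , drop = FALSE]),
                     error = function(err) NULL)
      null_r2[p] <- if (is.null(f2)) NA_real_ else f2$r2
    }
  }

  b_obs <- fit$estimates
  p_two <- vapply(seq_len(k), function(j) {
    perm_pvalue(sum(abs(null_b[, j]) >= abs(b_obs[j]), na.rm = TRUE), n_perm)
  }, numeric(1L))
  p_one <- vapply(seq_len(k), function(j) {
    s <- signs[j]
    if (is.na(s)) return(NA_real_)
    perm_pvalue(sum(s * null_b[, j] >= s * b_obs[j], na.rm = TRUE), n_perm)
  }, numeric(1L))
  model_p <- perm_pvalue(sum(null_r2 >= fit$r2, na.rm = TRUE), n_perm)

  out <- list(
    terms = data.frame(term = terms,
                       estimate = unname(b_obs),
                       std_estimate = unname(fit$std_estimates),
                       hypothesized_sign = unname(signs),
                       p_one_tailed = p_one,
                       p_two_tailed = p_two,
                       stringsAsFactors = FALSE),
    intercept = fit$intercept,
    r2 = fit$r2, r2_adj = fit$r2_adj, model_p = model_p,
    n_dyads = fit$n, n_dropped = fit$n_dropped,
    plan = list(n_perm = as.integer(n_perm), seed = as.integer(seed),
                method = "dsp", blocks = NULL),
    engine = "mrqap")
  if (store_null) out$null_dist <- null_b
  class(out) <- "qap_fit"
  out
}

#' @export
print.qap_fit <- function(x, digits = 3L, ...) {
  cat(sprintf("%s fit: %d dyads (%d dropped), %d permutations\n",
              toupper(x$engine), x$n_dyads, x$n_dropped, x$plan$n_perm))
  cat(sprintf("R^2 = %.*f, adjusted R^2 = %.*f, model p = %s\n",
              digits, x$r2, digits, x$r2_adj, format(x$model_p, digits = 3L)))
  if (!is.null(x$intercepts)) {
    cat("Intercepts (reference ", x$reference_group, "):\n", sep = "")
    print(round(x$intercepts, digits))
  } else {
    cat(sprintf("Intercept: %.*f\n", digits, x$intercept))
  }
  tt <- x$terms
  tt$estimate <- round(tt$estimate, digits)
  if (!is.null(tt$std_estimate)) tt$std_estimate <- round(tt$std_estimate, digits)
  tt$p <- ifelse(!is.na(tt$hypothesized_sign),
                 paste0(format(round(tt$p_one_tailed, 4L)), " (one-tailed)"),
                 paste0(format(round(tt$p_two_tailed, 4L)), " (two-tailed)"))
  print(tt[c("term", "estimate",
             if (!is.null(tt$std_estimate)) "std_estimate", "p")],
        row.names = FALSE)
  invisible(x)
}

#' Tidy the term table of a QAP fit
#' @param x a `qap_fit`.
#' @return The `$terms` data frame plus model-level columns.
#' @export
qap_terms <- function(x) {
  stopifnot(inherits(x, "qap_fit"))
  cbind(x$terms, r2_adj = x$r2_adj, model_p = x$model_p,
        n_dyads = x$n_dyads)
}
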