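#' Bundle one classroom network
#'
#' A `group_data` object carries everything known about one group: the
#' actor attribute table, the allocation outcome matrix, the named
#' predictor matrices, the scalar network-level group code used for
#' interaction terms (e.g. year group 0/1, or 0/1/2), and the per-actor
#' points kept for self.
#'
#' @param group_id label.
#' @param actors data frame with at least `actor_id` (unique); typically
#'   also `gender` (0 = female, 1 = male) and attribute totals.
#' @param Y allocation [dyad_matrix()].
#' @param predictors named list of [dyad_matrix()] objects in `Y`'s actor
#'   order.
#' @param group_code integer network-level code.
#' @param points_to_self optional per-actor numeric vector.
#' @return An object of class `group_data`.
#' @export
group_data <- function(group_id, actors, Y, predictors, group_code,
                       points_to_self = NULL) {
  stopifnot(is.data.frame(actors), "actor_id" %in% names(actors))
  ids <- as.character(actors$actor_id)
  if (anyDuplicated(ids)) stop("duplicate actor_id in group ", group_id)
  Y <- as_dyad_matrix(Y, kind = "allocation")
  if (!identical(rownames(Y), ids)) {
    stop("Y actor order must match actors$actor_id in group ", group_id)
  }
  if ("gender" %in% names(actors)) {
    g <- actors$gender
    if (any(!is.na(g) & !g %in% c(0, 1))) stop("gender must be 0/1")
  }
  for (nm in names(predictors)) {
    if (!identical(rownames(predictors[[nm]]), ids)) {
      stop("predictor '", nm, "' actor order mismatch in group ", group_id)
    }
  }
  structure(list(group_id = as.character(group_id), actors = actors, Y = Y,
                 predictors = predictors,
                 group_code = as.integer(group_code),
                 points_to_self = points_to_self),
            class = "group_data")
}

#' @export
print.group_data <- function(x, ...) {
  cat(sprintf("<group_data> %s: %d actors, code %d, predictors: %s\n",
              x$group_id, nrow(x$actors), x$group_code,
              paste(names(x$predictors), collapse = ", ")))
  invisible(x)
}

#' Group-interaction predictor matrix
#'
#' Multiplies every off-diagonal cell of a dyadic predictor by the group's
#' network-level code, so that in a pooled model the interaction
#' coefficient measures how much the predictor's slope changes per unit of
#' the code (reference group: code 0).
#'
#' @param X a [dyad_matrix()].
#' @param group_code integer code of the network the matrix belongs to.
#' @return A [dyad_matrix()] of the same kind.
#' @export
build_interaction_matrix <- function(X, group_code) {
  X <- as_dyad_matrix(X)
  dyad_matrix(unclass(X) * as.numeric(group_code), actors = actors(X),
              kind = attr(X, "kind"))
}

# Stack groups into one pooled dyad table with reference-coded intercept
# dummies and interaction columns.
build_mg_design <- function(groups, predictors, interactions) {
  ids <- vapply(groups, function(g) g$group_id, character(1L))
  if (anyDuplicated(ids)) stop("duplicate group_id")
  for (g in groups) {
    if (nrow(g$Y) < 3L) stop("group ", g$group_id, " has fewer than 3 actors")
    missing_p <- setdiff(predictors, names(g$predictors))
    if (length(missing_p)) {
      stop("group ", g$group_id, " lacks predictor(s): ",
           paste(missing_p, collapse = ", "))
    }
  }
  bad_int <- setdiff(interactions, predictors)
  if (length(bad_int)) {
    stop("interaction requested for predictor(s) not in the model: ",
         paste(bad_int, collapse = ", "),
         " (main effects are auto-retained)")
  }
  pieces <- lapply(groups, function(g) {
    tab <- vectorize_dyads(c(list(.y = g$Y), g$predictors[predictors]))
    tab$.group <- g$group_id
    for (nm in interactions) {
      tab[[paste0(nm, ":group")]] <- tab[[nm]] * g$group_code
    }
    tab
  })
  pooled <- do.call(rbind, pieces)
  # reference-coded intercept dummies: first group is the reference
  if (length(groups) > 1L) {
    for (gid in ids[-1L]) {
      pooled[[paste0("intercept:", gid)]] <- as.numeric(pooled$.group == gid)
    }
  }
  list(pooled = pooled, group_ids = ids,
       dummy_cols = if (length(groups) > 1L) paste0("intercept:", ids[-1L]) else character(0L),
       term_cols = c(predictors, if (length(interactions))
         paste0(interactions, ":group") else character(0L)))
}

#' Pooled multigroup MRQAP with class fixed effects
#'
#' Fits one linear model to the dyads of several classroom networks pooled
#' together: common slopes, one freely varying intercept per class (fixed
#' effects by class, reference-coded on the first group), and optional
#' group-interaction terms built by multiplying a predictor's cells by the
#' network-level group code.  Inference is by block-restricted permutation:
#' in each draw every group's outcome matrix is independently relabelled by
#' a random actor permutation of that group only (rows and columns
#' jointly), the pooled model is refit, and each coefficient's null
#' distribution is accumulated.  This within-class permutation respects the
#' nesting of actors in classes; it tends to be conservative (standard
#' errors somewhat overestimated).  Standardized coefficients are not
#' reported for multigroup models (they are not meaningful across pooled
#' class blocks with fixed effects).
#'
#' @param groups list of [group_data()] objects (>= 1; with a single group
#'   the fit reduces exactly to single-network OLS).
#' @param predictors character vector of predictor names present in every
#'   group.
#' @param interactions character subset of `predictors` to interact with
#'   the group code.
#' @param n_perm number of permutation draws (default 10000).
#' @param seed integer seed; mandatory.
#' @param hypotheses named sign vector as in [mrqap()]; interaction terms
#'   are named `"<predictor>:group"`.
#' @param method `"y-permute"` (default; each group's outcome block
#'   permuted) or `"dsp"` (double semipartialing restricted within blocks,
#'   for sensitivity analysis).
#' @param store_null keep the permutation null distributions?
#' @return A `qap_fit` with `$intercepts` (reference-group intercept plus
#'   per-group offsets) instead of a single `$intercept`.
#' @export
mg_mrqap <- function(groups, predictors, interactions = character(0L),
                     n_perm = 10000L, seed, hypotheses = NULL,
                     method = c("y-permute", "dsp"), store_null = FALSE) {
  method <- match.arg(method)
  if (inherits(groups, "group_data")) groups <- list(groups)
  stopifnot(length(groups) >= 1L, all(vapply(groups, inherits, logical(1L),
                                             "group_data")))
  if (missing(seed)) stop("`seed` is required for reproducibility")
  des <- build_mg_design(groups, predictors, interactions)
  pooled <- des$pooled
  terms <- c(des$term_cols, des$dummy_cols)
  X <- as.matrix(pooled[terms])
  y <- pooled$.y
  fit <- ols_dyadic(y, X)
  free_terms <- des$term_cols
  signs <- normalize_hypotheses(hypotheses, free_terms)

  ok <- fit$rows_used
  clean <- !anyNA(y) && !anyNA(X)
  n_per <- vapply(groups, function(g) nrow(g$Y), integer(1L))
  row_offsets <- c(0L, cumsum(n_per * (n_per - 1L)))
  idx_list <- lapply(n_per, offdiag_index)
  Ymats <- lapply(groups, function(g) unclass(g$Y))

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  k_all <- length(terms)
  null_b <- matrix(NA_real_, n_perm, k_all, dimnames = list(NULL, terms))
  null_r2 <- numeric(n_perm)

  if (method == "y-permute") {
    if (clean) {
      D <- cbind(`(Intercept)` = 1, X)
      qd <- qr(D)
      Q <- qr.Q(qd)
      tss <- sum((y - mean(y))^2)
      Nn <- length(y)
      for (p in seq_len(n_perm)) {
        ystar <- y
        for (g in seq_along(groups)) {
          pi_g <- sample.int(n_per[g])
          block <- Ymats[[g]][pi_g, pi_g][idx_list[[g]]]
          ystar[(row_offsets[g] + 1L):row_offsets[g + 1L]] <- block
        }
        cf <- qr.coef(qd, ystar)
        null_b[p, ] <- cf[-1L]
        qty <- crossprod(Q, ystar)
        null_r2[p] <- (sum(qty^2) - Nn * mean(ystar)^2) / tss
      }
    } else {
      for (p in seq_len(n_perm)) {
        ystar <- y
        for (g in seq_along(groups)) {
          pi_g <- sample.int(n_per[g])
          block <- Ymats[[g]][pi_g, pi_g][idx_list[[g]]]
          ystar[(row_offsets[g] + 1L):row_offsets[g + 1L]] <- block
        }
        f2 <- tryCatch(ols_dyadic(ystar, X), error = function(err) NULL)
        if (!is.null(f2)) {
          null_b[p, names(f2$estimates)] <- f2$estimates
          null_r2[p] <- f2$r2
        } else null_r2[p] <- NA_real_
      }
    }
  } else {
    # DSP restricted within blocks: residualise each focal free term on the
    # others, permute the residual matrix independently within each group's
    # block, refit via the FWL shortcut.
    kf <- length(free_terms)
    E_blocks <- vector("list", kf)
    Q_others <- vector("list", kf)
    y_res <- vector("list", kf)
    for (j in seq_len(kf)) {
      jcol <- match(free_terms[j], terms)
      others <- cbind(1, X[ok, -jcol, drop = FALSE])
      qo <- qr(others)
      ej <- X[ok, jcol] - qr.fitted(qo, X[ok, jcol])
      ev <- rep(NA_real_, nrow(pooled)); ev[ok] <- ej
      E_blocks[[j]] <- lapply(seq_along(groups), function(g) {
        offdiag_matrix(ev[(row_offsets[g] + 1L):row_offsets[g + 1L]], n_per[g])
      })
      Q_others[[j]] <- qr.Q(qo)
      y_res[[j]] <- y[ok] - qr.fitted(qo, y[ok])
    }
    Q_full <- qr.Q(qr(cbind(1, X[ok, , drop = FALSE])))
    tss <- sum((y[ok] - mean(y[ok]))^2)
    for (p in seq_len(n_perm)) {
      for (j in seq_len(kf)) {
        e <- unlist(lapply(seq_along(groups), function(g) {
          pi_g <- sample.int(n_per[g])
          E_blocks[[j]][[g]][pi_g, pi_g][idx_list[[g]]]
        }), use.names = FALSE)
        if (clean) {
          num <- sum(e * y_res[[j]])
          den <- sum(e^2) - sum(crossprod(Q_others[[j]], e)^2)
          null_b[p, free_terms[j]] <- if (den > 0) num / den else NA_real_
        } else {
          rows <- ok & !is.na(e)
          jcol <- match(free_terms[j], terms)
          D <- cbind(1, X[rows, -jcol, drop = FALSE], e[rows])
          cf <- tryCatch(qr.coef(qr(D), y[rows]), error = function(err) NULL)
          null_b[p, free_terms[j]] <- if (is.null(cf)) NA_real_ else cf[length(cf)]
        }
      }
      # model-level null from within-block Y relabelling
      ystar <- y
      for (g in seq_along(groups)) {
        pi_g <- sample.int(n_per[g])
        ystar[(row_offsets[g] + 1L):row_offsets[g + 1L]] <-
          Ymats[[g]][pi_g, pi_g][idx_list[[g]]]
      }
      if (clean) {
        null_r2[p] <- (sum(crossprod(Q_full, ystar)^2) -
                         length(ystar) * mean(ystar)^2) / tss
      } else {
        rows2 <- ok & !is.na(ystar)
        f2 <- tryCatch(ols_dyadic(ystar[rows2], X[rows2, , drop = FALSE]),
                       error = function(err) NULL)
        null_r2[p] <- if (is.null(f2)) NA_real_ else f2$r2
      }
    }
  }

  b_obs <- fit$estimates
  report_terms <- c(free_terms, des$dummy_cols)
  p_two <- vapply(report_terms, function(tm) {
    perm_pvalue(sum(abs(null_b[, tm]) >= abs(b_obs[tm]), na.rm = TRUE), n_perm)
  }, numeric(1L))
  signs_all <- stats::setNames(rep(NA_real_, length(report_terms)), report_terms)
  signs_all[free_terms] <- signs
  p_one <- vapply(report_terms, function(tm) {
    s <- signs_all[tm]
    if (is.na(s)) return(NA_real_)
    perm_pvalue(sum(s * null_b[, tm] >= s * b_obs[tm], na.rm = TRUE), n_perm)
  }, numeric(1L))
  model_p <- perm_pvalue(sum(null_r2 >= fit$r2, na.rm = TRUE), n_perm)

  intercepts <- c(fit$intercept,
                  if (length(des$dummy_cols)) b_obs[des$dummy_cols])
  names(intercepts) <- c(paste0("intercept:", des$group_ids[1L]),
                         des$dummy_cols)

  out <- list(
    terms = data.frame(term = report_terms,
                       estimate = unname(b_obs[report_terms]),
                       hypothesized_sign = unname(signs_all),
                       p_one_tailed = unname(p_one),
                       p_two_tailed = unname(p_two),
                       stringsAsFactors = FALSE),
    intercepts = intercepts,
    reference_group = des$group_ids[1L],
    r2 = fit$r2, r2_adj = fit$r2_adj, model_p = model_p,
    n_dyads = fit$n, n_dropped = fit$n_dropped,
    plan = list(n_perm = as.integer(n_perm), seed = as.integer(seed),
                method = method,
                blocks = stats::setNames(as.list(n_per), des$group_ids)),
    engine = "mg_mrqap",
    group_codes = stats::setNames(vapply(groups, function(g) g$group_code,
                                         integer(1L)), des$group_ids))
  if (store_null) out$null_dist <- null_b
  class(out) <- "qap_fit"
  out
}
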