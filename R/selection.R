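#' Configuration for directional backward elimination
#'
#' @param alpha significance level (default 0.05); directional terms are
#'   tested one-tailed, all others two-tailed.
#' @param directional_terms named sign vector (`"+"`/`"-"` or ±1) of
#'   sign-hypothesised terms.
#' @param protected_pairs named character vector mapping an interaction
#'   term to the main-effect term it protects: the main effect may not be
#'   dropped while its interaction is still in the model.
#' @param forced_keep terms never dropped regardless of significance
#'   (e.g. a main effect retained to examine its group interaction).
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(alpha = 0.05, directional_terms = NULL,
                             protected_pairs = NULL,
                             forced_keep = character(0L)) {
  stopifnot(alpha > 0, alpha < 1)
  if (!is.null(protected_pairs)) {
    if (is.null(names(protected_pairs)) || any(names(protected_pairs) == "")) {
      stop("`protected_pairs` must map interaction term -> main-effect term")
    }
  }
  structure(list(alpha = alpha, directional_terms = directional_terms,
                 protected_pairs = protected_pairs,
                 forced_keep = as.character(forced_keep)),
            class = "selection_config")
}

#' Backward elimination over permutation-regression models
#'
#' Implements the directional stepwise rule: refit, then drop the
#' non-significant term whose two-tailed p-value is closest to 1, refit,
#' and repeat until every remaining droppable term is significant at
#' `alpha` under its assigned tail (one-tailed for sign-hypothesised terms,
#' two-tailed otherwise).  Two protections apply: a main effect is never
#' dropped while its interaction term is still in the model, and terms in
#' `forced_keep` (e.g. a main effect retained purely to examine its group
#' interaction) are never dropped.  The drop criterion is always the
#' two-tailed p-value, even for directional terms; the significance check
#' uses the assigned tail.  Ties in p (possible at coarse permutation
#' counts) are broken by dropping the term later in the current order.
#'
#' p-values are recomputed by a full permutation refit after every drop;
#' each step gets a fresh seed derived deterministically from `seed`.
#'
#' @param terms character vector of initial model terms.
#' @param fit_fun function `(terms, seed) -> qap_fit` refitting the model
#'   on exactly those terms.
#' @param config a [selection_config()].
#' @param seed master integer seed.
#' @return An object of class `elimination_trace`: `$steps` (data frame
#'   with `step`, `dropped_term`, `p_two_tailed`, `remaining_terms`),
#'   `$final` (the final `qap_fit`), `$final_terms`.
#' @export
backward_eliminate <- function(terms, fit_fun, config = selection_config(),
                               seed) {
  stopifnot(inherits(config, "selection_config"), is.function(fit_fun))
  if (!length(terms)) stop("empty term set")
  if (missing(seed)) stop("`seed` is required")
  seed <- as.integer(seed)
  current <- terms
  steps <- list()
  step <- 0L
  repeat {
    step_seed <- seed + step
    fit <- tryCatch(fit_fun(current, step_seed), error = function(e) {
      stop("model fit failed at step ", step, " with terms [",
           paste(current, collapse = ", "), "]: ", conditionMessage(e))
    })
    tt <- fit$terms
    tt <- tt[tt$term %in% current, , drop = FALSE]
    sig <- ifelse(!is.na(tt$hypothesized_sign),
                  tt$p_one_tailed, tt$p_two_tailed) < config$alpha
    protected_mains <- unname(config$protected_pairs[
      names(config$protected_pairs) %in% current])
    droppable <- !sig &
      !(tt$term %in% config$forced_keep) &
      !(tt$term %in% protected_mains)
    if (!any(droppable)) break
    cand <- tt[droppable, , drop = FALSE]
    # closest to 1 on the two-tailed p; ties -> later term in current order
    best_p <- max(cand$p_two_tailed)
    tied <- cand$term[cand$p_two_tailed == best_p]
    drop_term <- tied[which.max(match(tied, current))]
    steps[[length(steps) + 1L]] <- data.frame(
      step = step + 1L, dropped_term = drop_term,
      p_two_tailed = cand$p_two_tailed[cand$term == drop_term][1L],
      remaining_terms = paste(setdiff(current, drop_term), collapse = "+"),
      tie_broken = length(tied) > 1L,
      stringsAsFactors = FALSE)
    current <- setdiff(current, drop_term)
    if (!length(current)) break
    step <- step + 1L
  }
  final_fit <- if (length(current)) fit else NULL
  structure(list(steps = if (length(steps)) do.call(rbind, steps) else
                   data.frame(step = integer(0L), dropped_term = character(0L),
                              p_two_tailed = numeric(0L),
                              remaining_terms = character(0L),
                              tie_broken = logical(0L)),
                 final = final_fit, final_terms = current,
                 initial_terms = terms, seed = seed),
            class = "elimination_trace")
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat("Backward elimination:", length(x$initial_terms), "->",
      length(x$final_terms), "terms\n")
  if (nrow(x$steps)) {
    print(x$steps[c("step", "dropped_term", "p_two_tailed")], row.names = FALSE)
  } else cat("(no terms dropped)\n")
  cat("Final terms:", if (length(x$final_terms))
    paste(x$final_terms, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
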