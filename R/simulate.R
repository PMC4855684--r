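#' Simulate questionnaire responses and a strength sociomatrix
#'
#' Draws a latent affinity for every ordered dyad, with the two directions
#' of each unordered pair sampled from a bivariate standard normal with
#' correlation `reciprocity_rho` — the dial controlling how strongly i's
#' feelings about j track j's feelings about i.  Each questionnaire item
#' response is a monotone discretisation of the same latent via fixed
#' per-item category probabilities (from the schema's `latent_probs`), so
#' all items of a dyad cohere and the scored link weights inherit the
#' dyadic reciprocity.  At `rho = 1` the two directions share one latent
#' and the strength matrix is exactly symmetric.
#'
#' @param n number of actors (>= 3).
#' @param schema an [item_schema()]; see [snq_schema()].
#' @param reciprocity_rho dyadic latent correlation in \[-1, 1\].
#' @param seed integer seed.
#' @param actor_ids optional actor labels (default `a1..an`).
#' @return List: `responses` (long-format dyad data frame with one column
#'   per item), `S` (the scored strength [dyad_matrix()]), `latent` (the
#'   latent affinity matrix, for diagnostics).
#' @export
simulate_strength_network <- function(n, schema = snq_schema("study1"),
                                      reciprocity_rho = 0.5, seed,
                                      actor_ids = NULL) {
  stopifnot(inherits(schema, "item_schema"))
  if (n < 3L) stop("need at least 3 actors")
  if (abs(reciprocity_rho) > 1) stop("|reciprocity_rho| must be <= 1")
  if (missing(seed)) stop("`seed` is required")
  if (is.null(actor_ids)) actor_ids <- paste0("a", seq_len(n))
  stopifnot(length(actor_ids) == n)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  # bivariate-normal latents per unordered pair
  Z <- matrix(NA_real_, n, n)
  r <- reciprocity_rho
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      z1 <- stats::rnorm(1L)
      z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(1L)
      Z[i, j] <- z1; Z[j, i] <- z2
    }
  }

  idx <- offdiag_index(n)
  items <- schema$items
  responses <- data.frame(ego = actor_ids[idx[, 1L]],
                          alter = actor_ids[idx[, 2L]],
                          stringsAsFactors = FALSE)
  u <- stats::pnorm(Z[idx])
  for (ritem in seq_len(nrow(items))) {
    nm <- items$name[ritem]
    levels <- items$min[ritem]:items$max[ritem]
    pr <- schema$latent_probs[[nm]]
    if (is.null(pr)) pr <- rep(1 / length(levels), length(levels))
    cuts <- cumsum(pr)[-length(pr)]
    responses[[nm]] <- levels[findInterval(u, cuts) + 1L]
  }
  S <- score_relationship_strength(responses, schema, actors = actor_ids)
  Zm <- Z; dimnames(Zm) <- list(actor_ids, actor_ids)
  list(responses = responses, S = S, latent = Zm)
}

#' Simulate an allocation matrix from a linear dyadic model
#'
#' Builds the outcome as a linear combination of relationship strength,
#' reciprocation, the reciprocation-by-group-code interaction and any
#' attribute matrices, plus Gaussian noise, truncated at zero (point
#' allocations cannot be negative).  If a point `budget` is supplied,
#' points-to-self is the budget minus the row total; rows exceeding the
#' budget are rescaled to it (count recorded).
#'
#' @param S strength [dyad_matrix()].
#' @param R reciprocation [dyad_matrix()] (usually
#'   `build_reciprocation(S)`).
#' @param attr_mats named list of attribute [dyad_matrix()] objects.
#' @param betas named list/vector: `intercept`, `strength`,
#'   `reciprocation`, `recip_x_group`, plus one entry per attribute matrix
#'   name.  Missing entries default to 0.
#' @param noise_sd Gaussian noise standard deviation (>= 0), in points.
#' @param seed integer seed.
#' @param group_code network-level code entering the interaction term.
#' @param budget optional total points per actor (e.g. 100).
#' @return List: `Y` (allocation [dyad_matrix()]), `points_to_self`
#'   (per-actor, `NULL` without a budget), `n_rescaled`.
#' @export
simulate_allocation <- function(S, R = build_reciprocation(S),
                                attr_mats = list(), betas, noise_sd = 0,
                                seed, group_code = 0L, budget = NULL) {
  S <- as_dyad_matrix(S); R <- as_dyad_matrix(R)
  if (missing(seed)) stop("`seed` is required")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(budget) && budget < 0) stop("budget must be non-negative")
  b <- function(nm) if (!is.null(betas[[nm]])) as.numeric(betas[[nm]]) else 0
  lp <- b("intercept") + b("strength") * unclass(S) +
    b("reciprocation") * unclass(R) +
    b("recip_x_group") * unclass(R) * as.numeric(group_code)
  for (nm in names(attr_mats)) {
    lp <- lp + b(nm) * unclass(as_dyad_matrix(attr_mats[[nm]]))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  n <- nrow(S)
  eps <- matrix(stats::rnorm(n * n, 0, noise_sd), n, n)
  Yv <- pmax(lp + if (noise_sd > 0) eps else 0, 0)
  Y <- dyad_matrix(Yv, actors = actors(S), kind = "allocation")
  pts_self <- NULL; n_rescaled <- 0L
  if (!is.null(budget)) {
    given <- rowSums(Y, na.rm = TRUE)
    over <- given > budget
    n_rescaled <- sum(over)
    if (n_rescaled) {
      Ym <- unclass(Y)
      Ym[over, ] <- Ym[over, , drop = FALSE] * (budget / given[over])
      Y <- dyad_matrix(Ym, actors = actors(S), kind = "allocation")
      given <- rowSums(Y, na.rm = TRUE)
    }
    pts_self <- pmax(budget - given, 0)
    names(pts_self) <- actors(S)
  }
  list(Y = Y, points_to_self = pts_self, n_rescaled = n_rescaled)
}

#' Simulation configuration with known ground truth
#'
#' Defaults encode a two-classroom study shaped like the first study's
#' networks: groups of 23 and 19 actors with year-group codes 0 and 1,
#' the five-item schema, dyadic reciprocity 0.5, a reciprocation slope
#' that grows with the group code, and gender sender/receiver effects.
#' `noise_sd` defaults to 1.2 points: the largest residual scatter (about
#' half the typical per-classmate allocation) at which truncation at zero
#' stays a rare event (under 5% of cells), so the generating model remains
#' effectively linear-Gaussian and slopes are recovered essentially
#' without bias.  Larger noise makes censoring at zero a first-order
#' feature and attenuates every slope, which would defeat the purpose of a
#' known-ground-truth generator.
#'
#' @param groups list of `list(n =, code =)` per group.
#' @param schema an [item_schema()].
#' @param reciprocity_rho dyadic latent correlation.
#' @param betas named list: `intercept` (scalar or one per group),
#'   `strength`, `reciprocation`, `recip_x_group`, `gender_giving`,
#'   `gender_receiving`.
#' @param noise_sd Gaussian noise SD in points.
#' @param seed integer seed.
#' @param budget optional per-actor point budget (off by default; the
#'   regressions do not model the budget constraint).
#' @param prop_male probability an actor is male (gender 1).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(groups = list(list(n = 23L, code = 0L),
                                     list(n = 19L, code = 1L)),
                       schema = snq_schema("study1"),
                       reciprocity_rho = 0.5,
                       betas = list(intercept = c(2.58, 2.35),
                                    strength = 4.82,
                                    reciprocation = -0.17,
                                    recip_x_group = 2.64,
                                    gender_giving = -1.18,
                                    gender_receiving = 0),
                       noise_sd = 1.2, seed = 1L, budget = NULL,
                       prop_male = 0.5) {
  stopifnot(length(groups) >= 1L)
  for (g in groups) {
    if (g$n < 3L) stop("each group needs n >= 3")
  }
  if (abs(reciprocity_rho) > 1) stop("|reciprocity_rho| must be <= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  ic <- betas$intercept %||% 0
  if (!length(ic) %in% c(1L, length(groups))) {
    stop("betas$intercept must be scalar or one per group")
  }
  structure(list(groups = groups, schema = schema,
                 reciprocity_rho = reciprocity_rho, betas = betas,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 budget = budget, prop_male = prop_male),
            class = "sim_config")
}

#' Simulate a full multi-classroom study
#'
#' Generates, per group: actor attributes (gender), questionnaire responses
#' and the scored strength matrix, the derived reciprocation matrix, gender
#' giving/receiving matrices, and an allocation matrix from the configured
#' linear model (reciprocation slope in group g is
#' `reciprocation + recip_x_group * code_g`).  Actor IDs are unique across
#' groups.  The returned `truth` record echoes the full configuration so
#' tests can assert against known ground truth.
#'
#' @param config a [sim_config()].
#' @return List of class `sim_study`: `groups` (list of [group_data()]),
#'   `truth` (betas, noise_sd, rho, seed, group sizes/codes).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  codes <- vapply(config$groups, function(g) as.integer(g$code), integer(1L))
  if (anyDuplicated(codes)) {
    # duplicate codes are legitimate (e.g. two parallel Year 11 classes)
    # but interactions then cannot separate those groups; allowed silently
    # only when distinct group sizes make intent clear, else flagged.
    if (anyDuplicated(vapply(config$groups, function(g) as.integer(g$n),
                             integer(1L)))) {
      warning("duplicate group codes; interaction terms will pool those groups")
    }
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  ic <- config$betas$intercept %||% 0
  if (length(ic) == 1L) ic <- rep(ic, length(config$groups))
  groups <- vector("list", length(config$groups))
  for (gi in seq_along(config$groups)) {
    g <- config$groups[[gi]]
    g$n <- as.integer(g$n)
    gid <- paste0("g", gi)
    ids <- sprintf("%s_a%02d", gid, seq_len(g$n))
    set.seed(seed + 1000L * gi)
    gender <- stats::rbinom(g$n, 1L, config$prop_male)
    net <- simulate_strength_network(g$n, config$schema,
                                     config$reciprocity_rho,
                                     seed = seed + 1000L * gi + 1L,
                                     actor_ids = ids)
    S <- net$S
    R <- build_reciprocation(S)
    gg <- build_attribute_matrix(stats::setNames(gender, ids), "giving")
    gr <- build_attribute_matrix(stats::setNames(gender, ids), "receiving")
    betas_g <- config$betas
    betas_g$intercept <- ic[gi]
    alloc <- simulate_allocation(
      S, R, attr_mats = list(gender_giving = gg, gender_receiving = gr),
      betas = betas_g, noise_sd = config$noise_sd,
      seed = seed + 1000L * gi + 2L, group_code = g$code,
      budget = config$budget)
    groups[[gi]] <- group_data(
      group_id = gid,
      actors = data.frame(actor_id = ids, group_id = gid, gender = gender,
                          stringsAsFactors = FALSE),
      Y = alloc$Y,
      predictors = list(strength = S, reciprocation = R,
                        gender_giving = gg, gender_receiving = gr),
      group_code = g$code,
      points_to_self = alloc$points_to_self)
  }
  structure(list(groups = groups,
                 truth = list(betas = config$betas,
                              noise_sd = config$noise_sd,
                              reciprocity_rho = config$reciprocity_rho,
                              seed = seed,
                              sizes = vapply(config$groups, function(g)
                                as.integer(g$n), integer(1L)),
                              codes = codes,
                              budget = config$budget)),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("<sim_study>", length(x$groups), "groups; sizes",
      paste(x$truth$sizes, collapse = "/"), "; codes",
      paste(x$truth$codes, collapse = "/"), "\n")
  invisible(x)
}
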