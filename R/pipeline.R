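#' Run the full three-stage study workflow
#'
#' Orchestrates the analysis strategy used for the classroom allocation
#' studies: (1) pairwise vertex-bootstrap density comparisons of the
#' network variables across groups; (2) per-group MRQAP of allocation on
#' the predictors with directional backward elimination; (3) pooled
#' multigroup MRQAP with class fixed effects and group-interaction terms,
#' again with backward elimination.  Predictors enter stage 3 if they
#' differed significantly between groups in stage 1 (network variables
#' only), had an effect in any group's stage-2 final model, or are needed
#' to test a focal interaction; interactions with the group code are added
#' for all entering dyadic predictors, and a main effect under interaction
#' test is force-retained.
#'
#' @param groups list of [group_data()] objects.
#' @param predictors character vector of predictor names to consider
#'   (must exist in every group); default: all predictors of the first
#'   group.
#' @param hypotheses named sign vector of directional hypotheses (see
#'   [mrqap()]); interaction terms may be named `"<predictor>:group"`.
#' @param focal_interactions predictors whose group interaction is the
#'   scientific target; their main effects are force-retained in stage 3.
#' @param force_include predictors to enter stage 3 regardless of stages
#'   1-2 (config override for the entry gate).
#' @param n_perm permutations for the regression stages.
#' @param n_boot bootstrap replicates for stage 1.
#' @param alpha significance level.
#' @param seed master integer seed.
#' @param out_dir optional directory; when given, writes
#'   `density_tests.tsv`, `mrqap_<group>.tsv` and elimination traces,
#'   `mg_model.tsv`, `mg_trace.tsv`, `run_log.txt` and `manifest.json`.
#' @return List of class `study_report`: `density`, `per_group` (fits and
#'   traces), `mg` (fit and trace), `mg_terms_entered`, `settings`.
#' @export
run_study <- function(groups, predictors = NULL, hypotheses = NULL,
                      focal_interactions = "reciprocation",
                      force_include = character(0L),
                      n_perm = 1000L, n_boot = 1000L, alpha = 0.05,
                      seed, out_dir = NULL) {
  stopifnot(length(groups) >= 2L,
            all(vapply(groups, inherits, logical(1L), "group_data")))
  if (missing(seed)) stop("`seed` is required")
  seed <- as.integer(seed)
  if (is.null(predictors)) predictors <- names(groups[[1L]]$predictors)
  gids <- vapply(groups, function(g) g$group_id, character(1L))

  ## Stage 1: density comparisons of outcome + dyadic (network) predictors.
  ## Attribute giving/receiving matrices broadcast individual scalars, so
  ## their between-group differences are individual-level comparisons and
  ## are not gated here.
  is_network_var <- vapply(predictors, function(p) {
    !attr(groups[[1L]]$predictors[[p]], "kind") %in%
      c("attribute_giving", "attribute_receiving")
  }, logical(1L))
  net_vars <- c("allocation", predictors[is_network_var])
  density_tests <- list()
  for (v in net_vars) {
    nets <- lapply(groups, function(g) if (v == "allocation") g$Y else
      g$predictors[[v]])
    names(nets) <- gids
    density_tests[[v]] <- pairwise_density_tests(
      nets, n_boot = n_boot, seed = seed + 100L * match(v, net_vars),
      alpha = alpha)
  }
  density_tab <- do.call(rbind, Map(function(v, d) cbind(variable = v, d),
                                    names(density_tests), density_tests))
  rownames(density_tab) <- NULL

  ## Stage 2: per-group MRQAP + elimination
  per_group <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    fit_fun <- function(tms, s) {
      mrqap(g$Y, g$predictors[tms], n_perm = n_perm, seed = s,
            hypotheses = hypotheses[intersect(names(hypotheses), tms)])
    }
    cfg <- selection_config(alpha = alpha, directional_terms = hypotheses)
    tr <- backward_eliminate(predictors, fit_fun, cfg,
                             seed = seed + 10000L + 100L * gi)
    per_group[[g$group_id]] <- tr
  }

  ## Stage 3 entry rule
  sig_density <- unique(density_tab$variable[density_tab$significant &
                                               density_tab$variable != "allocation"])
  sig_pergroup <- unique(unlist(lapply(per_group, function(tr) tr$final_terms)))
  entered <- unique(c(sig_density, sig_pergroup, focal_interactions,
                      force_include))
  entered <- intersect(predictors, entered)  # keep user-specified order
  if (!length(entered)) entered <- predictors  # degenerate: nothing survived
  interactions <- entered
  int_terms <- if (length(interactions)) paste0(interactions, ":group") else
    character(0L)

  mg_fit_fun <- function(tms, s) {
    mains <- intersect(entered, tms)
    ints <- sub(":group$", "", grep(":group$", tms, value = TRUE))
    mg_mrqap(groups, predictors = mains, interactions = ints,
             n_perm = n_perm, seed = s,
             hypotheses = hypotheses[intersect(names(hypotheses), tms)])
  }
  mg_cfg <- selection_config(
    alpha = alpha, directional_terms = hypotheses,
    protected_pairs = stats::setNames(interactions, int_terms),
    forced_keep = intersect(focal_interactions, entered))
  mg_trace <- backward_eliminate(c(entered, int_terms), mg_fit_fun, mg_cfg,
                                 seed = seed + 20000L)

  report <- structure(list(
    density = density_tab, per_group = per_group, mg = mg_trace,
    mg_terms_entered = c(entered, int_terms),
    settings = list(n_perm = n_perm, n_boot = n_boot, alpha = alpha,
                    seed = seed, predictors = predictors,
                    hypotheses = hypotheses,
                    focal_interactions = focal_interactions,
                    dropped_dyads = vapply(per_group, function(tr)
                      if (!is.null(tr$final)) tr$final$n_dropped else NA_integer_,
                      integer(1L)))),
    class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

trace_tsv <- function(tr) {
  if (!is.null(tr$final)) {
    tt <- tr$final$terms
    tt$tail <- ifelse(!is.na(tt$hypothesized_sign), "one-tailed", "two-tailed")
    tt$p <- ifelse(!is.na(tt$hypothesized_sign), tt$p_one_tailed,
                   tt$p_two_tailed)
    tt
  } else data.frame(term = character(0L))
}

#' Write the TSV/JSON report bundle of [run_study()]
#' @param report a `study_report`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(report$density, file.path(out_dir, "density_tests.tsv"))
  for (gid in names(report$per_group)) {
    tr <- report$per_group[[gid]]
    write_tsv(trace_tsv(tr), file.path(out_dir, paste0("mrqap_", gid, ".tsv")))
    write_tsv(tr$steps, file.path(out_dir, paste0("trace_", gid, ".tsv")))
  }
  write_tsv(trace_tsv(report$mg), file.path(out_dir, "mg_model.tsv"))
  write_tsv(report$mg$steps, file.path(out_dir, "mg_trace.tsv"))
  st <- report$settings
  writeLines(c(
    paste0("netalloc run log — ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("package version: ", as.character(utils::packageVersion("netalloc"))),
    paste0("R version: ", R.version.string),
    paste0("seed: ", st$seed),
    paste0("n_perm: ", st$n_perm, "; n_boot: ", st$n_boot,
           "; alpha: ", st$alpha),
    paste0("predictors: ", paste(st$predictors, collapse = ", ")),
    paste0("dropped dyads per group: ",
           paste(names(st$dropped_dyads), st$dropped_dyads,
                 sep = "=", collapse = ", "))),
    file.path(out_dir, "run_log.txt"))
  manifest <- list(
    stages = c("density", "per_group_mrqap", "mg_mrqap"),
    settings = st[c("n_perm", "n_boot", "alpha", "seed")],
    mg_terms_entered = report$mg_terms_entered,
    mg_final_terms = report$mg$final_terms,
    files = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report —", length(x$per_group), "groups\n\n")
  cat("Stage 1: density comparisons (significant after Bonferroni):\n")
  sig <- x$density[x$density$significant, c("variable", "network_a",
                                            "network_b", "t", "p_two_tailed")]
  if (nrow(sig)) print(sig, row.names = FALSE) else cat("  none\n")
  cat("\nStage 2: per-group final models:\n")
  for (gid in names(x$per_group)) {
    cat(" ", gid, ":", if (length(x$per_group[[gid]]$final_terms))
      paste(x$per_group[[gid]]$final_terms, collapse = ", ") else "(empty)",
      "\n")
  }
  cat("\nStage 3: multigroup final model:\n")
  if (!is.null(x$mg$final)) print(x$mg$final) else cat("  (empty)\n")
  invisible(x)
}

#' Read a study configuration from a YAML file
#'
#' The config mirrors the arguments of [run_study()] plus the item schema:
#' top-level keys `schema` (`study1`/`study2` or an inline item list),
#' `directional_hypotheses` (map term -> `"+"`/`"-"`), `group_codes`
#' (map group -> integer), and optional `n_perm`, `n_boot`, `alpha`,
#' `seed`, `focal_interactions`.
#'
#' @param path YAML file path.
#' @return Named list with a parsed `schema` ([item_schema()]) and the
#'   remaining settings.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$schema)) {
    if (is.character(cfg$schema)) {
      cfg$schema <- snq_schema(cfg$schema)
    } else {
      items <- do.call(rbind, lapply(cfg$schema$items, function(it) {
        data.frame(name = it$name, kind = it$kind, min = it$min,
                   max = it$max, strength = isTRUE(it$strength))
      }))
      cfg$schema <- item_schema(items, divisor = cfg$schema$divisor)
    }
  }
  if (!is.null(cfg$directional_hypotheses)) {
    cfg$directional_hypotheses <- unlist(cfg$directional_hypotheses)
  }
  cfg
}
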