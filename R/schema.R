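#' Define a social-network questionnaire item schema
#'
#' An item schema describes the questionnaire items administered for every
#' (ego, alter) dyad: the admissible response range of each item, which items
#' are components of the relationship-strength score, and the normalising
#' divisor (the maximum possible summed strength score).  Link weights are
#' computed by [score_relationship_strength()] as the sum of the
#' strength-component responses divided by `divisor`, so they range from
#' (sum of strength minima)/divisor up to 1.
#'
#' @param items data frame with columns `name` (character), `kind`
#'   (`"binary"` or `"ordinal"`), `min` (integer), `max` (integer),
#'   `strength` (logical; is the item a relationship-strength component).
#' @param divisor positive number; must equal the sum of `max` over
#'   strength-component items, i.e. the highest achievable summed score.
#' @param latent_probs optional named list mapping item names to a vector of
#'   category probabilities (ordered from `min` to `max`) used by the
#'   synthetic-data generator to discretise latent affinities.  Items without
#'   an entry get uniform category probabilities.
#'
#' @return An object of class `item_schema`.
#' @seealso [snq_schema()] for the two built-in classroom-study schemas.
#' @export
item_schema <- function(items, divisor, latent_probs = NULL) {
  stopifnot(is.data.frame(items))
  needed <- c("name", "kind", "min", "max", "strength")
  if (!all(needed %in% names(items))) {
    stop("`items` must have columns: ", paste(needed, collapse = ", "))
  }
  items$name <- as.character(items$name)
  if (anyDuplicated(items$name)) stop("duplicate item names in schema")
  if (!all(items$kind %in% c("binary", "ordinal"))) {
    stop("item kind must be 'binary' or 'ordinal'")
  }
  if (any(items$min > items$max)) stop("item has min > max")
  bad_bin <- items$kind == "binary" & !(items$min == 0 & items$max == 1)
  if (any(bad_bin)) {
    stop("binary items must have range {0,1}: ", paste(items$name[bad_bin], collapse = ", "))
  }
  if (!any(items$strength)) stop("schema has no strength-component items")
  max_sum <- sum(items$max[items$strength])
  if (!isTRUE(all.equal(divisor, max_sum))) {
    stop("divisor (", divisor, ") must equal the maximum summed strength score (",
         max_sum, ")")
  }
  if (is.null(latent_probs)) latent_probs <- list()
  for (nm in names(latent_probs)) {
    if (!nm %in% items$name) stop("latent_probs for unknown item: ", nm)
    p <- latent_probs[[nm]]
    k <- items$max[items$name == nm] - items$min[items$name == nm] + 1L
    if (length(p) != k || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("latent_probs for item '", nm, "' must be ", k,
           " non-negative values summing to 1")
    }
  }
  structure(list(items = items, divisor = divisor, latent_probs = latent_probs),
            class = "item_schema")
}

#' Built-in questionnaire schemas for the two classroom studies
#'
#' `snq_schema("study1")` holds the five relationship-strength items of the
#' first study: three binary items (time spent outside school, chosen to work
#' with academically, would confide bad news), the nature-of-relationship
#' item scored -1 (negative relationship) to 4 (best friend), and relative
#' trust scored -1/0/1.  The maximum summed score is 8, so link weights lie
#' in \[-0.25, 1\].  `snq_schema("study2")` adds the conflict-resolution item
#' (-1/0/1), giving a maximum summed score of 9 and link weights in
#' \[-1/3, 1\].
#'
#' The `latent_probs` entries are the fixed category frequencies used by the
#' synthetic-data generator; they approximate a classroom in which roughly
#' half of dyads share activities and strong negative ties are rare.
#'
#' @param study `"study1"` or `"study2"`.
#' @return An [item_schema()] object.
#' @examples
#' sch <- snq_schema("study1")
#' sch$divisor  # 8
#' @export
snq_schema <- function(study = c("study1", "study2")) {
  study <- match.arg(study)
  base_items <- data.frame(
    name = c("time_outside", "work_with", "confide", "nature", "trust"),
    kind = c("binary", "binary", "binary", "ordinal", "ordinal"),
    min = c(0L, 0L, 0L, -1L, -1L),
    max = c(1L, 1L, 1L, 4L, 1L),
    strength = TRUE
  )
  probs <- list(
    time_outside = c(0.55, 0.45),
    work_with    = c(0.50, 0.50),
    confide      = c(0.65, 0.35),
    nature       = c(0.05, 0.30, 0.25, 0.20, 0.12, 0.08),
    trust        = c(0.15, 0.60, 0.25)
  )
  if (study == "study1") {
    item_schema(base_items, divisor = 8, latent_probs = probs)
  } else {
    items <- rbind(base_items, data.frame(
      name = "conflict", kind = "ordinal", min = -1L, max = 1L, strength = TRUE
    ))
    probs$conflict <- c(0.10, 0.45, 0.45)
    item_schema(items, divisor = 9, latent_probs = probs)
  }
}

#' @export
print.item_schema <- function(x, ...) {
  cat("Item schema:", nrow(x$items), "items,",
      sum(x$items$strength), "strength components, divisor", x$divisor, "\n")
  print(x$items, row.names = FALSE)
  invisible(x)
}

#' Score dyadic questionnaire responses into a relationship-strength matrix
#'
#' Sums the strength-component item responses of each ordered (ego, alter)
#' dyad and divides by the schema divisor (the highest possible summed
#' score), producing a valued directed sociomatrix: rows are out-links (how
#' strongly ego rates each alter), columns are in-links.  Dyads absent from
#' `responses` become `NA` (missing), never zero, because zero is a
#' meaningful scale point.
#'
#' @param responses long-format data frame with columns `ego`, `alter` and
#'   one column per schema item.
#' @param schema an [item_schema()].
#' @param actors optional character vector fixing the actor order; defaults
#'   to order of first appearance in `ego` then `alter`.
#' @return A [dyad_matrix()] of kind `"strength"`.  The attribute
#'   `"n_missing"` records how many off-diagonal dyads had no response row.
#' @examples
#' sch <- snq_schema("study1")
#' resp <- data.frame(ego = "a", alter = "b", time_outside = 1, work_with = 1,
#'                    confide = 1, nature = 4, trust = 1)
#' score_relationship_strength(resp, sch, actors = c("a", "b"))  # weight 1
#' @export
score_relationship_strength <- function(responses, schema, actors = NULL) {
  stopifnot(inherits(schema, "item_schema"), is.data.frame(responses))
  if (!all(c("ego", "alter") %in% names(responses))) {
    stop("`responses` needs `ego` and `alter` columns")
  }
  items <- schema$items
  miss_items <- setdiff(items$name, names(responses))
  if (length(miss_items)) {
    stop("response table lacks item column(s): ", paste(miss_items, collapse = ", "))
  }
  ego <- as.character(responses$ego)
  alter <- as.character(responses$alter)
  if (any(ego == alter)) stop("self-dyads (ego == alter) are not allowed")
  key <- paste(ego, alter, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate dyad in responses: ", gsub("\r", " -> ", d))
  }
  # range validation, naming the offending item and dyad
  for (r in seq_len(nrow(items))) {
    v <- responses[[items$name[r]]]
    bad <- which(!is.na(v) & (v < items$min[r] | v > items$max[r]))
    if (length(bad)) {
      stop("response out of range for item '", items$name[r], "' on dyad ",
           ego[bad[1L]], " -> ", alter[bad[1L]], " (value ", v[bad[1L]],
           ", range [", items$min[r], ", ", items$max[r], "])")
    }
  }
  if (is.null(actors)) {
    actors <- unique(c(ego, alter))
  } else {
    actors <- as.character(actors)
    unknown <- setdiff(unique(c(ego, alter)), actors)
    if (length(unknown)) stop("actors in responses but not in `actors`: ",
                              paste(unknown, collapse = ", "))
  }
  strength_items <- items$name[items$strength]
  sums <- rowSums(as.matrix(responses[strength_items]))
  M <- matrix(NA_real_, length(actors), length(actors),
              dimnames = list(actors, actors))
  M[cbind(match(ego, actors), match(alter, actors))] <- sums / schema$divisor
  out <- dyad_matrix(M, kind = "strength")
  attr(out, "n_missing") <- sum(is.na(out)) - length(actors)
  out
}
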