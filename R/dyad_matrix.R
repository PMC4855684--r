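#' Valued dyadic (actor-by-actor) matrix
#'
#' The universal currency of the pipeline: a square numeric matrix over an
#' ordered set of actors, with the diagonal structurally masked (`NA`) —
#' self-ties are undefined and self-allocation is carried separately as
#' points-to-self.  Row i holds what actor i sends/reports toward each
#' column actor j (out-links); column j holds what j receives (in-links).
#'
#' @param values square numeric matrix; row/column names, if present, must
#'   agree and give the actor labels.
#' @param actors optional character vector of actor labels (overrides
#'   dimnames); defaults to existing dimnames or `a1..an`.
#' @param kind one of `"strength"`, `"reciprocation"`, `"allocation"`,
#'   `"attribute_giving"`, `"attribute_receiving"`, `"duration"`,
#'   `"generic"`.
#' @return A matrix of class `dyad_matrix` with `NA` diagonal and a `kind`
#'   attribute.
#' @export
dyad_matrix <- function(values, actors = NULL,
                        kind = c("generic", "strength", "reciprocation",
                                 "allocation", "attribute_giving",
                                 "attribute_receiving", "duration")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("dyad_matrix must be square; got ", nrow(values), " x ", ncol(values))
  }
  n <- nrow(values)
  if (n < 2L) stop("dyad_matrix needs at least 2 actors")
  if (is.null(actors)) {
    actors <- rownames(values)
    if (is.null(actors)) actors <- paste0("a", seq_len(n))
  }
  actors <- as.character(actors)
  if (length(actors) != n) stop("length(actors) != nrow(values)")
  if (anyDuplicated(actors)) stop("duplicate actor labels")
  storage.mode(values) <- "double"
  dimnames(values) <- list(actors, actors)
  diag(values) <- NA_real_
  structure(values, kind = kind, class = c("dyad_matrix", "matrix", "array"))
}

#' @export
print.dyad_matrix <- function(x, ...) {
  cat("<dyad_matrix> kind:", attr(x, "kind"), "-", nrow(x), "actors\n")
  y <- x
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  print(y, ...)
  invisible(x)
}

#' @rdname dyad_matrix
#' @param x object to test.
#' @export
is_dyad_matrix <- function(x) inherits(x, "dyad_matrix")

as_dyad_matrix <- function(x, kind = "generic") {
  if (is_dyad_matrix(x)) x else dyad_matrix(x, kind = kind)
}

#' Actors of a dyadic matrix
#' @param m a [dyad_matrix()].
#' @return Character vector of actor labels in matrix order.
#' @export
actors <- function(m) rownames(m)

# Row-major off-diagonal index pairs: (1,2),(1,3),...,(2,1),(2,3),...
# The fixed dyad ordering used everywhere a matrix is vectorised.
offdiag_index <- function(n) {
  i <- rep(seq_len(n), each = n - 1L)
  j <- unlist(lapply(seq_len(n), function(k) seq_len(n)[-k]), use.names = FALSE)
  cbind(i, j)
}

# Vectorise the off-diagonal cells of a square matrix in the fixed ordering.
offdiag_values <- function(m) {
  m[offdiag_index(nrow(m))]
}

# Inverse of offdiag_values: scatter a dyad vector back into a square matrix.
offdiag_matrix <- function(v, n, actors = NULL) {
  M <- matrix(NA_real_, n, n)
  M[offdiag_index(n)] <- v
  if (!is.null(actors)) dimnames(M) <- list(actors, actors)
  M
}

#' Reciprocation matrix of a strength sociomatrix
#'
#' `R = t(S) - S`: cell (i,j) is the alter's reported strength toward ego
#' minus ego's reported strength toward the alter.  Positive values mark
#' relationships where the in-link exceeds the out-link; the matrix is
#' antisymmetric, so its off-diagonal cells always sum to zero.
#'
#' @param S a square [dyad_matrix()] (typically kind `"strength"`).
#' @return A [dyad_matrix()] of kind `"reciprocation"`.
#' @examples
#' S <- dyad_matrix(matrix(c(NA, 1, 0.5, NA), 2, 2, byrow = TRUE))
#' build_reciprocation(S)
#' @export
build_reciprocation <- function(S) {
  S <- as_dyad_matrix(S)
  dyad_matrix(t(S) - unclass(S), actors = actors(S), kind = "reciprocation")
}

#' Broadcast an actor attribute across matrix rows or columns
#'
#' A "giving" matrix repeats each actor's value along their row (sender
#' effect: every dyad they rate/allocate to carries their own attribute);
#' a "receiving" matrix repeats it down their column (receiver effect).
#' Gender giving/receiving matrices, Mach giving/receiving, etc. are all
#' built this way.
#'
#' @param values named numeric vector, one value per actor (`NA` allowed and
#'   propagated), or an unnamed vector matching `actors` in order.
#' @param mode `"giving"` (rows) or `"receiving"` (columns).
#' @param actors actor labels defining matrix order; defaults to
#'   `names(values)`.
#' @return A [dyad_matrix()] of the corresponding attribute kind.
#' @export
build_attribute_matrix <- function(values, mode = c("giving", "receiving"),
                                   actors = NULL) {
  mode <- match.arg(mode)
  if (is.null(actors)) {
    actors <- names(values)
    if (is.null(actors)) stop("`values` must be named or `actors` supplied")
  } else if (!is.null(names(values))) {
    unknown <- setdiff(names(values), actors)
    if (length(unknown)) stop("unknown actor label(s): ",
                              paste(unknown, collapse = ", "))
    values <- values[match(actors, names(values))]
  }
  if (length(values) != length(actors)) stop("one value per actor required")
  n <- length(actors)
  M <- if (mode == "giving") {
    matrix(rep(as.numeric(values), each = n), n, n, byrow = TRUE)
  } else {
    matrix(rep(as.numeric(values), each = n), n, n)
  }
  dyad_matrix(M, actors = actors,
              kind = paste0("attribute_", mode))
}

#' Vectorise a set of dyadic matrices into a dyad design table
#'
#' One row per ordered off-diagonal dyad in a fixed row-major order (ego 1
#' vs all alters, then ego 2, ...), so an n-actor network contributes
#' n(n-1) rows.  Dyadic observations are non-independent, which is why all
#' inference downstream is by actor permutation; this table is only the
#' least-squares plumbing.
#'
#' @param matrices named list of [dyad_matrix()] objects sharing one actor
#'   order.
#' @return Data frame with columns `ego`, `alter`, then one numeric column
#'   per matrix.  Rows with any `NA` are retained here (flagged by
#'   `complete.cases`); model fitters drop them listwise and report counts.
#' @examples
#' S <- dyad_matrix(matrix(1, 3, 3))
#' nrow(vectorize_dyads(list(s = S)))  # 6
#' @export
vectorize_dyads <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  if (is.null(names(matrices)) || any(names(matrices) == "")) {
    stop("`matrices` must be a fully named list")
  }
  acts <- actors(as_dyad_matrix(matrices[[1L]]))
  for (nm in names(matrices)) {
    m <- matrices[[nm]]
    if (nrow(m) != length(acts) || !identical(rownames(m), acts)) {
      stop("matrix '", nm, "' has a different actor order")
    }
  }
  n <- length(acts)
  idx <- offdiag_index(n)
  out <- data.frame(ego = acts[idx[, 1L]], alter = acts[idx[, 2L]],
                    stringsAsFactors = FALSE)
  for (nm in names(matrices)) out[[nm]] <- matrices[[nm]][idx]
  out
}

#' Relabel a dyadic matrix by an actor permutation
#'
#' Applies one permutation jointly to rows and columns:
#' `M'(i,j) = M(pi(i), pi(j))`.  This is the elementary move of quadratic
#' assignment inference — it preserves the dyadic dependence structure while
#' breaking any alignment with other matrices.
#'
#' @param M a square matrix or [dyad_matrix()].
#' @param pi integer vector, a permutation of `1:nrow(M)`.
#' @return Matrix of the same class with rows and columns jointly permuted
#'   (actor labels follow the cells).
#' @export
permute_square <- function(M, pi) {
  n <- nrow(M)
  pi <- as.integer(pi)
  if (length(pi) != n || anyNA(pi) || !identical(sort(pi), seq_len(n))) {
    stop("`pi` must be a permutation of 1:", n)
  }
  out <- M[pi, pi, drop = FALSE]
  if (is_dyad_matrix(M)) {
    out <- structure(out, kind = attr(M, "kind"),
                     class = class(M))
  }
  out
}

#' Read / write an adjacency-matrix CSV
#'
#' The exchange format is a square CSV whose first row and first column
#' carry actor IDs and whose diagonal cells are empty.  Values are written
#' with full (17 significant digit) precision so a write/read round trip
#' reproduces them bit-exactly.
#'
#' @param path file path.
#' @param kind the [dyad_matrix()] kind tag to attach on read.
#' @return `read_adjacency_csv()` returns a [dyad_matrix()];
#'   `write_adjacency_csv()` returns `path` invisibly.
#' @export
read_adjacency_csv <- function(path, kind = "generic") {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  M <- as.matrix(df)
  if (!identical(rownames(M), colnames(M))) {
    stop("adjacency CSV row and column actor IDs disagree: ", path)
  }
  dyad_matrix(M, kind = kind)
}

#' @rdname read_adjacency_csv
#' @param M a [dyad_matrix()] (or square matrix) to write.
#' @export
write_adjacency_csv <- function(M, path) {
  M <- as_dyad_matrix(M)
  fmt <- ifelse(is.na(M), "", sprintf("%.17g", M))
  dimnames(fmt) <- dimnames(M)
  lines <- c(paste(c("", colnames(M)), collapse = ","),
             paste(rownames(M), apply(fmt, 1L, paste, collapse = ","),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}
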