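#' Generate a set of sparse binary patterns
#'
#' Draws `P` mutually independent binary patterns of length `N`, each with
#' exactly `n_on` ON bits sampled uniformly without replacement.  Patterns are
#' stored sparsely as sorted ON-index vectors (1-based).  At the default
#' cerebellar granule-layer sparsity of 0.7% the expected pairwise overlap
#' between two patterns is `n_on^2 / N` bits.
#'
#' @param N pattern length (number of synapses / parallel fibres).
#' @param n_on number of ON bits per pattern; `0 < n_on <= N`.
#' @param P number of patterns.
#' @param seed integer seed; the draw is reproducible under it.  `NULL` uses
#'   the current RNG state.
#' @return an object of class `pattern_set`: a list with elements `on`
#'   (list of `P` sorted integer vectors), `N`, `n_on` and `seed`.
#' @examples
#' ps <- generate_pattern_set(N = 1000, n_on = 7, P = 5, seed = 1)
#' lengths(ps$on)
#' @export
generate_pattern_set <- function(N, n_on, P, seed = NULL) {
  if (length(N) != 1L || !is.finite(N) || N < 1)
    stop("'N' must be a positive integer")
  if (length(n_on) != 1L || !is.finite(n_on) || n_on <= 0 || n_on > N)
    stop("'n_on' must satisfy 0 < n_on <= N")
  if (length(P) != 1L || !is.finite(P) || P < 1)
    stop("'P' must be >= 1")
  N <- as.integer(N); n_on <- as.integer(n_on); P <- as.integer(P)
  if (!is.null(seed)) set.seed(seed)
  on <- vector("list", P)
  for (j in seq_len(P))
    on[[j]] <- sort.int(sample.int(N, n_on))
  structure(list(on = on, N = N, n_on = n_on, seed = seed),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("pattern_set: %d patterns of %d bits, %d ON (%.2f%% sparsity)\n",
              length(x$on), x$N, x$n_on, 100 * x$n_on / x$N))
  invisible(x)
}

#' @export
length.pattern_set <- function(x) length(x$on)

#' Subset a pattern set
#'
#' @param x a `pattern_set`.
#' @param i pattern indices.
#' @param ... unused.
#' @return a `pattern_set` holding the selected patterns.
#' @export
`[.pattern_set` <- function(x, i, ...) {
  structure(list(on = x$on[i], N = x$N, n_on = x$n_on, seed = x$seed),
            class = "pattern_set")
}

#' Dense 0/1 matrix view of a pattern set
#'
#' Utility for small problems and oracle tests; the package otherwise works
#' on the sparse ON-index representation throughout.
#'
#' @param x a `pattern_set`.
#' @param ... unused.
#' @return a `P x N` integer matrix of 0s and 1s.
#' @export
as.matrix.pattern_set <- function(x, ...) {
  m <- matrix(0L, nrow = length(x$on), ncol = x$N)
  for (j in seq_along(x$on)) m[j, x$on[[j]]] <- 1L
  m
}

#' Build a pattern set from explicit ON-index lists
#'
#' @param on list of integer vectors of ON indices (1-based).
#' @param N pattern length.
#' @return a `pattern_set`.
#' @export
pattern_set <- function(on, N) {
  stopifnot(is.list(on), length(on) >= 1)
  on <- lapply(on, function(v) sort.int(as.integer(v)))
  n_on <- unique(lengths(on))
  for (v in on) {
    if (anyDuplicated(v)) stop("duplicated ON index within a pattern")
    if (length(v) && (min(v) < 1L || max(v) > N)) stop("ON index out of range")
  }
  structure(list(on = on, N = as.integer(N),
                 n_on = if (length(n_on) == 1L) n_on else NA_integer_,
                 seed = NULL),
            class = "pattern_set")
}

#' Write / read pattern sets as JSON
#'
#' Patterns are serialized as a list of per-pattern ON-index vectors plus the
#' pattern length, so files stay small at the sparsities studied here.
#'
#' @param x a `pattern_set`.
#' @param path file path.
#' @return `write_pattern_set` returns `path` invisibly; `read_pattern_set`
#'   returns a `pattern_set`.
#' @export
write_pattern_set <- function(x, path) {
  stopifnot(inherits(x, "pattern_set"))
  jsonlite::write_json(list(N = x$N, on = x$on), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pattern_set
#' @export
read_pattern_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  on <- obj$on
  if (is.matrix(on)) on <- split(on, row(on))   # equal-length case
  pattern_set(unname(lapply(on, as.integer)), N = as.integer(obj$N))
}
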