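# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring RNG state after
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a user-supplied seed gives bit-identical results
#' without clobbering the caller's RNG stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# stopifnot with a formatted message
abort_if <- function(cond, fmt, ...) {
  if (isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

# Symmetric matrix check used by invariants/tests
is_symmetric_zero_diag <- function(m, tol = 1e-12) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) <= tol && max(abs(diag(m))) <= tol
}

# Upper-triangle (i < j, row-major) vectorization shared by edge naming,
# similarity coefficients and edge tables.
upper_pairs <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

upper_vec <- function(m) {
  p <- upper_pairs(nrow(m))
  m[p]
}

#' Canonical edge names: "g005-w012", lower node first by (tissue, index)
#' @keywords internal
#' @noRd
edge_names <- function(node_ids, pairs) {
  paste(node_ids[pairs[, 1L]], node_ids[pairs[, 2L]], sep = "-")
}
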