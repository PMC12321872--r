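# Static FC and tapered sliding-window dynamic FC with the Fisher-z
# variability statistic.

#' Node time-series container
#'
#' Wraps one subject's nodes-by-timepoints BOLD matrix together with its
#' repetition time (TR) and node labels.
#'
#' @param data numeric matrix, nodes x timepoints, no missing values.
#' @param tr_seconds repetition time in seconds (sampling interval).
#' @param node_ids character vector of node labels, one per row; defaults to
#'   rownames(data) or `n001..`.
#' @param subject_id subject identifier.
#' @return An object of class `node_ts`.
#' @export
node_ts <- function(data, tr_seconds, node_ids = NULL, subject_id = "s1") {
  abort_if(!is.matrix(data) || !is.numeric(data), "data must be a numeric matrix")
  abort_if(anyNA(data) || any(!is.finite(data)), "time series contains missing/non-finite values")
  abort_if(nrow(data) < 2L, "need at least 2 nodes, got %d", nrow(data))
  abort_if(!is.numeric(tr_seconds) || tr_seconds <= 0, "tr_seconds must be positive")
  if (is.null(node_ids)) {
    node_ids <- rownames(data)
    if (is.null(node_ids)) node_ids <- sprintf("n%03d", seq_len(nrow(data)))
  }
  abort_if(length(node_ids) != nrow(data), "node_ids length %d != %d nodes",
           length(node_ids), nrow(data))
  rownames(data) <- node_ids
  structure(list(subject_id = subject_id, data = data,
                 tr_seconds = tr_seconds, node_ids = node_ids),
            class = "node_ts")
}

#' @export
print.node_ts <- function(x, ...) {
  cat(sprintf("<node_ts> subject %s: %d nodes x %d timepoints, TR = %gs\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' Sliding-window specification with taper
#'
#' Window lengths are counted in TRs.  Taper weights are strictly positive and
#' normalized to sum to one; `rectangular` reproduces the plain unweighted
#' Pearson correlation on each segment.
#'
#' @param shape one of "hamming", "gaussian", "rectangular".
#' @param length_tr window length in TRs (>= 2); 20, 30 and 50 are typical.
#' @param step_tr step between window starts in TRs (default 1; consecutive
#'   windows then overlap by (L-1)/L, i.e. 98% for L = 50).
#' @param gaussian_sigma_tr Gaussian taper sigma in TRs; default `length_tr/6`
#'   so +-3 sigma spans the window.
#' @return An object of class `window_spec` with a `weights` field.
#' @export
window_spec <- function(shape = c("hamming", "gaussian", "rectangular"),
                        length_tr, step_tr = 1L, gaussian_sigma_tr = NULL) {
  shape <- match.arg(shape)
  abort_if(!is_count(length_tr, 2L), "length_tr must be an integer >= 2")
  abort_if(!is_count(step_tr, 1L), "step_tr must be an integer >= 1")
  L <- as.integer(length_tr)
  w <- switch(shape,
    rectangular = rep(1, L),
    hamming = 0.54 - 0.46 * cos(2 * pi * (seq_len(L) - 1L) / (L - 1L)),
    gaussian = {
      if (is.null(gaussian_sigma_tr)) gaussian_sigma_tr <- L / 6
      abort_if(gaussian_sigma_tr <= 0, "gaussian_sigma_tr must be positive")
      k <- (seq_len(L) - 1L) - (L - 1L) / 2
      exp(-0.5 * (k / gaussian_sigma_tr)^2)
    })
  stopifnot(all(w > 0))
  structure(list(shape = shape, length_tr = L, step_tr = as.integer(step_tr),
                 gaussian_sigma_tr = if (shape == "gaussian") gaussian_sigma_tr else NULL,
                 weights = w / sum(w)),
            class = "window_spec")
}

#' Parse compact window codes like "ham20", "gau30", "rect50"
#' @param code character vector of codes; prefix ham/gau/rect + length in TRs.
#' @param step_tr window step in TRs.
#' @return A named list of `window_spec` objects.
#' @export
parse_window_code <- function(code, step_tr = 1L) {
  out <- lapply(code, function(cd) {
    m <- regmatches(cd, regexec("^(ham|gau|rect)([0-9]+)$", cd))[[1L]]
    abort_if(length(m) == 0L, "unrecognized window code '%s'", cd)
    shape <- c(ham = "hamming", gau = "gaussian", rect = "rectangular")[[m[2L]]]
    window_spec(shape, as.integer(m[3L]), step_tr = step_tr)
  })
  names(out) <- code
  out
}

#' Sliding-window index ranges
#'
#' @param T_len number of timepoints.
#' @param spec a [window_spec()].
#' @return data.frame with 1-based inclusive `start`/`end` columns and an
#'   `overlap` attribute giving the consecutive-window fractional overlap
#'   (L - step)/L.
#' @export
sliding_windows <- function(T_len, spec) {
  L <- spec$length_tr; s <- spec$step_tr
  abort_if(T_len < L, "series length %d shorter than window length %d", T_len, L)
  starts <- seq.int(1L, T_len - L + 1L, by = s)
  out <- data.frame(start = starts, end = starts + L - 1L)
  attr(out, "overlap") <- (L - s) / L
  out
}

#' Pearson correlation, optionally taper-weighted
#'
#' Unweighted case is the textbook formula
#' r = sum((x-xbar)(y-ybar)) / sqrt(sum((x-xbar)^2) sum((y-ybar)^2)).
#' With taper weights w (normalized to sum 1) the means and (co)variances are
#' weighted; uniform weights reduce exactly to the unweighted case.
#' Zero-variance input yields r = 0 with a `zero_variance` attribute rather
#' than NaN.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param weights optional nonnegative taper weights (internally normalized).
#' @return correlation in [-1, 1].
#' @export
pearson_r <- function(x, y, weights = NULL) {
  n <- length(x)
  abort_if(length(y) != n, "x and y lengths differ (%d vs %d)", n, length(y))
  abort_if(n < 3L, "need at least 3 samples, got %d", n)
  if (is.null(weights)) weights <- rep(1 / n, n)
  else {
    abort_if(length(weights) != n, "weights length %d != %d", length(weights), n)
    abort_if(any(weights < 0) || sum(weights) <= 0, "weights must be nonnegative, not all zero")
    weights <- weights / sum(weights)
  }
  mx <- sum(weights * x); my <- sum(weights * y)
  dx <- x - mx; dy <- y - my
  vx <- sum(weights * dx * dx); vy <- sum(weights * dy * dy)
  if (vx <= 0 || vy <= 0) {
    warning("zero-variance input; r defined as 0", call. = FALSE)
    return(structure(0, zero_variance = TRUE))
  }
  r <- sum(weights * dx * dy) / sqrt(vx * vy)
  min(1, max(-1, r))
}

#' Fisher r-to-z transform
#'
#' z = (1/2) ln((1+r)/(1-r)); r is clipped to +-(1 - clip_eps) first so the
#' result is always finite.  Strictly increasing and odd.
#'
#' @param r correlation(s), |r| <= 1.
#' @param clip_eps clipping margin (default 1e-7).
#' @return z score(s), same shape as `r`.
#' @export
fisher_z <- function(r, clip_eps = 1e-7) {
  abort_if(any(abs(r) > 1 + 1e-12, na.rm = TRUE), "|r| > 1 supplied")
  lim <- 1 - clip_eps
  atanh(pmin(pmax(r, -lim), lim))
}

# Weighted correlation matrix of a nodes x L block.  Zero-variance rows give
# r = 0 off-diagonal (flagged via attribute).
weighted_corr_matrix <- function(X, w) {
  w <- w / sum(w)
  m <- as.vector(X %*% w)
  Xc <- X - m
  Xs <- Xc * rep(sqrt(w), each = nrow(X))
  S <- tcrossprod(Xs)
  d <- sqrt(diag(S))
  bad <- d <= 0
  d[bad] <- 1
  R <- S / tcrossprod(d)
  if (any(bad)) {
    R[bad, ] <- 0; R[, bad] <- 0
  }
  diag(R) <- 1
  R[R > 1] <- 1; R[R < -1] <- -1
  attr(R, "zero_variance_nodes") <- which(bad)
  R
}

#' Static functional connectivity matrix (Fisher z)
#'
#' Whole-scan Pearson correlation between all node pairs (gray-gray,
#' white-white, gray-white), Fisher z-transformed.  With the default atlas of
#' 200 gray + 128 white nodes the result is the combined 328 x 328 matrix.
#'
#' @param ts a [node_ts()].
#' @return An `fc_matrix`: symmetric z matrix with a zero diagonal.
#' @export
static_fc <- function(ts) {
  stopifnot(inherits(ts, "node_ts"))
  R <- weighted_corr_matrix(ts$data, rep(1, ncol(ts$data)))
  zv <- attr(R, "zero_variance_nodes")
  if (length(zv)) warning(sprintf("%d zero-variance node(s): %s", length(zv),
                                  paste(ts$node_ids[zv], collapse = ", ")), call. = FALSE)
  Z <- fisher_z(R)
  diag(Z) <- 0
  dimnames(Z) <- list(ts$node_ids, ts$node_ids)
  structure(list(values = Z, node_ids = ts$node_ids, zero_variance_nodes = zv),
            class = "fc_matrix")
}

#' Dynamic FC variability (SD of Fisher z across sliding windows)
#'
#' For every node pair, the taper-weighted Pearson correlation is computed in
#' each sliding window, Fisher z-transformed, and summarized by the standard
#' deviation across windows ("dynamic variability").  A rectangular spec
#' reproduces plain per-segment Pearson exactly.
#'
#' @param ts a [node_ts()].
#' @param spec a [window_spec()].
#' @param sd_divisor "n" (population SD over windows, default) or "n-1".
#' @param keep_stack if TRUE, the full per-window z stack (n_windows x n_pairs
#'   upper-triangle matrix) is returned for downstream dynamic graph metrics.
#' @return A `dfc_variability` object: `values` (symmetric SD matrix, zero
#'   diagonal), `mean_z` (mean z matrix), `n_windows`, `window`, and
#'   optionally `z_stack` + `pairs`.
#' @export
dynamic_fc <- function(ts, spec, sd_divisor = c("n", "n-1"), keep_stack = FALSE) {
  stopifnot(inherits(ts, "node_ts"), inherits(spec, "window_spec"))
  sd_divisor <- match.arg(sd_divisor)
  Tn <- ncol(ts$data)
  win <- sliding_windows(Tn, spec)
  W <- nrow(win)
  abort_if(W < 2L, "only %d window(s); SD across windows undefined", W)
  p <- nrow(ts$data)
  pr <- upper_pairs(p)
  s1 <- matrix(0, p, p); s2 <- matrix(0, p, p)
  stack <- if (keep_stack) matrix(NA_real_, W, nrow(pr)) else NULL
  zero_var <- FALSE
  for (k in seq_len(W)) {
    X <- ts$data[, win$start[k]:win$end[k], drop = FALSE]
    R <- weighted_corr_matrix(X, spec$weights)
    if (length(attr(R, "zero_variance_nodes"))) zero_var <- TRUE
    Z <- fisher_z(R)
    diag(Z) <- 0
    s1 <- s1 + Z; s2 <- s2 + Z * Z
    if (keep_stack) stack[k, ] <- Z[pr]
  }
  if (zero_var) warning("zero-variance window(s) encountered; r = 0 used", call. = FALSE)
  mz <- s1 / W
  v <- s2 / W - mz * mz
  v[v < 0] <- 0          # guard tiny negative round-off
  if (sd_divisor == "n-1") v <- v * W / (W - 1)
  sdm <- sqrt(v)
  diag(sdm) <- 0
  sdm <- (sdm + t(sdm)) / 2
  dimnames(sdm) <- list(ts$node_ids, ts$node_ids)
  dimnames(mz) <- list(ts$node_ids, ts$node_ids)
  structure(list(values = sdm, mean_z = mz, n_windows = W, window = spec,
                 node_ids = ts$node_ids,
                 z_stack = stack, pairs = if (keep_stack) pr else NULL),
            class = "dfc_variability")
}

#' Zero-phase temporal band-pass filter
#'
#' Frequency-domain (FFT) band-pass: Fourier components with frequency inside
#' `[low_hz, high_hz]` are retained, all others (including DC) are zeroed, and
#' the signal is inverse-transformed.  This is zero-phase by construction and
#' is the filter conventionally applied to rs-fMRI node signals
#' (0.01-0.08 Hz).  The output is mean-free.
#'
#' @param ts a [node_ts()].
#' @param low_hz,high_hz band edges in Hz; 0 <= low < high < Nyquist.
#' @return A filtered [node_ts()].
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(ts, "node_ts"))
  nyq <- 1 / (2 * ts$tr_seconds)
  abort_if(!(low_hz >= 0 && low_hz < high_hz),
           "need 0 <= low < high, got [%g, %g]", low_hz, high_hz)
  abort_if(high_hz >= nyq, "high edge %g Hz >= Nyquist %g Hz", high_hz, nyq)
  Tn <- ncol(ts$data)
  f <- (seq_len(Tn) - 1L) / (Tn * ts$tr_seconds)
  f <- pmin(f, 1 / ts$tr_seconds - f)       # two-sided frequency magnitude
  keep <- f >= low_hz & f <= high_hz
  out <- t(apply(ts$data, 1L, function(x) {
    X <- stats::fft(x)
    X[!keep] <- 0 + 0i
    Re(stats::fft(X, inverse = TRUE)) / Tn
  }))
  node_ts(out, ts$tr_seconds, ts$node_ids, ts$subject_id)
}

#' Long-format edge table from a symmetric matrix
#'
#' Upper triangle (i < j), row-major, 1-based labels.
#' @param m symmetric matrix with dimnames, or an `fc_matrix`/`dfc_variability`.
#' @return data.frame(node_i, node_j, value).
#' @export
edge_table <- function(m) {
  if (inherits(m, c("fc_matrix", "dfc_variability"))) m <- m$values
  pr <- upper_pairs(nrow(m))
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("n%03d", seq_len(nrow(m)))
  data.frame(node_i = ids[pr[, 1L]], node_j = ids[pr[, 2L]], value = m[pr])
}
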