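# Independent oracles used across tests.

# Adjusted Rand index (Hubert & Arabie), computed directly from the
# contingency table — independent of any clustering code in the package.
adjusted_rand <- function(a, b) {
  ct <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(ct))
  sum_a <- sum(comb2(rowSums(ct)))
  sum_b <- sum(comb2(colSums(ct)))
  n2 <- comb2(sum(ct))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# Plain-formula Pearson r (the printed textbook formula), no weights.
pearson_oracle <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Brute-force rectangular-window DFC: plain Pearson per segment, Fisher z,
# population SD across windows.
dfc_brute_force <- function(X, L, step = 1L) {
  Tn <- ncol(X)
  starts <- seq.int(1L, Tn - L + 1L, by = step)
  p <- nrow(X)
  out <- matrix(0, p, p)
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    z <- vapply(starts, function(s) {
      r <- pearson_oracle(X[i, s:(s + L - 1L)], X[j, s:(s + L - 1L)])
      r <- min(1 - 1e-7, max(-(1 - 1e-7), r))
      atanh(r)
    }, 0)
    out[i, j] <- out[j, i] <- sqrt(mean((z - mean(z))^2))
  }
  out
}

# Exhaustive pair-counting AUC (Mann-Whitney definition).
auc_pair_oracle <- function(scores, labels, positive) {
  pos <- which(labels == positive); neg <- which(labels != positive)
  s <- 0
  for (i in pos) for (j in neg)
    s <- s + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  s / (length(pos) * length(neg))
}

# Two-site construction with a batch effect identical on every feature
# (shared subject noise): the complete-shrinkage regime in which EB ComBat
# removes the offset exactly.
make_offset_sites <- function(n = 24, pf = 40, offset = 10, group_shift = 0,
                              seed = 5) {
  set.seed(seed)
  e <- rnorm(2 * n); mu <- rnorm(pf)
  X <- outer(e, rep(1, pf)) + outer(rep(1, 2 * n), mu)
  site <- rep(1:2, each = n)
  grp <- rep(rep(c("A", "B"), n / 2), 2)
  X[site == 2, ] <- X[site == 2, ] + offset
  X[grp == "B", ] <- X[grp == "B", ] + group_shift
  list(X = X, site = site, grp = grp)
}

# Tiny cohort defaults used in several tests (atlas minimum is 7 gray + 12
# white nodes).
tiny_config <- function(n_cn = 10, n_smc = 0, n_ci = 10, Tn = 120, seed = 1,
                        n_sites = 1) {
  cohort_config(n_cn = n_cn, n_smc = n_smc, n_ci = n_ci, n_gray = 7,
                n_white = 12, n_timepoints = Tn, seed = seed,
                n_sites = n_sites)
}
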