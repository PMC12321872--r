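# Static/dynamic FC core: Pearson formula, Fisher z, windows, tapers,
# bandpass.

test_that("pearson_r matches the textbook formula and its symmetries", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  expect_equal(pearson_r(x, y), pearson_oracle(x, y), tolerance = 1e-14)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  # weighted with uniform weights reduces to unweighted
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(15); b <- rnorm(15)
    expect_equal(pearson_r(a, b, weights = rep(1, 15)), pearson_r(a, b),
                 tolerance = 1e-12)
  }
  expect_warning(r0 <- pearson_r(rep(2, 5), rnorm(5)), "zero-variance")
  expect_identical(as.numeric(r0), 0)
  expect_error(pearson_r(1:4, 1:5), "lengths differ")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("fisher_z: closed form, oddness, monotonicity, clipping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  expect_equal(fisher_z(-0.5), -fisher_z(0.5))
  expect_true(is.finite(fisher_z(1)) && is.finite(fisher_z(-1)))
  set.seed(2)
  r <- sort(runif(200, -1, 1))
  expect_true(all(diff(fisher_z(r)) >= 0))
})

test_that("sliding_windows counts, overlap and boundaries", {
  sw <- sliding_windows(197, window_spec("hamming", 30))
  expect_identical(nrow(sw), 168L)
  expect_equal(attr(sliding_windows(60, window_spec("rectangular", 50)), "overlap"), 0.98)
  one <- sliding_windows(30, window_spec("rectangular", 30))
  expect_identical(nrow(one), 1L)
  expect_identical(c(one$start, one$end), c(1L, 30L))
  expect_error(sliding_windows(10, window_spec("hamming", 20)), "shorter than")
  # general count law
  for (cfg in list(c(100, 20, 1), c(100, 20, 5), c(53, 7, 3))) {
    sp <- window_spec("rectangular", cfg[2], step_tr = cfg[3])
    expect_identical(nrow(sliding_windows(cfg[1], sp)),
                     as.integer(floor((cfg[1] - cfg[2]) / cfg[3]) + 1))
  }
})

test_that("taper weights are strictly positive and normalized", {
  for (sp in list(window_spec("hamming", 20), window_spec("gaussian", 30),
                  window_spec("rectangular", 50))) {
    expect_true(all(sp$weights > 0))
    expect_equal(sum(sp$weights), 1, tolerance = 1e-12)
    expect_identical(length(sp$weights), as.integer(sp$length_tr))
  }
  expect_error(window_spec("hamming", 1), "length_tr")
  expect_error(parse_window_code("box20"), "unrecognized")
  expect_identical(parse_window_code("gau30")$gau30$shape, "gaussian")
})

test_that("static_fc: dimensions, duplicate node, null z distribution", {
  set.seed(3)
  X <- matrix(rnorm(10 * 50), 10, 50)
  X[2, ] <- X[1, ]                      # duplicate series: r = 1 edge
  f <- suppressWarnings(static_fc(node_ts(X, 3)))
  expect_identical(dim(f$values), c(10L, 10L))
  expect_true(is_symmetric_zero_diag <- isTRUE(all.equal(f$values, t(f$values))))
  expect_equal(diag(f$values), rep(0, 10), ignore_attr = TRUE)
  expect_equal(f$values[1, 2], atanh(1 - 1e-7), tolerance = 1e-10)
  # independent noise: 95% of null z within 3/sqrt(T-3)
  Tn <- 1000
  f0 <- static_fc(node_ts(matrix(rnorm(30 * Tn), 30, Tn), 3))
  z <- f0$values[upper.tri(f0$values)]
  expect_gt(mean(abs(z) < 3 / sqrt(Tn - 3)), 0.95)
})

test_that("dynamic_fc equals the brute-force oracle for rectangular windows", {
  set.seed(4)
  for (i in 1:3) {
    X <- matrix(rnorm(5 * 70), 5, 70)
    L <- sample(c(10L, 20L), 1)
    d <- dynamic_fc(node_ts(X, 3), window_spec("rectangular", L))
    expect_lt(max(abs(d$values - dfc_brute_force(X, L))), 1e-12)
  }
})

test_that("dynamic_fc: constant-z case, window count, degenerate inputs", {
  # signal periodic with the step: every window sees identical data -> SD 0
  base <- rnorm(5)
  X <- rbind(rep(base, 12), rep(rev(base), 12))
  d <- dynamic_fc(node_ts(X, 2), window_spec("rectangular", 20, step_tr = 5))
  expect_equal(d$values[1, 2], 0, tolerance = 1e-14)
  expect_identical(d$n_windows, as.integer(floor((60 - 20) / 5) + 1))
  expect_error(dynamic_fc(node_ts(matrix(rnorm(40), 2, 20), 2),
                          window_spec("rectangular", 20)), "SD across windows")
})

test_that("DFC is invariant to affine rescaling and tapers agree broadly", {
  set.seed(5)
  X <- matrix(rnorm(6 * 150), 6, 150)
  sp <- window_spec("gaussian", 20)
  d1 <- dynamic_fc(node_ts(X, 3), sp)
  Y <- X; Y[1, ] <- 5 * X[1, ] - 7; Y[4, ] <- -2 * X[4, ] + 3
  d2 <- dynamic_fc(node_ts(Y, 3), sp)
  expect_equal(d1$values, d2$values, tolerance = 1e-10)
  ham <- dynamic_fc(node_ts(X, 3), window_spec("hamming", 20))
  expect_gt(cor(d1$values[upper.tri(d1$values)], ham$values[upper.tri(ham$values)]), 0.9)
})

test_that("bandpass passes in-band and rejects out-of-band power", {
  tt <- seq(0, by = 2, length.out = 200)   # TR = 2 s
  X <- rbind(sin(2 * pi * 0.05 * tt), sin(2 * pi * 0.2 * tt), rep(4, 200))
  bp <- bandpass(node_ts(X, 2), 0.01, 0.08)
  expect_gt(var(bp$data[1, ]) / var(X[1, ]), 0.9)
  expect_lt(var(bp$data[2, ]) / var(X[2, ]), 0.05)
  expect_equal(max(abs(bp$data[3, ])), 0, tolerance = 1e-10)
  expect_error(bandpass(node_ts(X, 2), 0.01, 0.3), "Nyquist")
  expect_error(bandpass(node_ts(X, 2), 0.08, 0.01), "low < high")
})

test_that("node_ts validates its inputs", {
  expect_error(node_ts(matrix(c(1, NA, 2, 3), 2, 2), 2), "missing")
  expect_error(node_ts(matrix(1:10, 1, 10), 2), "2 nodes")
  expect_error(node_ts(matrix(rnorm(8), 2, 4), -1), "positive")
})
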