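# ComBat, differential connections, chord aggregation, demographic tests,
# clinical-scale correlations, cross-cohort similarity.

test_that("combat removes a pure additive site offset exactly", {
  d <- make_offset_sites(group_shift = 2)
  H <- combat(d$X, d$site, covariates = data.frame(group = d$grp))
  site_diff <- colMeans(H[d$site == 1, ]) - colMeans(H[d$site == 2, ])
  expect_lt(max(abs(site_diff)) / 10, 1e-6)
  # group effect preserved within 5%
  d0 <- colMeans(d$X[d$grp == "B", ]) - colMeans(d$X[d$grp == "A", ])
  d1 <- colMeans(H[d$grp == "B", ]) - colMeans(H[d$grp == "A", ])
  expect_lt(max(abs(d1 - d0) / abs(d0)), 0.05)
})

test_that("combat: identity on one site, idempotence, guards", {
  d <- make_offset_sites()
  expect_warning(H1 <- combat(d$X, rep(1, nrow(d$X))), "single site")
  expect_identical(H1, as.matrix(d$X))
  H <- combat(d$X, d$site)
  H2 <- combat(H, d$site)
  expect_lt(max(abs(H2 - H)) / max(abs(H)), 1e-6)
  expect_error(combat(d$X, rep(1:2, c(2, nrow(d$X) - 2))), ">= 3 subjects")
  expect_error(combat(d$X, d$site, covariates = data.frame(s = d$site)),
               "rank-deficient")
})

test_that("combat reduces generic site offsets while keeping group signal", {
  set.seed(6)
  n <- 30; pf <- 50
  X <- matrix(rnorm(2 * n * pf), 2 * n, pf)
  site <- rep(1:2, each = n)
  grp <- rep(rep(c("A", "B"), n / 2), 2)
  X[site == 2, ] <- X[site == 2, ] + 3
  X[grp == "B", ] <- X[grp == "B", ] + 1.5
  H <- combat(X, site, covariates = data.frame(group = grp))
  pre <- mean(abs(colMeans(X[site == 1, ]) - colMeans(X[site == 2, ])))
  post <- mean(abs(colMeans(H[site == 1, ]) - colMeans(H[site == 2, ])))
  expect_lt(post, pre / 5)
  d1 <- mean(colMeans(H[grp == "B", ]) - colMeans(H[grp == "A", ]))
  expect_equal(d1, 1.5, tolerance = 0.08)
})

test_that("differential_connections: nulls, power, ordering, monotonicity", {
  set.seed(7)
  A <- matrix(rnorm(20 * 50), 20, 50)
  # same data in both groups: no entries at any alpha
  expect_identical(nrow(differential_connections(A, A, alpha = 0.5)$entries), 0L)
  # planted 1-SD shift on 10 designated edges, n = 50/50, bonferroni
  X1 <- matrix(rnorm(50 * 100), 50, 100)
  X2 <- matrix(rnorm(50 * 100), 50, 100)
  X2[, 1:10] <- X2[, 1:10] + 1
  colnames(X1) <- colnames(X2) <- sprintf("e%03d", 1:100)
  dc <- differential_connections(X1, X2, alpha = 0.05, correction = "bonferroni")
  expect_gte(sum(sprintf("e%03d", 1:10) %in% dc$entries$edge), 9)
  expect_true(all(diff(dc$entries$p) >= 0))
  # monotone nondecreasing entry count in alpha
  dcs <- vapply(c(0.001, 0.01, 0.05, 0.2),
                function(a) nrow(differential_connections(X1, X2, alpha = a)$entries), 0L)
  expect_true(all(diff(dcs) >= 0))
  # zero-variance edge flagged with p = 1
  Z1 <- cbind(A, const = 1); Z2 <- cbind(matrix(rnorm(20 * 50), 20), const = 1)
  colnames(Z1) <- colnames(Z2) <- c(sprintf("e%03d", 1:50), "const")
  dz <- differential_connections(Z1, Z2, alpha = 1.1)
  expect_identical(dz$flagged, "const")
  expect_equal(dz$entries$p[dz$entries$edge == "const"], 1)
  # Welch flag runs
  expect_s3_class(differential_connections(X1, X2, var_equal = FALSE), "diff_connections")
  expect_error(differential_connections(X1[1, , drop = FALSE], X2), ">= 2 subjects")
})

test_that("chord_aggregate sums |mean difference| into subnetwork blocks", {
  atlas <- atlas_map(7, 12)
  empty <- structure(list(entries = data.frame(edge = character(0),
                                               mean_diff = numeric(0))),
                     class = "diff_connections")
  expect_true(all(chord_aggregate(empty, atlas) == 0))
  nets <- c(atlas$subnetwork[atlas$node_id == "g007"],
            atlas$subnetwork[atlas$node_id == "w002"])
  one <- structure(list(entries = data.frame(edge = "g007-w002", mean_diff = -0.3)),
                   class = "diff_connections")
  ch <- chord_aggregate(one, atlas)
  expect_equal(ch[nets[1], nets[2]], 0.3)
  expect_equal(ch, t(ch))
  # additivity + conservation
  two <- structure(list(entries = data.frame(edge = c("g007-w002", "g006-w002", "g001-g002"),
                                             mean_diff = c(-0.3, 0.2, 0.1))),
                   class = "diff_connections")
  ch2 <- chord_aggregate(two, atlas)
  expect_equal(sum(ch2[upper.tri(ch2, diag = TRUE)]), 0.6)
  bad <- structure(list(entries = data.frame(edge = "g007-x999", mean_diff = 1)),
                   class = "diff_connections")
  expect_error(chord_aggregate(bad, atlas), "x999")
})

test_that("anova_tukey: identical groups, t-squared identity, planted shifts", {
  v <- rep(c(1, 2, 3), 3)
  g <- rep(c("a", "b", "c"), each = 3)
  # same data in every group
  at0 <- anova_tukey(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(at0$F, 0)
  expect_equal(at0$p, 1)
  # two groups: F = t^2
  set.seed(8)
  x <- rnorm(40); gg <- rep(c("a", "b"), 20)
  at <- anova_tukey(x, gg)
  tt <- t.test(x ~ gg, var.equal = TRUE)
  expect_equal(at$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(at$p, tt$p.value, tolerance = 1e-10)
  # large planted shifts: every Tukey pair significant
  y <- c(rnorm(10), rnorm(10, 5), rnorm(10, 10))
  at3 <- anova_tukey(y, rep(c("a", "b", "c"), each = 10))
  expect_true(all(at3$tukey$p_adj < 0.05))
  expect_error(anova_tukey(1:3, c("a", "b", "b")), ">= 2")
})

test_that("chi_square_test: degenerate table, transposition, Yates flag", {
  ind <- matrix(10, 2, 2)
  cs <- chi_square_test(ind)
  expect_equal(cs$statistic, 0)
  expect_equal(cs$p, 1)
  m <- matrix(c(30, 10, 15, 25), 2)
  expect_equal(chi_square_test(m)$statistic, chi_square_test(t(m))$statistic)
  expect_lt(chi_square_test(m, yates = TRUE)$statistic, chi_square_test(m)$statistic)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2)), "marginal")
  expect_error(chi_square_test(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("scale_correlations: identity, bonferroni, flags, validation", {
  set.seed(9)
  n <- 50
  sc <- data.frame(mmse = rnorm(n, 28), moca = rnorm(n, 25), cdr_sb = rnorm(n, 1))
  F1 <- cbind(exact = sc$mmse, noise = rnorm(n))
  out <- scale_correlations(F1, sc)
  expect_equal(out$r[out$feature == "exact" & out$scale == "mmse"], 1)
  expect_equal(out$p_bonferroni, pmin(1, out$p * nrow(out)))
  Fc <- cbind(flat = rep(1, n))
  expect_warning(oc <- scale_correlations(Fc, sc), "constant")
  expect_true(all(is.na(oc$r)))
  expect_error(scale_correlations(F1[1:3, ], sc[1:3, ]), "4 complete")
})

test_that("similarity_coefficient: identity, sign flip, null, dimensions", {
  set.seed(10)
  m <- matrix(rnorm(400), 20, 20); m <- m + t(m); diag(m) <- 0
  expect_equal(similarity_coefficient(m, m), 1)
  expect_equal(similarity_coefficient(m, -m), -1)
  sims <- vapply(1:3, function(r) {
    set.seed(r)
    a <- matrix(rnorm(328^2), 328); a <- a + t(a)
    b <- matrix(rnorm(328^2), 328); b <- b + t(b)
    abs(similarity_coefficient(a, b))
  }, 0)
  expect_true(all(sims < 0.02))
  expect_error(similarity_coefficient(m, m[1:5, 1:5]), "mismatch")
})
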