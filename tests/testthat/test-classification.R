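# LASSO, SMOTE, SMO-SVM, cross-validation and ROC.

test_that("lasso_select reproduces closed-form soft-thresholding", {
  set.seed(1)
  n <- 64; p <- 8
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))      # orthonormal columns
  b <- c(3, -2, 1.5, 0, 0, 0.5, -0.2, 0)
  y <- as.numeric(Q %*% b)
  thresh <- 0.5
  # glmnet's lambda is threshold/n for an orthonormal design without
  # intercept/standardization
  ls <- lasso_select(Q, y, lambda_grid = thresh / n, cv_folds = 0,
                     family = "gaussian", standardize = FALSE, intercept = FALSE)
  oracle <- sign(b) * pmax(abs(b) - thresh, 0)
  expect_lt(max(abs(ls$coef - oracle)), 1e-6)
  expect_identical(ls$selected, which(oracle != 0))
})

test_that("lasso_select: full shrinkage, informative recovery, determinism", {
  set.seed(2)
  n <- 100; X <- matrix(rnorm(n * 20), n, 20)
  y <- factor(rep(c("a", "b"), each = n / 2))
  expect_warning(e <- lasso_select(X, y, lambda_grid = 1e6, cv_folds = 0),
                 "no features")
  expect_identical(length(e$selected), 0L)
  # one perfectly separating feature among many noise features
  hits <- vapply(1:5, function(s) {
    set.seed(s + 10)
    Xs <- matrix(rnorm(200 * 201), 200, 201)
    ys <- rep(c("a", "b"), each = 100)
    Xs[, 1] <- ifelse(ys == "a", -2, 2) + rnorm(200, 0, 0.1)
    1L %in% suppressWarnings(lasso_select(Xs, ys, seed = s)$selected)
  }, TRUE)
  expect_gte(sum(hits), 4)
  # determinism (pure-noise X may legitimately select nothing)
  s1 <- suppressWarnings(lasso_select(X, y, seed = 3))
  s2 <- suppressWarnings(lasso_select(X, y, seed = 3))
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$lambda, s2$lambda)
})

test_that("smote_oversample: counts, convexity, determinism, k guard", {
  set.seed(3)
  X <- matrix(rnorm(45 * 3), 45, 3)
  y <- rep(c("min", "maj"), c(5, 40))
  sm <- smote_oversample(X, y, k = 3, seed = 4)
  expect_identical(sm$n_synthetic, 35L)
  expect_identical(sum(sm$y == "min"), 40L)
  # every synthetic point lies on a segment between two real minority points
  Xm <- X[y == "min", ]
  syn <- sm$X[46:80, , drop = FALSE]
  on_segment <- apply(syn, 1, function(pt) {
    ok <- FALSE
    for (i in 1:4) for (j in (i + 1):5) {
      d <- Xm[j, ] - Xm[i, ]
      tpar <- sum((pt - Xm[i, ]) * d) / sum(d * d)
      if (tpar >= -1e-9 && tpar <= 1 + 1e-9 &&
          sqrt(sum((Xm[i, ] + tpar * d - pt)^2)) < 1e-8) ok <- TRUE
    }
    ok
  })
  expect_true(all(on_segment))
  expect_identical(smote_oversample(X, y, k = 3, seed = 4)$X, sm$X)
  expect_warning(smote_oversample(X, y, k = 10, seed = 1), "using k")
})

test_that("train_svm: separable data, XOR kernels, degenerate input", {
  set.seed(5)
  n <- 60
  # separable by construction: classes occupy disjoint half-planes with margin
  X <- cbind(c(runif(n / 2, 0.5, 2), runif(n / 2, -2, -0.5)), rnorm(n))
  y <- rep(c("a", "b"), each = n / 2)
  fit <- train_svm(X, y, model_spec("linear"))
  expect_equal(mean(predict(fit, X, type = "class") == y), 1)
  expect_error(train_svm(X, rep("a", n)), "single class")
  # XOR: linear fails, RBF succeeds
  nx <- 400
  Xx <- matrix(runif(2 * nx, -1, 1), nx, 2)
  yx <- ifelse(Xx[, 1] * Xx[, 2] > 0, "p", "q")
  acc_lin <- cross_validate(Xx, yx, model_spec("linear"), folds = 10,
                            seed = 6)$aggregate["accuracy", "mean"]
  acc_rbf <- cross_validate(Xx, yx, model_spec("rbf", gamma = 1), folds = 10,
                            seed = 6)$aggregate["accuracy", "mean"]
  expect_lte(acc_lin, 0.75)
  expect_gte(acc_rbf, 0.95)
  # polynomial and sigmoid kernels at least run and score
  for (k in c("polynomial", "sigmoid")) {
    f <- train_svm(X, y, model_spec(k))
    expect_length(predict(f, X), n)
  }
})

test_that("roc_auc: degenerate cases, pair-counting oracle, invariance", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c("n", "n", "p", "p"), "p")$auc, 1)
  expect_equal(roc_auc(rep(1, 6), rep(c("n", "p"), 3), "p")$auc, 0.5)
  set.seed(7)
  for (i in 1:20) {
    sc <- sample(seq(0, 1, 0.1), 5, replace = TRUE)   # tied scores likely
    lb <- c("p", sample(c("p", "n"), 3, replace = TRUE), "n")
    expect_equal(roc_auc(sc, lb, "p")$auc, auc_pair_oracle(sc, lb, "p"))
  }
  sc <- rnorm(40); lb <- rep(c("n", "p"), 20)
  expect_equal(roc_auc(exp(sc), lb, "p")$auc, roc_auc(sc, lb, "p")$auc)
  expect_error(roc_auc(1:3, rep("p", 3)), "2 classes")
  # curve starts at (0,0) and ends at (1,1)
  cv <- roc_auc(sc, lb, "p")$curve
  expect_equal(c(cv$fpr[1], cv$tpr[1]), c(0, 0))
  expect_equal(c(cv$fpr[nrow(cv)], cv$tpr[nrow(cv)]), c(1, 1))
})

test_that("cross_validate: separable, noise, determinism, fold hygiene", {
  set.seed(8)
  n <- 60
  X <- rbind(matrix(rnorm(n, 3), n / 2, 2), matrix(rnorm(n, -3), n / 2, 2))
  y <- rep(c("a", "b"), each = n / 2)
  cv <- cross_validate(X, y, model_spec("linear"), folds = 10, seed = 9)
  expect_gte(cv$aggregate["accuracy", "mean"], 0.95)
  expect_gte(cv$auc, 0.99)
  expect_equal(sum(cv$confusion), n)
  # fold assignment partitions subjects exactly once, stratified
  expect_identical(sort(unique(cv$fold_id)), 1:10)
  expect_true(all(table(cv$fold_id, y) == 3))
  # determinism
  cv2 <- cross_validate(X, y, model_spec("linear"), folds = 10, seed = 9)
  expect_identical(cv$per_fold, cv2$per_fold)
  expect_identical(cv$auc, cv2$auc)
  # pure noise: near base rate
  Xn <- matrix(rnorm(80 * 5), 80, 5)
  yn <- rep(c("a", "b"), 40)
  cvn <- cross_validate(Xn, yn, model_spec("linear"), folds = 10, seed = 10)
  expect_lt(abs(cvn$aggregate["accuracy", "mean"] - 0.5), 0.2)
  # a class with a single member starves one training fold of that class
  expect_error(cross_validate(X[1:6, ], c(rep("a", 5), "b"),
                              model_spec("linear"), folds = 3), "single class")
})

test_that("no leakage: validation labels never touch training-fold fits", {
  set.seed(11)
  n <- 60
  X <- matrix(rnorm(n * 30), n, 30)
  y <- rep(c("a", "b"), each = n / 2)
  X[, 1] <- ifelse(y == "a", -1, 1) + rnorm(n, 0, 0.5)
  fid <- rep_len(1:5, n)
  spec <- model_spec("linear", smote = TRUE, lasso = TRUE, lambda_grid = 0.05)
  cv1 <- cross_validate(X, y, spec, folds = 5, seed = 12, fold_id = fid)
  # flip every validation label in fold 1; its decision scores must be
  # bit-identical because fold-1 labels are unseen by its training pipeline
  y2 <- y
  y2[fid == 1] <- ifelse(y[fid == 1] == "a", "b", "a")
  cv2 <- cross_validate(X, y2, spec, folds = 5, seed = 12, fold_id = fid)
  expect_identical(cv1$scores[fid == 1], cv2$scores[fid == 1])
  expect_identical(cv1$selected_features[[1]], cv2$selected_features[[1]])
})

test_that("one_vs_rest macro-averages a 3-class separable problem", {
  set.seed(13)
  # three classes at the corners of a triangle: each is linearly separable
  # from the union of the other two
  centers <- rbind(c(0, 6), c(6, -3), c(-6, -3))
  X <- do.call(rbind, lapply(1:3, function(c)
    cbind(rnorm(20, centers[c, 1]), rnorm(20, centers[c, 2]))))
  y <- rep(c("CN", "SMC", "CI"), each = 20)
  ovr <- one_vs_rest(X, y, model_spec("linear"), folds = 5, seed = 14)
  expect_named(ovr$per_class, c("CI", "CN", "SMC"))
  expect_gte(unname(ovr$macro["accuracy"]), 0.95)
})
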