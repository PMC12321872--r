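# Kernel SVM via sequential minimal optimization (SMO).  Written in-package
# because no SVM library ships with the target image; sizes here (hundreds
# of subjects) are well within reach of a pure-R SMO.

kernel_matrix <- function(X, Y, kernel, gamma, degree, coef0) {
  G <- X %*% t(Y)
  switch(kernel,
    linear = G,
    polynomial = (gamma * G + coef0)^degree,
    sigmoid = tanh(gamma * G + coef0),
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * G
      exp(-gamma * pmax(d2, 0))
    })
}

#' SVM model specification
#'
#' @param kernel one of "linear", "polynomial", "rbf", "sigmoid".
#' @param C soft-margin cost (default 1).
#' @param gamma kernel coefficient; NULL means 1/(n_features * var(X))
#'   computed on the training data.
#' @param degree,coef0 polynomial/sigmoid parameters.
#' @param smote logical, SMOTE minority oversampling inside training folds.
#' @param smote_k SMOTE neighbor count (default 5).
#' @param lasso logical, LASSO feature selection inside training folds.
#' @param lambda_grid optional LASSO lambda grid.
#' @return A `model_spec` list.
#' @export
model_spec <- function(kernel = c("rbf", "linear", "polynomial", "sigmoid"),
                       C = 1, gamma = NULL, degree = 3, coef0 = 0,
                       smote = FALSE, smote_k = 5L,
                       lasso = FALSE, lambda_grid = NULL) {
  kernel <- match.arg(kernel)
  abort_if(C <= 0, "C must be positive")
  structure(list(kernel = kernel, C = C, gamma = gamma, degree = degree,
                 coef0 = coef0, smote = smote, smote_k = as.integer(smote_k),
                 lasso = lasso, lambda_grid = lambda_grid),
            class = "model_spec")
}

#' Train a kernel SVM (binary, SMO)
#'
#' Features are standardized internally with parameters learned from the
#' training data (stored for prediction).  Deterministic given `seed`.
#'
#' @param X training matrix (n x p).
#' @param y labels with exactly two levels; the second sorted level is the
#'   positive class unless `positive` is given.
#' @param spec a [model_spec()].
#' @param positive positive-class label.
#' @param seed RNG seed for SMO pair selection.
#' @param tol KKT tolerance.
#' @param max_passes SMO passes without change before stopping.
#' @return An `svm_model` with `decision_function` support via [predict()].
#' @export
train_svm <- function(X, y, spec = model_spec("linear"), positive = NULL,
                      seed = 1L, tol = 1e-3, max_passes = 10L) {
  X <- as.matrix(X)
  lev <- sort(unique(as.character(y)))
  abort_if(length(lev) < 2L, "training set has a single class ('%s')", lev[1L])
  abort_if(length(lev) > 2L, "train_svm is binary; got %d classes", length(lev))
  if (is.null(positive)) positive <- lev[2L]
  abort_if(!positive %in% lev, "positive class '%s' not in labels", positive)
  yy <- ifelse(as.character(y) == positive, 1, -1)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  gamma <- spec$gamma
  if (is.null(gamma)) {
    v <- stats::var(as.vector(Xs))
    gamma <- 1 / (ncol(Xs) * ifelse(v > 0, v, 1))
  }
  K <- kernel_matrix(Xs, Xs, spec$kernel, gamma, spec$degree, spec$coef0)
  n <- nrow(Xs); C <- spec$C
  alpha <- numeric(n); b <- 0
  f_cache <- function(i) sum(alpha * yy * K[, i]) + b - yy[i]
  with_seed(seed, {
    passes <- 0L; it <- 0L
    while (passes < max_passes && it < 200L) {
      it <- it + 1L
      changed <- 0L
      for (i in seq_len(n)) {
        Ei <- f_cache(i)
        if ((yy[i] * Ei < -tol && alpha[i] < C) ||
            (yy[i] * Ei > tol && alpha[i] > 0)) {
          j <- sample.int(n - 1L, 1L); if (j >= i) j <- j + 1L
          Ej <- f_cache(j)
          ai_old <- alpha[i]; aj_old <- alpha[j]
          if (yy[i] != yy[j]) {
            L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
          } else {
            L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
          }
          if (L >= H) next
          eta <- 2 * K[i, j] - K[i, i] - K[j, j]
          if (eta >= 0) next
          aj <- aj_old - yy[j] * (Ei - Ej) / eta
          aj <- min(H, max(L, aj))
          if (abs(aj - aj_old) < 1e-6) next
          ai <- ai_old + yy[i] * yy[j] * (aj_old - aj)
          alpha[i] <- ai; alpha[j] <- aj
          b1 <- b - Ei - yy[i] * (ai - ai_old) * K[i, i] -
            yy[j] * (aj - aj_old) * K[i, j]
          b2 <- b - Ej - yy[i] * (ai - ai_old) * K[i, j] -
            yy[j] * (aj - aj_old) * K[j, j]
          b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else (b1 + b2) / 2
          changed <- changed + 1L
        }
      }
      passes <- if (changed == 0L) passes + 1L else 0L
    }
  })
  sv <- which(alpha > 1e-8)
  structure(list(spec = spec, gamma = gamma, center = ctr, scale = scl,
                 sv = Xs[sv, , drop = FALSE], sv_alpha = alpha[sv],
                 sv_y = yy[sv], b = b, positive = positive,
                 negative = setdiff(lev, positive)),
            class = "svm_model")
}

#' Decision scores / class predictions from a fitted SVM
#'
#' @param object an `svm_model`.
#' @param newdata matrix of new observations.
#' @param type "decision" for raw scores (positive class at score > 0) or
#'   "class" for labels.
#' @param ... unused.
#' @export
predict.svm_model <- function(object, newdata, type = c("decision", "class"), ...) {
  type <- match.arg(type)
  Xs <- scale(as.matrix(newdata), object$center, object$scale)
  if (nrow(object$sv) == 0L) scores <- rep(object$b, nrow(Xs))
  else {
    K <- kernel_matrix(Xs, object$sv, object$spec$kernel, object$gamma,
                       object$spec$degree, object$spec$coef0)
    scores <- as.numeric(K %*% (object$sv_alpha * object$sv_y)) + object$b
  }
  if (type == "decision") scores
  else ifelse(scores > 0, object$positive, object$negative)
}
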