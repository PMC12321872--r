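# LASSO feature selection, SMOTE oversampling, cross-validated SVM
# classification and ROC/AUC reporting.

#' LASSO feature selection
#'
#' L1-penalized logistic regression (classification default); lambda chosen
#' by cross-validated deviance (`lambda.min`, or the 1-SE rule by flag).
#' Selected features are those with nonzero coefficients at the chosen
#' lambda.  A gaussian (least-squares) mode is kept for closed-form
#' soft-threshold checking.
#'
#' @param X n x p feature matrix (standardized internally by default).
#' @param y binary labels (for `family = "binomial"`) or numeric response.
#' @param lambda_grid optional lambda sequence; NULL lets glmnet choose.
#' @param cv_folds folds for lambda selection (default 10; 0 skips CV and
#'   requires a single `lambda_grid` value).
#' @param seed fold-assignment seed.
#' @param family "binomial" or "gaussian".
#' @param one_se use the 1-SE rule (default FALSE).
#' @param standardize,intercept passed to glmnet.
#' @return list(selected = integer indices, names, lambda, coef, path =
#'   glmnet fit).  Empty selection at every lambda yields a warning and an
#'   empty set.
#' @export
lasso_select <- function(X, y, lambda_grid = NULL, cv_folds = 10L, seed = 1L,
                         family = c("binomial", "gaussian"), one_se = FALSE,
                         standardize = TRUE, intercept = TRUE) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (family == "binomial") {
    y <- factor(y)
    abort_if(nlevels(y) != 2L, "binomial y needs exactly 2 classes")
    abort_if(any(table(y) < 2L), "need >= 2 observations per class")
  }
  if (cv_folds == 0L) {
    abort_if(is.null(lambda_grid) || length(lambda_grid) != 1L,
             "cv_folds = 0 requires a single lambda")
    fit <- glmnet::glmnet(X, y, family = family, lambda = lambda_grid,
                          standardize = standardize, intercept = intercept,
                          thresh = 1e-12)
    lam <- lambda_grid
  } else {
    n <- nrow(X)
    foldid <- with_seed(seed, {
      if (family == "binomial") {
        id <- integer(n)
        for (cl in levels(y)) {
          idx <- which(y == cl)
          id[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
        }
        id
      } else sample(rep_len(seq_len(cv_folds), n))
    })
    fit <- glmnet::cv.glmnet(X, y, family = family, lambda = lambda_grid,
                             foldid = foldid, standardize = standardize,
                             intercept = intercept, thresh = 1e-12)
    lam <- if (one_se) fit$lambda.1se else fit$lambda.min
  }
  cf <- as.matrix(stats::coef(fit, s = lam))
  cf <- cf[setdiff(rownames(cf), "(Intercept)"), , drop = FALSE]
  sel <- which(cf[, 1L] != 0)
  if (length(sel) == 0L)
    warning("LASSO selected no features at the chosen lambda", call. = FALSE)
  nm <- colnames(X)
  list(selected = unname(sel),
       names = if (is.null(nm)) NULL else nm[sel],
       lambda = lam, coef = cf[, 1L], path = fit)
}

#' SMOTE minority oversampling
#'
#' Synthetic minority points `x_new = x_i + u (x_nn - x_i)` with
#' `u ~ U(0, 1)` and `x_nn` one of the `k` nearest minority neighbors of
#' `x_i`.  Meant to be applied inside training folds only; [cross_validate()]
#' does so automatically.
#'
#' @param X n x p matrix.
#' @param y labels; the least frequent class is oversampled.
#' @param k neighbor count (default 5; reduced with a warning when the
#'   minority class is too small).
#' @param target "parity" (default) or an integer count of synthetic points.
#' @param seed RNG seed.
#' @return list(X, y, n_synthetic) with synthetic rows appended.
#' @export
smote_oversample <- function(X, y, k = 5L, target = "parity", seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  tab <- sort(table(y))
  minority <- names(tab)[1L]
  n_min <- tab[[1L]]
  abort_if(n_min < 2L, "minority class has %d observation(s)", n_min)
  n_syn <- if (identical(target, "parity")) max(tab) - n_min else as.integer(target)
  if (n_syn <= 0L) return(list(X = X, y = y, n_synthetic = 0L))
  if (n_min <= k) {
    warning(sprintf("minority size %d <= k = %d; using k = %d", n_min, k, n_min - 1L),
            call. = FALSE)
    k <- n_min - 1L
  }
  Xm <- X[y == minority, , drop = FALSE]
  D <- as.matrix(stats::dist(Xm))
  diag(D) <- Inf
  nn <- t(apply(D, 1L, function(d) order(d)[seq_len(k)]))
  syn <- with_seed(seed, {
    base_i <- rep_len(seq_len(n_min), n_syn)
    pick <- nn[cbind(base_i, sample.int(k, n_syn, replace = TRUE))]
    u <- stats::runif(n_syn)
    Xm[base_i, , drop = FALSE] + u * (Xm[pick, , drop = FALSE] - Xm[base_i, , drop = FALSE])
  })
  list(X = rbind(X, syn), y = c(y, rep(minority, n_syn)), n_synthetic = n_syn)
}

#' ROC curve and AUC
#'
#' AUC by the midrank (Mann-Whitney) convention, identical to the
#' trapezoidal rule over the tie-grouped ROC curve.
#'
#' @param scores numeric decision scores (higher = more positive).
#' @param labels binary labels.
#' @param positive positive-class label (default: second sorted level).
#' @return list(auc, curve = data.frame(threshold, fpr, tpr)).
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  abort_if(length(lev) != 2L, "need exactly 2 classes, got %d", length(lev))
  if (is.null(positive)) positive <- lev[2L]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)          # midranks handle ties
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) mean(scores[!pos] >= t), 0)),
    tpr = c(0, vapply(thr, function(t) mean(scores[pos] >= t), 0)))
  list(auc = auc, curve = curve)
}

stratified_folds <- function(y, folds, seed) {
  y <- as.character(y)
  id <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  id
}

#' Stratified k-fold cross-validated SVM with in-fold LASSO/SMOTE
#'
#' All leakage-prone steps — feature standardization, LASSO selection and
#' SMOTE augmentation — are refit inside each training fold; the validation
#' fold only ever passes through transforms learned on its training folds.
#'
#' @param X n x p feature matrix.
#' @param y binary labels.
#' @param spec a [model_spec()] (kernel, C, smote/lasso toggles).
#' @param folds fold count (default 10).
#' @param seed seed for fold assignment and all in-fold randomness.
#' @param positive positive-class label.
#' @param fold_id optional explicit fold assignment (overrides the seeded
#'   stratified split; used e.g. to audit leakage with fixed folds).
#' @return A `cv_report`: per-fold and aggregate accuracy/sensitivity/
#'   specificity (mean +- SD over folds), pooled-ROC AUC, summed confusion
#'   matrix, ROC points, selected feature names per fold, seed.
#' @export
cross_validate <- function(X, y, spec = model_spec("rbf"), folds = 10L,
                           seed = 1L, positive = NULL, fold_id = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  lev <- sort(unique(y))
  abort_if(length(lev) != 2L, "cross_validate is binary; got %d classes (use one_vs_rest)",
           length(lev))
  if (is.null(positive)) positive <- lev[2L]
  if (is.null(fold_id)) fold_id <- stratified_folds(y, folds, seed)
  else abort_if(length(fold_id) != length(y), "fold_id length mismatch")
  bad <- vapply(seq_len(folds), function(f) length(unique(y[fold_id != f])) < 2L, TRUE)
  abort_if(any(bad), "a training fold has a single class; use fewer folds")
  per <- data.frame(fold = seq_len(folds), accuracy = NA_real_,
                    sensitivity = NA_real_, specificity = NA_real_)
  conf <- matrix(0L, 2L, 2L,
                 dimnames = list(truth = lev, predicted = lev))
  all_scores <- numeric(0); all_labels <- character(0)
  subj_scores <- rep(NA_real_, length(y))
  sel_names <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f; va <- !tr
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    Xva <- X[va, , drop = FALSE]; yva <- y[va]
    keep <- seq_len(ncol(X))
    if (isTRUE(spec$lasso)) {
      fixed_lam <- !is.null(spec$lambda_grid) && length(spec$lambda_grid) == 1L
      ls <- lasso_select(Xtr, ytr, lambda_grid = spec$lambda_grid,
                         cv_folds = if (fixed_lam) 0L else 10L,
                         seed = seed + f)
      if (length(ls$selected) > 0L) keep <- ls$selected
      sel_names[[f]] <- if (!is.null(ls$names)) ls$names else keep
      Xtr <- Xtr[, keep, drop = FALSE]; Xva <- Xva[, keep, drop = FALSE]
    }
    if (isTRUE(spec$smote)) {
      sm <- smote_oversample(Xtr, ytr, k = spec$smote_k, seed = seed + 100L + f)
      Xtr <- sm$X; ytr <- sm$y
    }
    fit <- train_svm(Xtr, ytr, spec, positive = positive, seed = seed + 200L + f)
    sc <- predict(fit, Xva, type = "decision")
    pred <- ifelse(sc > 0, positive, setdiff(lev, positive))
    tp <- sum(pred == positive & yva == positive)
    tn <- sum(pred != positive & yva != positive)
    npos <- sum(yva == positive); nneg <- sum(yva != positive)
    per$accuracy[f] <- mean(pred == yva)
    per$sensitivity[f] <- if (npos > 0) tp / npos else NA_real_
    per$specificity[f] <- if (nneg > 0) tn / nneg else NA_real_
    for (a in lev) for (b in lev)
      conf[a, b] <- conf[a, b] + sum(yva == a & pred == b)
    all_scores <- c(all_scores, sc); all_labels <- c(all_labels, yva)
    subj_scores[va] <- sc
  }
  roc <- roc_auc(all_scores, all_labels, positive = positive)
  agg <- function(v) c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
  structure(list(per_fold = per,
                 aggregate = rbind(accuracy = agg(per$accuracy),
                                   sensitivity = agg(per$sensitivity),
                                   specificity = agg(per$specificity)),
                 auc = roc$auc, roc_curve = roc$curve, confusion = conf,
                 scores = subj_scores, fold_id = fold_id,
                 selected_features = sel_names, positive = positive,
                 folds = folds, seed = seed, spec = spec),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<cv_report> %d-fold CV (%s kernel%s%s)\n", x$folds, x$spec$kernel,
              if (isTRUE(x$spec$lasso)) " + LASSO" else "",
              if (isTRUE(x$spec$smote)) " + SMOTE" else ""))
  cat(sprintf("  accuracy    %.1f%% +- %.1f%%\n", 100 * a["accuracy", "mean"],
              100 * a["accuracy", "sd"]))
  cat(sprintf("  sensitivity %.1f%% +- %.1f%%\n", 100 * a["sensitivity", "mean"],
              100 * a["sensitivity", "sd"]))
  cat(sprintf("  specificity %.1f%% +- %.1f%%\n", 100 * a["specificity", "mean"],
              100 * a["specificity", "sd"]))
  cat(sprintf("  AUC (pooled ROC) %.3f\n", x$auc))
  invisible(x)
}

#' One-vs-rest multiclass cross-validation
#'
#' Runs [cross_validate()] once per class (that class vs the rest) and
#' macro-averages the aggregate metrics.
#'
#' @inheritParams cross_validate
#' @return list(per_class = named list of `cv_report`, macro = named numeric
#'   of macro-averaged accuracy/sensitivity/specificity/auc).
#' @export
one_vs_rest <- function(X, y, spec = model_spec("rbf"), folds = 10L, seed = 1L) {
  y <- as.character(y)
  classes <- sort(unique(y))
  abort_if(length(classes) < 3L, "use cross_validate for binary problems")
  reports <- lapply(classes, function(cl) {
    yb <- ifelse(y == cl, cl, "rest")
    cross_validate(X, yb, spec, folds = folds, seed = seed, positive = cl)
  })
  names(reports) <- classes
  macro <- c(accuracy = mean(vapply(reports, function(r) r$aggregate["accuracy", "mean"], 0)),
             sensitivity = mean(vapply(reports, function(r) r$aggregate["sensitivity", "mean"], 0)),
             specificity = mean(vapply(reports, function(r) r$aggregate["specificity", "mean"], 0)),
             auc = mean(vapply(reports, function(r) r$auc, 0)))
  list(per_class = reports, macro = macro)
}
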