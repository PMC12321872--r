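# ComBat harmonization, group differential-connection testing, subnetwork
# aggregation, demographic tests, cross-cohort similarity and clinical-scale
# correlations.

#' Parametric empirical-Bayes ComBat harmonization
#'
#' Location/scale batch adjustment: features are standardized on a
#' covariate-adjusted fit, per-site means are shrunk under a normal prior and
#' per-site variances under an inverse-gamma prior (moment-matched
#' hyperpriors, iterative conditional-mode solution), then the data are
#' reconstructed with covariate (e.g. group) effects preserved.
#'
#' @param features subjects x features numeric matrix (or data.frame).
#' @param batch site label per subject (>= 2 sites, each with >= 3 subjects;
#'   a single site returns the input unchanged with a warning).
#' @param covariates optional design columns to preserve (factor/character
#'   columns are expanded to dummies); must be full rank together with the
#'   intercept.
#' @param eb use empirical-Bayes shrinkage (TRUE) or per-site L/S estimates.
#' @return harmonized matrix, same shape and dimnames.
#' @export
combat <- function(features, batch, covariates = NULL, eb = TRUE) {
  X <- t(as.matrix(features))           # features x samples internally
  n <- ncol(X)
  batch <- factor(batch)
  abort_if(length(batch) != n, "batch length %d != %d subjects", length(batch), n)
  if (nlevels(batch) < 2L) {
    warning("single site: ComBat is the identity transform", call. = FALSE)
    return(as.matrix(features))
  }
  tab <- table(batch)
  abort_if(any(tab < 3L), "every site needs >= 3 subjects (smallest has %d)", min(tab))
  B <- stats::model.matrix(~ batch - 1)
  if (!is.null(covariates)) {
    cov_df <- as.data.frame(covariates)
    C <- stats::model.matrix(~ ., data = cov_df)[, -1L, drop = FALSE]
  } else C <- NULL
  design <- cbind(B, C)
  abort_if(qr(design)$rank < ncol(design),
           "rank-deficient design (batch + covariates collinear)")
  # feature-wise OLS
  beta <- solve(crossprod(design), crossprod(design, t(X)))  # coef x features
  nb <- nlevels(batch)
  grand <- as.numeric(crossprod(as.numeric(tab) / n, beta[seq_len(nb), , drop = FALSE]))
  stand_mean <- matrix(grand, nrow(X), n)                    # features x samples
  if (!is.null(C)) stand_mean <- stand_mean + t(C %*% beta[-seq_len(nb), , drop = FALSE])
  resid <- X - t(design %*% beta)
  var_pooled <- rowMeans(resid^2)
  var_pooled[var_pooled <= 0] <- .Machine$double.eps
  s_data <- (X - stand_mean) / sqrt(var_pooled)

  gamma_hat <- t(vapply(levels(batch), function(b)
    rowMeans(s_data[, batch == b, drop = FALSE]), numeric(nrow(X))))
  # batch variances from covariate-adjusted residuals with the population
  # (n_k) divisor — consistent with var_pooled, so repeated application is a
  # fixed point in the complete-shrinkage limit
  s_resid <- resid / sqrt(var_pooled)
  delta_hat <- t(vapply(levels(batch), function(b)
    rowMeans(s_resid[, batch == b, drop = FALSE]^2), numeric(nrow(X))))
  delta_hat[delta_hat <= 0] <- .Machine$double.eps

  if (eb) {
    gamma_star <- gamma_hat; delta_star <- delta_hat
    for (bi in seq_len(nb)) {
      g <- gamma_hat[bi, ]; d <- delta_hat[bi, ]
      g_bar <- mean(g); t2 <- stats::var(g)
      m <- mean(d); s2 <- stats::var(d)
      nk <- sum(batch == levels(batch)[bi])
      sd_b <- s_data[, batch == levels(batch)[bi], drop = FALSE]
      if (t2 < 1e-12 || s2 < 1e-12) {
        # degenerate hyperpriors: identical batch effect (or variance) on
        # every feature -> complete shrinkage is the exact EB limit
        gamma_star[bi, ] <- if (t2 < 1e-12) rep(g_bar, length(g)) else g
        delta_star[bi, ] <- if (s2 < 1e-12) rep(m, length(d)) else d
        next
      }
      a_prior <- (2 * s2 + m^2) / s2
      b_prior <- (m * s2 + m^3) / s2
      g_new <- g; d_new <- d
      for (it in seq_len(100L)) {
        g_old <- g_new; d_old <- d_new
        g_new <- (nk * t2 * g + d_new * g_bar) / (nk * t2 + d_new)
        sse <- rowSums((sd_b - g_new)^2)
        d_new <- (0.5 * sse + b_prior) / (nk / 2 + a_prior - 1)
        if (max(abs(g_new - g_old), abs(d_new - d_old)) < 1e-8) break
      }
      gamma_star[bi, ] <- g_new; delta_star[bi, ] <- d_new
    }
  } else {
    gamma_star <- gamma_hat; delta_star <- delta_hat
  }
  out <- s_data
  for (bi in seq_len(nb)) {
    idx <- batch == levels(batch)[bi]
    out[, idx] <- (s_data[, idx, drop = FALSE] - gamma_star[bi, ]) /
      sqrt(delta_star[bi, ])
  }
  out <- out * sqrt(var_pooled) + stand_mean
  res <- t(out)
  dimnames(res) <- dimnames(as.matrix(features))
  res
}

#' Edge-wise two-sample t-tests between groups
#'
#' Student's equal-variance t (default; Welch by flag) per feature column,
#' with optional multiplicity correction; entries with corrected p < alpha
#' are returned ordered by p then edge label.  Zero-pooled-variance edges
#' get p = 1 and are flagged.
#'
#' @param features_a,features_b subjects x features matrices for the two
#'   groups (same columns, >= 2 subjects each).
#' @param alpha significance threshold applied to corrected p.
#' @param correction "none" (default, mirroring raw p < .05/.01/.001
#'   reporting), "bonferroni" or "fdr".
#' @param var_equal pooled-variance Student t (default) vs Welch.
#' @param group_pair labels for reporting.
#' @return A `diff_connections` object: `entries` data.frame(edge, t, p,
#'   p_corrected, mean_diff), plus alpha/correction/group_pair/n_tested and
#'   `flagged` (zero-variance edges).
#' @export
differential_connections <- function(features_a, features_b, alpha = 0.05,
                                     correction = c("none", "bonferroni", "fdr"),
                                     var_equal = TRUE,
                                     group_pair = c("A", "B")) {
  correction <- match.arg(correction)
  A <- as.matrix(features_a); B <- as.matrix(features_b)
  abort_if(ncol(A) != ncol(B), "feature columns differ (%d vs %d)", ncol(A), ncol(B))
  na <- nrow(A); nb <- nrow(B)
  abort_if(na < 2L || nb < 2L, "need >= 2 subjects per group")
  ma <- colMeans(A); mb <- colMeans(B)
  va <- apply(A, 2L, stats::var); vb <- apply(B, 2L, stats::var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, ncol(A))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  bad <- se <= 0 | !is.finite(se)
  tstat <- (ma - mb) / ifelse(bad, 1, se)
  tstat[bad] <- 0
  p <- 2 * stats::pt(-abs(tstat), df)
  p[bad] <- 1
  p_corr <- stats::p.adjust(p, method = if (correction == "none") "none" else correction)
  edges <- colnames(A)
  if (is.null(edges)) edges <- sprintf("f%05d", seq_len(ncol(A)))
  sel <- which(p_corr < alpha)
  ent <- data.frame(edge = edges[sel], t = tstat[sel], p = p[sel],
                    p_corrected = p_corr[sel], mean_diff = (ma - mb)[sel],
                    stringsAsFactors = FALSE)
  ent <- ent[order(ent$p, ent$edge), , drop = FALSE]
  rownames(ent) <- NULL
  structure(list(group_pair = group_pair, entries = ent, alpha = alpha,
                 correction = correction, n_tested = ncol(A),
                 flagged = edges[bad]),
            class = "diff_connections")
}

#' @export
print.diff_connections <- function(x, ...) {
  cat(sprintf("<diff_connections> %s vs %s: %d/%d edges at %s p < %g\n",
              x$group_pair[1L], x$group_pair[2L], nrow(x$entries), x$n_tested,
              x$correction, x$alpha))
  invisible(x)
}

#' Aggregate differential connections into a subnetwork chord matrix
#'
#' For each subnetwork pair, sums |mean difference| of the differential
#' connections whose endpoints fall in those subnetworks (7 gray + 12 white
#' = 19 blocks with the default atlas).
#'
#' @param diff a [differential_connections()] result whose edge names are
#'   `node_i-node_j`.
#' @param atlas an [atlas_map()].
#' @return symmetric nonnegative subnetwork x subnetwork matrix.
#' @export
chord_aggregate <- function(diff, atlas) {
  nets <- unique(atlas$subnetwork)
  M <- matrix(0, length(nets), length(nets), dimnames = list(nets, nets))
  if (nrow(diff$entries) == 0L) return(M)
  lookup <- stats::setNames(atlas$subnetwork, atlas$node_id)
  parts <- strsplit(diff$entries$edge, "-", fixed = TRUE)
  for (e in seq_along(parts)) {
    nd <- parts[[e]]
    abort_if(length(nd) != 2L, "edge '%s' is not 'node_i-node_j'", diff$entries$edge[e])
    miss <- nd[!nd %in% names(lookup)]
    abort_if(length(miss) > 0L, "unknown node '%s' in atlas", miss[1L])
    a <- lookup[[nd[1L]]]; b <- lookup[[nd[2L]]]
    v <- abs(diff$entries$mean_diff[e])
    M[a, b] <- M[a, b] + v
    if (a != b) M[b, a] <- M[b, a] + v
  }
  M
}

#' One-way ANOVA with Tukey HSD post-hoc
#'
#' @param values numeric response per subject.
#' @param groups group label per subject (>= 2 groups, >= 2 per group).
#' @return list(F, p, df, tukey = data.frame(comparison, diff, lwr, upr,
#'   p_adj)).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  abort_if(nlevels(groups) < 2L, "need >= 2 groups")
  abort_if(any(table(groups) < 2L), "every group needs >= 2 observations")
  fit <- stats::aov(values ~ groups)
  sm <- summary(fit)[[1L]]
  Fv <- sm$`F value`[1L]; pv <- sm$`Pr(>F)`[1L]
  ss <- sm$`Sum Sq`
  # identical group distributions: between-group SS is numerically zero
  if (!is.finite(Fv) || ss[1L] <= 1e-12 * sum(ss)) { Fv <- 0; pv <- 1 }
  tk <- stats::TukeyHSD(fit)$groups
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(F = Fv, p = pv, df = sm$Df, tukey = tukey)
}

#' Pearson chi-square test on a contingency table
#'
#' @param counts nonnegative integer matrix (2x2 or r x c).
#' @param yates apply Yates continuity correction (default FALSE).
#' @return list(statistic, df, p).
#' @export
chi_square_test <- function(counts, yates = FALSE) {
  m <- as.matrix(counts)
  abort_if(any(m < 0) || any(m != round(m)), "counts must be nonnegative integers")
  abort_if(any(rowSums(m) == 0) || any(colSums(m) == 0), "zero marginal in table")
  ht <- stats::chisq.test(m, correct = yates)
  abort_if(any(ht$expected == 0), "expected cell count of 0")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Correlations between connectivity features and clinical scales
#'
#' Pairwise-complete Pearson r with two-sided p per (feature, scale) pair and
#' Bonferroni correction over all tested pairs.
#'
#' @param features subjects x features matrix.
#' @param scales subjects x scales data.frame/matrix (e.g. mmse, moca,
#'   cdr_sb).
#' @return data.frame(feature, scale, n, r, p, p_bonferroni); constant
#'   columns yield NA r with a `flagged` attribute.
#' @export
scale_correlations <- function(features, scales) {
  X <- as.matrix(features); S <- as.matrix(scales)
  abort_if(nrow(X) != nrow(S), "row mismatch: %d vs %d", nrow(X), nrow(S))
  fn <- colnames(X); if (is.null(fn)) fn <- sprintf("f%05d", seq_len(ncol(X)))
  sn <- colnames(S); if (is.null(sn)) sn <- sprintf("scale%d", seq_len(ncol(S)))
  out <- expand.grid(feature = fn, scale = sn, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out$n <- NA_integer_; out$r <- NA_real_; out$p <- NA_real_
  flagged <- character(0)
  for (row in seq_len(nrow(out))) {
    x <- X[, out$feature[row]]; y <- S[, match(out$scale[row], sn)]
    ok <- stats::complete.cases(x, y)
    out$n[row] <- sum(ok)
    abort_if(sum(ok) < 4L, "fewer than 4 complete pairs for %s ~ %s",
             out$feature[row], out$scale[row])
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      flagged <- c(flagged, paste(out$feature[row], out$scale[row], sep = "~"))
      next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    out$r[row] <- unname(ct$estimate); out$p[row] <- ct$p.value
  }
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  if (length(flagged)) {
    warning(sprintf("constant column(s): %s", paste(flagged, collapse = ", ")),
            call. = FALSE)
    attr(out, "flagged") <- flagged
  }
  out
}

#' Cross-cohort similarity of two (group-mean) FC matrices
#'
#' Pearson correlation of the vectorized upper triangles (i < j, row-major);
#' a documented interpretation of the published "similarity coefficient".
#'
#' @param fc_a,fc_b `fc_matrix` objects or symmetric matrices over the same
#'   node set.
#' @return similarity in [-1, 1].
#' @export
similarity_coefficient <- function(fc_a, fc_b) {
  a <- if (inherits(fc_a, c("fc_matrix", "dfc_variability"))) fc_a$values else fc_a
  b <- if (inherits(fc_b, c("fc_matrix", "dfc_variability"))) fc_b$values else fc_b
  abort_if(!all(dim(a) == dim(b)), "dimension mismatch: %dx%d vs %dx%d",
           nrow(a), ncol(a), nrow(b), ncol(b))
  stats::cor(upper_vec(a), upper_vec(b))
}
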