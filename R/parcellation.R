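# Data-driven white-matter parcellation: K-means over voxel time series with
# subset-reproducibility (matched Dice) validation.

# k-means++ seeding (Arthur & Vassilvitskii): each next center is sampled
# with probability proportional to squared distance from the nearest chosen
# center.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums((X - rep(X[idx[1L], ], each = n))^2)
  for (c in 2L:k) {
    pr <- if (sum(d2) > 0) d2 / sum(d2) else as.numeric(!seq_len(n) %in% idx)
    idx[c] <- sample.int(n, 1L, prob = pr)
    d2 <- pmin(d2, rowSums((X - rep(X[idx[c], ], each = n))^2))
  }
  X[idx, , drop = FALSE]
}

#' K-means parcellation of voxel time series
#'
#' Each voxel series is standardized (zero mean, unit variance) before
#' clustering; constant (zero-variance) voxels are excluded with a warning
#' and reported in the result.  Best of `n_init` restarts by within-cluster
#' sum of squares; deterministic under a fixed seed.
#'
#' @param voxel_series voxels x time numeric matrix.
#' @param k number of clusters (>= 2; the white-matter pipeline sweeps 2-22).
#' @param n_init random restarts (default 10).
#' @param seed RNG seed.
#' @param iter_max Lloyd iteration cap per restart.
#' @return A `parcellation_result`: `labels` (named integer in 1..k, NA for
#'   excluded voxels), `k`, `inertia`, `seed`, `excluded`.
#' @export
kmeans_parcellate <- function(voxel_series, k, n_init = 10L, seed = 1L,
                              iter_max = 100L) {
  X <- as.matrix(voxel_series)
  abort_if(!is_count(k, 2L), "k must be an integer >= 2")
  abort_if(nrow(X) < k, "k = %d exceeds %d voxels", k, nrow(X))
  v <- apply(X, 1L, stats::var)
  excluded <- which(v <= 0)
  if (length(excluded)) {
    warning(sprintf("excluding %d zero-variance voxel(s)", length(excluded)),
            call. = FALSE)
    abort_if(nrow(X) - length(excluded) < k,
             "fewer than k voxels remain after exclusions")
  }
  keep <- setdiff(seq_len(nrow(X)), excluded)
  Xs <- t(scale(t(X[keep, , drop = FALSE])))
  # best of n_init k-means++ seeded restarts (random-partition init gets
  # stuck in merge/split local optima at this k)
  fit <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_init)) {
      ctr <- kmeanspp_centers(Xs, k)
      # Hartigan-Wong requires k < n; Lloyd handles the degenerate k = n case
      f <- stats::kmeans(Xs, centers = ctr, iter.max = iter_max,
                         algorithm = if (k == nrow(Xs)) "Lloyd" else "Hartigan-Wong")
      if (is.null(best) || f$tot.withinss < best$tot.withinss) best <- f
    }
    best
  })
  labels <- rep(NA_integer_, nrow(X))
  labels[keep] <- fit$cluster
  names(labels) <- if (is.null(rownames(X))) sprintf("v%04d", seq_len(nrow(X))) else rownames(X)
  structure(list(labels = labels, k = as.integer(k),
                 inertia = fit$tot.withinss, seed = as.integer(seed),
                 excluded = excluded),
            class = "parcellation_result")
}

#' @export
print.parcellation_result <- function(x, ...) {
  cat(sprintf("<parcellation> k = %d, %d voxels (%d excluded), inertia = %.4g\n",
              x$k, length(x$labels), length(x$excluded), x$inertia))
  invisible(x)
}

#' Dice overlap between two labelings after optimal cluster matching
#'
#' K-means labels are arbitrary, so clusters are first matched one-to-one by
#' maximizing total overlap (Hungarian assignment on the contingency table);
#' Dice_c = 2|A_c n B_c| / (|A_c| + |B_c|) is then computed per matched pair.
#'
#' @param labels_a,labels_b integer labelings of the same voxel universe with
#'   the same number of clusters (NAs dropped pairwise).
#' @return list(per_cluster, mean, matching) where `matching[c]` is the
#'   cluster of B matched to cluster c of A.
#' @export
matched_dice <- function(labels_a, labels_b) {
  if (inherits(labels_a, "parcellation_result")) labels_a <- labels_a$labels
  if (inherits(labels_b, "parcellation_result")) labels_b <- labels_b$labels
  abort_if(length(labels_a) != length(labels_b),
           "labelings cover different universes (%d vs %d voxels)",
           length(labels_a), length(labels_b))
  ok <- !is.na(labels_a) & !is.na(labels_b)
  a <- as.integer(factor(labels_a[ok], levels = sort(unique(labels_a[ok]))))
  b <- as.integer(factor(labels_b[ok], levels = sort(unique(labels_b[ok]))))
  ka <- max(a); kb <- max(b)
  abort_if(ka != kb, "cluster counts differ: %d vs %d", ka, kb)
  ct <- table(factor(a, levels = 1:ka), factor(b, levels = 1:kb))
  m <- as.integer(clue::solve_LSAP(matrix(as.numeric(ct), ka, kb), maximum = TRUE))
  na <- tabulate(a, ka); nb <- tabulate(b, kb)
  inter <- ct[cbind(1:ka, m)]
  dice <- 2 * as.numeric(inter) / (na + nb[m])
  list(per_cluster = dice, mean = mean(dice), matching = m)
}

#' Subset reproducibility of a parcellation
#'
#' The data are split into `n_subsets` disjoint subsets — by subject when a
#' list of matrices is supplied, else by contiguous timepoint blocks — the
#' parcellation is run independently on each, and the mean pairwise matched
#' Dice across subset pairs is returned (the >0.85 validation convention).
#'
#' @param voxel_series voxels x time matrix, or a list of such matrices (one
#'   per subject) sharing the voxel universe.
#' @param k cluster count.
#' @param n_subsets number of disjoint subsets (default 4, >= 2).
#' @param seed RNG seed (split + each K-means run).
#' @param n_init restarts per run.
#' @return list(mean_dice, pairwise = data.frame(a, b, dice), parcellations).
#' @export
subset_reproducibility <- function(voxel_series, k, n_subsets = 4L, seed = 1L,
                                   n_init = 10L) {
  abort_if(!is_count(n_subsets, 2L), "n_subsets must be >= 2")
  if (is.list(voxel_series) && !is.data.frame(voxel_series)) {
    ns <- length(voxel_series)
    abort_if(ns < n_subsets, "only %d subjects for %d subsets", ns, n_subsets)
    grp <- with_seed(seed, sample(rep_len(seq_len(n_subsets), ns)))
    subsets <- lapply(seq_len(n_subsets), function(s)
      do.call(cbind, voxel_series[grp == s]))
  } else {
    X <- as.matrix(voxel_series)
    Tn <- ncol(X)
    abort_if(Tn < 2L * n_subsets,
             "only %d timepoints; too few to split into %d subsets", Tn, n_subsets)
    brk <- floor(seq(0, Tn, length.out = n_subsets + 1L))
    subsets <- lapply(seq_len(n_subsets), function(s)
      X[, (brk[s] + 1L):brk[s + 1L], drop = FALSE])
  }
  parc <- lapply(seq_along(subsets), function(s)
    kmeans_parcellate(subsets[[s]], k, n_init = n_init, seed = seed + s))
  pairs <- utils::combn(n_subsets, 2L)
  dice <- apply(pairs, 2L, function(pr)
    matched_dice(parc[[pr[1L]]], parc[[pr[2L]]])$mean)
  list(mean_dice = mean(dice),
       pairwise = data.frame(a = pairs[1L, ], b = pairs[2L, ], dice = dice),
       parcellations = parc)
}

#' Two-stage (hierarchical) parcellation refinement
#'
#' Network-level K-means (k <= 22 as in the published sweep) optionally
#' refined by clustering within each network, yielding a finer region set
#' (e.g., 128 regions across 12 networks).  Controlled by `regions_total`.
#'
#' @param voxel_series voxels x time matrix.
#' @param k_networks network-level cluster count (e.g., 12).
#' @param regions_total if not NULL, total region count to distribute across
#'   networks proportionally to network size (each network >= 1 region).
#' @param seed,n_init as in [kmeans_parcellate()].
#' @return list(networks = parcellation_result, regions = integer labels in
#'   1..regions_total or NULL, region_network = network of each region).
#' @export
hierarchical_parcellate <- function(voxel_series, k_networks, regions_total = NULL,
                                    seed = 1L, n_init = 10L) {
  top <- kmeans_parcellate(voxel_series, k_networks, n_init = n_init, seed = seed)
  if (is.null(regions_total)) {
    return(list(networks = top, regions = NULL, region_network = NULL))
  }
  abort_if(regions_total < k_networks, "regions_total < k_networks")
  sizes <- tabulate(top$labels, k_networks)
  # proportional allocation, at least one region per network
  alloc <- pmax(1L, floor(regions_total * sizes / sum(sizes)))
  while (sum(alloc) < regions_total) {
    i <- which.max(sizes / alloc); alloc[i] <- alloc[i] + 1L
  }
  while (sum(alloc) > regions_total) {
    i <- which.max(ifelse(alloc > 1L, alloc / sizes, -Inf)); alloc[i] <- alloc[i] - 1L
  }
  regions <- rep(NA_integer_, length(top$labels))
  region_network <- integer(0)
  nxt <- 0L
  X <- as.matrix(voxel_series)
  for (c in seq_len(k_networks)) {
    idx <- which(top$labels == c)
    kc <- min(alloc[c], length(idx))
    if (kc <= 1L) {
      regions[idx] <- nxt + 1L
      kc <- 1L
    } else {
      sub <- kmeans_parcellate(X[idx, , drop = FALSE], kc, n_init = n_init,
                               seed = seed + 1000L + c)
      regions[idx] <- nxt + sub$labels
    }
    region_network <- c(region_network, rep(c, kc))
    nxt <- nxt + kc
  }
  list(networks = top, regions = regions, region_network = region_network)
}
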