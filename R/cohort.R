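# Synthetic multi-site, multi-group cohort generator with planted static and
# time-varying coupling, so every downstream stage has ground truth.

GROUPS <- c("CN", "SMC", "CI")
GRAY_NETS <- c("default mode", "visual", "somatomotor", "limbic",
               "frontoparietal control", "dorsal attention",
               "salience/ventral attention")

#' Cohort configuration
#'
#' @param n_cn,n_smc,n_ci subjects per diagnostic group (CN, SMC, CI).
#' @param n_gray,n_white gray/white node counts (defaults 200/128).
#' @param n_timepoints scan length in TRs (default 197).
#' @param tr_seconds repetition time (default 3 s).
#' @param n_sites number of acquisition sites (>= 1).
#' @param seed RNG seed; same config + seed gives a bit-identical cohort.
#' @param imbalance logical; if TRUE, n_ci is reset to
#'   `round(imbalance_ratio * n_smc)` emulating the ~8:1 CI:SMC skew.
#' @param imbalance_ratio CI:SMC ratio used when `imbalance` is TRUE.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_cn = 20L, n_smc = 20L, n_ci = 20L,
                          n_gray = 200L, n_white = 128L,
                          n_timepoints = 197L, tr_seconds = 3,
                          n_sites = 1L, seed = 1L,
                          imbalance = FALSE, imbalance_ratio = 8) {
  for (v in c(n_cn, n_smc, n_ci)) abort_if(!is_count(v, 0L), "group counts must be nonnegative integers")
  abort_if(!is_count(n_gray, 1L) || !is_count(n_white, 1L), "node counts must be positive")
  abort_if(!is_count(n_timepoints, 4L), "n_timepoints must be an integer >= 4")
  abort_if(tr_seconds <= 0, "tr_seconds must be positive")
  abort_if(!is_count(n_sites, 1L), "n_sites must be >= 1")
  if (imbalance) n_ci <- as.integer(round(imbalance_ratio * n_smc))
  structure(list(n_per_group = c(CN = as.integer(n_cn), SMC = as.integer(n_smc),
                                 CI = as.integer(n_ci)),
                 n_gray = as.integer(n_gray), n_white = as.integer(n_white),
                 n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds,
                 n_sites = as.integer(n_sites), seed = as.integer(seed)),
            class = "cohort_config")
}

#' Planted ground-truth structure for the cohort generator
#'
#' Static edges carry constant group-dependent coupling; dynamic edges carry a
#' group-dependent *modulation amplitude* on a sinusoidal (default) or
#' two-state Markov coupling schedule — the structure the sliding-window
#' SD-of-z statistic detects.  Clinical scale means are linear in the true
#' per-subject edge variability.
#'
#' @param static_edges data.frame(i, j, CN, SMC, CI): node index pair plus a
#'   coupling per group on the correlation scale (population correlation
#'   equals the coupling; |c| < 1).
#' @param dynamic_edges data.frame(i, j, CN, SMC, CI, period_tr): modulation
#'   amplitude per group (peak |correlation|, in [0, 1)) and schedule period
#'   in TRs (>= 2).
#' @param schedule "sinusoid" or "markov" (two-state on/off switching with
#'   mean dwell time `period_tr/2`).
#' @param amp_sd between-subject SD of the modulation amplitude around its
#'   group mean (truncated at 0).  Nonzero heterogeneity is what makes the
#'   clinical-scale loadings recoverable from measured variability.
#' @param noise_sd idiosyncratic noise SD (> 0).
#' @param site_offset_sd,site_scale_sd feature-level batch effect sizes:
#'   per-site additive offsets ~ N(0, site_offset_sd) and multiplicative
#'   log-scales ~ N(0, site_scale_sd), drawn per feature by
#'   [apply_site_effects()].
#' @param scale_loadings named numeric: correlation-scale loading of the first
#'   dynamic edge's true variability on mmse/moca/cdr_sb (|loading| < 1).
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(static_edges = NULL, dynamic_edges = NULL,
                         schedule = c("sinusoid", "markov"),
                         amp_sd = 0.25, noise_sd = 1,
                         site_offset_sd = 0, site_scale_sd = 0,
                         scale_loadings = c(mmse = 0, moca = 0, cdr_sb = 0)) {
  schedule <- match.arg(schedule)
  abort_if(noise_sd <= 0, "noise_sd must be positive, got %g", noise_sd)
  chk <- function(df, dyn) {
    if (is.null(df)) return(df)
    need <- c("i", "j", GROUPS, if (dyn) "period_tr")
    abort_if(!all(need %in% names(df)), "edge table needs columns: %s",
             paste(need, collapse = ", "))
    abort_if(anyDuplicated(paste(pmin(df$i, df$j), pmax(df$i, df$j))) > 0,
             "each pair may be listed once per set")
    if (dyn) {
      abort_if(any(df$period_tr < 2), "modulation period < 2 TRs is sub-Nyquist")
      abort_if(any(df[GROUPS] < 0), "modulation amplitudes must be >= 0")
      abort_if(any(df[GROUPS] >= 1), "amplitudes are peak correlations; need < 1")
    } else {
      abort_if(any(abs(df[GROUPS]) >= 1), "couplings are correlations; need |c| < 1")
    }
    df
  }
  sl <- c(mmse = 0, moca = 0, cdr_sb = 0)
  sl[names(scale_loadings)] <- scale_loadings
  abort_if(any(abs(sl) >= 1), "scale loadings must have |loading| < 1")
  structure(list(static_edges = chk(static_edges, FALSE),
                 dynamic_edges = chk(dynamic_edges, TRUE),
                 schedule = schedule, amp_sd = amp_sd, noise_sd = noise_sd,
                 site_offset_sd = site_offset_sd, site_scale_sd = site_scale_sd,
                 scale_loadings = sl),
            class = "ground_truth")
}

#' Atlas bookkeeping: nodes -> (tissue, subnetwork)
#'
#' Gray nodes `g001..` are split into 7 contiguous near-equal subnetwork
#' blocks (named after the 7 cortical networks); white nodes `w001..` into 12
#' blocks WM1-WM12.
#'
#' @param n_gray,n_white node counts.
#' @return data.frame(node_id, tissue, subnetwork), class `atlas_map`.
#' @export
atlas_map <- function(n_gray = 200L, n_white = 128L) {
  abort_if(n_gray < 7L, "need >= 7 gray nodes for 7 subnetworks")
  abort_if(n_white < 12L, "need >= 12 white nodes for 12 subnetworks")
  blocks <- function(n, k, labels) {
    sizes <- diff(floor(seq(0, n, length.out = k + 1L)))
    rep(labels, times = sizes)
  }
  out <- data.frame(
    node_id = c(sprintf("g%03d", seq_len(n_gray)), sprintf("w%03d", seq_len(n_white))),
    tissue = rep(c("gray", "white"), c(n_gray, n_white)),
    subnetwork = c(blocks(n_gray, 7L, GRAY_NETS),
                   blocks(n_white, 12L, sprintf("WM%d", 1:12))),
    stringsAsFactors = FALSE)
  class(out) <- c("atlas_map", "data.frame")
  out
}

# Coupling schedule m(t) in [-1, 1] (sinusoid) or {0, 1} (markov)
coupling_schedule <- function(schedule, Tn, period, phase = 0) {
  if (schedule == "sinusoid") {
    sin(2 * pi * seq_len(Tn) / period + phase)
  } else {
    # two-state switching, mean dwell period/2, started in a random state
    p_flip <- min(1, 2 / period)
    s <- integer(Tn)
    s[1L] <- stats::rbinom(1L, 1L, 0.5)
    flips <- stats::runif(Tn - 1L) < p_flip
    for (t in 2L:Tn) s[t] <- if (flips[t - 1L]) 1L - s[t - 1L] else s[t - 1L]
    as.numeric(s)
  }
}

# Couplings are parameterized on the correlation scale: a planted coupling c
# (|c| < 1) yields population correlation exactly c between the two nodes via
# shared-factor loadings +-sigma*sqrt(|c|/(1-|c|)) (sign carried by node i).
coupling_loading <- function(c, noise_sd) noise_sd * sqrt(abs(c) / (1 - abs(c)))

# Theoretical z(t) trace of a dynamic edge: r(t) = c(t), so z(t) = atanh(c(t));
# its SD over t is the subject's "true variability" used for clinical scales.
true_edge_variability <- function(amp, sched) {
  z <- fisher_z(amp * sched)
  stats::sd(z) * sqrt((length(z) - 1) / length(z))
}

#' Generate a synthetic multi-group, multi-site cohort
#'
#' Each subject's node signals follow a latent-factor model
#' `x_i(t) = sum_e a_ie(t) f_e(t) + eps_i(t)`: every planted edge contributes
#' a shared standard-normal factor loaded on both of its nodes, with a
#' constant loading for static edges and a time-modulated loading (amplitude
#' times schedule) for dynamic edges.  Modulation amplitudes get per-subject
#' heterogeneity (SD `amp_sd`) and, for sinusoids, a random phase.  Clinical
#' scales are generated as `loading * z(true variability) + sqrt(1-loading^2)
#' * noise`, mapped affinely onto realistic group-specific score ranges.
#'
#' @param config a [cohort_config()].
#' @param truth a [ground_truth()].
#' @return list with `series` (list of [node_ts()]), `meta` (subject table:
#'   subject_id, group, site, apoe4, abeta, mmse, moca, cdr_sb), `atlas`
#'   ([atlas_map()]), and `truth_vars` (per-subject true variability of each
#'   dynamic edge, subjects x edges).
#' @export
generate_cohort <- function(config, truth = ground_truth()) {
  stopifnot(inherits(config, "cohort_config"), inherits(truth, "ground_truth"))
  p <- config$n_gray + config$n_white
  for (df in list(truth$static_edges, truth$dynamic_edges))
    if (!is.null(df)) abort_if(any(df$i > p | df$j > p | df$i < 1 | df$j < 1),
                               "truth node index outside 1..%d", p)
  Tn <- config$n_timepoints
  atlas <- atlas_map(config$n_gray, config$n_white)
  grp <- rep(GROUPS, times = config$n_per_group)
  n <- length(grp)
  abort_if(n == 0L, "empty cohort")
  # group-level risk factor prevalences (ADNI-like)
  p_apoe <- c(CN = 0.30, SMC = 0.34, CI = 0.57)
  p_abeta <- c(CN = 0.25, SMC = 0.30, CI = 0.40)
  sc_means <- list(mmse = c(CN = 29.0, SMC = 28.9, CI = 25.8),
                   moca = c(CN = 26.0, SMC = 25.5, CI = 21.5),
                   cdr_sb = c(CN = 0.05, SMC = 0.21, CI = 2.68))
  sc_sd <- c(mmse = 1.2, moca = 2.0, cdr_sb = 1.5)

  nd <- if (is.null(truth$dynamic_edges)) 0L else nrow(truth$dynamic_edges)
  with_seed(config$seed, {
    site <- rep_len(seq_len(config$n_sites), n)[sample.int(n)]
    apoe4 <- stats::rbinom(n, 1L, p_apoe[grp])
    abeta <- stats::rbinom(n, 1L, p_abeta[grp])
    series <- vector("list", n)
    tv <- matrix(0, n, max(nd, 1L))
    for (s in seq_len(n)) {
      X <- matrix(stats::rnorm(p * Tn, sd = truth$noise_sd), p, Tn)
      g <- grp[s]
      if (!is.null(truth$static_edges)) {
        se <- truth$static_edges
        for (e in seq_len(nrow(se))) {
          cc <- se[[g]][e]
          if (cc != 0) {
            f <- stats::rnorm(Tn)
            l <- coupling_loading(cc, truth$noise_sd)
            X[se$i[e], ] <- X[se$i[e], ] + sign(cc) * l * f
            X[se$j[e], ] <- X[se$j[e], ] + l * f
          }
        }
      }
      if (nd > 0L) {
        de <- truth$dynamic_edges
        for (e in seq_len(nd)) {
          amp <- de[[g]][e]
          if (amp > 0) amp <- min(0.95, max(0.02, amp + stats::rnorm(1L, 0, truth$amp_sd)))
          phase <- stats::runif(1L, 0, 2 * pi)
          sched <- coupling_schedule(truth$schedule, Tn, de$period_tr[e], phase)
          tv[s, e] <- true_edge_variability(amp, sched)
          if (amp > 0) {
            f <- stats::rnorm(Tn)
            ct <- amp * sched
            l <- coupling_loading(ct, truth$noise_sd)
            X[de$i[e], ] <- X[de$i[e], ] + sign(ct) * l * f
            X[de$j[e], ] <- X[de$j[e], ] + l * f
          }
        }
      }
      series[[s]] <- node_ts(X, config$tr_seconds, atlas$node_id,
                             subject_id = sprintf("sub%04d", s))
    }
    # clinical scales: loading on the FIRST dynamic edge's true variability
    zv <- if (nd > 0L && n > 1L && stats::sd(tv[, 1L]) > 0)
      as.vector(scale(tv[, 1L])) else rep(0, n)
    mk_scale <- function(name) {
      lam <- truth$scale_loadings[[name]]
      lat <- lam * zv + sqrt(1 - lam^2) * stats::rnorm(n)
      round(sc_means[[name]][grp] + sc_sd[[name]] * lat, 1)
    }
    meta <- data.frame(subject_id = vapply(series, function(x) x$subject_id, ""),
                       group = grp, site = site, apoe4 = apoe4, abeta = abeta,
                       mmse = mk_scale("mmse"), moca = mk_scale("moca"),
                       cdr_sb = pmax(0, mk_scale("cdr_sb")),
                       stringsAsFactors = FALSE)
    list(series = series, meta = meta, atlas = atlas,
         truth_vars = if (nd > 0L) tv else NULL)
  })
}

#' Inject feature-level site batch effects
#'
#' Correlation features are invariant to affine transforms of the raw
#' signals, so batch effects are planted on the assembled feature table:
#' feature k at site s becomes `scale_sk * x + offset_sk`, with offsets
#' ~ N(0, site_offset_sd) and log-scales ~ N(0, site_scale_sd) drawn per
#' (site, feature).
#'
#' @param features subjects x features numeric matrix/data.frame.
#' @param site integer/character site label per subject.
#' @param truth a [ground_truth()] carrying the effect-size parameters.
#' @param seed RNG seed for the effect draws.
#' @return matrix of the same shape with batch effects applied.
#' @export
apply_site_effects <- function(features, site, truth, seed = 1L) {
  X <- as.matrix(features)
  sites <- sort(unique(site))
  with_seed(seed, {
    for (s in sites) {
      off <- stats::rnorm(ncol(X), 0, truth$site_offset_sd)
      scl <- exp(stats::rnorm(ncol(X), 0, truth$site_scale_sd))
      idx <- site == s
      X[idx, ] <- sweep(sweep(X[idx, , drop = FALSE], 2L, scl, "*"), 2L, off, "+")
    }
    X
  })
}

#' Synthetic voxel grid with planted cluster structure
#'
#' Voxels in the same true cluster share a latent standard-normal signal
#' scaled by `separation`, plus unit idiosyncratic noise — the fixture for
#' K-means white-matter parcellation and its Dice validation.
#'
#' @param n_voxels,n_clusters grid size; `n_clusters >= 2`, `<= n_voxels`.
#' @param separation latent signal scale (>= 0); 0 means pure noise.
#' @param n_timepoints series length.
#' @param seed RNG seed.
#' @return list(series = voxels x time matrix, labels = true cluster ids).
#' @export
generate_voxel_grid <- function(n_voxels, n_clusters, separation,
                                n_timepoints, seed = 1L) {
  abort_if(!is_count(n_clusters, 2L), "n_clusters must be >= 2")
  abort_if(n_clusters > n_voxels, "n_clusters %d > n_voxels %d", n_clusters, n_voxels)
  abort_if(separation < 0, "separation must be >= 0")
  with_seed(seed, {
    labels <- rep_len(seq_len(n_clusters), n_voxels)
    lat <- matrix(stats::rnorm(n_clusters * n_timepoints), n_clusters)
    X <- separation * lat[labels, , drop = FALSE] +
      matrix(stats::rnorm(n_voxels * n_timepoints), n_voxels)
    rownames(X) <- sprintf("v%04d", seq_len(n_voxels))
    list(series = X, labels = labels)
  })
}
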