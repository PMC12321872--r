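# End-to-end orchestration: simulate -> connect -> features -> stats ->
# classify, with a manifest recording seeds, hashes and stage timings.

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf("[dynconn %s] %s", format(Sys.time(), "%H:%M:%S"),
                              sprintf(fmt, ...)))
}

#' Run the full pipeline from a validated config
#'
#' Stages run in dependency order; any stage failure aborts with the stage
#' name and cause.  Re-running the same config reproduces byte-identical
#' numeric outputs (all randomness flows through the per-stage seeds).
#'
#' @param cfg a `pipeline_config` (see [read_pipeline_config()]); the
#'   `cohort` entry supplies [cohort_config()] arguments, `truth` (optional)
#'   supplies [ground_truth()] arguments.
#' @param quiet suppress progress logging.
#' @return manifest list (also written to `manifest.json` under `out_dir`):
#'   config echo, per-stage seeds, output files with MD5 hashes, timings,
#'   package version.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  cfg <- validate_pipeline_config(unclass(cfg))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(version = as.character(utils::packageVersion("dynconn")),
                   config = unclass(cfg), stages = list(), files = character(0))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    log_stage(quiet, "stage %s ...", name)
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                                     seed = cfg$seeds[[name]])
    res
  }

  cohort <- stage("simulate", {
    cc <- do.call(cohort_config, c(cfg$cohort, list(seed = cfg$seeds$simulate)))
    gt <- if (!is.null(cfg$truth)) do.call(ground_truth, cfg$truth) else ground_truth()
    ch <- generate_cohort(cc, gt)
    write_cohort_tables(ch$meta, ch$atlas, cfg$out_dir)
    ts_dir <- file.path(cfg$out_dir, "timeseries")
    dir.create(ts_dir, showWarnings = FALSE)
    for (s in ch$series) write_timeseries(s, file.path(ts_dir, paste0(s$subject_id, ".tsv")))
    jsonlite::write_json(list(schedule = gt$schedule,
                              static_edges = gt$static_edges,
                              dynamic_edges = gt$dynamic_edges,
                              scale_loadings = as.list(gt$scale_loadings)),
                         file.path(cfg$out_dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    ch
  })

  specs <- parse_window_code(cfg$windows)
  conn <- stage("connect", {
    lapply(cohort$series, function(ts) {
      sfc <- static_fc(ts)
      dfc <- lapply(specs, function(sp) dynamic_fc(ts, sp))
      list(sfc = sfc, dfc = dfc)
    })
  })
  # per-window edge feature tables (subjects x edges, DFC SD-of-z)
  edge_feats <- lapply(names(specs), function(wn) {
    t(vapply(conn, function(x) upper_vec(x$dfc[[wn]]$values),
             numeric(length(upper_vec(conn[[1L]]$sfc$values)))))
  })
  names(edge_feats) <- names(specs)
  pr <- upper_pairs(length(cohort$atlas$node_id))
  enames <- edge_names(cohort$atlas$node_id, pr)
  for (wn in names(edge_feats)) {
    colnames(edge_feats[[wn]]) <- enames
    df <- data.frame(node_i = cohort$atlas$node_id[pr[, 1L]],
                     node_j = cohort$atlas$node_id[pr[, 2L]],
                     t(edge_feats[[wn]]), check.names = FALSE)
    utils::write.table(df, file.path(cfg$out_dir, sprintf("edges_%s.tsv", wn)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  feats <- stage("stats", {
    wn <- names(specs)[1L]
    Fm <- edge_feats[[wn]]
    if (cfg$combat && length(unique(cohort$meta$site)) > 1L)
      Fm <- combat(Fm, cohort$meta$site,
                   covariates = data.frame(group = cohort$meta$group))
    groups <- split(seq_len(nrow(Fm)), cohort$meta$group)
    pairs <- utils::combn(names(groups), 2L)
    for (cpair in seq_len(ncol(pairs))) {
      a <- pairs[1L, cpair]; b <- pairs[2L, cpair]
      dc <- differential_connections(Fm[groups[[a]], , drop = FALSE],
                                     Fm[groups[[b]], , drop = FALSE],
                                     alpha = cfg$alpha, group_pair = c(a, b))
      utils::write.table(dc$entries,
                         file.path(cfg$out_dir, sprintf("diff_%s_vs_%s_%s.tsv", a, b, wn)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ch <- chord_aggregate(dc, cohort$atlas)
      write_matrix_tsv(ch, file.path(cfg$out_dir, sprintf("chord_%s_vs_%s_%s.tsv", a, b, wn)))
    }
    sc <- scale_correlations(Fm[, utils::head(order(-apply(Fm, 2L, stats::var)), 50L),
                                drop = FALSE],
                             cohort$meta[, c("mmse", "moca", "cdr_sb")])
    utils::write.table(sc, file.path(cfg$out_dir, "correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    Fm
  })

  stage("classify", {
    keep <- cohort$meta$group %in% c("CN", "CI")
    if (sum(keep) >= 2L * cfg$folds && length(unique(cohort$meta$group[keep])) == 2L) {
      spec <- model_spec("linear", smote = cfg$smote)
      rep <- cross_validate(feats[keep, , drop = FALSE], cohort$meta$group[keep],
                            spec, folds = cfg$folds, seed = cfg$seeds$classify,
                            positive = "CI")
      jsonlite::write_json(list(accuracy = unname(rep$aggregate["accuracy", "mean"]),
                                accuracy_sd = unname(rep$aggregate["accuracy", "sd"]),
                                sensitivity = unname(rep$aggregate["sensitivity", "mean"]),
                                specificity = unname(rep$aggregate["specificity", "mean"]),
                                auc = rep$auc, folds = rep$folds, seed = rep$seed),
                           file.path(cfg$out_dir, "cv_report.json"),
                           auto_unbox = TRUE, digits = NA)
      utils::write.table(rep$roc_curve, file.path(cfg$out_dir, "roc_points.csv"),
                         sep = ",", quote = FALSE, row.names = FALSE)
      utils::write.table(rep$confusion, file.path(cfg$out_dir, "confusion.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
      rep
    } else NULL
  })

  files <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$files <- data.frame(path = sub(paste0("^", cfg$out_dir, "/?"), "", files),
                               md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_stage(quiet, "done: %d files in %s", nrow(manifest$files), cfg$out_dir)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `simulate --config FILE [--out DIR] [--seed N]`,
#' `parcellate --in voxels.tsv --k K [--subsets N] [--seed N] --out DIR`,
#' `run --config FILE`, `--version`.  Installed as `exec/dynconn`.
#'
#' @param argv character vector of arguments (default: command line).
#' @return exit status (0 on success), invisibly.
#' @export
dynconn_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L || argv[1L] %in% c("--help", "-h")) {
    cat("usage: dynconn <simulate|parcellate|run> [options] | --version\n")
    return(invisible(0L))
  }
  if (argv[1L] == "--version") {
    cat(sprintf("dynconn %s\n", utils::packageVersion("dynconn")))
    return(invisible(0L))
  }
  opt <- function(flag, default = NULL) {
    i <- which(argv == flag)
    if (length(i) == 1L && i < length(argv)) argv[i + 1L] else default
  }
  cmd <- argv[1L]
  status <- tryCatch({
    switch(cmd,
      simulate = {
        cfg <- read_pipeline_config(opt("--config"))
        out <- opt("--out"); if (!is.null(out)) cfg$out_dir <- out
        seed <- opt("--seed"); if (!is.null(seed)) cfg$seeds$simulate <- as.integer(seed)
        cc <- do.call(cohort_config, c(cfg$cohort, list(seed = cfg$seeds$simulate)))
        gt <- if (!is.null(cfg$truth)) do.call(ground_truth, cfg$truth) else ground_truth()
        ch <- generate_cohort(cc, gt)
        dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
        write_cohort_tables(ch$meta, ch$atlas, cfg$out_dir)
        ts_dir <- file.path(cfg$out_dir, "timeseries")
        dir.create(ts_dir, showWarnings = FALSE)
        for (s in ch$series)
          write_timeseries(s, file.path(ts_dir, paste0(s$subject_id, ".tsv")))
        0L
      },
      parcellate = {
        X <- as.matrix(read_table_tsv(opt("--in")))
        k <- as.integer(opt("--k", "12"))
        ns <- as.integer(opt("--subsets", "4"))
        seed <- as.integer(opt("--seed", "1"))
        out <- opt("--out", ".")
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        rep <- subset_reproducibility(X, k, n_subsets = ns, seed = seed)
        parc <- kmeans_parcellate(X, k, seed = seed)
        utils::write.table(data.frame(voxel_id = names(parc$labels),
                                      cluster = parc$labels),
                           file.path(out, "parcellation.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(list(k = k, n_subsets = ns,
                                  mean_dice = rep$mean_dice,
                                  pairwise = rep$pairwise),
                             file.path(out, "dice_report.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
        cat(sprintf("mean matched Dice over %d subset pairs: %.3f\n",
                    nrow(rep$pairwise), rep$mean_dice))
        0L
      },
      run = {
        run_pipeline(read_pipeline_config(opt("--config")))
        0L
      },
      { cat(sprintf("unknown subcommand '%s'\n", cmd)); 2L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
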