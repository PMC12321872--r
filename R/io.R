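# File I/O contracts: TSV everywhere with documented columns, JSON for
# reports and the manifest, YAML or JSON for configs.

#' Write / read one subject's node time series
#'
#' TSV with a header row of node IDs; rows are timepoints, "."-decimal,
#' UTF-8.
#'
#' @param ts a [node_ts()].
#' @param path output file.
#' @return `write_timeseries` the path invisibly; `read_timeseries` a
#'   [node_ts()].
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "node_ts"))
  df <- as.data.frame(t(ts$data))
  colnames(df) <- ts$node_ids
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @param tr_seconds TR of the stored series (TSVs do not carry it).
#' @param nodes optional [atlas_map()] / nodes table to validate the header
#'   against; mismatches are errors listing the difference.
#' @param subject_id subject identifier.
#' @export
read_timeseries <- function(path, tr_seconds, nodes = NULL, subject_id = NULL) {
  abort_if(!file.exists(path), "no such file: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  abort_if(length(lines) < 2L, "%s: no data rows", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  ncol_exp <- length(header)
  rows <- lapply(seq.int(2L, length(lines)), function(ln) {
    cells <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    abort_if(length(cells) != ncol_exp, "%s: line %d has %d fields, expected %d",
             path, ln, length(cells), ncol_exp)
    v <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(v) | !is.finite(v))
    abort_if(length(bad) > 0L, "%s: line %d, column '%s': non-numeric or non-finite cell",
             path, ln, header[bad[1L]])
    v
  })
  X <- t(do.call(rbind, rows))          # nodes x timepoints
  rownames(X) <- header
  if (!is.null(nodes)) {
    want <- if (inherits(nodes, "atlas_map") || is.data.frame(nodes)) nodes$node_id else nodes
    extra <- setdiff(header, want); miss <- setdiff(want, header)
    abort_if(length(extra) + length(miss) > 0L,
             "%s: node set mismatch (missing: %s; unexpected: %s)", path,
             paste(utils::head(miss, 5L), collapse = ","),
             paste(utils::head(extra, 5L), collapse = ","))
    X <- X[want, , drop = FALSE]
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.tsv$", "", basename(path))
  node_ts(X, tr_seconds, rownames(X), subject_id)
}

#' Write cohort metadata tables
#'
#' `subjects.tsv`: subject_id, group, site, apoe4, abeta, mmse, moca,
#' cdr_sb.  `nodes.tsv`: node_id, tissue, subnetwork.
#'
#' @param meta,atlas tables from [generate_cohort()].
#' @param dir output directory.
#' @return paths invisibly.
#' @export
write_cohort_tables <- function(meta, atlas, dir) {
  ps <- file.path(dir, "subjects.tsv"); pn <- file.path(dir, "nodes.tsv")
  utils::write.table(meta, ps, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(atlas, pn, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(ps, pn))
}

#' @rdname write_cohort_tables
#' @param path a TSV written by [write_cohort_tables()].
#' @export
read_table_tsv <- function(path) {
  abort_if(!file.exists(path), "no such file: %s", path)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a symmetric matrix as square TSV (node IDs as header and rownames)
#' @param m matrix or fc container.
#' @param path output file.
#' @export
write_matrix_tsv <- function(m, path) {
  if (inherits(m, c("fc_matrix", "dfc_variability"))) m <- m$values
  utils::write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Read/validate a pipeline configuration (YAML or JSON)
#'
#' Required fields: `out_dir`, `windows` (codes like "gau20"), `alpha`,
#' `density`, `folds`, `seeds` (named list with simulate/parcellate/connect/
#' stats/classify entries — every random stage must carry an explicit seed),
#' `cohort` (arguments to [cohort_config()] minus seed), and toggles
#' `combat`, `smote`.
#'
#' @param path config file ending in .yaml/.yml or .json.
#' @return validated config list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  abort_if(!file.exists(path), "no such file: %s", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    abort_if(!requireNamespace("yaml", quietly = TRUE), "yaml package unavailable")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg a config list.
#' @export
validate_pipeline_config <- function(cfg) {
  need <- c("out_dir", "windows", "alpha", "density", "folds", "seeds", "cohort")
  miss <- setdiff(need, names(cfg))
  abort_if(length(miss) > 0L, "config missing field(s): %s", paste(miss, collapse = ", "))
  stages <- c("simulate", "connect", "stats", "classify")
  sm <- setdiff(stages, names(cfg$seeds))
  abort_if(length(sm) > 0L, "config missing seed(s) for stage(s): %s",
           paste(sm, collapse = ", "))
  for (s in stages) abort_if(!is_count(cfg$seeds[[s]], 0L), "seed for '%s' must be an integer", s)
  cfg$combat <- isTRUE(cfg$combat)
  cfg$smote <- isTRUE(cfg$smote)
  structure(cfg, class = "pipeline_config")
}

#' Round-trip a config to disk
#' @param cfg config list.
#' @param path .json or .yaml target.
#' @export
write_pipeline_config <- function(cfg, path) {
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(unclass(cfg), path)
  else jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE,
                            digits = NA)
  invisible(path)
}
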