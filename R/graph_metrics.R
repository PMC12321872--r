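# Graph-theory feature extraction from FC matrices and per-window stacks.
# The published classifier rows ("static/dynamic graph theory") never
# enumerate their metric list; the implemented set is a documented superset:
# per-node strength, weighted clustering, local efficiency; global
# characteristic path length, global efficiency and modularity Q.

#' Proportional threshold of an FC matrix
#'
#' Keeps the top `density` fraction of edges ranked by |z| (the retained
#' edges keep their z values); ties at the cutoff are broken by (i, j)
#' lexicographic order so the result is deterministic.  Negative-weight
#' surviving edges are dropped afterwards (standard practice for
#' graph-metric computation on FC).
#'
#' @param fc an `fc_matrix` or symmetric numeric matrix (zero diagonal).
#' @param density fraction of edges to keep, in (0, 1].
#' @param drop_negative drop surviving negative-z edges (default TRUE).
#' @return symmetric weighted adjacency matrix.
#' @export
threshold_graph <- function(fc, density, drop_negative = TRUE) {
  m <- if (inherits(fc, c("fc_matrix", "dfc_variability"))) fc$values else fc
  abort_if(!is.numeric(density) || density <= 0 || density > 1,
           "density must be in (0, 1], got %g", density)
  p <- nrow(m)
  pr <- upper_pairs(p)
  vals <- m[pr]
  n_keep <- floor(density * nrow(pr) + 1e-9)
  abort_if(n_keep < 1L, "density %g keeps < 1 of %d edges", density, nrow(pr))
  ord <- order(-abs(vals), pr[, 1L], pr[, 2L])
  keep <- ord[seq_len(n_keep)]
  adj <- matrix(0, p, p, dimnames = dimnames(m))
  adj[pr[keep, , drop = FALSE]] <- vals[keep]
  if (drop_negative) adj[adj < 0] <- 0
  adj + t(adj)
}

as_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", weighted = TRUE,
                                      diag = FALSE)
}

#' Graph metrics of a weighted adjacency matrix
#'
#' Per-node: strength (weighted degree), weighted clustering coefficient
#' (Barrat generalization of Watts-Strogatz), local efficiency.  Global:
#' characteristic path length (shortest paths on 1/weight lengths, computed
#' on the largest connected component and flagged when the graph is
#' disconnected), global efficiency (mean of 1/d over ordered pairs,
#' unreachable pairs contributing 0), and modularity Q from seeded Louvain
#' (best of `n_restarts`).
#'
#' @param adj symmetric nonnegative weighted adjacency (zero diagonal).
#' @param seed seed for the modularity optimizer.
#' @param n_restarts Louvain restarts (default 10).
#' @return A `graph_feature_set`: list(node = data.frame(strength,
#'   clustering, local_efficiency), global = named numeric(char_path_length,
#'   global_efficiency, modularity), disconnected flag, membership).
#' @export
compute_metrics <- function(adj, seed = 1L, n_restarts = 10L) {
  abort_if(!is.matrix(adj) || nrow(adj) != ncol(adj), "adjacency must be square")
  abort_if(any(adj < 0), "adjacency must be nonnegative (threshold first)")
  abort_if(sum(adj) == 0, "empty graph: no edges")
  g <- as_graph(adj)
  w <- igraph::E(g)$weight
  strength <- igraph::strength(g)
  cl <- igraph::transitivity(g, type = "weighted", isolates = "zero")
  le <- igraph::local_efficiency(g, weights = 1 / w)
  D <- igraph::distances(g, weights = 1 / w)
  comp <- igraph::components(g)
  disconnected <- comp$no > 1L
  if (disconnected) {
    big <- which(comp$membership == which.max(comp$csize))
    Dc <- D[big, big, drop = FALSE]
  } else Dc <- D
  cpl <- mean(Dc[upper.tri(Dc)])
  inv <- 1 / D; diag(inv) <- 0; inv[!is.finite(inv)] <- 0
  geff <- sum(inv) / (nrow(D) * (nrow(D) - 1L))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    cm <- with_seed(seed + r - 1L, igraph::cluster_louvain(g, weights = w))
    if (is.null(best) || igraph::modularity(cm) > igraph::modularity(best)) best <- cm
  }
  structure(list(
    node = data.frame(strength = as.numeric(strength),
                      clustering = as.numeric(cl),
                      local_efficiency = as.numeric(le),
                      row.names = rownames(adj)),
    global = c(char_path_length = cpl, global_efficiency = geff,
               modularity = igraph::modularity(best)),
    disconnected = disconnected,
    membership = igraph::membership(best)),
    class = "graph_feature_set")
}

# Flatten a graph_feature_set into a named numeric vector with a namespace
# prefix; node metrics are summarized by their mean over nodes, plus the
# full per-node values when per_node = TRUE.
flatten_metrics <- function(gfs, prefix, per_node = FALSE) {
  out <- c(gfs$global,
           strength_mean = mean(gfs$node$strength),
           clustering_mean = mean(gfs$node$clustering),
           local_efficiency_mean = mean(gfs$node$local_efficiency))
  if (per_node) {
    for (col in names(gfs$node)) {
      v <- gfs$node[[col]]
      names(v) <- paste0(col, ".", rownames(gfs$node))
      out <- c(out, v)
    }
  }
  names(out) <- paste0(prefix, ".", names(out))
  out
}

#' Dynamic graph metrics from a per-window z stack
#'
#' Computes [compute_metrics()] on each window's thresholded matrix and
#' summarizes every metric by its mean (`dyn_mean.*`) and SD (`dyn_sd.*`)
#' across windows ("dynamic graph theory" features such as modularity and
#' path-length variability).
#'
#' @param dfc a [dynamic_fc()] result built with `keep_stack = TRUE`, or a
#'   list of symmetric matrices (one per window).
#' @param density proportional threshold per window (default 0.15).
#' @param seed modularity seed.
#' @param sd_divisor "n" (population, default) or "n-1".
#' @return named numeric vector of `dyn_mean.*` and `dyn_sd.*` features.
#' @export
dynamic_metrics <- function(dfc, density = 0.15, seed = 1L,
                            sd_divisor = c("n", "n-1")) {
  sd_divisor <- match.arg(sd_divisor)
  if (inherits(dfc, "dfc_variability")) {
    abort_if(is.null(dfc$z_stack), "dynamic_fc must be run with keep_stack = TRUE")
    p <- length(dfc$node_ids)
    mats <- lapply(seq_len(nrow(dfc$z_stack)), function(k) {
      m <- matrix(0, p, p, dimnames = list(dfc$node_ids, dfc$node_ids))
      m[dfc$pairs] <- dfc$z_stack[k, ]
      m + t(m)
    })
  } else mats <- dfc
  abort_if(length(mats) < 2L, "need >= 2 windows, got %d", length(mats))
  per <- lapply(mats, function(m)
    flatten_metrics(compute_metrics(threshold_graph(m, density), seed = seed), "w"))
  M <- do.call(rbind, per)
  mu <- colMeans(M)
  W <- nrow(M)
  sdv <- apply(M, 2L, stats::sd)
  if (sd_divisor == "n") sdv <- sdv * sqrt((W - 1) / W)
  nm <- sub("^w\\.", "", colnames(M))
  stats::setNames(c(mu, sdv), c(paste0("dyn_mean.", nm), paste0("dyn_sd.", nm)))
}

#' Static + dynamic graph feature vector for one subject
#'
#' @param sfc an `fc_matrix` (static features, prefix `static.`).
#' @param dfc optional [dynamic_fc()] stack result for dynamic features.
#' @param density proportional threshold.
#' @param seed modularity seed.
#' @return named numeric feature vector.
#' @export
graph_features <- function(sfc, dfc = NULL, density = 0.15, seed = 1L) {
  out <- flatten_metrics(compute_metrics(threshold_graph(sfc, density),
                                         seed = seed), "static")
  if (!is.null(dfc)) out <- c(out, dynamic_metrics(dfc, density, seed))
  out
}
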