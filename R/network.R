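#' Pairwise Pearson similarity matrix over selected features
#'
#' @param norm a `normalized_matrix` or plain matrix (features x samples).
#' @param features feature ids to include (e.g. the relaxed-regime DE list).
#' @param samples sample ids defining the group (e.g. one group's tumor
#'   samples).
#' @param group optional group label carried through to downstream objects.
#' @return a `similarity_matrix`: symmetric matrix of Pearson r with unit
#'   diagonal; constant features get r = 0 against all others (with a
#'   warning).
#' @export
similarity_matrix <- function(norm, features, samples, group = NULL) {
  x <- if (inherits(norm, "normalized_matrix")) norm$log_expr else norm
  missing_f <- setdiff(features, rownames(x))
  if (length(missing_f)) {
    stopf("feature(s) absent from the matrix: %s", paste(missing_f, collapse = ", "))
  }
  missing_s <- setdiff(samples, colnames(x))
  if (length(missing_s)) {
    stopf("sample(s) absent from the matrix: %s", paste(missing_s, collapse = ", "))
  }
  if (length(samples) < 3) stopf("need at least 3 samples for correlations")
  sub <- x[features, samples, drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  r <- suppressWarnings(stats::cor(t(sub)))
  if (any(sds == 0)) {
    warnf("constant feature(s) set to r = 0: %s",
          paste(features[sds == 0], collapse = ", "))
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 1
  structure(r, class = c("similarity_matrix", "matrix"), group = group)
}

# mean local clustering coefficient of a 0/1 adjacency matrix, averaging
# over ALL nodes with local CC defined as 0 for degree < 2
# (network-analyzer convention)
local_cc_mean <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(NA_real_)
  k <- rowSums(adj)
  tri <- rowSums((adj %*% adj) * adj)  # = diag(A^3): twice the edges among neighbours
  cc <- ifelse(k < 2, 0, tri / (k * (k - 1)))
  mean(cc)
}

# adjacency of an Erdos-Renyi G(n, m) draw
random_gnm_adj <- function(n, m, pair_idx) {
  pick <- pair_idx[sample.int(nrow(pair_idx), m), , drop = FALSE]
  adj <- matrix(0, n, n)
  adj[pick] <- 1
  adj + t(adj)
}

#' Similarity-threshold selection by the clustering-coefficient criterion
#'
#' For every candidate threshold tau the graph with edges `r >= tau`
#' (signed r, isolated nodes dropped) is compared with Erdos-Renyi random
#' graphs of identical node and edge counts: the criterion curve is the
#' observed mean local clustering coefficient minus the random-graph mean.
#' The raw difference curve is noisy at desk-scale sample sizes (both the
#' observed clustering coefficient and the Monte-Carlo random reference
#' fluctuate between adjacent grid points), so the selection works on a
#' centered 3-point moving average of the difference: the selected tau is
#' the first interior local maximum of the smoothed curve scanning
#' ascending tau among thresholds retaining at least `min_nodes` nodes; if
#' no interior local maximum exists, the global maximum; ties resolve to
#' the smallest tau.  The returned scan keeps both the raw and the smoothed
#' curve.
#'
#' @param sim a `similarity_matrix`.
#' @param grid ascending candidate thresholds within (0, 1).
#' @param n_random number of random graphs per grid point.
#' @param seed RNG seed for the random-graph reference.
#' @param min_nodes minimum retained nodes for a threshold to be eligible.
#' @return a `threshold_scan` data frame (tau, n_nodes, n_edges,
#'   observed_cc, random_cc, difference) with attribute `selected`.
#' @export
select_threshold <- function(sim, grid = seq(0.1, 0.9, by = 0.05),
                             n_random = 100, seed = 1, min_nodes = 5) {
  if (any(diff(grid) <= 0) || any(grid <= 0) || any(grid >= 1)) {
    stopf("'grid' must be ascending within (0, 1)")
  }
  r <- unclass(sim)
  diag(r) <- -Inf  # no self-loops
  scan <- data.frame(tau = grid, n_nodes = 0L, n_edges = 0L,
                     observed_cc = NA_real_, random_cc = NA_real_,
                     difference = NA_real_)
  # the random reference depends only on the retained (n, m); it is drawn
  # once per distinct pair so grid points with identical graphs get an
  # identical reference (a flat stretch of the curve stays exactly flat)
  ref_cache <- new.env(parent = emptyenv())
  with_seed(seed, {
    for (i in seq_along(grid)) {
      adj <- (r >= grid[i]) * 1
      deg <- rowSums(adj)
      keep <- deg > 0
      adj <- adj[keep, keep, drop = FALSE]
      n <- nrow(adj)
      m <- sum(adj) / 2
      scan$n_nodes[i] <- n
      scan$n_edges[i] <- m
      if (n == 0) next
      scan$observed_cc[i] <- local_cc_mean(adj)
      key <- paste(n, m)
      if (is.null(ref_cache[[key]])) {
        pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
        ref_cache[[key]] <- mean(vapply(seq_len(n_random), function(b) {
          local_cc_mean(random_gnm_adj(n, m, pair_idx))
        }, 0))
      }
      scan$random_cc[i] <- ref_cache[[key]]
      scan$difference[i] <- scan$observed_cc[i] - scan$random_cc[i]
    }
  })
  eligible <- which(scan$n_nodes >= min_nodes & !is.na(scan$difference))
  if (!length(eligible)) stopf("no threshold retains at least %d nodes", min_nodes)
  d_raw <- scan$difference[eligible]
  # centered 3-point moving average (partial at the ends)
  nd <- length(d_raw)
  d <- vapply(seq_len(nd), function(j) {
    mean(d_raw[max(1, j - 1):min(nd, j + 1)])
  }, 0)
  scan$difference_smooth <- NA_real_
  scan$difference_smooth[eligible] <- d
  selected <- NA_real_
  if (nd >= 3) {
    # interior local maximum: strict rise into the point, no rise out of it
    # (a flat curve therefore falls through to the global-maximum rule,
    # whose which.max picks the smallest tau on ties)
    for (j in 2:(nd - 1)) {
      if (d[j] > d[j - 1] && d[j] >= d[j + 1]) {
        selected <- grid[eligible[j]]
        break
      }
    }
  }
  if (is.na(selected)) selected <- grid[eligible[which.max(d)]]
  structure(scan, class = c("threshold_scan", "data.frame"),
            selected = selected, n_random = n_random, seed = seed)
}

#' Binarize a similarity matrix into an unweighted coexpression graph
#'
#' Edges connect feature pairs with signed `r >= tau`; degree-0 nodes are
#' removed and node order is lexicographic.
#'
#' @param sim a `similarity_matrix`.
#' @param tau threshold in (0, 1).
#' @return a `coexpression_graph`: list with `nodes`, `adj` (0/1 matrix) and
#'   `edges` (two-column data frame), plus the group label.
#' @export
binarize <- function(sim, tau) {
  if (tau <= 0 || tau >= 1) stopf("'tau' must lie in (0, 1)")
  r <- unclass(sim)
  ord <- order(rownames(r))
  r <- r[ord, ord, drop = FALSE]
  adj <- (r >= tau) * 1
  diag(adj) <- 0
  keep <- rowSums(adj) > 0
  adj <- adj[keep, keep, drop = FALSE]
  nodes <- rownames(adj)
  ij <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  edges <- data.frame(from = nodes[ij[, 1]], to = nodes[ij[, 2]],
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, adj = adj, edges = edges,
                 tau = tau, group = attr(sim, "group")),
            class = "coexpression_graph")
}

#' Build a coexpression graph directly from an edge list
#'
#' Mainly useful for constructing reference topologies (cliques, stars,
#' random graphs) to feed [network_stats()], [maximal_cliques()] and
#' [mcc_scores()].  Unlike [binarize()], isolated nodes passed via `nodes`
#' are kept.
#'
#' @param edges two-column data frame (or matrix) of undirected edges.
#' @param nodes optional full node set (to include isolated nodes).
#' @param tau,group optional annotations.
#' @return a `coexpression_graph`.
#' @export
make_coexpression_graph <- function(edges, nodes = NULL, tau = NA_real_, group = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges) <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(edges$from == edges$to)) stopf("self-loops are not allowed")
  all_nodes <- sort(unique(c(edges$from, edges$to, as.character(nodes))))
  n <- length(all_nodes)
  adj <- matrix(0, n, n, dimnames = list(all_nodes, all_nodes))
  if (nrow(edges)) {
    i <- match(edges$from, all_nodes)
    j <- match(edges$to, all_nodes)
    adj[cbind(i, j)] <- 1
    adj[cbind(j, i)] <- 1
  }
  ij <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  structure(list(nodes = all_nodes, adj = adj,
                 edges = data.frame(from = all_nodes[ij[, 1]], to = all_nodes[ij[, 2]],
                                    stringsAsFactors = FALSE),
                 tau = tau, group = group),
            class = "coexpression_graph")
}

#' Cytoscape-convention network statistics
#'
#' Mean local clustering coefficient (degree < 2 contributes 0; average over
#' all nodes), Freeman degree centralization
#' `(n / (n - 2)) * (k_max / (n - 1) - density)` for n >= 3 (0 otherwise),
#' connected-component count, and mean neighbours `2|E| / n`.
#'
#' @param g a `coexpression_graph`.
#' @return a `network_stats` list: `n_nodes`, `n_edges`, `n_components`,
#'   `clustering_coefficient`, `centralization`, `mean_neighbors`.
#' @export
network_stats <- function(g) {
  stopifnot(inherits(g, "coexpression_graph"))
  n <- length(g$nodes)
  if (n == 0) stopf("empty graph")
  adj <- g$adj
  m <- sum(adj) / 2
  k <- rowSums(adj)
  dens <- if (n > 1) 2 * m / (n * (n - 1)) else 0
  centralization <- if (n >= 3) (n / (n - 2)) * (max(k) / (n - 1) - dens) else 0
  # connected components by repeated BFS over the adjacency matrix
  comp <- integer(n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0) next
    cid <- cid + 1L
    frontier <- v
    comp[v] <- cid
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0)
      comp[nb] <- cid
      frontier <- nb
    }
  }
  structure(list(
    n_nodes = n,
    n_edges = m,
    n_components = cid,
    clustering_coefficient = local_cc_mean(adj),
    centralization = centralization,
    mean_neighbors = 2 * m / n
  ), class = "network_stats")
}

#' Export a coexpression graph
#'
#' Writes a GraphML file (via igraph) and a two-column edge-list TSV.
#'
#' @param g a `coexpression_graph`.
#' @param graphml_path,edgelist_path output paths (NULL to skip either).
#' @return invisibly, the paths written.
#' @export
write_graph_files <- function(g, graphml_path = NULL, edgelist_path = NULL) {
  stopifnot(inherits(g, "coexpression_graph"))
  written <- character(0)
  if (!is.null(graphml_path)) {
    ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                        vertices = data.frame(name = g$nodes))
    igraph::write_graph(ig, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  if (!is.null(edgelist_path)) {
    utils::write.table(g$edges, edgelist_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- c(written, edgelist_path)
  }
  invisible(written)
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("threshold_scan: %d grid points, selected tau = %.3f\n",
              nrow(x), attr(x, "selected")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
print.coexpression_graph <- function(x, ...) {
  cat(sprintf("coexpression_graph%s: %d nodes, %d edges (tau = %.3f)\n",
              if (is.null(x$group)) "" else paste0(" [", x$group, "]"),
              length(x$nodes), nrow(x$edges), x$tau))
  invisible(x)
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf(paste0("network_stats: %d nodes, %d components, clustering %.3f, ",
                     "centralization %.3f, mean neighbours %.2f\n"),
              x$n_nodes, x$n_components, x$clustering_coefficient,
              x$centralization, x$mean_neighbors))
  invisible(x)
}
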