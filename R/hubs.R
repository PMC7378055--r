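#' Enumerate all maximal cliques (Bron-Kerbosch with pivoting)
#'
#' Returns exactly the maximal cliques of a simple undirected graph: every
#' returned node set is complete and none is a subset of another.  Output is
#' canonicalized: members sorted, cliques ordered by size descending then
#' lexicographically.
#'
#' @param g a `coexpression_graph`, or a 0/1 adjacency matrix with dimnames.
#' @return list of character vectors.
#' @export
maximal_cliques <- function(g) {
  adj <- if (inherits(g, "coexpression_graph")) g$adj else g
  n <- nrow(adj)
  if (n == 0) return(list())
  nodes <- rownames(adj)
  nb <- lapply(seq_len(n), function(i) which(adj[i, ] != 0))
  cliques <- vector("list", 0)
  rec <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      cliques[[length(cliques) + 1L]] <<- R
      return(invisible())
    }
    PX <- c(P, X)
    # pivot u maximizing |P intersect N(u)|
    cnt <- vapply(PX, function(u) length(intersect(P, nb[[u]])), 0L)
    u <- PX[which.max(cnt)]
    for (v in setdiff(P, nb[[u]])) {
      rec(c(R, v), intersect(P, nb[[v]]), intersect(X, nb[[v]]))
      P <- setdiff(P, v)
      X <- union(X, v)
    }
  }
  rec(integer(0), seq_len(n), integer(0))
  out <- lapply(cliques, function(idx) sort(nodes[idx]))
  keys <- vapply(out, paste, "", collapse = "\r")
  sizes <- lengths(out)
  out[order(-sizes, keys)]
}

#' Maximal Clique Centrality scores
#'
#' `MCC(v)` is the sum of `(|C| - 1)!` over all maximal cliques `C`
#' containing `v`.  On triangle-free graphs this reduces to the degree.
#' Factorials and sums are computed in exact arbitrary-precision integer
#' arithmetic; the numeric return value is exact whenever it fits in a
#' double (< 2^53) and the attribute `"exact"` carries the full decimal
#' strings.
#'
#' @param g a `coexpression_graph` or 0/1 adjacency matrix.
#' @return named numeric vector of scores with attribute `exact`
#'   (named character vector of exact decimal values).
#' @export
mcc_scores <- function(g) {
  adj <- if (inherits(g, "coexpression_graph")) g$adj else g
  nodes <- rownames(adj)
  cl <- maximal_cliques(adj)
  bigs <- stats::setNames(replicate(length(nodes), 0, simplify = FALSE), nodes)
  fact_cache <- list()
  for (C in cl) {
    key <- as.character(length(C))
    if (is.null(fact_cache[[key]])) {
      fact_cache[[key]] <- big_factorial(length(C) - 1L)
    }
    f <- fact_cache[[key]]
    for (v in C) bigs[[v]] <- big_add(bigs[[v]], f)
  }
  exact <- vapply(bigs, big_to_string, "")
  scores <- vapply(bigs, big_to_num, 0)
  structure(scores, exact = exact)
}

#' Rank nodes by MCC and extract the top-k hubs
#'
#' Nodes are ordered by MCC (descending, compared exactly), then degree
#' (descending), then id (ascending).  Ranks are dense: nodes tied on both
#' MCC and degree share a rank.
#'
#' @param scores output of [mcc_scores()].
#' @param g the graph the scores came from.
#' @param k number of hubs to return (all nodes if fewer).
#' @param group optional group label.
#' @return a `hub_ranking` data frame: `rank`, `feature`, `mcc`, `degree`
#'   (plus attribute `mcc_exact`).
#' @export
rank_hubs <- function(scores, g, k = 20, group = NULL) {
  k <- check_count(k, "k")
  adj <- if (inherits(g, "coexpression_graph")) g$adj else g
  nodes <- names(scores)
  degree <- rowSums(adj)[nodes]
  exact <- attr(scores, "exact")
  key_mcc <- pad_decimal(exact)
  ord <- order(key_mcc, degree, rank(nodes), method = "radix",
               decreasing = c(TRUE, TRUE, FALSE))
  nodes <- nodes[ord]
  tie_key <- paste(key_mcc[ord], degree[ord])
  dense_rank <- cumsum(!duplicated(tie_key))
  top <- seq_len(min(k, length(nodes)))
  out <- data.frame(
    rank = dense_rank[top],
    feature = nodes[top],
    mcc = as.numeric(scores[nodes[top]]),
    degree = as.numeric(degree[nodes[top]]),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("hub_ranking", "data.frame"),
            mcc_exact = exact[nodes[top]], k = k, group = group)
}

#' Compare the top-k hub sets of the two age groups
#'
#' @param rank_young,rank_old `hub_ranking` objects.
#' @param de_young,de_old the groups' `de_result` tables, used to annotate
#'   each hub with its direction of regulation and its significance in the
#'   other group.
#' @param sig_fdr FDR cutoff used for the "significant in other group" flag.
#' @return a `hub_comparison`: list with `shared`, `exclusive_young`,
#'   `exclusive_old` (disjoint id sets) and an `annotation` data frame.
#' @export
compare_hub_sets <- function(rank_young, rank_old, de_young = NULL, de_old = NULL,
                             sig_fdr = 0.05) {
  y <- rank_young$feature
  o <- rank_old$feature
  ann <- data.frame(feature = union(y, o), stringsAsFactors = FALSE)
  ann$in_young <- ann$feature %in% y
  ann$in_old <- ann$feature %in% o
  annotate <- function(de, features) {
    if (is.null(de)) return(list(dir = NA_character_, sig = NA))
    i <- match(features, de$feature)
    list(dir = ifelse(is.na(i), NA, ifelse(de$log2fc[i] > 0, "up", "down")),
         sig = ifelse(is.na(i), NA, de$fdr[i] < sig_fdr))
  }
  ay <- annotate(de_young, ann$feature)
  ao <- annotate(de_old, ann$feature)
  ann$direction_young <- ay$dir
  ann$direction_old <- ao$dir
  ann$significant_young <- ay$sig
  ann$significant_old <- ao$sig
  structure(list(
    shared = sort(intersect(y, o)),
    exclusive_young = sort(setdiff(y, o)),
    exclusive_old = sort(setdiff(o, y)),
    annotation = ann
  ), class = "hub_comparison")
}

#' @export
print.hub_ranking <- function(x, ...) {
  cat(sprintf("hub_ranking%s: top %d of the MCC ranking\n",
              if (is.null(attr(x, "group"))) "" else paste0(" [", attr(x, "group"), "]"),
              nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
print.hub_comparison <- function(x, ...) {
  cat(sprintf("hub_comparison: %d shared, %d young-only, %d old-only\n",
              length(x$shared), length(x$exclusive_young), length(x$exclusive_old)))
  invisible(x)
}
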