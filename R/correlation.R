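#' Hub-miRNA / mRNA correlation matrix
#'
#' Pearson correlations between each hub miRNA's expression profile and
#' every mRNA gene over the intersection of sample ids (order-aligned).
#'
#' @param mirna_matrix miRNA log expression (features x samples), typically
#'   a `normalized_matrix`'s `log_expr`.
#' @param mrna_matrix mRNA log intensity (genes x samples).
#' @param hubs hub miRNA ids (rows of `mirna_matrix`).
#' @param samples sample ids of one group; intersected with both matrices.
#' @return matrix of Pearson r, hubs x genes, attribute `n_samples`.
#' @export
hub_gene_correlations <- function(mirna_matrix, mrna_matrix, hubs, samples = NULL) {
  x <- if (inherits(mirna_matrix, "normalized_matrix")) mirna_matrix$log_expr else mirna_matrix
  missing_hubs <- setdiff(hubs, rownames(x))
  if (length(missing_hubs)) {
    stopf("hub(s) absent from the miRNA matrix: %s", paste(missing_hubs, collapse = ", "))
  }
  shared <- intersect(colnames(x), colnames(mrna_matrix))
  if (!is.null(samples)) shared <- intersect(shared, samples)
  if (length(shared) < 3) stopf("fewer than 3 shared samples (%d)", length(shared))
  r <- stats::cor(t(x[hubs, shared, drop = FALSE]),
                  t(mrna_matrix[, shared, drop = FALSE]))
  structure(r, n_samples = length(shared))
}

#' Permutation-calibrated correlation significance threshold
#'
#' The mRNA matrix's sample labels are randomly permuted (one permutation
#' per iteration, shared by all genes, preserving the inter-gene
#' correlation structure) and all (hub, gene) correlations are recomputed;
#' the pooled null |r| values across permutations, hubs and genes yield
#' `r_critical` as their (1 - alpha) empirical quantile.  Deterministic for
#' a fixed seed.  (Internally the permutation is applied to the hub
#' profiles, which is elementwise identical to permuting the mRNA sample
#' labels by the inverse permutation and far cheaper.)
#'
#' @inheritParams hub_gene_correlations
#' @param n_perm number of permutations (>= 100).
#' @param alpha two-sided significance level; the conventional operating
#'   point is 0.002.
#' @param seed RNG seed.
#' @return a `perm_threshold` list: `r_critical`, `alpha`, `n_perm`, `seed`,
#'   `n_samples`.
#' @export
permutation_threshold <- function(mirna_matrix, mrna_matrix, hubs,
                                  n_perm = 1000, alpha = 0.002, seed = 1,
                                  samples = NULL) {
  if (n_perm < 100) stopf("'n_perm' must be at least 100")
  if (alpha <= 0 || alpha > 1) stopf("'alpha' must lie in (0, 1]")
  x <- if (inherits(mirna_matrix, "normalized_matrix")) mirna_matrix$log_expr else mirna_matrix
  shared <- intersect(colnames(x), colnames(mrna_matrix))
  if (!is.null(samples)) shared <- intersect(shared, samples)
  if (length(shared) < 3) stopf("fewer than 3 shared samples (%d)", length(shared))
  H <- t(x[hubs, shared, drop = FALSE])
  X <- t(mrna_matrix[, shared, drop = FALSE])
  if (any(apply(H, 2, stats::sd) == 0)) stopf("constant hub profile(s)")
  n <- nrow(H)
  # drop constant genes from the null pool (their correlation is undefined)
  keep <- matrixStats_colSds(X) > 0
  X <- X[, keep, drop = FALSE]
  Hs <- scale(H) / sqrt(n - 1)
  Xs <- scale(X) / sqrt(n - 1)
  if (alpha == 1) {
    r_critical <- 0
  } else {
    # permutations are stacked column-wise so one BLAS crossprod serves a
    # whole chunk; results are identical to the one-permutation-at-a-time
    # loop because the permutation draws happen in the same order
    nh <- ncol(Hs)
    # keep each chunk's correlation block near 2e7 entries
    chunk <- max(1L, min(n_perm, floor(2e7 / max(1, nh * ncol(Xs)))))
    pool <- numeric(n_perm * nh * ncol(Xs))
    idx <- 0L
    with_seed(seed, {
      done <- 0L
      while (done < n_perm) {
        b <- min(chunk, n_perm - done)
        HP <- matrix(0, n, nh * b)
        for (j in seq_len(b)) {
          HP[, (j - 1L) * nh + seq_len(nh)] <- Hs[sample.int(n), , drop = FALSE]
        }
        rb <- crossprod(HP, Xs)
        pool[idx + seq_along(rb)] <- abs(rb)
        idx <- idx + length(rb)
        done <- done + b
      }
    })
    r_critical <- as.numeric(stats::quantile(pool, 1 - alpha, names = FALSE))
  }
  structure(list(r_critical = r_critical, alpha = alpha, n_perm = n_perm,
                 seed = seed, n_samples = n),
            class = "perm_threshold")
}

# column sds without the matrixStats dependency
matrixStats_colSds <- function(x) apply(x, 2, stats::sd)

#' Select coexpressed genes per hub
#'
#' @param r matrix from [hub_gene_correlations()] (hubs x genes).
#' @param r_critical non-negative cutoff (a `perm_threshold` is accepted).
#' @return a `coexpression_selection`: named list (per hub) of data frames
#'   `gene`, `r`, ordered by |r| descending; attribute `counts`.
#' @export
select_coexpressed <- function(r, r_critical) {
  if (inherits(r_critical, "perm_threshold")) r_critical <- r_critical$r_critical
  if (r_critical < 0) stopf("'r_critical' must be >= 0")
  out <- lapply(rownames(r), function(h) {
    v <- r[h, ]
    sel <- which(abs(v) >= r_critical)
    sel <- sel[order(-abs(v[sel]))]
    data.frame(gene = colnames(r)[sel], r = as.numeric(v[sel]),
               stringsAsFactors = FALSE)
  })
  names(out) <- rownames(r)
  structure(out, class = "coexpression_selection",
            counts = vapply(out, nrow, 0L))
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf("perm_threshold: r_critical = %.4f (alpha = %g, %d permutations, n = %d)\n",
              x$r_critical, x$alpha, x$n_perm, x$n_samples))
  invisible(x)
}

#' @export
print.coexpression_selection <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat("coexpressed genes per hub:\n")
  for (h in names(x)) cat(sprintf("  %s: %d\n", h, cnt[[h]]))
  invisible(x)
}
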