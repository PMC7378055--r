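#' TMM normalization of a count matrix
#'
#' Computes trimmed-mean-of-M-values scale factors (trim fractions 30% on M,
#' 5% on A, precision weights from the asymptotic binomial variance) against
#' a reference sample — by default the sample whose upper-quartile count is
#' closest to the mean upper quartile — and returns log2 counts-per-million
#' on effective library sizes with pseudocount 0.5.  Factors are scaled so
#' their log-mean is zero.
#'
#' @param counts a `count_matrix` (see [read_count_matrix()]).
#' @param reference_sample optional sample id to normalize against.
#' @return a `normalized_matrix`: list with `log_expr` (features x samples,
#'   log2 CPM), `scale_factors`, `lib_sizes`, `metadata` and `provenance`.
#' @export
tmm_normalize <- function(counts, reference_sample = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  if (ncol(m) < 2) stopf("TMM needs at least 2 samples")
  lib <- colSums(m)
  if (any(lib == 0)) {
    stopf("sample(s) with all-zero counts: %s",
          paste(colnames(m)[lib == 0], collapse = ", "))
  }
  ref <- NULL
  if (!is.null(reference_sample)) {
    ref <- match(reference_sample, colnames(m))
    if (is.na(ref)) stopf("reference sample '%s' not found", reference_sample)
  }
  f <- edgeR::calcNormFactors(m, method = "TMM", refColumn = ref,
                              logratioTrim = 0.3, sumTrim = 0.05,
                              doWeighting = TRUE)
  eff <- lib * f
  log_expr <- log2(sweep(m + 0.5, 2, eff, "/") * 1e6)
  structure(list(
    log_expr = log_expr,
    scale_factors = stats::setNames(f, colnames(m)),
    lib_sizes = lib,
    metadata = counts$metadata,
    provenance = "tmm_log2cpm(pseudocount=0.5, trimM=0.3, trimA=0.05)"
  ), class = "normalized_matrix")
}

# iterative joint EB solution for the batch location/scale posteriors
# (standard parametric empirical-Bayes iteration)
eb_it_sol <- function(sdat, g_hat, d_hat, g_bar, t2, a, b, conv = 1e-4) {
  n <- ncol(sdat)
  g_old <- g_hat
  d_old <- d_hat
  repeat {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- rowSums((sdat - g_new)^2)
    d_new <- (0.5 * sum2 + b) / (n / 2 + a - 1)
    change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-8),
                  abs(d_new - d_old) / (abs(d_old) + 1e-8))
    g_old <- g_new
    d_old <- d_new
    if (change < conv) break
  }
  list(gamma_star = g_new, delta_star = d_new)
}

#' Empirical-Bayes batch adjustment (parametric location/scale)
#'
#' Removes additive/multiplicative batch effects with the parametric
#' empirical-Bayes location/scale model: features are standardized on a
#' batch-size-weighted grand-mean model, per-batch location effects get a
#' normal prior and per-batch scale effects an inverse-gamma prior, both
#' with hyperparameters moment-matched across features; the shrunken batch
#' effects are removed, the data back-transformed, and each feature's
#' original grand mean restored exactly.  Degenerate priors (zero
#' across-feature variance of the batch-effect estimates) reduce to the
#' unshrunken adjustment, so an exact constant shift between batches is
#' removed exactly.  With a single batch the input is returned unchanged.
#'
#' @param matrix_in a `normalized_matrix` or a plain numeric matrix
#'   (features x samples).
#' @param batch batch labels, one per sample; defaults to the metadata
#'   `batch` column when `matrix_in` is a `normalized_matrix`.
#' @return same type as `matrix_in`, batch-adjusted.
#' @export
batch_adjust <- function(matrix_in, batch = NULL) {
  is_nm <- inherits(matrix_in, "normalized_matrix")
  x <- if (is_nm) matrix_in$log_expr else matrix_in
  if (is.null(batch)) {
    if (!is_nm) stopf("'batch' labels are required for a plain matrix")
    batch <- matrix_in$metadata$batch
  }
  if (length(batch) != ncol(x)) stopf("one batch label per sample is required")
  batch <- factor(batch)
  if (nlevels(batch) == 1) {
    adj <- x
  } else {
    tab <- table(batch)
    if (any(tab < 2)) {
      stopf("batch(es) with fewer than 2 samples: %s",
            paste(names(tab)[tab < 2], collapse = ", "))
    }
    n <- ncol(x)
    nb <- nlevels(batch)
    ni <- as.numeric(table(batch))
    cols_of <- lapply(levels(batch), function(l) which(batch == l))
    # batch-wise means and the batch-size-weighted grand mean
    b_hat <- vapply(cols_of, function(cl) rowMeans(x[, cl, drop = FALSE]),
                    numeric(nrow(x)))                       # G x nb
    grand <- as.numeric(b_hat %*% (ni / n))
    resid <- x - b_hat[, as.integer(batch)]
    var_pooled <- rowSums(resid^2) / n
    if (any(var_pooled == 0)) {
      stopf("feature(s) with zero residual variance cannot be batch-adjusted: %s",
            paste(rownames(x)[var_pooled == 0], collapse = ", "))
    }
    z <- (x - grand) / sqrt(var_pooled)
    adj <- z
    for (i in seq_len(nb)) {
      cl <- cols_of[[i]]
      zb <- z[, cl, drop = FALSE]
      g_hat <- rowMeans(zb)
      d_hat <- apply(zb, 1, stats::var)
      g_bar <- mean(g_hat)
      t2 <- stats::var(g_hat)
      m <- mean(d_hat)
      s2 <- stats::var(d_hat)
      if (is.na(t2) || t2 <= 0 || is.na(s2) || s2 <= 0) {
        # degenerate prior: no information to shrink with
        g_star <- if (!is.na(t2) && t2 > 0) g_hat else rep(g_bar, length(g_hat))
        d_star <- d_hat
      } else {
        aprior <- (2 * s2 + m^2) / s2
        bprior <- (m * s2 + m^3) / s2
        sol <- eb_it_sol(zb, g_hat, d_hat, g_bar, t2, aprior, bprior)
        g_star <- sol$gamma_star
        d_star <- sol$delta_star
      }
      adj[, cl] <- (zb - g_star) / sqrt(d_star)
    }
    adj <- adj * sqrt(var_pooled) + grand
    # contract: feature-wise grand means preserved exactly
    adj <- adj - rowMeans(adj) + rowMeans(x)
  }
  if (is_nm) {
    matrix_in$log_expr <- adj
    matrix_in$provenance <- c(matrix_in$provenance,
                              sprintf("batch_adjust(parametric, %d batches)", nlevels(batch)))
    matrix_in
  } else adj
}

#' Quantile normalization
#'
#' Forces every sample (column) to the across-sample mean distribution of
#' order statistics; ties receive the mean of their tied quantiles.
#' Idempotent.
#'
#' @param x numeric matrix, features x samples, no missing values.
#' @return matrix of the same shape.
#' @export
quantile_normalize <- function(x) {
  if (anyNA(x)) stopf("quantile_normalize requires a complete matrix")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Correlation-based outlier sample detection
#'
#' A sample is flagged when its mean Pearson correlation with all other
#' samples falls below `threshold`.  Evaluation is single-pass: flags are
#' computed once against the full sample set, with no iterative
#' re-evaluation after removals.
#'
#' @param x numeric matrix, features x samples.
#' @param threshold correlation cutoff in (0, 1]; default 0.9.
#' @return character vector of excluded sample ids (possibly empty).
#' @export
detect_outliers <- function(x, threshold = 0.9) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    stopf("'threshold' must lie in (0, 1]")
  }
  if (ncol(x) < 3) stopf("outlier detection needs at least 3 samples")
  cc <- stats::cor(x)
  diag(cc) <- NA
  mean_cor <- rowMeans(cc, na.rm = TRUE)
  colnames(x)[mean_cor < threshold]
}

#' PCA check of residual batch structure
#'
#' Principal components of the sample-space covariance, the fraction of
#' variance each explains, and per component the R^2 of its scores
#' regressed on the batch indicator.
#'
#' @param x numeric matrix, features x samples.
#' @param batch batch labels, one per sample.
#' @param n_components number of leading components to report.
#' @return data frame with columns `component`, `var_explained`, `batch_r2`.
#' @export
pca_batch_check <- function(x, batch, n_components = 5) {
  if (length(batch) != ncol(x)) stopf("one batch label per sample is required")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  batch <- factor(batch)
  r2 <- vapply(seq_len(k), function(i) {
    if (nlevels(batch) < 2 || stats::sd(pc$x[, i]) == 0) return(0)
    summary(stats::lm(pc$x[, i] ~ batch))$r.squared
  }, 0)
  data.frame(component = seq_len(k),
             var_explained = varfrac[seq_len(k)],
             batch_r2 = r2)
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d features x %d samples\n  provenance: %s\n",
              nrow(x$log_expr), ncol(x$log_expr),
              paste(x$provenance, collapse = " -> ")))
  invisible(x)
}
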