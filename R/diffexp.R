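#' Moderated paired differential expression (tumor vs normal)
#'
#' Fits the paired model on within-patient tumor-minus-normal differences of
#' log2 expression for one age group and moderates the per-feature variances
#' by empirical Bayes: the posterior variance is
#' `(d0 * s0^2 + d * s^2) / (d0 + d)` with prior df `d0` and prior variance
#' `s0^2` estimated from the distribution of log sample variances by
#' digamma/trigamma moment matching (limma's estimator).  The moderated t
#' has `d0 + d` degrees of freedom; p-values are two-sided and BH-adjusted
#' across features.  `log2fc` is the mean paired difference.
#'
#' Setting `prior_df = Inf` forces the large-prior limit: the pooled prior
#' variance (mean of the per-feature sample variances, or `prior_var` if
#' given) replaces every feature's variance and the statistic becomes a z
#' statistic with normal p-values.
#'
#' @param norm a `normalized_matrix` (or plain matrix plus `metadata`).
#' @param group which age group to analyse ("young" or "old").
#' @param metadata sample metadata; defaults to the one carried by `norm`.
#' @param prior_df optional override of the prior degrees of freedom
#'   (currently only `Inf` is supported as an override).
#' @param prior_var pooled prior variance used when `prior_df = Inf`.
#' @return a `de_result` data frame: `feature`, `log2fc`, `mean_expr`,
#'   `t_stat`, `p_value`, `fdr`, plus attributes `group`, `n_pairs`,
#'   `prior_df`.
#' @export
moderated_de <- function(norm, group, metadata = NULL,
                         prior_df = NULL, prior_var = NULL) {
  x <- if (inherits(norm, "normalized_matrix")) norm$log_expr else norm
  if (is.null(metadata)) {
    if (!inherits(norm, "normalized_matrix")) stopf("'metadata' is required")
    metadata <- norm$metadata
  }
  meta <- metadata[metadata$group == group, , drop = FALSE]
  if (!nrow(meta)) stopf("no samples in group '%s'", group)
  split_t <- split(meta$sample_id[meta$tissue == "tumor"],
                   meta$patient_id[meta$tissue == "tumor"])
  split_n <- split(meta$sample_id[meta$tissue == "normal"],
                   meta$patient_id[meta$tissue == "normal"])
  patients <- sort(unique(meta$patient_id))
  bad <- patients[vapply(patients, function(p) {
    length(split_t[[p]]) != 1 || length(split_n[[p]]) != 1
  }, TRUE)]
  if (length(bad)) {
    stopf("unpaired patient(s) in group '%s': %s", group, paste(bad, collapse = ", "))
  }
  if (length(patients) < 3) stopf("need at least 3 tumor/normal pairs")
  tum <- vapply(patients, function(p) split_t[[p]], "")
  nor <- vapply(patients, function(p) split_n[[p]], "")
  diffs <- x[, tum, drop = FALSE] - x[, nor, drop = FALSE]
  n <- length(patients)
  mean_diff <- rowMeans(diffs)
  mean_expr <- rowMeans(x[, meta$sample_id, drop = FALSE])

  if (!is.null(prior_df) && is.infinite(prior_df)) {
    s2 <- apply(diffs, 1, stats::var)
    s0sq <- if (is.null(prior_var)) mean(s2) else prior_var
    t_stat <- mean_diff / sqrt(s0sq / n)
    p <- 2 * stats::pnorm(-abs(t_stat))
    d0 <- Inf
  } else {
    if (!is.null(prior_df)) stopf("only prior_df = Inf is supported as an override")
    fit <- limma::lmFit(diffs, design = matrix(1, n, 1))
    eb <- limma::eBayes(fit)
    t_stat <- eb$t[, 1]
    p <- eb$p.value[, 1]
    d0 <- eb$df.prior
  }
  out <- data.frame(
    feature = rownames(x),
    log2fc = mean_diff,
    mean_expr = mean_expr,
    t_stat = as.numeric(t_stat),
    p_value = as.numeric(p),
    fdr = bh_adjust(as.numeric(p)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, class = c("de_result", "data.frame"),
            group = group, n_pairs = n, prior_df = d0)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in input order, capped at 1.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Threshold-based selection of differentially expressed features
#'
#' A feature is selected when its linear fold change reaches `fc_cut`
#' (inclusive: `log2fc >= log2(fc_cut)` or `<= -log2(fc_cut)`) and its BH
#' FDR is strictly below `fdr_cut`.  The conventional regimes are
#' strict = (2, 0.01) and relaxed = (1.5, 0.05).
#'
#' @param result a `de_result` from [moderated_de()].
#' @param fc_cut linear fold-change cutoff, > 1.
#' @param fdr_cut FDR cutoff in (0, 1).
#' @param regime label stored with the list ("strict"/"relaxed"/custom).
#' @return a `de_list` data frame: `feature`, `direction`, `regime`.
#' @export
select_de <- function(result, fc_cut = 2, fdr_cut = 0.01,
                      regime = if (fc_cut == 2 && fdr_cut == 0.01) "strict" else
                               if (fc_cut == 1.5 && fdr_cut == 0.05) "relaxed" else "custom") {
  if (fc_cut <= 1) stopf("'fc_cut' must exceed 1")
  if (fdr_cut <= 0 || fdr_cut >= 1) stopf("'fdr_cut' must lie in (0, 1)")
  lcut <- log2(fc_cut)
  keep <- (result$log2fc >= lcut | result$log2fc <= -lcut) & result$fdr < fdr_cut
  out <- data.frame(
    feature = result$feature[keep],
    direction = ifelse(result$log2fc[keep] > 0, "up", "down"),
    regime = rep_len(regime, sum(keep)),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("de_list", "data.frame"),
            group = attr(result, "group"))
}

#' Set arithmetic between two DE lists
#'
#' @param list_a,list_b `de_list` data frames (or plain character vectors of
#'   feature ids).
#' @return a `venn_summary` list: `exclusive_a`, `exclusive_b`, `shared`,
#'   `union` (with `union = exclusive_a + exclusive_b + shared`).
#' @export
compare_de_lists <- function(list_a, list_b) {
  a <- unique(if (is.data.frame(list_a)) list_a$feature else list_a)
  b <- unique(if (is.data.frame(list_b)) list_b$feature else list_b)
  shared <- length(intersect(a, b))
  out <- list(
    exclusive_a = length(setdiff(a, b)),
    exclusive_b = length(setdiff(b, a)),
    shared = shared,
    union = length(union(a, b))
  )
  structure(out, class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf("venn: %d exclusive-A, %d exclusive-B, %d shared, union %d\n",
              x$exclusive_a, x$exclusive_b, x$shared, x$union))
  invisible(x)
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result (%s, %d pairs): %d features, %d with FDR < 0.05\n",
              attr(x, "group"), attr(x, "n_pairs"), nrow(x), sum(x$fdr < 0.05)))
  invisible(x)
}
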