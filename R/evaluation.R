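# Simulation studies that measure the pipeline's operating characteristics
# against the generator's planted ground truth.  These back the package's
# validation claims: differential-expression recovery, hub recovery through
# the thresholded network + MCC ranking, enrichment recovery, permutation
# calibration and type-I calibration of the moderated paired test.

#' Planted-structure recovery study
#'
#' Repeatedly simulates a cohort from `config`, runs the miRNA arm
#' (TMM normalization, batch adjustment, strict/relaxed paired DE, per-group
#' threshold scan, MCC ranking) and the mRNA arm (quantile normalization,
#' batch adjustment, outlier exclusion, permutation-calibrated hub/mRNA
#' correlation, enrichment battery for the young group), and scores each
#' replicate against the planted truth.
#'
#' @param config a [sim_config()]; its seed is replaced per replicate by
#'   `seed + replicate`.
#' @param n_reps number of replicates.
#' @param seed base seed.
#' @param n_perm permutations for the correlation cutoff within each
#'   replicate.
#' @param k hubs per group.
#' @param alpha significance level for the correlation cutoff.
#' @return data frame with one row per replicate: strict-DE sensitivity and
#'   false discovery proportion per group, the fraction of planted hubs
#'   inside the top-k MCC ranking (over both group networks), and whether
#'   the planted enriched set is the top enrichment row.
#' @export
recovery_study <- function(config = sim_config(), n_reps = 100, seed = 1,
                           n_perm = 250, k = 20, alpha = 0.002) {
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    gen <- generate_mirna_counts(cfg)
    truth <- gen$truth
    norm0 <- tmm_normalize(gen$counts)
    norm <- batch_adjust(norm0)
    meta <- norm$metadata

    sens <- fdp <- stats::setNames(numeric(2), c("young", "old"))
    relaxed <- list()
    for (g in c("young", "old")) {
      de <- moderated_de(norm, g)
      strict <- select_de(de, 2, 0.01, "strict")
      relaxed[[g]] <- select_de(de, 1.5, 0.05, "relaxed")
      planted <- truth[[paste0("de_", g)]]$feature
      tp <- sum(strict$feature %in% planted)
      sens[g] <- tp / length(planted)
      fdp[g] <- if (nrow(strict)) (nrow(strict) - tp) / nrow(strict) else 0
    }
    feats <- sort(union(relaxed$young$feature, relaxed$old$feature))

    hub_hits <- logical(0)
    rankings <- list()
    for (gi in 1:2) {
      g <- c("young", "old")[gi]
      samp <- meta$sample_id[meta$group == g & meta$tissue == "tumor"]
      sim <- similarity_matrix(norm, feats, samp, group = g)
      scan <- select_threshold(sim, seed = cfg$seed + 101L + gi)
      graph <- binarize(sim, attr(scan, "selected"))
      rankings[[g]] <- rank_hubs(mcc_scores(graph), graph, k = k, group = g)
      hub_hits <- c(hub_hits, truth$planted_hubs %in% rankings[[g]]$feature)
    }

    mrna <- generate_mrna_matrix(cfg, truth, norm0$log_expr)
    mq <- quantile_normalize(mrna)
    mq <- batch_adjust(mq, meta$batch[match(colnames(mq), meta$sample_id)])
    outl <- detect_outliers(mq)
    mq <- mq[, setdiff(colnames(mq), outl), drop = FALSE]
    sets <- generate_gene_sets(cfg, truth)
    truth <- attr(sets, "truth")

    samp <- intersect(meta$sample_id[meta$group == "young"], colnames(mq))
    hubs <- rankings$young$feature
    r <- hub_gene_correlations(norm, mq, hubs, samp)
    thr <- permutation_threshold(norm, mq, hubs, n_perm = n_perm, alpha = alpha,
                                 seed = cfg$seed + 104L, samples = samp)
    selection <- select_coexpressed(r, thr)
    battery <- run_enrichment_battery(selection, sets, rownames(mq))
    enriched_name <- names(truth$enriched_sets)[1]
    rows[[i]] <- data.frame(
      replicate = i,
      de_sensitivity_young = sens["young"], de_fdp_young = fdp["young"],
      de_sensitivity_old = sens["old"], de_fdp_old = fdp["old"],
      hub_top_k_rate = mean(hub_hits),
      enriched_set_top = nrow(battery) > 0 && battery$set[1] == enriched_name,
      r_critical = thr$r_critical
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation-threshold calibration study
#'
#' Draws independent Gaussian null data (no true hub/gene correlation),
#' computes `r_critical` by permutation, and records the realized fraction
#' of null (hub, gene) correlations exceeding it.  Calibration means this
#' fraction matches `alpha`.
#'
#' @param n_reps replicates.
#' @param n_samples,n_hubs,n_genes dimensions of each null dataset.
#' @param alpha significance level.
#' @param n_perm permutations per replicate.
#' @param seed base seed.
#' @return data frame with per-replicate `r_critical` and
#'   `exceedance_fraction`.
#' @export
permutation_calibration_study <- function(n_reps = 20, n_samples = 21,
                                          n_hubs = 5, n_genes = 1000,
                                          alpha = 0.002, n_perm = 1000,
                                          seed = 1) {
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    dat <- with_seed(seed + i, {
      list(
        mirna = matrix(stats::rnorm(n_hubs * n_samples), n_hubs, n_samples,
                       dimnames = list(sprintf("hub%02d", seq_len(n_hubs)),
                                       sprintf("s%03d", seq_len(n_samples)))),
        mrna = matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
                      dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                      sprintf("s%03d", seq_len(n_samples))))
      )
    })
    thr <- permutation_threshold(dat$mirna, dat$mrna, rownames(dat$mirna),
                                 n_perm = n_perm, alpha = alpha,
                                 seed = seed + 1000L + i)
    r <- hub_gene_correlations(dat$mirna, dat$mrna, rownames(dat$mirna))
    rows[[i]] <- data.frame(replicate = i, r_critical = thr$r_critical,
                            exceedance_fraction = mean(abs(r) >= thr$r_critical))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Type-I calibration of the moderated paired test
#'
#' Simulates Gaussian log-expression with no tumor/normal effect and
#' records the fraction of raw p-values below `p_cut` per replicate; a
#' calibrated test keeps this near `p_cut`.
#'
#' @param n_reps replicates.
#' @param n_pairs tumor/normal pairs.
#' @param n_features features per replicate.
#' @param p_cut nominal level.
#' @param seed base seed.
#' @return data frame with per-replicate `frac_p_below`.
#' @export
de_null_calibration <- function(n_reps = 500, n_pairs = 20, n_features = 300,
                                p_cut = 0.05, seed = 1) {
  meta <- data.frame(
    sample_id = c(sprintf("P%02d_T", seq_len(n_pairs)), sprintf("P%02d_N", seq_len(n_pairs))),
    patient_id = rep(sprintf("P%02d", seq_len(n_pairs)), 2),
    tissue = rep(c("tumor", "normal"), each = n_pairs),
    group = "young",
    batch = 1,
    stringsAsFactors = FALSE
  )
  frac <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    x <- with_seed(seed + i, {
      # per-feature means and variances vary so the moderation has work to do
      mu <- stats::runif(n_features, 2, 10)
      sd <- stats::rchisq(n_features, df = 4) / 4 + 0.2
      matrix(stats::rnorm(n_features * 2 * n_pairs, mu, sd), n_features, 2 * n_pairs,
             dimnames = list(sprintf("f%04d", seq_len(n_features)), meta$sample_id))
    })
    de <- moderated_de(x, "young", metadata = meta)
    frac[i] <- mean(de$p_value < p_cut)
  }
  data.frame(replicate = seq_len(n_reps), frac_p_below = frac)
}
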