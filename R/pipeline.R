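#' Pipeline configuration
#'
#' Exactly one of `input_paths` (a list with `counts`, `metadata`, `mrna`,
#' `gmt`) or `sim` (a [sim_config()]) must be supplied.
#'
#' @param input_paths list of input file paths, or NULL to simulate.
#' @param sim a [sim_config()], or NULL to read files.
#' @param strict,relaxed fold-change / FDR threshold pairs for the two DE
#'   regimes.
#' @param tau_grid candidate similarity thresholds.
#' @param n_random random graphs per grid point in the threshold scan.
#' @param k number of hubs per group.
#' @param alpha,n_perm permutation-test significance level and permutation
#'   count for the correlation cutoff.
#' @param enrichment_fdr FDR cutoff for reported enrichment rows.
#' @param outlier_threshold mean-correlation cutoff for mRNA sample
#'   exclusion.
#' @param network_samples `"tumor"` (default) restricts the coexpression
#'   networks to each group's tumor samples; `"all"` uses both tissues.
#' @param batch_correct apply empirical-Bayes batch adjustment.
#' @param seed global seed; per-stage seeds are derived as
#'   `seed + 10 * stage_index + group_index` so stages can be re-run in
#'   isolation.
#' @param out_dir output directory (NULL for no file output).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_paths = NULL, sim = NULL,
                            strict = c(2, 0.01), relaxed = c(1.5, 0.05),
                            tau_grid = seq(0.1, 0.9, by = 0.05),
                            n_random = 100, k = 20,
                            alpha = 0.002, n_perm = 1000,
                            enrichment_fdr = 0.05,
                            outlier_threshold = 0.9,
                            network_samples = c("tumor", "all"),
                            batch_correct = TRUE,
                            seed = 1L, out_dir = NULL) {
  if (is.null(input_paths) == is.null(sim)) {
    stopf("provide exactly one of 'input_paths' or 'sim'")
  }
  if (strict[1] <= 1 || relaxed[1] <= 1) stopf("fold-change cutoffs must exceed 1")
  structure(list(
    input_paths = input_paths, sim = sim,
    strict = strict, relaxed = relaxed,
    tau_grid = tau_grid, n_random = check_count(n_random, "n_random"),
    k = check_count(k, "k"),
    alpha = check_fraction(alpha, "alpha", 1e-12, 1),
    n_perm = check_count(n_perm, "n_perm", 100L),
    enrichment_fdr = check_fraction(enrichment_fdr, "enrichment_fdr", 1e-12, 1),
    outlier_threshold = check_fraction(outlier_threshold, "outlier_threshold", 1e-12, 1),
    network_samples = match.arg(network_samples),
    batch_correct = isTRUE(batch_correct),
    seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

#' Validate pipeline inputs
#'
#' Checks id uniqueness, metadata completeness, tumor/normal pairing and
#' sample overlap between the miRNA and mRNA matrices.
#'
#' @param counts a `count_matrix`.
#' @param mrna mRNA matrix (genes x samples), or NULL.
#' @return list with character vectors `fatal` and `warnings`.
#' @export
validate_inputs <- function(counts, mrna = NULL) {
  fatal <- character(0)
  warnings <- character(0)
  meta <- counts$metadata
  if (anyDuplicated(rownames(counts$counts))) fatal <- c(fatal, "duplicate feature ids")
  if (anyDuplicated(meta$sample_id)) fatal <- c(fatal, "duplicate sample ids")
  need <- c("sample_id", "patient_id", "tissue", "group", "batch")
  miss <- setdiff(need, names(meta))
  if (length(miss)) fatal <- c(fatal, paste("missing metadata columns:", paste(miss, collapse = ", ")))
  if (!length(fatal)) {
    if (anyNA(meta[need])) fatal <- c(fatal, "incomplete sample metadata")
    tab <- table(meta$patient_id, meta$tissue)
    bad <- rownames(tab)[tab[, "tumor", drop = TRUE] != 1 | tab[, "normal", drop = TRUE] != 1]
    if (length(bad)) {
      fatal <- c(fatal, paste("tumor/normal pairing violated for patient(s):",
                              paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(mrna)) {
    ov <- length(intersect(colnames(counts$counts), colnames(mrna)))
    if (ov == 0) {
      fatal <- c(fatal, "no shared samples between miRNA and mRNA matrices")
    } else if (ov < ncol(counts$counts)) {
      warnings <- c(warnings, sprintf("miRNA/mRNA sample intersection is %d of %d",
                                      ov, ncol(counts$counts)))
    }
  }
  list(fatal = fatal, warnings = warnings)
}

#' Run the full two-group analysis
#'
#' Executes, per age group: TMM normalization and batch adjustment of the
#' miRNA counts (with a PCA batch check), strict- and relaxed-regime paired
#' differential expression, the cross-group Venn summaries, a hard-threshold
#' coexpression network on the shared relaxed-regime feature list with a
#' per-group threshold scan, network statistics and MCC hub ranking; then
#' quantile normalization, batch adjustment and outlier exclusion of the
#' mRNA matrix, hub/mRNA correlation with a permutation-calibrated cutoff,
#' and the hypergeometric enrichment battery.  All tables are written to
#' `config$out_dir` (when set) together with an MD5 manifest; identical
#' config and seed give identical manifests.
#'
#' @param config a [pipeline_config()].
#' @return a `mirhub_run` list with per-stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "load inputs"
  res <- try({
    if (!is.null(config$sim)) {
      gen <- generate_mirna_counts(config$sim)
      counts <- gen$counts
      truth <- gen$truth
      norm0 <- tmm_normalize(counts)
      mrna <- generate_mrna_matrix(config$sim, truth, norm0$log_expr)
      sets <- generate_gene_sets(config$sim, truth)
      truth <- attr(sets, "truth")
    } else {
      p <- config$input_paths
      counts <- read_count_matrix(p$counts, p$metadata)
      mr <- utils::read.delim(p$mrna, check.names = FALSE, stringsAsFactors = FALSE)
      mrna <- as.matrix(mr[, -1, drop = FALSE]); rownames(mrna) <- mr[[1]]
      sets <- read_gmt(p$gmt)
      truth <- NULL
      norm0 <- NULL
    }
    v <- validate_inputs(counts, mrna)
    if (length(v$fatal)) stopf("input validation failed: %s", paste(v$fatal, collapse = "; "))
    for (w in v$warnings) warnf("%s", w)
    list(counts = counts, mrna = mrna, sets = sets, truth = truth, norm0 = norm0)
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    stopf("pipeline stage '%s' failed: %s", stage, attr(res, "condition")$message)
  }
  counts <- res$counts; mrna_raw <- res$mrna; sets <- res$sets; truth <- res$truth

  run_stage <- function(stage, expr) {
    out <- try(expr, silent = TRUE)
    if (inherits(out, "try-error")) {
      if (!is.null(config$out_dir)) {
        dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
        writeLines(stage, file.path(config$out_dir, "FAILED"))
      }
      stopf("pipeline stage '%s' failed: %s", stage, attr(out, "condition")$message)
    }
    out
  }

  ## miRNA preprocessing -----------------------------------------------
  norm <- run_stage("miRNA normalization", {
    n <- if (is.null(res$norm0)) tmm_normalize(counts) else res$norm0
    pca_pre <- pca_batch_check(n$log_expr, n$metadata$batch)
    if (config$batch_correct && length(unique(n$metadata$batch)) > 1) {
      n <- batch_adjust(n)
    }
    attr(n, "pca_pre") <- pca_pre
    attr(n, "pca_post") <- pca_batch_check(n$log_expr, n$metadata$batch)
    n
  })

  ## differential expression -------------------------------------------
  groups <- c("young", "old")
  de <- run_stage("differential expression", {
    lapply(stats::setNames(groups, groups), function(g) {
      r <- moderated_de(norm, g)
      list(result = r,
           strict = select_de(r, config$strict[1], config$strict[2], "strict"),
           relaxed = select_de(r, config$relaxed[1], config$relaxed[2], "relaxed"))
    })
  })
  venn_strict <- compare_de_lists(de$young$strict, de$old$strict)
  venn_relaxed <- compare_de_lists(de$young$relaxed, de$old$relaxed)
  # the shared feature list both networks are built from
  shared_list <- sort(union(de$young$relaxed$feature, de$old$relaxed$feature))

  ## networks and hubs ---------------------------------------------------
  nets <- run_stage("network construction", {
    lapply(stats::setNames(seq_along(groups), groups), function(gi) {
      g <- groups[gi]
      meta <- norm$metadata
      samp <- meta$sample_id[meta$group == g &
                               (config$network_samples == "all" | meta$tissue == "tumor")]
      if (length(shared_list) < 2) stopf("fewer than 2 features in the shared DE list")
      sim <- similarity_matrix(norm, shared_list, samp, group = g)
      scan <- select_threshold(sim, config$tau_grid, config$n_random,
                               seed = config$seed + 10L + gi)
      graph <- binarize(sim, attr(scan, "selected"))
      stats <- network_stats(graph)
      scores <- mcc_scores(graph)
      ranking <- rank_hubs(scores, graph, k = config$k, group = g)
      list(similarity = sim, scan = scan, graph = graph, stats = stats,
           ranking = ranking)
    })
  })
  hub_cmp <- compare_hub_sets(nets$young$ranking, nets$old$ranking,
                              de$young$result, de$old$result)

  ## mRNA preprocessing --------------------------------------------------
  mrna <- run_stage("mRNA preprocessing", {
    m <- quantile_normalize(mrna_raw)
    meta <- counts$metadata[match(colnames(m), counts$metadata$sample_id), ]
    if (config$batch_correct && length(unique(meta$batch)) > 1) {
      m <- batch_adjust(m, meta$batch)
    }
    out <- detect_outliers(m, config$outlier_threshold)
    list(matrix = m[, setdiff(colnames(m), out), drop = FALSE], outliers = out)
  })

  ## correlation + enrichment per group ---------------------------------
  correl <- run_stage("hub-gene correlation", {
    lapply(stats::setNames(seq_along(groups), groups), function(gi) {
      g <- groups[gi]
      meta <- norm$metadata
      samp <- intersect(meta$sample_id[meta$group == g], colnames(mrna$matrix))
      hubs <- nets[[g]]$ranking$feature
      r <- hub_gene_correlations(norm, mrna$matrix, hubs, samp)
      thr <- permutation_threshold(norm, mrna$matrix, hubs,
                                   n_perm = config$n_perm, alpha = config$alpha,
                                   seed = config$seed + 20L + gi, samples = samp)
      selection <- select_coexpressed(r, thr)
      universe <- rownames(mrna$matrix)
      battery <- run_enrichment_battery(selection, sets, universe,
                                        fdr_cut = config$enrichment_fdr)
      list(r = r, threshold = thr, selection = selection, battery = battery)
    })
  })

  run <- structure(list(
    config = config, truth = truth,
    normalized = norm, de = de,
    venn_strict = venn_strict, venn_relaxed = venn_relaxed,
    shared_feature_list = shared_list,
    networks = nets, hub_comparison = hub_cmp,
    mrna = mrna, correlation = correl
  ), class = "mirhub_run")

  if (!is.null(config$out_dir)) {
    run$manifest <- write_run_outputs(run, config$out_dir)
  }
  run
}

# write the standard output tables and return an MD5 manifest
write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (g in c("young", "old")) {
    d <- run$de[[g]]
    tab <- d$result
    tab$selected_strict <- tab$feature %in% d$strict$feature
    tab$selected_relaxed <- tab$feature %in% d$relaxed$feature
    tab$direction <- ifelse(tab$log2fc > 0, "up", "down")
    p <- file.path(out_dir, sprintf("de_%s.csv", g))
    write_table_6sig(tab, p); paths <- c(paths, p)

    nt <- run$networks[[g]]
    p <- file.path(out_dir, sprintf("threshold_scan_%s.csv", g))
    write_table_6sig(as.data.frame(nt$scan), p); paths <- c(paths, p)
    p2 <- file.path(out_dir, sprintf("network_%s.graphml", g))
    p3 <- file.path(out_dir, sprintf("edges_%s.tsv", g))
    write_graph_files(nt$graph, p2, p3); paths <- c(paths, p2, p3)

    hub_tab <- as.data.frame(nt$ranking)
    i <- match(hub_tab$feature, run$de[[g]]$result$feature)
    hub_tab$log2fc <- run$de[[g]]$result$log2fc[i]
    hub_tab$fdr <- run$de[[g]]$result$fdr[i]
    p <- file.path(out_dir, sprintf("hubs_%s.csv", g))
    write_table_6sig(hub_tab, p); paths <- c(paths, p)

    co <- run$correlation[[g]]
    sel_rows <- do.call(rbind, lapply(names(co$selection), function(h) {
      s <- co$selection[[h]]
      if (!nrow(s)) return(NULL)
      cbind(hub = h, s, stringsAsFactors = FALSE)
    }))
    if (is.null(sel_rows)) sel_rows <- data.frame(hub = character(0),
                                                  gene = character(0), r = numeric(0))
    p <- file.path(out_dir, sprintf("coexpressed_%s.csv", g))
    write_table_6sig(sel_rows, p); paths <- c(paths, p)
    p <- file.path(out_dir, sprintf("enrichment_%s.csv", g))
    write_table_6sig(run$correlation[[g]]$battery, p); paths <- c(paths, p)
  }
  report <- list(
    venn_strict = unclass(run$venn_strict),
    venn_relaxed = unclass(run$venn_relaxed),
    selected_tau = lapply(run$networks, function(n) attr(n$scan, "selected")),
    network_stats = lapply(run$networks, function(n) unclass(n$stats)),
    r_critical = lapply(run$correlation, function(cc) cc$threshold$r_critical),
    mrna_outliers = run$mrna$outliers,
    seed = run$config$seed
  )
  p <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  manifest <- data.frame(file = basename(paths),
                         md5 = as.character(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' @export
print.mirhub_run <- function(x, ...) {
  cat("mirhub_run\n")
  cat(sprintf("  strict DE: young %d, old %d (union %d, shared %d)\n",
              nrow(x$de$young$strict), nrow(x$de$old$strict),
              x$venn_strict$union, x$venn_strict$shared))
  cat(sprintf("  relaxed DE union (network feature list): %d\n",
              length(x$shared_feature_list)))
  for (g in c("young", "old")) {
    n <- x$networks[[g]]
    cat(sprintf("  %s network: tau = %.2f, %d nodes, %d components, clustering %.3f\n",
                g, attr(n$scan, "selected"), n$stats$n_nodes,
                n$stats$n_components, n$stats$clustering_coefficient))
    cat(sprintf("  %s r_critical = %.3f; %d significant enrichment rows\n",
                g, x$correlation[[g]]$threshold$r_critical,
                nrow(x$correlation[[g]]$battery)))
  }
  invisible(x)
}

#' @export
summary.mirhub_run <- function(object, ...) {
  print(object)
  cat("  top hubs (young):",
      paste(utils::head(object$networks$young$ranking$feature, 5), collapse = ", "), "\n")
  cat("  top hubs (old):  ",
      paste(utils::head(object$networks$old$ranking$feature, 5), collapse = ", "), "\n")
  invisible(object)
}
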