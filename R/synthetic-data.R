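#' Simulation configuration for the synthetic cohort
#'
#' Describes a paired tumor/normal miRNA-seq cohort in two age groups with
#' planted differential expression, hub-centred coexpression modules,
#' miRNA-correlated mRNA genes and an enriched gene set.  Defaults mirror the
#' study design the package targets: 24 young + 25 old patients, one tumor
#' and one matched normal sample each, two sequencing batches, and a
#' feature universe downscaled to 300 miRNAs / 2000 mRNA genes so the full
#' analysis runs at desk scale.
#'
#' @param n_young_patients,n_old_patients patients per age group (each
#'   contributes a tumor and a normal sample).
#' @param n_mirnas,n_mrnas numbers of miRNA and mRNA features.
#' @param n_batches number of sequencing batches; patients are assigned to
#'   batches in a balanced round-robin within each group, both samples of a
#'   patient sharing the batch.
#' @param de_fraction fraction of miRNAs planted as differentially expressed
#'   (tumor vs normal).  The planted set is split 1/6 young-exclusive,
#'   1/6 old-exclusive and 2/3 shared; signs are balanced and coexpression
#'   module members are drawn from the shared portion so both group networks
#'   contain them.
#' @param planted_log2fc magnitude of the planted tumor/normal log2 fold
#'   change.
#' @param module_specs list of module descriptions, each a list with
#'   `direction` ("up"/"down"), `n_members`, `hub_count` and
#'   `within_module_correlation` (target Pearson correlation between two
#'   non-hub members on the log2 scale).
#' @param nb_dispersion negative-binomial dispersion phi (variance
#'   mu + phi * mu^2), constant across features.
#' @param library_size_range range from which per-sample library sizes are
#'   drawn uniformly.
#' @param batch_effect_sd sd of the additive per-(feature, batch) shift on
#'   the log2 scale.
#' @param mirna_mrna_links list of links, each a list with `hub` (index into
#'   the planted hub list), `n_correlated_genes` and `target_correlation`
#'   (population Pearson rho in (-1, 1), sign retained).
#' @param n_gene_sets number of gene sets written to the GMT collection
#'   (one of them enriched when `enriched_set_spec` is given).
#' @param enriched_set_spec list with `hub` (index into the planted hub
#'   list) and `overlap_fraction`: the enriched set contains that fraction
#'   of the hub's planted correlated genes plus random padding.
#' @param mrna_mean_range,mrna_noise_sd base mean range and residual sd of
#'   the Gaussian log-intensity mRNA matrix.  Defaults give sample-sample
#'   correlations around 0.97, as on real arrays, so the 0.9 outlier rule
#'   does not fire on clean data.
#' @param module_loading_hub,module_loading_member latent-factor loadings;
#'   hubs load most strongly so they are densest in the thresholded graph.
#' @param seed integer seed; identical seeds give bit-identical fixtures.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_young_patients = 24,
                       n_old_patients = 25,
                       n_mirnas = 300,
                       n_mrnas = 2000,
                       n_batches = 2,
                       de_fraction = 0.2,
                       planted_log2fc = 2,
                       module_specs = list(
                         list(direction = "up", n_members = 15, hub_count = 1,
                              within_module_correlation = 0.7),
                         list(direction = "down", n_members = 15, hub_count = 1,
                              within_module_correlation = 0.7)
                       ),
                       nb_dispersion = 0.15,
                       library_size_range = c(8e5, 1.2e6),
                       batch_effect_sd = 0.3,
                       mirna_mrna_links = list(
                         list(hub = 1, n_correlated_genes = 40, target_correlation = 0.8),
                         list(hub = 2, n_correlated_genes = 40, target_correlation = -0.8)
                       ),
                       n_gene_sets = 22,
                       enriched_set_spec = list(hub = 1, overlap_fraction = 0.8),
                       mrna_mean_range = c(4, 14),
                       mrna_noise_sd = 0.5,
                       module_loading_hub = 1.0,
                       module_loading_member = 0.6,
                       seed = 1L) {
  cfg <- list(
    n_young_patients = check_count(n_young_patients, "n_young_patients"),
    n_old_patients = check_count(n_old_patients, "n_old_patients"),
    n_mirnas = check_count(n_mirnas, "n_mirnas"),
    n_mrnas = check_count(n_mrnas, "n_mrnas"),
    n_batches = check_count(n_batches, "n_batches"),
    de_fraction = check_fraction(de_fraction, "de_fraction"),
    planted_log2fc = as.numeric(planted_log2fc),
    module_specs = module_specs,
    nb_dispersion = as.numeric(nb_dispersion),
    library_size_range = as.numeric(library_size_range),
    batch_effect_sd = as.numeric(batch_effect_sd),
    mirna_mrna_links = mirna_mrna_links,
    n_gene_sets = check_count(n_gene_sets, "n_gene_sets", min = 0L),
    enriched_set_spec = enriched_set_spec,
    mrna_mean_range = as.numeric(mrna_mean_range),
    mrna_noise_sd = as.numeric(mrna_noise_sd),
    module_loading_hub = as.numeric(module_loading_hub),
    module_loading_member = as.numeric(module_loading_member),
    seed = as.integer(seed)
  )
  if (cfg$nb_dispersion <= 0) stopf("'nb_dispersion' must be > 0")
  if (cfg$batch_effect_sd < 0) stopf("'batch_effect_sd' must be >= 0")
  if (length(cfg$library_size_range) != 2 || any(cfg$library_size_range <= 0) ||
      diff(cfg$library_size_range) < 0) {
    stopf("'library_size_range' must be an increasing pair of positive counts")
  }
  for (m in cfg$module_specs) {
    if (!m$direction %in% c("up", "down")) stopf("module direction must be 'up' or 'down'")
    check_count(m$n_members, "n_members")
    check_count(m$hub_count, "hub_count")
    if (m$hub_count > m$n_members) stopf("hub_count exceeds module size")
    check_fraction(m$within_module_correlation, "within_module_correlation", 1e-9, 1 - 1e-9)
  }
  n_module <- sum(vapply(cfg$module_specs, function(m) m$n_members, 0))
  if (n_module > cfg$n_mirnas) {
    stopf("module member counts (%d) exceed n_mirnas (%d)", n_module, cfg$n_mirnas)
  }
  for (l in cfg$mirna_mrna_links) {
    check_count(l$hub, "link hub index")
    check_count(l$n_correlated_genes, "n_correlated_genes")
    if (abs(l$target_correlation) >= 1) stopf("target_correlation must lie in (-1, 1)")
  }
  if (!is.null(cfg$enriched_set_spec)) {
    check_fraction(cfg$enriched_set_spec$overlap_fraction, "overlap_fraction")
  }
  structure(cfg, class = "sim_config")
}

# balanced batch assignment per patient, interleaving groups so every batch
# contains both groups
assign_batches <- function(patients, n_batches) {
  rep_len(seq_len(n_batches), length(patients))
}

#' Generate a synthetic paired tumor/normal miRNA count matrix
#'
#' Draws negative-binomial counts (variance mu + phi * mu^2) with per-sample
#' library sizes, planted tumor/normal log2 fold changes per age group,
#' additive per-(feature, batch) shifts on the log2 scale, and shared
#' latent factors inducing coexpression modules in tumor samples.  Hubs load
#' on the module factor with loading 1.0, other members with 0.6, so hubs
#' end up densest once the correlation matrix is thresholded.
#'
#' @param config a [sim_config()].
#' @return a list with elements `counts` (a `count_matrix`: integer matrix
#'   features x samples plus a metadata data frame) and `truth` (a
#'   `ground_truth` record of everything planted).
#' @export
generate_mirna_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_mi <- config$n_mirnas
    mirnas <- sprintf("miR-%04d", seq_len(n_mi))
    pat_y <- sprintf("Y%02d", seq_len(config$n_young_patients))
    pat_o <- sprintf("O%02d", seq_len(config$n_old_patients))
    patients <- c(pat_y, pat_o)
    group <- c(rep("young", length(pat_y)), rep("old", length(pat_o)))
    batch_of <- c(assign_batches(pat_y, config$n_batches),
                  assign_batches(pat_o, config$n_batches))
    meta <- data.frame(
      sample_id = c(paste0(patients, "_T"), paste0(patients, "_N")),
      patient_id = rep(patients, 2),
      tissue = rep(c("tumor", "normal"), each = length(patients)),
      group = rep(group, 2),
      batch = rep(batch_of, 2),
      stringsAsFactors = FALSE
    )
    n_s <- nrow(meta)

    ## ---- plant differential expression --------------------------------
    n_de <- round(config$de_fraction * n_mi)
    module_sizes <- vapply(config$module_specs, function(m) m$n_members, 0)
    n_module <- sum(module_sizes)
    if (n_de > 0 && n_module > n_de) {
      stopf("de_fraction too small to hold all module members (%d planted DE < %d members)",
            n_de, n_module)
    }
    # module members occupy the front of the planted-DE block (shared
    # between groups); the remainder is split 2:1:1 shared/young/old
    idx_de <- seq_len(n_de)
    rest <- setdiff(idx_de, seq_len(n_module))
    n_rest <- length(rest)
    n_shared_extra <- floor(n_rest / 2)
    n_young_only <- ceiling((n_rest - n_shared_extra) / 2)
    shared_extra <- rest[seq_len(n_shared_extra)]
    young_only <- rest[n_shared_extra + seq_len(n_young_only)]
    old_only <- setdiff(rest, c(shared_extra, young_only))
    shared <- c(seq_len(n_module), shared_extra)

    sign_of <- numeric(n_mi)
    module_membership <- rep(NA_character_, n_mi)
    hub_flags <- logical(n_mi)
    offset <- 0L
    for (mi in seq_along(config$module_specs)) {
      m <- config$module_specs[[mi]]
      members <- offset + seq_len(m$n_members)
      module_membership[members] <- sprintf("module_%d_%s", mi, m$direction)
      hub_flags[members[seq_len(m$hub_count)]] <- TRUE
      sign_of[members] <- if (m$direction == "up") 1 else -1
      offset <- offset + m$n_members
    }
    # balance signs in the non-module planted features
    alt_sign <- function(idx) if (length(idx)) rep_len(c(1, -1), length(idx)) else numeric(0)
    sign_of[shared_extra] <- alt_sign(shared_extra)
    sign_of[young_only] <- alt_sign(young_only)
    sign_of[old_only] <- alt_sign(old_only)

    de_young <- sort(c(shared, young_only))
    de_old <- sort(c(shared, old_only))

    ## ---- expected log2 abundances --------------------------------------
    base_mu <- stats::runif(n_mi, 3, 12)
    # module members get a comfortable abundance so dispersion, not shot
    # noise, dominates their log-scale variance (keeps the correlation
    # calibration honest)
    in_module <- !is.na(module_membership)
    base_mu[in_module] <- stats::runif(sum(in_module), 8, 10)

    batch_shift <- matrix(stats::rnorm(n_mi * config$n_batches, 0, config$batch_effect_sd),
                          n_mi, config$n_batches)

    # latent module factors: per tumor sample, one draw per module
    ln2 <- log(2)
    log2_mean <- matrix(base_mu, n_mi, n_s)
    tumor_cols <- which(meta$tissue == "tumor")
    for (j in seq_len(n_s)) {
      g <- meta$group[j]
      de_idx <- if (g == "young") de_young else de_old
      if (meta$tissue[j] == "tumor" && length(de_idx)) {
        log2_mean[de_idx, j] <- log2_mean[de_idx, j] +
          sign_of[de_idx] * config$planted_log2fc
      }
      log2_mean[, j] <- log2_mean[, j] + batch_shift[, meta$batch[j]]
    }
    factor_scores <- matrix(0, length(config$module_specs), n_s)
    for (mi in seq_along(config$module_specs)) {
      m <- config$module_specs[[mi]]
      members <- which(module_membership == sprintf("module_%d_%s", mi, m$direction))
      hubs_m <- members[hub_flags[members]]
      nonhubs <- setdiff(members, hubs_m)
      # approximate per-member log2 noise variance from expected tumor counts
      lib_mid <- mean(config$library_size_range)
      mu_counts <- 2^(base_mu[members] + sign_of[members] * config$planted_log2fc)
      mu_counts <- mu_counts / sum(2^base_mu) * lib_mid
      sigma_e2 <- mean((1 / mu_counts + config$nb_dispersion) / ln2^2)
      rho <- m$within_module_correlation
      lam <- config$module_loading_member
      sigma_f2 <- sigma_e2 * rho / (lam^2 * (1 - rho))
      f <- stats::rnorm(length(tumor_cols), 0, sqrt(sigma_f2))
      factor_scores[mi, tumor_cols] <- f
      loading <- ifelse(hub_flags[members], config$module_loading_hub,
                        config$module_loading_member)
      log2_mean[members, tumor_cols] <- log2_mean[members, tumor_cols] +
        outer(loading, f)
    }

    ## ---- sample counts --------------------------------------------------
    lib_sizes <- round(stats::runif(n_s, config$library_size_range[1],
                                    config$library_size_range[2]))
    counts <- matrix(0L, n_mi, n_s, dimnames = list(mirnas, meta$sample_id))
    size <- 1 / config$nb_dispersion
    for (j in seq_len(n_s)) {
      w <- 2^log2_mean[, j]
      mu <- lib_sizes[j] * w / sum(w)
      counts[, j] <- as.integer(stats::rnbinom(n_mi, mu = mu, size = size))
    }

    ## ---- ground truth ---------------------------------------------------
    planted_hubs <- mirnas[hub_flags]
    genes <- sprintf("gene%04d", seq_len(config$n_mrnas))
    correlated_gene_map <- list()
    used <- integer(0)
    for (l in config$mirna_mrna_links) {
      if (l$hub > length(planted_hubs)) {
        stopf("link refers to hub index %d but only %d hubs are planted",
              l$hub, length(planted_hubs))
      }
      free <- setdiff(seq_len(config$n_mrnas), used)
      pick <- free[seq_len(l$n_correlated_genes)]
      used <- c(used, pick)
      hub_id <- planted_hubs[l$hub]
      correlated_gene_map[[hub_id]] <- data.frame(
        gene = genes[pick], rho = l$target_correlation, stringsAsFactors = FALSE)
    }

    truth <- structure(list(
      de_young = data.frame(feature = mirnas[de_young],
                            log2fc = sign_of[de_young] * config$planted_log2fc,
                            stringsAsFactors = FALSE),
      de_old = data.frame(feature = mirnas[de_old],
                          log2fc = sign_of[de_old] * config$planted_log2fc,
                          stringsAsFactors = FALSE),
      module_membership = stats::setNames(module_membership, mirnas)[in_module],
      planted_hubs = planted_hubs,
      correlated_gene_map = correlated_gene_map,
      mrna_features = genes,
      enriched_sets = list(),
      factor_scores = factor_scores
    ), class = "ground_truth")

    cm <- structure(list(counts = counts, metadata = meta), class = "count_matrix")
    list(counts = cm, truth = truth)
  })
}

#' Generate a Gaussian log-intensity mRNA matrix with planted miRNA links
#'
#' Unlinked genes are independent Gaussian noise around gene-specific means.
#' For every planted (hub, gene, rho) link the gene profile is
#' `rho * z(hub) + sqrt(1 - rho^2) * noise` (times the residual sd), where
#' `z(hub)` is the hub's log expression standardized over the supplied
#' samples, so the population Pearson correlation equals rho.
#'
#' @param config a [sim_config()].
#' @param truth the `ground_truth` from [generate_mirna_counts()].
#' @param mirna_log_expr matrix of miRNA log2 expression (features x
#'   samples) covering all planted hubs; typically the TMM log-CPM of the
#'   generated counts.
#' @return numeric matrix genes x samples with the same column names.
#' @export
generate_mrna_matrix <- function(config, truth, mirna_log_expr) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  missing_hubs <- setdiff(names(truth$correlated_gene_map), rownames(mirna_log_expr))
  if (length(missing_hubs)) {
    stopf("hub(s) absent from mirna_log_expr: %s", paste(missing_hubs, collapse = ", "))
  }
  with_seed(config$seed + 1L, {
    genes <- truth$mrna_features
    n_g <- length(genes)
    samples <- colnames(mirna_log_expr)
    n_s <- length(samples)
    gene_means <- stats::runif(n_g, config$mrna_mean_range[1], config$mrna_mean_range[2])
    sd_e <- config$mrna_noise_sd
    expr <- matrix(stats::rnorm(n_g * n_s, 0, sd_e), n_g, n_s,
                   dimnames = list(genes, samples))
    for (hub_id in names(truth$correlated_gene_map)) {
      link <- truth$correlated_gene_map[[hub_id]]
      prof <- mirna_log_expr[hub_id, ]
      if (stats::sd(prof) == 0) stopf("hub '%s' has constant expression", hub_id)
      z <- as.numeric(scale(prof))
      for (i in seq_len(nrow(link))) {
        rho <- link$rho[i]
        eps <- stats::rnorm(n_s)
        expr[link$gene[i], ] <- sd_e * (rho * z + sqrt(1 - rho^2) * eps)
      }
    }
    expr + gene_means
  })
}

#' Generate a GMT-serializable gene-set collection
#'
#' All sets are uniform random draws from the mRNA universe except the
#' enriched one, which contains `overlap_fraction` of the designated hub's
#' planted correlated genes plus random padding.  The enriched set's name
#' and planted members are recorded in the returned truth.
#'
#' @param config a [sim_config()].
#' @param truth the `ground_truth` from [generate_mirna_counts()]; returned
#'   updated (R copy semantics) as attribute `"truth"` of the collection.
#' @return a named list of character vectors of class `gene_set_collection`
#'   with attributes `universe` and `truth`.
#' @export
generate_gene_sets <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  if (!is.null(config$enriched_set_spec) &&
      config$enriched_set_spec$overlap_fraction > 1) {
    stopf("overlap_fraction must be <= 1")
  }
  with_seed(config$seed + 2L, {
    universe <- truth$mrna_features
    n_sets <- config$n_gene_sets
    sets <- list()
    if (n_sets > 0) {
      sizes <- sample(50:300, n_sets, replace = TRUE)
      names_all <- sprintf("PC_PATHWAY_%02d", seq_len(n_sets))
      for (i in seq_len(n_sets)) {
        sets[[names_all[i]]] <- sort(sample(universe, min(sizes[i], length(universe))))
      }
      spec <- config$enriched_set_spec
      if (!is.null(spec) && length(truth$correlated_gene_map)) {
        hub_id <- names(truth$correlated_gene_map)[spec$hub]
        if (is.na(hub_id)) stopf("enriched_set_spec refers to a missing hub index")
        linked <- truth$correlated_gene_map[[hub_id]]$gene
        n_in <- round(spec$overlap_fraction * length(linked))
        core <- linked[seq_len(n_in)]
        target_size <- max(length(core), sizes[1])
        pad <- sample(setdiff(universe, linked), target_size - length(core))
        enriched_name <- "PLANTED_PC_SET"
        sets[[names_all[1]]] <- NULL
        sets <- c(stats::setNames(list(sort(c(core, pad))), enriched_name), sets)
        truth$enriched_sets <- stats::setNames(
          list(list(hub = hub_id, planted_overlap = core)), enriched_name)
      }
    }
    structure(sets, class = "gene_set_collection", universe = universe, truth = truth)
  })
}

#' Write a synthetic fixture to disk
#'
#' Writes `mirna_counts.tsv`, `mrna_expression.tsv`, `metadata.tsv`,
#' `gene_sets.gmt` and `truth.json` to `dir_path`.  [read_fixture()]
#' round-trips the objects exactly.
#'
#' @param dir_path output directory (created if needed).
#' @param counts the `count_matrix` from [generate_mirna_counts()].
#' @param mrna the matrix from [generate_mrna_matrix()].
#' @param sets the collection from [generate_gene_sets()].
#' @param truth the `ground_truth` record (the one attached to `sets` if it
#'   carries planted enrichment).
#' @return invisibly, the vector of written file paths.
#' @export
write_fixture <- function(dir_path, counts, mrna, sets, truth) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!identical(colnames(counts$counts), counts$metadata$sample_id)) {
    stopf("count columns and metadata rows disagree on sample identifiers")
  }
  if (!all(colnames(mrna) %in% counts$metadata$sample_id)) {
    stopf("mRNA matrix has samples missing from the metadata")
  }
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir_path, c("mirna_counts.tsv", "mrna_expression.tsv",
                                 "metadata.tsv", "gene_sets.gmt", "truth.json"))
  cdf <- data.frame(feature = rownames(counts$counts), counts$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cdf, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  mdf <- data.frame(feature = rownames(mrna),
                    format(mrna, digits = 15, trim = TRUE, scientific = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(mdf, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(counts$metadata, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(sets, paths[4])
  tr <- list(
    de_young = truth$de_young,
    de_old = truth$de_old,
    module_membership = as.list(truth$module_membership),
    planted_hubs = truth$planted_hubs,
    correlated_gene_map = truth$correlated_gene_map,
    mrna_features = truth$mrna_features,
    enriched_sets = truth$enriched_sets
  )
  jsonlite::write_json(tr, paths[5], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a fixture written by [write_fixture()]
#'
#' @param dir_path directory holding the fixture files.
#' @return list with `counts` (`count_matrix`), `mrna` (matrix), `sets`
#'   (`gene_set_collection`) and `truth` (`ground_truth`).
#' @export
read_fixture <- function(dir_path) {
  counts <- read_count_matrix(file.path(dir_path, "mirna_counts.tsv"),
                              file.path(dir_path, "metadata.tsv"))
  mr <- utils::read.delim(file.path(dir_path, "mrna_expression.tsv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  mrna <- as.matrix(mr[, -1, drop = FALSE])
  rownames(mrna) <- mr$feature
  sets <- read_gmt(file.path(dir_path, "gene_sets.gmt"))
  tr <- jsonlite::read_json(file.path(dir_path, "truth.json"), simplifyVector = TRUE)
  truth <- structure(list(
    de_young = as.data.frame(tr$de_young),
    de_old = as.data.frame(tr$de_old),
    module_membership = unlist(tr$module_membership),
    planted_hubs = tr$planted_hubs,
    correlated_gene_map = lapply(tr$correlated_gene_map, as.data.frame),
    mrna_features = tr$mrna_features,
    enriched_sets = tr$enriched_sets
  ), class = "ground_truth")
  attr(sets, "universe") <- truth$mrna_features
  list(counts = counts, mrna = mrna, sets = sets, truth = truth)
}

#' Read a count matrix and its sample metadata from TSV files
#'
#' @param counts_path TSV with a leading `feature` column and one integer
#'   column per sample.
#' @param metadata_path TSV with columns `sample_id`, `patient_id`,
#'   `tissue`, `group`, `batch`.
#' @return a `count_matrix`.
#' @export
read_count_matrix <- function(counts_path, metadata_path) {
  cd <- utils::read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.delim(metadata_path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(cd[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- cd$feature
  if (anyDuplicated(rownames(m))) stopf("duplicate feature identifiers in %s", counts_path)
  if (anyDuplicated(meta$sample_id)) stopf("duplicate sample identifiers in %s", metadata_path)
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stopf("metadata missing for some samples")
  rownames(meta) <- NULL
  structure(list(counts = m, metadata = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%d patients, %d batches)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$metadata$patient_id)),
              length(unique(x$metadata$batch))))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("ground_truth: %d/%d planted DE miRNAs (young/old), ",
                     "%d modules, %d hubs, %d mRNA link blocks\n"),
              nrow(x$de_young), nrow(x$de_old),
              length(unique(x$module_membership)), length(x$planted_hubs),
              length(x$correlated_gene_map)))
  invisible(x)
}
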