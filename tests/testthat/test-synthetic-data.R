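test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_mirnas = 10), "exceed")
  expect_error(sim_config(de_fraction = 1.5), "de_fraction")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(mirna_mrna_links = list(
    list(hub = 1, n_correlated_genes = 10, target_correlation = 1.2))), "target_correlation")
})

test_that("generated cohorts are paired, complete and deterministic", {
  cfg <- small_sim_config(seed = 42)
  g1 <- generate_mirna_counts(cfg)
  g2 <- generate_mirna_counts(cfg)
  expect_identical(g1$counts$counts, g2$counts$counts)
  expect_identical(g1$truth$de_young, g2$truth$de_young)

  meta <- g1$counts$metadata
  # every patient appears exactly twice: one tumor, one normal
  tab <- table(meta$patient_id, meta$tissue)
  expect_true(all(tab == 1))
  expect_identical(sort(unique(meta$group)), c("old", "young"))
  expect_true(all(g1$counts$counts >= 0))
  expect_identical(storage.mode(g1$counts$counts), "integer")
  # planted hubs are module members
  expect_true(all(g1$truth$planted_hubs %in% names(g1$truth$module_membership)))
  # every linked gene is in the mRNA universe
  for (l in g1$truth$correlated_gene_map) {
    expect_true(all(l$gene %in% g1$truth$mrna_features))
  }
})

test_that("null configuration plants no systematic tumor/normal ratio", {
  cfg <- sim_config(n_young_patients = 12, n_old_patients = 12, n_mirnas = 60,
                    n_mrnas = 50, de_fraction = 0, module_specs = list(),
                    mirna_mrna_links = list(), enriched_set_spec = NULL,
                    n_gene_sets = 2, batch_effect_sd = 0, seed = 5)
  gen <- generate_mirna_counts(cfg)
  m <- gen$counts$counts
  meta <- gen$counts$metadata
  lcpm <- log2((sweep(m, 2, colSums(m), "/") * 1e6) + 0.5)
  d <- rowMeans(lcpm[, meta$tissue == "tumor"]) - rowMeans(lcpm[, meta$tissue == "normal"])
  expect_true(nrow(gen$truth$de_young) == 0)
  # mean ratio centred on 1 (log2 ratio on 0) across features
  expect_lt(abs(mean(d)), 0.05)
  expect_lt(max(abs(d)), 0.5)
})

test_that("planted fold change is recovered by the generator's own means", {
  # near-Poisson, high depth, a small planted fraction (so count
  # renormalization cannot shift the composition): the empirical
  # tumor/normal log2 ratio of planted features concentrates on the
  # planted value
  reps <- 200
  ratios <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg <- sim_config(n_young_patients = 4, n_old_patients = 4, n_mirnas = 200,
                      n_mrnas = 50, de_fraction = 0.05, planted_log2fc = 2,
                      nb_dispersion = 1e-4, library_size_range = c(5e6, 5e6),
                      module_specs = list(), mirna_mrna_links = list(),
                      enriched_set_spec = NULL, n_gene_sets = 2,
                      batch_effect_sd = 0, seed = 1000 + i)
    gen <- generate_mirna_counts(cfg)
    m <- gen$counts$counts
    meta <- gen$counts$metadata
    y <- meta$group == "young"
    lt <- log2(rowMeans(m[, y & meta$tissue == "tumor", drop = FALSE]) + 0.5)
    ln <- log2(rowMeans(m[, y & meta$tissue == "normal", drop = FALSE]) + 0.5)
    planted <- gen$truth$de_young
    i_up <- match(planted$feature[planted$log2fc > 0], rownames(m))
    ratios[i] <- mean(lt[i_up] - ln[i_up])
  }
  expect_lt(abs(mean(ratios) - 2), 0.2)
})

test_that("mRNA links hit their target correlation", {
  cfg <- small_sim_config(seed = 9)
  gen <- generate_mirna_counts(cfg)
  norm <- tmm_normalize(gen$counts)
  mrna <- generate_mrna_matrix(cfg, gen$truth, norm$log_expr)
  expect_identical(colnames(mrna), colnames(norm$log_expr))

  # rho = 0.8 link at n = 40 samples: sample r inside the Fisher-z 95% band
  hub <- names(gen$truth$correlated_gene_map)[1]
  link <- gen$truth$correlated_gene_map[[hub]]
  n <- ncol(mrna)
  band <- tanh(atanh(0.8) + c(-1, 1) * 1.96 / sqrt(n - 3))
  r_obs <- cor(norm$log_expr[hub, ], mrna[link$gene[1], ])
  expect_gt(r_obs, band[1])
  expect_lt(r_obs, band[2])

  # rho = 1 is reproduced exactly
  cfg1 <- small_sim_config(seed = 10,
    mirna_mrna_links = list(list(hub = 1, n_correlated_genes = 1,
                                 target_correlation = 1 - 1e-12)))
  gen1 <- generate_mirna_counts(cfg1)
  norm1 <- tmm_normalize(gen1$counts)
  mr1 <- generate_mrna_matrix(cfg1, gen1$truth, norm1$log_expr)
  h1 <- names(gen1$truth$correlated_gene_map)[1]
  g1 <- gen1$truth$correlated_gene_map[[h1]]$gene[1]
  expect_equal(cor(norm1$log_expr[h1, ], mr1[g1, ]), 1, tolerance = 1e-6)
})

test_that("unlinked genes behave as null correlations", {
  # exact null law: P(|r| < 0.5) = pbeta(0.25, 1/2, (n-2)/2) = 0.979 at n = 21
  p_exact <- pbeta(0.25, 0.5, 19 / 2)
  # a 2-member module provides the planted hub the link needs
  cfg <- sim_config(n_young_patients = 6, n_old_patients = 5, n_mirnas = 40,
                    n_mrnas = 800, de_fraction = 0.1,
                    module_specs = list(list(direction = "up", n_members = 2,
                                             hub_count = 1,
                                             within_module_correlation = 0.5)),
                    mirna_mrna_links = list(list(hub = 1, n_correlated_genes = 1,
                                                 target_correlation = 0.5)),
                    enriched_set_spec = NULL, n_gene_sets = 2, seed = 77)
  gen <- generate_mirna_counts(cfg)
  norm <- tmm_normalize(gen$counts)
  mrna <- generate_mrna_matrix(cfg, gen$truth, norm$log_expr)
  hub <- names(gen$truth$correlated_gene_map)[1]
  linked <- gen$truth$correlated_gene_map[[hub]]$gene
  unlinked <- setdiff(rownames(mrna), linked)
  samp <- colnames(mrna)[seq_len(21)]  # n = 21 samples
  r <- as.numeric(cor(norm$log_expr[hub, samp], t(mrna[unlinked, samp])))
  frac <- mean(abs(r) < 0.5)
  se <- sqrt(p_exact * (1 - p_exact) / length(r))
  expect_lt(abs(frac - p_exact), 4 * se + 0.01)
})

test_that("gene-set generation plants the promised overlap", {
  cfg <- small_sim_config(seed = 3,
                          enriched_set_spec = list(hub = 1, overlap_fraction = 1))
  gen <- generate_mirna_counts(cfg)
  sets <- generate_gene_sets(cfg, gen$truth)
  truth <- attr(sets, "truth")
  enriched <- names(truth$enriched_sets)[1]
  hub <- truth$enriched_sets[[1]]$hub
  linked <- truth$correlated_gene_map[[hub]]$gene
  # overlap_fraction = 1: every linked gene is inside the enriched set
  expect_true(all(linked %in% sets[[enriched]]))
  expect_setequal(truth$enriched_sets[[1]]$planted_overlap, linked)

  # random sets have overlap near the hypergeometric expectation m*K/N
  N <- length(attr(sets, "universe"))
  other <- setdiff(names(sets), enriched)
  obs <- vapply(other, function(nm) length(intersect(sets[[nm]], linked)), 0)
  expected <- vapply(other, function(nm) length(sets[[nm]]) * length(linked) / N, 0)
  expect_lt(abs(mean(obs - expected)), 3 * sqrt(sum(expected)) / length(other) + 1)

  # zero sets -> empty collection and empty downstream ORA
  cfg0 <- small_sim_config(seed = 4, n_gene_sets = 0)
  sets0 <- generate_gene_sets(cfg0, generate_mirna_counts(cfg0)$truth)
  expect_length(sets0, 0)
  ora0 <- run_enrichment_battery(list(h = c("gene0001", "gene0002")), sets0,
                                 sprintf("gene%04d", 1:100))
  expect_identical(nrow(ora0), 0L)
})

test_that("fixtures round-trip through disk exactly", {
  cfg <- small_sim_config(seed = 12)
  gen <- generate_mirna_counts(cfg)
  norm <- tmm_normalize(gen$counts)
  mrna <- generate_mrna_matrix(cfg, gen$truth, norm$log_expr)
  sets <- generate_gene_sets(cfg, gen$truth)
  truth <- attr(sets, "truth")
  dir <- withr::local_tempdir()
  write_fixture(dir, gen$counts, mrna, sets, truth)

  back <- read_fixture(dir)
  expect_identical(back$counts$counts, gen$counts$counts)
  expect_identical(back$counts$metadata, gen$counts$metadata)
  expect_equal(back$mrna, mrna, tolerance = 1e-12)
  expect_identical(lapply(back$sets, identity)[names(sets)],
                   lapply(sets, identity))
  expect_identical(back$truth$planted_hubs, truth$planted_hubs)
  # metadata row count equals sample count; GMT line count equals set count
  expect_identical(nrow(back$counts$metadata), ncol(gen$counts$counts))
  expect_length(readLines(file.path(dir, "gene_sets.gmt")), length(sets))
})
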