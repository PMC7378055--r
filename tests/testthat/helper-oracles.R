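# Independent reference implementations used as oracles, plus small fixture
# builders.  These deliberately re-derive results from first principles and
# never call the package functions they check.

# Step-by-step TMM factors (trim 30% of M, 5% of A, inverse asymptotic
# binomial variance weights), written directly from the published
# definition of the method.
hand_tmm_factors <- function(counts, ref) {
  lib <- colSums(counts)
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]
    refc <- counts[, ref]
    nO <- lib[j]
    nR <- lib[ref]
    keep <- obs > 0 & refc > 0
    obs <- obs[keep]
    refc <- refc[keep]
    M <- log2((obs / nO) / (refc / nR))
    A <- (log2(obs / nO) + log2(refc / nR)) / 2
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    v <- (nO - obs) / (nO * obs) + (nR - refc) / (nR * refc)
    2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
  }, 0)
  f / exp(mean(log(f)))
}

# Brute-force maximal cliques by exhaustive subset enumeration (graphs with
# at most ~12 nodes).
brute_maximal_cliques <- function(adj) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  complete <- list()
  for (code in seq_len(2^n - 1)) {
    s <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    if (length(s) == 1 || all(adj[s, s][upper.tri(adj[s, s])] == 1)) {
      complete[[length(complete) + 1]] <- s
    }
  }
  is_max <- vapply(complete, function(s) {
    !any(vapply(complete, function(t) length(t) > length(s) && all(s %in% t), TRUE))
  }, TRUE)
  lapply(complete[is_max], function(s) sort(nodes[s]))
}

brute_mcc <- function(adj) {
  cl <- brute_maximal_cliques(adj)
  scores <- stats::setNames(numeric(nrow(adj)), rownames(adj))
  for (C in cl) scores[C] <- scores[C] + factorial(length(C) - 1)
  scores
}

# random adjacency matrix with edge probability p
random_adj <- function(n, p) {
  adj <- matrix(0, n, n, dimnames = list(paste0("n", seq_len(n)), paste0("n", seq_len(n))))
  up <- which(upper.tri(adj))
  adj[up] <- stats::rbinom(length(up), 1, p)
  adj + t(adj)
}

graph_from_adj <- function(adj) {
  ij <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  make_coexpression_graph(data.frame(from = rownames(adj)[ij[, 1]],
                                     to = rownames(adj)[ij[, 2]]),
                          nodes = rownames(adj))
}

# small cohort configuration for fast end-to-end tests; any sim_config
# argument can be overridden through ...
small_sim_config <- function(seed = 1, ...) {
  args <- list(
    n_young_patients = 10, n_old_patients = 10, n_mirnas = 120, n_mrnas = 500,
    de_fraction = 0.25,
    module_specs = list(
      list(direction = "up", n_members = 8, hub_count = 1, within_module_correlation = 0.7),
      list(direction = "down", n_members = 8, hub_count = 1, within_module_correlation = 0.7)
    ),
    mirna_mrna_links = list(
      list(hub = 1, n_correlated_genes = 20, target_correlation = 0.8),
      list(hub = 2, n_correlated_genes = 20, target_correlation = -0.8)
    ),
    n_gene_sets = 8,
    seed = seed
  )
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_config, args)
}

# sample metadata for a single-group paired design
paired_meta <- function(n_pairs, group = "young", batch = 1) {
  data.frame(
    sample_id = c(sprintf("P%02d_T", seq_len(n_pairs)), sprintf("P%02d_N", seq_len(n_pairs))),
    patient_id = rep(sprintf("P%02d", seq_len(n_pairs)), 2),
    tissue = rep(c("tumor", "normal"), each = n_pairs),
    group = group, batch = batch,
    stringsAsFactors = FALSE
  )
}
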