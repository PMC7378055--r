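test_that("maximal cliques are exact on canonical graphs", {
  a4 <- matrix(1, 4, 4) - diag(4)
  dimnames(a4) <- list(letters[1:4], letters[1:4])
  expect_identical(maximal_cliques(a4), list(c("a", "b", "c", "d")))

  path <- make_coexpression_graph(data.frame(from = c("a", "b"), to = c("b", "c")))
  expect_identical(maximal_cliques(path), list(c("a", "b"), c("b", "c")))

  # isolated node is its own maximal clique
  lone <- make_coexpression_graph(data.frame(from = "a", to = "b"), nodes = "z")
  expect_identical(maximal_cliques(lone), list(c("a", "b"), "z"))
})

test_that("maximal cliques agree with exhaustive enumeration on random graphs", {
  for (i in 1:50) {
    set.seed(i)
    adj <- random_adj(8, 0.4)
    got <- maximal_cliques(adj)
    want <- brute_maximal_cliques(adj)
    key <- function(l) sort(vapply(l, paste, "", collapse = "|"))
    expect_identical(key(got), key(want))
    # every returned set is complete and none is contained in another
    for (C in got) {
      s <- match(C, rownames(adj))
      expect_true(length(s) == 1 || all(adj[s, s][upper.tri(adj[s, s])] == 1))
    }
  }
})

test_that("MCC scores follow the factorial clique sum", {
  a3 <- matrix(1, 3, 3) - diag(3)
  dimnames(a3) <- list(letters[1:3], letters[1:3])
  expect_equal(unname(mcc_scores(a3)), rep(2, 3), ignore_attr = TRUE)  # (3-1)! each

  star <- make_coexpression_graph(data.frame(from = "hub", to = paste0("l", 1:5)))
  sc <- mcc_scores(star)
  expect_equal(sc[["hub"]], 5)
  expect_true(all(sc[paste0("l", 1:5)] == 1))

  # triangle-free graphs: MCC equals degree (trees and bipartite graphs)
  set.seed(3)
  for (i in 1:10) {
    # random tree via random parent links
    n <- 10
    parent <- c(NA, vapply(2:n, function(v) sample(v - 1, 1), 0))
    tree <- make_coexpression_graph(
      data.frame(from = paste0("n", parent[-1]), to = paste0("n", 2:n)))
    sc_t <- mcc_scores(tree)
    deg <- rowSums(tree$adj)
    expect_equal(sc_t[names(deg)], deg)

    # random bipartite graph
    adj <- matrix(0, 8, 8, dimnames = list(paste0("n", 1:8), paste0("n", 1:8)))
    cross <- matrix(rbinom(16, 1, 0.5), 4, 4)
    adj[1:4, 5:8] <- cross
    adj[5:8, 1:4] <- t(cross)
    keep <- rowSums(adj) > 0
    adj <- adj[keep, keep, drop = FALSE]
    if (nrow(adj)) expect_equal(mcc_scores(adj), rowSums(adj), ignore_attr = TRUE)
  }
})

test_that("MCC agrees with brute force and is relabeling-invariant", {
  for (i in 1:30) {
    set.seed(100 + i)
    adj <- random_adj(8, 0.45)
    expect_equal(mcc_scores(adj), brute_mcc(adj), ignore_attr = TRUE)

    perm <- sample(8)
    padj <- adj[perm, perm]
    expect_equal(mcc_scores(padj)[rownames(adj)], mcc_scores(adj),
                 ignore_attr = TRUE)
  }
})

test_that("exact big-integer arithmetic survives large cliques", {
  # a 21-clique: every node scores 20! = 2432902008176640000, which exceeds
  # 2^53 and must come out exactly in the decimal representation
  n <- 21
  adj <- matrix(1, n, n) - diag(n)
  dimnames(adj) <- list(sprintf("v%02d", 1:n), sprintf("v%02d", 1:n))
  sc <- mcc_scores(adj)
  expect_identical(unique(unname(attr(sc, "exact"))), "2432902008176640000")

  # 26-clique: 25! is a 26-digit number
  n <- 26
  adj <- matrix(1, n, n) - diag(n)
  dimnames(adj) <- list(sprintf("v%02d", 1:n), sprintf("v%02d", 1:n))
  sc26 <- mcc_scores(adj)
  expect_identical(unique(unname(attr(sc26, "exact"))),
                   "15511210043330985984000000")
})

test_that("hub ranking orders by MCC, degree, then id with dense ranks", {
  # two triangles sharing node x, plus a pendant on one triangle
  g <- make_coexpression_graph(data.frame(
    from = c("x", "x", "a", "x", "x", "c", "a"),
    to   = c("a", "b", "b", "c", "d", "d", "p")))
  sc <- mcc_scores(g)
  rk <- rank_hubs(sc, g, k = 20)
  expect_identical(nrow(rk), 6L)          # k beyond n returns all nodes
  expect_identical(rk$feature[1], "x")    # two triangles: MCC 4
  # a (triangle + pendant edge: 2 + 1 = 3) precedes b, c, d (2)
  expect_identical(rk$feature[2], "a")
  # b, c, d tie on MCC = 2 and degree = 2: lexicographic, same dense rank
  expect_identical(rk$feature[3:5], c("b", "c", "d"))
  expect_identical(rk$rank[3:5], rep(rk$rank[3], 3))
  expect_true(all(diff(rk$mcc) <= 0))

  # degree breaks MCC ties
  g2 <- make_coexpression_graph(data.frame(
    from = c("a", "b", "c", "c", "c"), to = c("b", "z1", "z2", "z3", "a")))
  sc2 <- mcc_scores(g2)
  rk2 <- rank_hubs(sc2, g2, k = 3)
  expect_identical(rk2$feature[1], "c")   # MCC 3 beats everyone
  expect_identical(nrow(rk2), 3L)
})

test_that("hub-set comparison partitions and annotates correctly", {
  mk_rank <- function(features) {
    structure(data.frame(rank = seq_along(features), feature = features,
                         mcc = rev(seq_along(features)), degree = 1,
                         stringsAsFactors = FALSE),
              class = c("hub_ranking", "data.frame"))
  }
  de <- function(features, lfc, fdr) {
    structure(data.frame(feature = features, log2fc = lfc, mean_expr = 1,
                         t_stat = 0, p_value = fdr, fdr = fdr,
                         stringsAsFactors = FALSE),
              class = c("de_result", "data.frame"))
  }
  ry <- mk_rank(c("m1", "m2", "m3"))
  ro <- mk_rank(c("m2", "m3", "m4"))
  dey <- de(paste0("m", 1:4), c(2, -1.5, 1.2, 0.1), c(0.001, 0.01, 0.02, 0.9))
  deo <- de(paste0("m", 1:4), c(0.1, -1.4, 1.1, 2.3), c(0.8, 0.01, 0.03, 0.001))
  cmp <- compare_hub_sets(ry, ro, dey, deo)
  expect_identical(cmp$shared, c("m2", "m3"))
  expect_identical(cmp$exclusive_young, "m1")
  expect_identical(cmp$exclusive_old, "m4")
  expect_length(intersect(cmp$shared, cmp$exclusive_young), 0)
  ann <- cmp$annotation
  expect_identical(ann$direction_young[ann$feature == "m1"], "up")
  expect_false(ann$significant_old[ann$feature == "m1"])

  # identical and disjoint rankings
  expect_length(compare_hub_sets(ry, ry)$exclusive_young, 0)
  expect_length(compare_hub_sets(ry, mk_rank(c("z1", "z2")))$shared, 0)
})
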