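count_matrix_from <- function(m, batch = 1) {
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  rownames(m) <- sprintf("f%03d", seq_len(nrow(m)))
  storage.mode(m) <- "integer"
  meta <- data.frame(sample_id = colnames(m),
                     patient_id = colnames(m),
                     tissue = "tumor", group = "young",
                     batch = rep_len(batch, ncol(m)),
                     stringsAsFactors = FALSE)
  structure(list(counts = m, metadata = meta), class = "count_matrix")
}

test_that("TMM factors are 1 in symmetric and pure-depth cases", {
  set.seed(1)
  base <- matrix(rpois(20 * 4, 100), 20, 4)
  cm <- count_matrix_from(cbind(base[, 1], base[, 1], base[, 1], base[, 1]))
  norm <- tmm_normalize(cm)
  expect_equal(unname(norm$scale_factors), rep(1, 4), tolerance = 1e-12)

  # doubling depth is absorbed by the library size, not the factor
  cm2 <- count_matrix_from(cbind(base[, 1], base[, 1] * 2L))
  norm2 <- tmm_normalize(cm2)
  expect_equal(unname(norm2$scale_factors), c(1, 1), tolerance = 1e-12)
  # and the log-CPM columns agree up to the pseudocount's depth effect
  expect_lt(max(abs(norm2$log_expr[, 1] - norm2$log_expr[, 2])), 0.01)
})

test_that("TMM factors match a step-by-step reference calculation", {
  set.seed(42)
  m <- matrix(rpois(20 * 4, 200), 20, 4)
  m[1, 2] <- 5000L  # one inflated feature distorts sample 2's composition
  cm <- count_matrix_from(m)
  norm <- tmm_normalize(cm, reference_sample = "s01")
  expect_equal(unname(norm$scale_factors),
               unname(hand_tmm_factors(cm$counts, ref = 1)),
               tolerance = 1e-10)
  # factors multiply to 1 on the log scale
  expect_equal(mean(log(norm$scale_factors)), 0, tolerance = 1e-12)
})

test_that("TMM is scale-invariant and errors on all-zero samples", {
  set.seed(3)
  m <- matrix(rpois(30 * 4, 150), 30, 4)
  cm <- count_matrix_from(m)
  f1 <- tmm_normalize(cm, reference_sample = "s01")$scale_factors
  m2 <- m
  m2[, 3] <- m2[, 3] * 4L
  f2 <- tmm_normalize(count_matrix_from(m2), reference_sample = "s01")$scale_factors
  expect_equal(unname(f1[-3] / exp(mean(log(f1[-3])))),
               unname(f2[-3] / exp(mean(log(f2[-3])))), tolerance = 1e-10)

  m3 <- m
  m3[, 2] <- 0L
  expect_error(tmm_normalize(count_matrix_from(m3)), "s02")
})

test_that("quantile normalization matches the order-statistic definition", {
  x <- cbind(c(2, 4, 6), c(1, 9, 5), c(3, 8, 7))
  colnames(x) <- paste0("s", 1:3)
  rownames(x) <- paste0("f", 1:3)
  qn <- quantile_normalize(x)
  mean_sorted <- rowMeans(apply(x, 2, sort))  # (2, 16/3, 23/3)
  expected <- cbind(mean_sorted[c(1, 2, 3)],
                    mean_sorted[c(1, 3, 2)],
                    mean_sorted[c(1, 3, 2)])
  dimnames(expected) <- dimnames(x)
  expect_equal(qn, expected, tolerance = 1e-12)

  # identical samples unchanged
  y <- cbind(c(1, 5, 9), c(1, 5, 9))
  expect_equal(unname(quantile_normalize(y)), unname(y))

  # monotone transforms of one another end up identical
  z <- cbind(c(1, 2, 3, 4), exp(c(1, 2, 3, 4)))
  qz <- quantile_normalize(z)
  expect_equal(qz[, 1], qz[, 2], tolerance = 1e-12)

  # idempotent
  set.seed(8)
  w <- matrix(rnorm(200), 50, 4)
  expect_equal(quantile_normalize(quantile_normalize(w)),
               quantile_normalize(w), tolerance = 1e-12)
})

test_that("batch adjustment removes location shifts and preserves feature means", {
  # single batch: identity
  set.seed(5)
  x <- matrix(rnorm(40 * 10, 8), 40, 10,
              dimnames = list(paste0("f", 1:40), paste0("s", 1:10)))
  expect_identical(batch_adjust(x, rep(1, 10)), x)

  # identical features, pure shift delta on batch 2, no other noise:
  # the shift is removed exactly
  base <- rnorm(10, 8)
  xs <- matrix(rep(base, each = 30), 30, 10, byrow = FALSE,
               dimnames = list(paste0("f", 1:30), paste0("s", 1:10)))
  xs <- t(matrix(base, 10, 30))
  dimnames(xs) <- list(paste0("f", 1:30), paste0("s", 1:10))
  batch <- rep(1:2, each = 5)
  xs[, batch == 2] <- xs[, batch == 2] + 3
  adj <- batch_adjust(xs, batch)
  gap <- rowMeans(adj[, batch == 2]) - rowMeans(adj[, batch == 1])
  expect_equal(unname(gap), rep(0, 30), tolerance = 1e-8)

  # noisy case: feature grand means preserved to 1e-8
  xn <- x
  xn[, 1:5] <- xn[, 1:5] + rnorm(40)
  adj2 <- batch_adjust(xn, rep(1:2, each = 5))
  expect_equal(rowMeans(adj2), rowMeans(xn), tolerance = 1e-8)

  expect_error(batch_adjust(x, c(1, rep(2, 9))), "fewer than 2")
})

test_that("batch adjustment agrees with the reference empirical-Bayes tool", {
  # independent cross-check against sva::ComBat on a regular noisy dataset
  skip_if_not_installed("sva")
  set.seed(17)
  x <- matrix(rnorm(200 * 16, rep(runif(200, 4, 12), 16), 1), 200, 16,
              dimnames = list(sprintf("f%03d", 1:200), sprintf("s%02d", 1:16)))
  batch <- rep(1:2, each = 8)
  x[, batch == 2] <- x[, batch == 2] + rnorm(200, 0, 0.8)
  mine <- batch_adjust(x, batch)
  ref <- suppressMessages(sva::ComBat(dat = x, batch = batch, mod = NULL,
                                      par.prior = TRUE, prior.plots = FALSE))
  # same algorithm up to the grand-mean restoration: compare centred outputs
  expect_equal(mine - rowMeans(mine), ref - rowMeans(ref), tolerance = 1e-6)
})

test_that("batch adjustment collapses the batch component of the PCA", {
  cfg <- small_sim_config(seed = 21, batch_effect_sd = 1)
  gen <- generate_mirna_counts(cfg)
  norm <- tmm_normalize(gen$counts)
  pre <- pca_batch_check(norm$log_expr, norm$metadata$batch)
  adj <- batch_adjust(norm)
  post <- pca_batch_check(adj$log_expr, adj$metadata$batch)
  expect_lt(post$batch_r2[1], 0.05)
  expect_lt(post$batch_r2[1], pre$batch_r2[1])
})

test_that("pca_batch_check reports sane variance fractions", {
  # deterministic rank-1 matrix: PC1 carries everything
  u <- 1:20
  v <- seq(0.5, 3, length.out = 6)
  x <- outer(u, v)
  dimnames(x) <- list(paste0("f", 1:20), paste0("s", 1:6))
  chk <- pca_batch_check(x, rep(1:2, 3))
  expect_equal(chk$var_explained[1], 1, tolerance = 1e-10)

  # batch-free noise: batch R2 on PC1 stays small in most draws
  set.seed(99)
  hits <- vapply(1:40, function(i) {
    y <- matrix(rnorm(60 * 12), 60, 12)
    pca_batch_check(y, rep(1:2, each = 6))$batch_r2[1] < 0.2
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("outlier detection flags exactly the planted sample", {
  set.seed(11)
  means <- runif(500, 2, 14)
  x <- matrix(rnorm(500 * 20, means, 0.5), 500, 20,
              dimnames = list(NULL, sprintf("s%02d", 1:20)))
  # all structured samples share the gene-mean profile: none excluded
  expect_length(detect_outliers(x), 0)
  # one sample replaced by independent noise: exactly that one excluded
  x[, 7] <- rnorm(500, mean(means), 2)
  expect_identical(detect_outliers(x), "s07")
  # contract on the threshold
  expect_error(detect_outliers(x, threshold = 0), "threshold")
  expect_error(detect_outliers(x, threshold = 1.2), "threshold")
})
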