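test_that("Spearman correlations match hand-computed values", {
  mat <- cbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3), s3 = c(3, 2, 1),
               s4 = c(3, 1, 2))
  rownames(mat) <- c("g1", "g2", "g3")
  cc <- sampleCorrelation(mat, rownames(mat))
  expect_equal(cc["s1", "s2"], 1)                  # duplicated sample
  expect_equal(cc["s1", "s3"], -1)                 # rank reversal
  expect_equal(cc["s1", "s4"], -0.5)               # 1 - 6*6/(3*8)
  expect_true(isSymmetric(cc))
  expect_equal(unname(diag(cc)), rep(1, 4))
  expect_error(sampleCorrelation(mat, character(0)), "empty")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(2)
  mat <- matrix(rnorm(40 * 6), 40,
                dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:6)))
  a <- sampleCorrelation(mat, rownames(mat))
  b <- sampleCorrelation(exp(mat) + 5, rownames(mat))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("hierarchical clustering merges nearest items first", {
  mat <- rbind(g = c(0, 0, 1, 10))
  colnames(mat) <- paste0("s", 1:4)
  hc <- hierarchicalCluster(mat, axis = "samples")$hclust
  expect_equal(hc$height[1], 0)                    # identical pair first
  expect_equal(sort(-hc$merge[1, ]), c(1, 2))      # s1, s2 merge at 0
  expect_equal(hc$height[2], 1)                    # then {0,1} with s3
  expect_true(-3 %in% hc$merge[2, ])
  expect_error(hierarchicalCluster(mat, axis = "samples", k = 9), "exceeds")
})

test_that("planted blocks are recovered by a k = 3 cut", {
  set.seed(5)
  centers <- c(0, 10, 20)
  mat <- sapply(rep(1:3, each = 6), function(b) rnorm(25, centers[b], 1))
  rownames(mat) <- sprintf("g%02d", 1:25)
  colnames(mat) <- sprintf("s%02d", 1:18)
  cl <- hierarchicalCluster(mat, axis = "samples", k = 3)$clusters
  truth <- rep(1:3, each = 6)
  expect_equal(length(unique(paste(cl, truth))), 3) # perfect recovery
})

test_that("t-SNE embedding is reproducible and validates perplexity", {
  set.seed(8)
  mat <- matrix(rnorm(20 * 40), 20,
                dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:40)))
  e1 <- embedSamples(mat, perplexity = 5, seed = 3)
  e2 <- embedSamples(mat, perplexity = 5, seed = 3)
  expect_identical(e1$coords, e2$coords)
  expect_equal(dim(e1$coords), c(40, 2))
  expect_error(embedSamples(mat, perplexity = 15), "perplexity")
})

test_that("t-SNE separates well-separated planted clusters", {
  set.seed(11)
  mat <- cbind(matrix(rnorm(15 * 20, 0), 15), matrix(rnorm(15 * 20, 8), 15))
  rownames(mat) <- sprintf("g%02d", 1:15)
  colnames(mat) <- sprintf("s%02d", 1:40)
  emb <- embedSamples(mat, perplexity = 5, seed = 1)$coords
  truth <- rep(1:2, each = 20)
  # silhouette of the true labels on the embedding
  d <- as.matrix(dist(emb))
  sil <- vapply(seq_len(40), function(i) {
    a <- mean(d[i, truth == truth[i]][-which(which(truth == truth[i]) == i)])
    b <- mean(d[i, truth != truth[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("discrimination scoring maps clusters to groups at its best", {
  groups <- stats::setNames(rep(c("young", "middle", "old"), each = 4),
                            paste0("s", 1:12))
  clusters <- stats::setNames(rep(c(3, 1, 2), each = 4), names(groups))
  sc <- scoreAgeDiscrimination(clusters, groups)
  expect_equal(sc$n_correct, 12)                   # perfect under remapping
  expect_equal(sc$accuracy, 1)
  # invariant to relabeling the clusters
  sc2 <- scoreAgeDiscrimination(stats::setNames(c(1, 2, 3)[clusters],
                                                names(clusters)), groups)
  expect_equal(sc2$n_correct, sc$n_correct)
})

test_that("individuals are scored by the majority of their samples", {
  samples <- paste0("s", 1:10)
  groups <- stats::setNames(c(rep("young", 8), "middle", "old"), samples)
  individuals <- stats::setNames(c(rep("indA", 8), "indB", "indC"), samples)
  # indA: 6 samples in the young cluster, 2 elsewhere -> majority correct
  clusters <- stats::setNames(c(rep(1, 6), 2, 2, 2, 3), samples)
  sc <- scoreAgeDiscrimination(clusters, groups, individuals)
  expect_true(sc$per_individual$correct[sc$per_individual$individual ==
                                          "indA"])
})

test_that("random clusters score near chance after best-of-6 correction", {
  set.seed(21)
  n <- 300
  samples <- paste0("s", seq_len(n))
  groups <- stats::setNames(rep(c("young", "middle", "old"), each = n / 3),
                            samples)
  accs <- replicate(40, {
    cl <- stats::setNames(sample(1:3, n, replace = TRUE), samples)
    scoreAgeDiscrimination(cl, groups)$accuracy
  })
  expect_lt(abs(mean(accs) - 1 / 3), 0.05)
})

test_that("heatmap z-scores use the n-1 SD convention and clip", {
  mat <- rbind(r1 = c(0, 10), r2 = c(5, 5))
  z <- standardizeForHeatmap(mat, clip = 3)
  expect_equal(unname(z["r1", ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(z["r2", ]), c(0, 0))         # constant row -> zeros
  big <- rbind(r = c(rep(0, 99), 100))
  expect_equal(max(standardizeForHeatmap(big, clip = 3)), 3)  # clipped
})
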