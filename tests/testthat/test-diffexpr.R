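test_that("age-group bounds follow the cohort definition", {
  expect_equal(assignAgeGroup(c(16, 44, 45, 74, 75, 106)),
               c("young", "young", "middle", "middle", "old", "old"))
  expect_error(assignAgeGroup(15), "below 16")
})

test_that("gene-level summary is the per-sample probe-set median", {
  m <- rbind(p1 = c(1, 2), p2 = c(5, 6), p3 = c(100, 0),
             q1 = c(2, 2), q2 = c(4, 4))
  out <- summarizeGeneLevel(m, c("tA", "tA", "tA", "tB", "tB"))
  expect_equal(out["tA", ], c(5, 2))          # odd count: middle value
  expect_equal(out["tB", ], c(3, 3))          # even count: mean of middle
  one <- summarizeGeneLevel(m[1, , drop = FALSE], "tA")
  expect_equal(one["tA", ], m["p1", ])        # single probe set: identity
  expect_warning(summarizeGeneLevel(m, c("tA", "tA", "tA", "tB", "tB"),
                                    transcripts = c("tA", "tB", "tC")),
                 "tC")
})

test_that("rowwise ANOVA agrees with the classical single-gene fit", {
  set.seed(42)
  mat <- matrix(rnorm(20 * 30), 20,
                dimnames = list(sprintf("g%02d", 1:20), NULL))
  groups <- rep(c("young", "middle", "old"), each = 10)
  res <- anovaAging(mat, group_labels = groups)
  for (i in c(1, 7, 20)) {
    ref <- stats::oneway.test(mat[i, ] ~ factor(groups), var.equal = TRUE)
    expect_equal(res$F[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("ANOVA handles flat and degenerate genes as specified", {
  groups <- rep(c("young", "middle", "old"), each = 3)
  flat <- matrix(rep(c(1, 2, 3), 3), nrow = 1,
                 dimnames = list("flat", NULL))
  res <- anovaAging(flat, group_labels = groups)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  sep <- matrix(c(0, 0, 0, 0, 0, 0, 3, 3, 3), nrow = 1,
                dimnames = list("sep", NULL))
  res2 <- anovaAging(sep, group_labels = groups)
  expect_true(is.infinite(res2$F))
  expect_equal(res2$p, 0)
  # groups with < 2 samples are dropped; < 2 usable groups -> untestable
  res3 <- anovaAging(flat, group_labels = c(rep("young", 7), "middle",
                                            "old"))
  expect_true(is.na(res3$p))
})

test_that("BH adjustment matches the hand computation", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrAdjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdrAdjust(0.005), 0.005)
  q <- fdrAdjust(c(0.01, NA, 0.5))
  expect_true(is.na(q[2]))
  p <- runif(50)
  expect_true(all(fdrAdjust(p) >= p))          # q >= p, always
  expect_error(fdrAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("fold change reports delta and direction with a 'none' tie", {
  mat <- rbind(up = c(1, 1, 2, 2), down = c(3, 3, 1, 1), tie = c(2, 2, 2, 2))
  labs <- c("young", "young", "old", "old")
  fc <- foldChange(mat, labs)
  expect_equal(fc$delta_log2, c(1, -2, 0))
  expect_equal(fc$direction, c("up", "down", "none"))
  expect_error(foldChange(mat, rep("old", 4)), "young")
})

test_that("regional breadth follows the 1 / 2-7 / >=8 / all-10 taxonomy", {
  regions <- paste0("R", 1:10)
  sets <- stats::setNames(
    list(c("g1", "gS"), c("g1", "g2"), c("g1", "g2"), c("g1", "g2"),
         c("g1", "g2"), c("g1", "g2"), c("g1", "g2"), c("g1", "g2", "g8"),
         c("g1", "g2", "g8"), c("g1", "g8")),
    regions)
  br <- classifyRegionalBreadth(sets)
  cat_of <- function(g) br$category[br$gene == g]
  expect_equal(cat_of("g1"), "cross_regional")    # all 10 regions
  expect_equal(cat_of("g2"), "multi_regional")    # 8 regions
  expect_equal(cat_of("g8"), "region_selective")  # 3 regions
  expect_equal(cat_of("gS"), "region_specific")   # exactly 1 region
})

test_that("breadth boundaries sit exactly at 1, 7, 8 and 10 regions", {
  mk <- function(n) {
    sets <- stats::setNames(rep(list(character(0)), 10), paste0("R", 1:10))
    for (i in seq_len(n)) sets[[i]] <- "g"
    classifyRegionalBreadth(sets)$category
  }
  expect_equal(mk(1), "region_specific")
  expect_equal(mk(2), "region_selective")
  expect_equal(mk(7), "region_selective")
  expect_equal(mk(8), "multi_regional")
  expect_equal(mk(9), "multi_regional")
  expect_equal(mk(10), "cross_regional")
})

test_that("breadth is invariant to region order and partitions the genes", {
  set.seed(7)
  regions <- paste0("R", 1:10)
  sets <- lapply(regions, function(r)
    sample(sprintf("g%02d", 1:40), sample(5:20, 1)))
  names(sets) <- regions
  a <- classifyRegionalBreadth(sets)
  b <- classifyRegionalBreadth(sets[sample(10)])
  expect_equal(a[order(a$gene), ], b[order(b$gene), ], ignore_attr = TRUE)
  sig_any <- unique(unlist(sets))
  expect_setequal(a$gene, sig_any)                 # partition of sig genes
  expect_equal(sum(table(a$category)), length(sig_any))
  expect_error(classifyRegionalBreadth(sets[1:5], n_regions_total = 5),
               "thresholds")
})

test_that("top-gene selection ranks by q, then p, then gene id", {
  tab <- data.frame(
    gene = c("gB", "gA", "gC", "gD"), region = "FCTX",
    F = 1, p = c(1e-6, 1e-6, 2e-6, 0.5),
    q = c(1e-4, 1e-4, 1e-4, 0.5))
  expect_equal(selectTopGenes(tab, "FCTX", 1), "gA")   # lexical tie-break
  expect_equal(selectTopGenes(tab, "FCTX", 3), c("gA", "gB", "gC"))
  expect_message(got <- selectTopGenes(tab, "FCTX", 10), "only 3")
  expect_equal(got, c("gA", "gB", "gC"))
})

test_that("over-representation p matches exact hypergeometric values", {
  universe <- sprintf("u%02d", 1:20)
  r <- overrepresentationTest(universe[1:10], universe[1:10], universe)
  expect_equal(r$p, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(overrepresentationTest(universe[1:5], universe, universe)$p,
               1)                                   # category = universe
  expect_error(overrepresentationTest("a", "a", character(0)), "universe")
})

test_that("over-representation agrees with brute-force enumeration", {
  universe <- letters[1:12]
  gene_set <- letters[1:5]
  category <- letters[c(1, 2, 6, 7)]
  got <- overrepresentationTest(gene_set, category, universe)$p
  expect_equal(got, bruteOverlapP(gene_set, category, universe),
               tolerance = 1e-12)
  # zero overlap with nonempty sets: tail sum equals 1 by enumeration
  cat0 <- letters[6:9]
  got0 <- overrepresentationTest(gene_set, cat0, universe)$p
  expect_equal(got0, bruteOverlapP(gene_set, cat0, universe),
               tolerance = 1e-12)
})
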