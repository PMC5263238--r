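test_that("histogram entropy hits its closed-form landmarks", {
  const <- array(128, dim = c(10, 10, 3))
  expect_equal(computeTileEntropy(const), 0)
  two <- array(0, dim = c(16, 16, 3))
  two[1:8, , ] <- 255                               # two equal gray levels
  expect_equal(computeTileEntropy(two), 1)
  all256 <- array(rep(0:255, each = 3), dim = c(16, 16, 3))
  all256[, , 1] <- matrix(0:255, 16); all256[, , 2] <- matrix(0:255, 16)
  all256[, , 3] <- matrix(0:255, 16)                # uniform 256 levels
  expect_equal(computeTileEntropy(all256), 8)
  expect_true(computeTileEntropy(array(runif(300) * 255,
                                       c(10, 10, 3))) <= 8)
})

test_that("entropy QC keeps only tiles above the exclusion threshold", {
  lowt <- methods::new("StainedTile",
                       pixels = array(200, dim = c(8, 8, 3)),
                       tileId = "flat", caseId = "c", ageGroup = "young",
                       groundTruth = data.frame())
  rich <- generateTile(tileConfig(width = 120, height = 100, n_stained = 6,
                                  n_counterstained = 6, noise_sd = 30,
                                  radius_range = c(8, 14),
                                  overlap_allowed = TRUE, seed = 2),
                       tile_id = "rich")
  qc <- entropyQC(list(lowt, rich), min_entropy = 5)
  expect_equal(qc$keep, c(FALSE, TRUE))
})

test_that("labeling is 8-connected (diagonal pixels join one object)", {
  mask <- matrix(0, 6, 6)
  mask[2, 2] <- 1; mask[3, 3] <- 1; mask[4, 2] <- 1   # diagonal chain
  mask[6, 6] <- 1                                      # separate
  lab <- neuroAging:::.label8(mask)
  expect_equal(max(lab), 2)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_equal(lab[3, 3], lab[4, 2])
  expect_true(lab[6, 6] != lab[2, 2])
})

test_that("segmentation recovers exact class counts on disjoint disks", {
  tl <- generateTile(tileConfig(width = 800, height = 600, n_stained = 10,
                                n_counterstained = 15,
                                radius_range = c(12, 20), seed = 17))
  obj <- segmentCells(tl)
  expect_equal(sum(obj$class == "stained"), 10)
  expect_equal(sum(obj$class == "other"), 15)
  expect_equal(nrow(obj), 25)                       # stained + other = total
  # centroids land near the planted centers
  gt <- groundTruth(tl)
  d <- sqrt(outer(obj$x, gt$x, `-`)^2 + outer(obj$y, gt$y, `-`)^2)
  expect_lt(max(apply(d, 2, min)), 3)
})

test_that("size bins follow the printed boundaries and partition >= 500", {
  expect_equal(unname(binByArea(c(499, 500, 3500, 7000, 10000))),
               c(1, 1, 1, 1))                       # 499 excluded
  expect_equal(binByArea(2999)[["small"]], 1)
  expect_equal(binByArea(3000)[["medium"]], 1)
  expect_equal(binByArea(9000)[["large"]], 1)       # large is [6000, 9000]
  expect_equal(binByArea(9001)[["very_large"]], 1)
  set.seed(3)
  areas <- runif(500, 500, 20000)
  expect_equal(sum(binByArea(areas)), 500)          # every area in one bin
})

test_that("per-tile stats are conserved and tidy summaries are additive", {
  tiles <- lapply(1:2, function(i)
    generateTile(tileConfig(width = 300, height = 240, n_stained = 3,
                            n_counterstained = 4, seed = i),
                 tile_id = paste0("t", i), case_id = "caseA",
                 age_group = "old"))
  st <- do.call(rbind, lapply(tiles, tileStats))
  expect_equal(st$stained + st$other, st$total)
  summ <- summarizeCase(st)
  tot <- summ[summ$tile_id == "(case total)" & summ$measure == "total",
              "count"]
  expect_equal(tot, sum(st$total))
})

test_that("density terciles split pooled counts 1..300 at 100/200", {
  stats <- data.frame(tile_id = sprintf("t%03d", 1:300),
                      case_id = rep(c("c1", "c2"), each = 150),
                      total = 1:300)
  out <- classifyDensity(stats, k = 30)
  expect_setequal(out$tile_id[out$density_class == "low"],
                  sprintf("t%03d", 1:100))
  expect_setequal(out$tile_id[out$density_class == "high"],
                  sprintf("t%03d", 201:300))
  # the k most extreme per case within each class are selected
  sel_low_c1 <- out$tile_id[out$selected & out$case_id == "c1" &
                              out$density_class == "low"]
  expect_setequal(sel_low_c1, sprintf("t%03d", 1:30))
  sel_high_c2 <- out$tile_id[out$selected & out$case_id == "c2" &
                               out$density_class == "high"]
  expect_setequal(sel_high_c2, sprintf("t%03d", 271:300))
})

test_that("density selection is deterministic on ties and logs shortfalls", {
  stats <- data.frame(tile_id = sprintf("t%02d", 1:9),
                      case_id = "c1", total = rep(5, 9))
  expect_message(out <- classifyDensity(stats, k = 50), "only")
  expect_identical(out$selected,
                   classifyDensity(stats, k = 50)$selected)
})

test_that("tile ranking by density matches a full sort oracle", {
  set.seed(4)
  stats <- data.frame(tile_id = sprintf("t%03d", 1:40),
                      total = sample(0:100, 40, TRUE))
  top <- rankTilesByDensity(stats, 10)
  oracle <- stats[order(-stats$total, stats$tile_id), ][1:10, ]
  expect_equal(top$tile_id, oracle$tile_id)
  expect_equal(rankTilesByDensity(stats, 1)$total, max(stats$total))
  expect_equal(nrow(rankTilesByDensity(stats, 999)), 40)
})
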