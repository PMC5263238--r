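# Shared fixture builders; everything is generated in code at test time.

# Small three-region study with one planted pan-regional effect.
smallPlantedStudy <- function(seed = 1L, effect = 2, n_individuals = 24,
                              regions = c("FCTX", "CRBL", "THAL"),
                              n_genes = 200) {
  cfg <- expressionStudyConfig(
    n_individuals = n_individuals, regions = regions, n_genes = n_genes,
    planted_effects = list(
      plantedEffect("G00001", regions, "up", effect)),
    noise_sd = 0.5, missing_region_rate = 0, seed = seed)
  generateExpressionStudy(cfg)
}

# Hand-built reference with known means (no generator involved).
handReference <- function(means) {
  methods::new("CellTypeReference", means = means,
               markerTruth = data.frame(gene = character(),
                                        cell_type = character()),
               params = list())
}

# Exhaustive-enumeration oracle for the right-tailed permutation p of a
# pooled two-sample t (all ways to choose the first group's tiles).
exactPermP <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  obs <- twoSampleT(x, y)
  picks <- utils::combn(length(v), n1)
  ts <- apply(picks, 2, function(i) twoSampleT(v[i], v[-i]))
  mean(ts >= obs - 1e-12)
}

# Brute-force over-representation oracle: enumerate every possible category
# draw of size k from the universe and count overlaps >= observed.
bruteOverlapP <- function(gene_set, category_genes, universe) {
  k <- length(category_genes)
  x <- length(intersect(gene_set, category_genes))
  draws <- utils::combn(length(universe), k)
  hits <- apply(draws, 2, function(i)
    length(intersect(universe[i], gene_set)) >= x)
  mean(hits)
}
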