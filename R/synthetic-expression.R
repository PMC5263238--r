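#' @importFrom stats rnorm runif
NULL

#' The ten sampled brain regions
#'
#' Region labels used by default throughout the package: frontal, temporal and
#' occipital cortex, intralobular white matter, cerebellum, substantia nigra,
#' putamen, thalamus, hippocampus and medulla.
#' @export
brainRegions <- function() {
  c("FCTX", "TCTX", "OCTX", "WHMT", "CRBL", "SNIG", "PUTM", "THAL",
    "HIPP", "MEDU")
}

#' Describe an aging effect to plant in a synthetic cohort
#'
#' @param gene_id gene identifier (must exist in the generated study).
#' @param affected_regions character vector of region labels carrying the
#'   effect; must be non-empty.
#' @param direction \code{"up"} or \code{"down"} with age.
#' @param effect_size log2 difference between the old and young group means
#'   (the middle group sits at the midpoint); must be >= 0.
#' @param celltype_label optional cell-type tag carried through to the truth
#'   table (used when simulating marker/breadth overlap).
#' @return a list of class \code{PlantedEffect}.
#' @export
plantedEffect <- function(gene_id, affected_regions,
                          direction = c("up", "down"), effect_size,
                          celltype_label = NA_character_) {
  direction <- match.arg(direction)
  if (length(affected_regions) < 1L)
    stop("'affected_regions' must be non-empty", call. = FALSE)
  .assertScalarNumber(effect_size, "effect_size", lower = 0)
  structure(list(gene_id = as.character(gene_id),
                 affected_regions = as.character(affected_regions),
                 direction = direction,
                 effect_size = effect_size,
                 celltype_label = as.character(celltype_label)),
            class = "PlantedEffect")
}

#' Configure a synthetic multi-region expression cohort
#'
#' The generated cohort emulates a post-mortem brain expression study: each
#' individual contributes one sample per region (some dropped at random),
#' ages are drawn uniformly over \code{age_range} so that the three age
#' groups (young 16-44, middle 45-74, old >= 75) have unequal sizes, and
#' aging effects listed in \code{planted_effects} are added as monotone
#' group-mean shifts on the log2 scale.
#'
#' @param n_individuals number of individuals (>= 6).
#' @param regions unique region labels, at most 10.
#' @param age_range integer years, within [16, 106].
#' @param n_genes number of genes.
#' @param planted_effects list of \code{\link{plantedEffect}} objects.
#' @param noise_sd residual SD in log2 units (> 0).
#' @param baseline_mean grand mean log2 signal.
#' @param region_offset_sd SD of per-region per-gene-block log2 shifts giving
#'   each region a transcriptional identity; 0 disables them.
#' @param n_gene_blocks number of gene blocks sharing a region offset.
#' @param missing_region_rate probability that an individual lacks a given
#'   region's sample.
#' @param seed integer seed; the same config and seed give bit-identical
#'   studies.
#' @return a list of class \code{ExpressionStudyConfig}.
#' @export
expressionStudyConfig <- function(n_individuals = 45,
                                  regions = brainRegions(),
                                  age_range = c(16, 106),
                                  n_genes = 5000,
                                  planted_effects = list(),
                                  noise_sd = 0.5,
                                  baseline_mean = 8,
                                  region_offset_sd = 0.3,
                                  n_gene_blocks = 20,
                                  missing_region_rate = 0.08,
                                  seed = 1L) {
  .assertScalarNumber(n_individuals, "n_individuals", lower = 6)
  if (anyDuplicated(regions)) stop("regions must be unique", call. = FALSE)
  if (length(regions) < 1L || length(regions) > 10L)
    stop("between 1 and 10 regions are supported", call. = FALSE)
  if (length(age_range) != 2L || age_range[1] < 16 || age_range[2] > 106 ||
      age_range[1] > age_range[2])
    stop("age_range must lie within [16, 106]", call. = FALSE)
  .assertScalarNumber(n_genes, "n_genes", lower = 1)
  .assertScalarNumber(noise_sd, "noise_sd", lower = 0, strict_lower = TRUE)
  .assertScalarNumber(missing_region_rate, "missing_region_rate",
                      lower = 0, upper = 1)
  .assertScalarNumber(region_offset_sd, "region_offset_sd", lower = 0)
  if (!all(vapply(planted_effects, inherits, logical(1), "PlantedEffect")))
    stop("planted_effects must be a list of plantedEffect() objects",
         call. = FALSE)
  bad <- unlist(lapply(planted_effects,
                       function(e) setdiff(e$affected_regions, regions)))
  if (length(bad))
    stop("planted effect names unknown region(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  structure(list(n_individuals = as.integer(n_individuals),
                 regions = as.character(regions),
                 age_range = as.numeric(age_range),
                 n_genes = as.integer(n_genes),
                 planted_effects = planted_effects,
                 noise_sd = noise_sd,
                 baseline_mean = baseline_mean,
                 region_offset_sd = region_offset_sd,
                 n_gene_blocks = as.integer(n_gene_blocks),
                 missing_region_rate = missing_region_rate,
                 seed = as.integer(seed)),
            class = "ExpressionStudyConfig")
}

## Planted group-mean shift for one sample: young 0, middle half, old full,
## signed by direction.
.plantedShift <- function(effect, age_group) {
  s <- if (effect$direction == "up") 1 else -1
  frac <- c(young = 0, middle = 0.5, old = 1)[[age_group]]
  s * effect$effect_size * frac
}

#' Generate a synthetic multi-region expression study
#'
#' @param config an \code{\link{expressionStudyConfig}}.
#' @return an \linkS4class{ExpressionStudy}; planted effects are recorded in
#'   the truth table returned by \code{\link{plantedEffects}}.
#' @examples
#' cfg <- expressionStudyConfig(n_individuals = 8, regions = c("FCTX", "CRBL"),
#'                              n_genes = 50, seed = 7)
#' study <- generateExpressionStudy(cfg)
#' study
#' @export
generateExpressionStudy <- function(config) {
  if (!inherits(config, "ExpressionStudyConfig"))
    stop("config must come from expressionStudyConfig()", call. = FALSE)
  plant_genes <- vapply(config$planted_effects, `[[`, character(1), "gene_id")
  if (anyDuplicated(plant_genes))
    stop("one planted effect per gene_id is supported", call. = FALSE)

  .withSeed(config$seed, {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    if (length(plant_genes) && !all(plant_genes %in% genes))
      stop("planted gene_id(s) not among generated genes: ",
           paste(setdiff(plant_genes, genes), collapse = ", "),
           call. = FALSE)

    inds <- sprintf("IND%03d", seq_len(config$n_individuals))
    ages <- sample(seq(config$age_range[1], config$age_range[2]),
                   config$n_individuals, replace = TRUE)
    sexes <- sample(c("F", "M"), config$n_individuals, replace = TRUE)
    banks <- sample(c("bankA", "bankB"), config$n_individuals, replace = TRUE)
    cods <- sample(c("cardiac", "respiratory", "other"),
                   config$n_individuals, replace = TRUE)

    present <- matrix(
      runif(config$n_individuals * length(config$regions)) >=
        config$missing_region_rate,
      nrow = config$n_individuals)
    ## every individual keeps at least one sample, every region at least two
    for (i in which(rowSums(present) == 0))
      present[i, sample.int(ncol(present), 1)] <- TRUE
    for (j in which(colSums(present) < 2))
      present[sample.int(nrow(present), 2), j] <- TRUE

    idx <- which(present, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    n_samp <- nrow(idx)
    meta <- data.frame(
      sample_id = sprintf("%s_%s", inds[idx[, 1]], config$regions[idx[, 2]]),
      individual_id = inds[idx[, 1]],
      region = config$regions[idx[, 2]],
      age = ages[idx[, 1]],
      sex = sexes[idx[, 1]],
      bank = banks[idx[, 1]],
      cause_of_death = cods[idx[, 1]],
      stringsAsFactors = FALSE)
    meta$age_group <- assignAgeGroup(meta$age)

    ## baseline + block-wise region identity + noise
    mat <- matrix(rnorm(config$n_genes * n_samp, sd = config$noise_sd),
                  nrow = config$n_genes) + config$baseline_mean
    if (config$region_offset_sd > 0) {
      blocks <- rep_len(seq_len(config$n_gene_blocks), config$n_genes)
      off <- matrix(rnorm(config$n_gene_blocks * length(config$regions),
                          sd = config$region_offset_sd),
                    nrow = config$n_gene_blocks,
                    dimnames = list(NULL, config$regions))
      mat <- mat + off[blocks, match(meta$region, config$regions),
                       drop = FALSE]
    }

    for (eff in config$planted_effects) {
      g <- match(eff$gene_id, genes)
      hit <- meta$region %in% eff$affected_regions
      if (any(hit)) {
        shifts <- vapply(meta$age_group[hit], function(ag)
          .plantedShift(eff, ag), numeric(1))
        mat[g, hit] <- mat[g, hit] + shifts
      }
    }

    dimnames(mat) <- list(genes, meta$sample_id)
    truth <- if (length(config$planted_effects)) {
      do.call(rbind, lapply(config$planted_effects, function(e)
        data.frame(gene_id = e$gene_id,
                   regions = paste(e$affected_regions, collapse = ","),
                   direction = e$direction,
                   effect_size = e$effect_size,
                   celltype_label = e$celltype_label,
                   stringsAsFactors = FALSE)))
    } else {
      data.frame(gene_id = character(), regions = character(),
                 direction = character(), effect_size = numeric(),
                 celltype_label = character())
    }

    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(log2expr = mat),
      colData = S4Vectors::DataFrame(meta, row.names = meta$sample_id))
    S4Vectors::metadata(se)$truth <- truth
    S4Vectors::metadata(se)$config <- config
    methods::new("ExpressionStudy", se)
  })
}

#' Write / read an expression study as delimited text
#'
#' The on-disk dialect is three TSV files: \code{expression.tsv} (gene_id
#' column then one column per sample), \code{metadata.tsv} (sample_id,
#' individual_id, region, age, sex, bank, cause_of_death) and, when planted
#' effects exist, \code{truth.tsv}.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param dir output/input directory (created if needed).
#' @return \code{writeExpressionStudy}: the directory, invisibly;
#'   \code{readExpressionStudy}: an \linkS4class{ExpressionStudy}.
#' @export
writeExpressionStudy <- function(study, dir) {
  stopifnot(methods::is(study, "ExpressionStudy"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat <- SummarizedExperiment::assay(study, "log2expr")
  utils::write.table(
    data.frame(gene_id = rownames(mat), mat, check.names = FALSE),
    file.path(dir, "expression.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(study))
  utils::write.table(cd[, c("sample_id", "individual_id", "region", "age",
                            "sex", "bank", "cause_of_death")],
                     file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- plantedEffects(study)
  if (nrow(tr))
    utils::write.table(tr, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeExpressionStudy
#' @export
readExpressionStudy <- function(dir) {
  expr <- utils::read.delim(file.path(dir, "expression.tsv"),
                            check.names = FALSE)
  meta <- utils::read.delim(file.path(dir, "metadata.tsv"))
  mat <- as.matrix(expr[, -1, drop = FALSE])
  rownames(mat) <- expr$gene_id
  meta <- meta[match(colnames(mat), meta$sample_id), ]
  meta$age_group <- assignAgeGroup(meta$age)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = mat),
    colData = S4Vectors::DataFrame(meta, row.names = meta$sample_id))
  tf <- file.path(dir, "truth.tsv")
  if (file.exists(tf))
    S4Vectors::metadata(se)$truth <- utils::read.delim(tf)
  methods::new("ExpressionStudy", se)
}
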