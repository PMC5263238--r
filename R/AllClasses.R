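#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ExpressionStudy: a multi-region brain expression cohort
#'
#' A \linkS4class{SummarizedExperiment} whose single assay holds log2
#' expression (genes x samples) and whose column data carries the cohort
#' metadata (\code{individual_id}, \code{region}, \code{age}, \code{sex},
#' \code{bank}, \code{cause_of_death}). Synthetic studies additionally carry
#' a planted-effect truth table in \code{metadata(x)$truth}.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @seealso \code{\link{generateExpressionStudy}}, \code{\link{plantedEffects}}
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
  msg <- character()
  needed <- c("individual_id", "region", "age", "sex", "bank",
              "cause_of_death")
  miss <- setdiff(needed, colnames(SummarizedExperiment::colData(object)))
  if (length(miss)) {
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  }
  if (!"log2expr" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'log2expr' is required")
  }
  if (length(msg) == 0 &&
      any(SummarizedExperiment::colData(object)$age < 16)) {
    msg <- c(msg, "ages below 16 years are outside the cohort design")
  }
  if (length(msg)) msg else TRUE
})

#' CellTypeReference: reference expression profiles for CNS cell types
#'
#' Mean expression (linear scale) of each gene in each reference cell type,
#' with the marker truth table when the reference is synthetic.
#'
#' @slot means numeric matrix, genes x cell types, linear scale, >= 0.
#' @slot markerTruth data.frame with columns \code{gene}, \code{cell_type}
#'   for planted markers (zero rows for real references).
#' @slot params list of generation parameters (empty for real references).
#' @seealso \code{\link{generateCellTypeReference}},
#'   \code{\link{specificityScore}}
#' @export
setClass("CellTypeReference",
         representation(means = "matrix", markerTruth = "data.frame",
                        params = "list"))

setValidity("CellTypeReference", function(object) {
  msg <- character()
  if (!is.numeric(object@means)) msg <- c(msg, "means must be numeric")
  if (is.null(rownames(object@means)) || is.null(colnames(object@means)))
    msg <- c(msg, "means must have gene rownames and cell-type colnames")
  if (is.numeric(object@means) && any(object@means < 0))
    msg <- c(msg, "reference means must be non-negative (linear scale)")
  if (nrow(object@markerTruth) &&
      !all(c("gene", "cell_type") %in% colnames(object@markerTruth)))
    msg <- c(msg, "markerTruth needs columns gene, cell_type")
  if (length(msg)) msg else TRUE
})

#' StainedTile: one RGB image tile of an immunostained section
#'
#' Pixels are stored as a numeric array \code{[row, col, channel]} on the
#' 0..255 scale with origin at the top-left (x = column - 1 rightward,
#' y = row - 1 downward, 0-based, matching the detection output). Synthetic
#' tiles carry the disk ground truth.
#'
#' @slot pixels numeric array height x width x 3 in [0, 255].
#' @slot tileId,caseId,ageGroup character scalars identifying the tile.
#' @slot groundTruth data.frame with columns \code{x}, \code{y},
#'   \code{radius}, \code{class} (zero rows when unknown).
#' @seealso \code{\link{generateTile}}, \code{\link{segmentCells}}
#' @export
setClass("StainedTile",
         representation(pixels = "array", tileId = "character",
                        caseId = "character", ageGroup = "character",
                        groundTruth = "data.frame"))

setValidity("StainedTile", function(object) {
  d <- dim(object@pixels)
  msg <- character()
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "pixels must be a height x width x 3 array")
  else if (d[1] * d[2] == 0) msg <- c(msg, "tile must be non-empty")
  else if (min(object@pixels) < 0 || max(object@pixels) > 255)
    msg <- c(msg, "pixel values must lie in [0, 255]")
  if (nrow(object@groundTruth) &&
      !all(c("x", "y", "radius", "class") %in% colnames(object@groundTruth)))
    msg <- c(msg, "groundTruth needs columns x, y, radius, class")
  if (length(msg)) msg else TRUE
})

#' PermutationResult: a shuffled-label permutation test outcome
#'
#' @slot observed mean true-label t statistic across resampling rounds.
#' @slot nulls numeric vector of shuffled-label t statistics (pooled across
#'   rounds).
#' @slot p permutation p-value (add-one convention, never 0).
#' @slot nullSd standard deviation of the null t values.
#' @slot scheme list describing the permutation scheme (iterations,
#'   permutations per round, tail, subsample size, seed).
#' @seealso \code{\link{permutationTest}}
#' @export
setClass("PermutationResult",
         representation(observed = "numeric", nulls = "numeric",
                        p = "numeric", nullSd = "numeric", scheme = "list"))

setValidity("PermutationResult", function(object) {
  msg <- character()
  if (length(object@p) != 1L || object@p <= 0 || object@p > 1)
    msg <- c(msg, "p must be a single value in (0, 1]")
  if (length(object@nulls) < 1L) msg <- c(msg, "null distribution is empty")
  if (length(msg)) msg else TRUE
})

#' AgeModelFit: a stepwise age-associative regression fit
#'
#' @slot terms character vector of selected model terms (gene ids,
#'   \code{"gA:gB"} interactions, and forced covariate columns).
#' @slot coefficients named numeric vector of OLS coefficients
#'   (including the intercept).
#' @slot r2,adjR2 coefficient of determination of the final model and its
#'   adjusted version.
#' @slot covariateR2 R-squared of the forced covariate-only model.
#' @slot fitted per-sample predicted age (years) on the training data.
#' @slot spec the \code{ageModelSpec} used.
#' @slot trace data.frame logging each stepwise action.
#' @seealso \code{\link{fitStepwiseAgeModel}}, \code{\link{predictAge}}
#' @export
setClass("AgeModelFit",
         representation(terms = "character", coefficients = "numeric",
                        r2 = "numeric", adjR2 = "numeric",
                        covariateR2 = "numeric", fitted = "numeric",
                        spec = "list", trace = "data.frame"))

setValidity("AgeModelFit", function(object) {
  if (object@r2 < -1e-8 || object@r2 > 1 + 1e-8)
    "r2 must lie in [0, 1]" else TRUE
})

setMethod("show", "ExpressionStudy", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("ExpressionStudy:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  individuals:", length(unique(cd$individual_id)),
      " regions:", length(unique(cd$region)),
      " age range:", paste(range(cd$age), collapse = "-"), "years\n")
  tr <- S4Vectors::metadata(object)$truth
  if (!is.null(tr)) cat("  planted effects:", nrow(tr), "\n")
  invisible(NULL)
})

setMethod("show", "CellTypeReference", function(object) {
  cat("CellTypeReference:", nrow(object@means), "genes x",
      ncol(object@means), "cell types\n")
  cat("  types:", paste(colnames(object@means), collapse = ", "), "\n")
  if (nrow(object@markerTruth))
    cat("  planted markers:", nrow(object@markerTruth), "\n")
  invisible(NULL)
})

setMethod("show", "StainedTile", function(object) {
  d <- dim(object@pixels)
  cat("StainedTile", object@tileId, ":", d[2], "x", d[1], "pixels",
      sprintf("(case %s, %s)\n", object@caseId, object@ageGroup))
  if (nrow(object@groundTruth)) {
    tb <- table(object@groundTruth$class)
    cat("  ground truth:", paste(names(tb), tb, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(NULL)
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult: observed t = %.4f, p = %.4g (%s tail, %d nulls, null SD %.3f)\n",
    object@observed, object@p, object@scheme$tail, length(object@nulls),
    object@nullSd))
  invisible(NULL)
})

setMethod("show", "AgeModelFit", function(object) {
  gene_terms <- setdiff(object@terms, object@spec$covariate_columns)
  cat(sprintf("AgeModelFit: R2 = %.3f (adj %.3f, covariates-only %.3f)\n",
              object@r2, object@adjR2, object@covariateR2))
  cat("  selected gene terms:",
      if (length(gene_terms)) paste(gene_terms, collapse = ", ") else "none",
      "\n")
  invisible(NULL)
})
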