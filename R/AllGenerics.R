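#' Planted-effect truth table of a synthetic study
#'
#' @param x an \linkS4class{ExpressionStudy}.
#' @return data.frame of planted effects (zero rows when none were planted).
#' @export
setGeneric("plantedEffects", function(x) standardGeneric("plantedEffects"))

#' @rdname plantedEffects
#' @export
setMethod("plantedEffects", "ExpressionStudy", function(x) {
  tr <- S4Vectors::metadata(x)$truth
  if (is.null(tr)) {
    data.frame(gene_id = character(), regions = character(),
               direction = character(), effect_size = numeric(),
               celltype_label = character())
  } else {
    tr
  }
})

#' Reference mean-expression matrix
#'
#' @param x a \linkS4class{CellTypeReference}.
#' @return numeric matrix, genes x cell types (linear scale).
#' @export
setGeneric("referenceMeans", function(x) standardGeneric("referenceMeans"))

#' @rdname referenceMeans
#' @export
setMethod("referenceMeans", "CellTypeReference", function(x) x@means)

#' Planted marker truth of a synthetic reference
#'
#' @param x a \linkS4class{CellTypeReference}.
#' @return data.frame with columns \code{gene}, \code{cell_type}.
#' @export
setGeneric("markerTruth", function(x) standardGeneric("markerTruth"))

#' @rdname markerTruth
#' @export
setMethod("markerTruth", "CellTypeReference", function(x) x@markerTruth)

#' Pixel array of a tile
#'
#' @param x a \linkS4class{StainedTile}.
#' @return numeric array height x width x 3 on the 0..255 scale.
#' @export
setGeneric("tilePixels", function(x) standardGeneric("tilePixels"))

#' @rdname tilePixels
#' @export
setMethod("tilePixels", "StainedTile", function(x) x@pixels)

#' Ground-truth object table of a synthetic tile
#'
#' @param x a \linkS4class{StainedTile}.
#' @return data.frame with columns \code{x}, \code{y}, \code{radius},
#'   \code{class}; coordinates are 0-based from the top-left corner.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "StainedTile", function(x) x@groundTruth)

#' Accessors for permutation test results
#'
#' @param x a \linkS4class{PermutationResult}.
#' @return \code{observedT}: the mean true-label t statistic;
#'   \code{nullValues}: the pooled shuffled-label t statistics;
#'   \code{permPValue}: the add-one permutation p-value.
#' @name permutation-accessors
NULL

#' @rdname permutation-accessors
#' @export
setGeneric("observedT", function(x) standardGeneric("observedT"))

#' @rdname permutation-accessors
#' @export
setMethod("observedT", "PermutationResult", function(x) x@observed)

#' @rdname permutation-accessors
#' @export
setGeneric("nullValues", function(x) standardGeneric("nullValues"))

#' @rdname permutation-accessors
#' @export
setMethod("nullValues", "PermutationResult", function(x) x@nulls)

#' @rdname permutation-accessors
#' @export
setGeneric("permPValue", function(x) standardGeneric("permPValue"))

#' @rdname permutation-accessors
#' @export
setMethod("permPValue", "PermutationResult", function(x) x@p)

#' Accessors for stepwise age-model fits
#'
#' @param x an \linkS4class{AgeModelFit}.
#' @return \code{selectedTerms}: character vector of selected terms;
#'   \code{modelR2}: the final-model R-squared.
#' @name agemodel-accessors
NULL

#' @rdname agemodel-accessors
#' @export
setGeneric("selectedTerms", function(x) standardGeneric("selectedTerms"))

#' @rdname agemodel-accessors
#' @export
setMethod("selectedTerms", "AgeModelFit", function(x) x@terms)

#' @rdname agemodel-accessors
#' @export
setGeneric("modelR2", function(x) standardGeneric("modelR2"))

#' @rdname agemodel-accessors
#' @export
setMethod("modelR2", "AgeModelFit", function(x) x@r2)
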