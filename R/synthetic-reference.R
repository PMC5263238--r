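#' @importFrom stats rlnorm
NULL

#' The seven CNS reference cell types
#' @export
cnsCellTypes <- function() {
  c("neuron", "astrocyte", "OPC", "newly_formed_OLG", "myelinating_OLG",
    "microglia", "endothelial")
}

#' Configure a synthetic cell-type reference
#'
#' Emulates mean expression profiles of purified CNS cell types: every gene
#' gets a baseline linear-scale mean per type; each planted marker's mean in
#' its home type is set to \code{marker_fold} times its maximum over the
#' other types (before noise), so with noise disabled its specificity score
#' equals \code{marker_fold} exactly as the pseudocount vanishes.
#'
#' @param cell_types cell-type labels (7 by default).
#' @param n_genes number of genes.
#' @param markers_per_type planted markers per type;
#'   \code{markers_per_type * length(cell_types)} must not exceed
#'   \code{n_genes}.
#' @param marker_fold linear-scale enrichment of a marker in its home type
#'   (> 1).
#' @param noise_cv multiplicative lognormal coefficient of variation applied
#'   to every mean; 0 disables noise.
#' @param seed integer seed.
#' @return a list of class \code{CellTypeReferenceConfig}.
#' @export
cellTypeReferenceConfig <- function(cell_types = cnsCellTypes(),
                                    n_genes = 2000,
                                    markers_per_type = 50,
                                    marker_fold = 20,
                                    noise_cv = 0.1,
                                    seed = 1L) {
  if (anyDuplicated(cell_types)) stop("cell_types must be unique",
                                      call. = FALSE)
  .assertScalarNumber(n_genes, "n_genes", lower = 1)
  .assertScalarNumber(markers_per_type, "markers_per_type", lower = 0)
  .assertScalarNumber(marker_fold, "marker_fold", lower = 1,
                      strict_lower = TRUE)
  .assertScalarNumber(noise_cv, "noise_cv", lower = 0)
  if (markers_per_type * length(cell_types) > n_genes)
    stop("markers_per_type x number of types exceeds n_genes", call. = FALSE)
  structure(list(cell_types = as.character(cell_types),
                 n_genes = as.integer(n_genes),
                 markers_per_type = as.integer(markers_per_type),
                 marker_fold = marker_fold,
                 noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "CellTypeReferenceConfig")
}

#' Generate a synthetic cell-type reference
#'
#' @param config a \code{\link{cellTypeReferenceConfig}}.
#' @return a \linkS4class{CellTypeReference} with the planted markers
#'   recorded in \code{\link{markerTruth}}.
#' @examples
#' ref <- generateCellTypeReference(cellTypeReferenceConfig(n_genes = 200,
#'                                                          markers_per_type = 5,
#'                                                          seed = 3))
#' head(markerTruth(ref))
#' @export
generateCellTypeReference <- function(config) {
  if (!inherits(config, "CellTypeReferenceConfig"))
    stop("config must come from cellTypeReferenceConfig()", call. = FALSE)
  .withSeed(config$seed, {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    k <- length(config$cell_types)
    ## baseline expression, broadly lognormal like real mean profiles
    means <- matrix(rlnorm(config$n_genes * k, meanlog = log(50),
                           sdlog = 0.6),
                    nrow = config$n_genes,
                    dimnames = list(genes, config$cell_types))
    n_mark <- config$markers_per_type * k
    truth <- data.frame(gene = character(), cell_type = character())
    if (n_mark > 0) {
      marker_genes <- genes[seq_len(n_mark)]
      home <- rep(config$cell_types, each = config$markers_per_type)
      for (i in seq_len(n_mark)) {
        g <- match(marker_genes[i], genes)
        t <- match(home[i], config$cell_types)
        means[g, t] <- config$marker_fold * max(means[g, -t])
      }
      truth <- data.frame(gene = marker_genes, cell_type = home,
                          stringsAsFactors = FALSE)
    }
    if (config$noise_cv > 0) {
      sdlog <- sqrt(log(1 + config$noise_cv^2))
      means <- means * matrix(
        rlnorm(length(means), meanlog = -sdlog^2 / 2, sdlog = sdlog),
        nrow = nrow(means))
    }
    methods::new("CellTypeReference", means = means, markerTruth = truth,
                 params = unclass(config))
  })
}

#' Write / read a cell-type reference as TSV
#'
#' Layout: a \code{gene} column followed by one column per cell type
#' (linear-scale means).
#'
#' @param reference a \linkS4class{CellTypeReference}.
#' @param path TSV file path.
#' @return \code{readCellTypeReference}: a \linkS4class{CellTypeReference}
#'   (with an empty marker truth table).
#' @export
writeCellTypeReference <- function(reference, path) {
  stopifnot(methods::is(reference, "CellTypeReference"))
  m <- referenceMeans(reference)
  utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCellTypeReference
#' @export
readCellTypeReference <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene
  methods::new("CellTypeReference", means = m,
               markerTruth = data.frame(gene = character(),
                                        cell_type = character()),
               params = list())
}
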