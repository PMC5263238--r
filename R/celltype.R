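#' Cell-type specificity scores
#'
#' The specificity score of gene g in cell type t is
#' \code{(mean(g, t) + eps) / (max over other types of mean(g, .) + eps)} on
#' the linear scale. A flat gene scores 1 everywhere; a gene expressed only
#' in one type scores highly there. With a threshold above 1 a gene can be a
#' marker of at most one type.
#'
#' @param reference a \linkS4class{CellTypeReference}.
#' @param genes,cell_types optional subsets (defaults: all).
#' @param eps pseudocount on the linear scale (> 0), default 1.
#' @return numeric matrix of scores, genes x cell types.
#' @examples
#' ref <- generateCellTypeReference(cellTypeReferenceConfig(n_genes = 100,
#'                                                          markers_per_type = 2,
#'                                                          noise_cv = 0, seed = 1))
#' m <- markerTruth(ref)[1, ]
#' specificityScore(ref, genes = m$gene, cell_types = m$cell_type)
#' @export
specificityScore <- function(reference, genes = NULL, cell_types = NULL,
                             eps = 1) {
  stopifnot(methods::is(reference, "CellTypeReference"))
  .assertScalarNumber(eps, "eps", lower = 0, strict_lower = TRUE)
  m <- referenceMeans(reference)
  if (is.null(genes)) genes <- rownames(m)
  if (is.null(cell_types)) cell_types <- colnames(m)
  if (!all(genes %in% rownames(m)))
    stop("unknown gene(s): ",
         paste(utils::head(setdiff(genes, rownames(m))), collapse = ", "),
         call. = FALSE)
  if (!all(cell_types %in% colnames(m)))
    stop("unknown cell type(s): ",
         paste(setdiff(cell_types, colnames(m)), collapse = ", "),
         call. = FALSE)
  m <- m[genes, , drop = FALSE]
  scores <- sapply(cell_types, function(ct) {
    others <- m[, setdiff(colnames(m), ct), drop = FALSE]
    (m[, ct] + eps) / (apply(others, 1, max) + eps)
  })
  scores <- matrix(scores, nrow = length(genes),
                   dimnames = list(genes, cell_types))
  scores
}

#' Derive cell-type marker lists from a reference
#'
#' A gene is assigned to a cell type when its specificity score there meets
#' \code{threshold}; with \code{threshold > 1} the per-type lists are
#' automatically disjoint.
#'
#' @param reference a \linkS4class{CellTypeReference}.
#' @param threshold specificity threshold (> 1), default 5.
#' @param eps pseudocount passed to \code{\link{specificityScore}}.
#' @return named list (by cell type) of marker gene character vectors.
#' @export
deriveMarkerLists <- function(reference, threshold = 5, eps = 1) {
  .assertScalarNumber(threshold, "threshold", lower = 1, strict_lower = TRUE)
  sc <- specificityScore(reference, eps = eps)
  lists <- lapply(colnames(sc), function(ct)
    rownames(sc)[sc[, ct] >= threshold])
  names(lists) <- colnames(sc)
  lists
}

#' Consensus markers supported by two independent lists
#'
#' @param list_a,list_b named lists (by cell type) of marker genes; the type
#'   labels must share at least one name.
#' @return named list of per-type intersections over the shared types.
#' @examples
#' consensusLists(list(neuron = c("g1", "g2", "g3")),
#'                list(neuron = c("g2", "g3", "g4")))
#' @export
consensusLists <- function(list_a, list_b) {
  shared <- intersect(names(list_a), names(list_b))
  if (length(shared) == 0)
    stop("the two lists share no cell-type labels", call. = FALSE)
  out <- lapply(shared, function(ct) intersect(list_a[[ct]], list_b[[ct]]))
  names(out) <- shared
  out
}

#' Enrichment of cell-type markers within regional-breadth categories
#'
#' Hypergeometric over-representation of each marker list within each breadth
#' category, against the universe of tested genes.
#'
#' @param marker_lists named list (by cell type) of marker genes.
#' @param breadth a \code{\link{classifyRegionalBreadth}} data.frame.
#' @param universe character vector of all tested genes.
#' @return data.frame with one row per (cell type, category): \code{p},
#'   \code{odds_ratio}, \code{overlap}, \code{n_markers},
#'   \code{n_category}, and \code{flag} (\code{"empty"} when either side is
#'   empty, in which case p = 1).
#' @export
celltypeBreadthEnrichment <- function(marker_lists, breadth, universe) {
  stopifnot(all(c("gene", "category") %in% colnames(breadth)))
  cats <- setdiff(unique(breadth$category), "uncategorized")
  rows <- list()
  for (ct in names(marker_lists)) {
    markers <- intersect(marker_lists[[ct]], universe)
    for (cat in cats) {
      cat_genes <- intersect(breadth$gene[breadth$category == cat], universe)
      if (length(markers) == 0 || length(cat_genes) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          cell_type = ct, category = cat, p = 1, odds_ratio = NA_real_,
          overlap = 0L, n_markers = length(markers),
          n_category = length(cat_genes), flag = "empty")
        next
      }
      r <- overrepresentationTest(markers, cat_genes, universe)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = ct, category = cat, p = r$p, odds_ratio = r$odds_ratio,
        overlap = r$overlap, n_markers = length(markers),
        n_category = length(cat_genes), flag = "")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export marker lists in GMT format
#'
#' One line per cell type: name, description, then the marker genes
#' (tab-separated), the standard gene-set exchange format.
#'
#' @param marker_lists named list of marker gene vectors.
#' @param path output file path.
#' @export
writeMarkersGMT <- function(marker_lists, path) {
  lines <- vapply(names(marker_lists), function(ct)
    paste(c(ct, "neuroAging_markers", marker_lists[[ct]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return named list of gene character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1L)
  sets
}
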