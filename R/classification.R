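#' @importFrom stats cor dist hclust cutree sd
NULL

#' Sample-sample Spearman correlation on a gene subset
#'
#' @param study an \linkS4class{ExpressionStudy} or a genes x samples matrix.
#' @param gene_subset non-empty character vector of gene ids (rows).
#' @return symmetric samples x samples matrix of Spearman rank correlations;
#'   pairs involving a constant sample vector are NaN.
#' @export
sampleCorrelation <- function(study, gene_subset) {
  mat <- if (methods::is(study, "ExpressionStudy"))
    SummarizedExperiment::assay(study, "log2expr") else study
  stopifnot(is.matrix(mat))
  if (length(gene_subset) == 0) stop("gene_subset is empty", call. = FALSE)
  if (!all(gene_subset %in% rownames(mat)))
    stop("gene_subset contains unknown genes", call. = FALSE)
  if (ncol(mat) < 2) stop("need at least 2 samples", call. = FALSE)
  suppressWarnings(cor(mat[gene_subset, , drop = FALSE],
                       method = "spearman"))
}

#' Hierarchical clustering of samples or genes
#'
#' Agglomerative clustering on Euclidean distance (complete linkage by
#' default, the convention for expression heatmaps).
#'
#' @param study an \linkS4class{ExpressionStudy} or a genes x samples matrix.
#' @param gene_subset gene ids to use (default: all).
#' @param axis \code{"samples"} or \code{"genes"}.
#' @param linkage linkage method passed to \code{\link[stats]{hclust}}.
#' @param k optional number of flat clusters to cut.
#' @return list with \code{hclust} (the tree) and, when \code{k} is given,
#'   \code{clusters} (named integer vector).
#' @export
hierarchicalCluster <- function(study, gene_subset = NULL,
                                axis = c("samples", "genes"),
                                linkage = "complete", k = NULL) {
  axis <- match.arg(axis)
  mat <- if (methods::is(study, "ExpressionStudy"))
    SummarizedExperiment::assay(study, "log2expr") else study
  stopifnot(is.matrix(mat))
  if (!is.null(gene_subset)) {
    if (!all(gene_subset %in% rownames(mat)))
      stop("gene_subset contains unknown genes", call. = FALSE)
    mat <- mat[gene_subset, , drop = FALSE]
  }
  items <- if (axis == "samples") t(mat) else mat
  if (nrow(items) < 2) stop("need at least 2 items to cluster",
                            call. = FALSE)
  hc <- hclust(dist(items, method = "euclidean"), method = linkage)
  out <- list(hclust = hc)
  if (!is.null(k)) {
    if (k > nrow(items)) stop("k exceeds the number of items", call. = FALSE)
    out$clusters <- cutree(hc, k = k)
  }
  out
}

#' Export a dendrogram in Newick format
#'
#' @param hc an \code{\link[stats]{hclust}} tree.
#' @param path output file path.
#' @export
writeNewick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Two-dimensional t-SNE embedding of samples
#'
#' t-distributed stochastic neighbor embedding of samples on a gene subset.
#' Requires \code{n samples > 3 * perplexity}; coordinates are reproducible
#' given the seed.
#'
#' @param study an \linkS4class{ExpressionStudy} or a genes x samples matrix.
#' @param gene_subset gene ids to use (default: all).
#' @param perplexity t-SNE perplexity (default 30).
#' @param seed integer seed (default 0).
#' @param max_iter optimisation iterations (default 1000).
#' @return list with \code{coords} (samples x 2 matrix, rownames = sample
#'   ids) and \code{params} (method descriptor, perplexity, seed,
#'   iterations).
#' @export
embedSamples <- function(study, gene_subset = NULL, perplexity = 30,
                         seed = 0L, max_iter = 1000L) {
  mat <- if (methods::is(study, "ExpressionStudy"))
    SummarizedExperiment::assay(study, "log2expr") else study
  stopifnot(is.matrix(mat))
  if (!is.null(gene_subset)) {
    if (!all(gene_subset %in% rownames(mat)))
      stop("gene_subset contains unknown genes", call. = FALSE)
    mat <- mat[gene_subset, , drop = FALSE]
  }
  n <- ncol(mat)
  if (n <= 3 * perplexity)
    stop(sprintf("perplexity %g too large for %d samples (need n > 3*perplexity)",
                 perplexity, n), call. = FALSE)
  x <- t(mat)
  res <- .withSeed(seed,
    Rtsne::Rtsne(x, dims = 2, perplexity = perplexity, max_iter = max_iter,
                 check_duplicates = FALSE, pca = ncol(x) > 50,
                 verbose = FALSE))
  coords <- res$Y
  rownames(coords) <- colnames(mat)
  colnames(coords) <- c("tsne1", "tsne2")
  list(coords = coords,
       params = list(method = "tsne", perplexity = perplexity,
                     seed = seed, max_iter = max_iter))
}

#' Score age-group discrimination of a sample clustering
#'
#' Cuts the sample dendrogram (or uses supplied flat clusters) into three
#' clusters, maps clusters to the three age groups by the assignment that
#' maximises total agreement (exhaustive over the 3! mappings), and counts an
#' individual as correctly discriminated when the majority of its samples
#' land in its own group's cluster.
#'
#' @param clusters named integer vector of cluster ids per sample (values in
#'   1..3), or a list from \code{\link{hierarchicalCluster}} (cut to k = 3 if
#'   needed).
#' @param true_groups named character vector of age groups per sample.
#' @param individuals named character vector of individual ids per sample
#'   (default: each sample is its own individual).
#' @return list with \code{n_correct}, \code{n_total}, \code{accuracy},
#'   \code{mapping} (cluster id -> age group) and \code{per_individual}
#'   data.frame.
#' @export
scoreAgeDiscrimination <- function(clusters, true_groups,
                                   individuals = NULL) {
  if (is.list(clusters) && !is.null(clusters$hclust)) {
    clusters <- if (!is.null(clusters$clusters)) clusters$clusters
    else cutree(clusters$hclust, k = 3)
  }
  samples <- names(clusters)
  stopifnot(!is.null(samples), all(samples %in% names(true_groups)))
  true_groups <- true_groups[samples]
  groups <- sort(unique(true_groups))
  if (length(groups) != 3)
    stop("all three age groups must be present", call. = FALSE)
  if (is.null(individuals)) {
    individuals <- stats::setNames(samples, samples)
  }
  individuals <- individuals[samples]

  cl_ids <- sort(unique(clusters))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  best <- NULL
  best_agree <- -1L
  for (pm in perms) {
    ## mapping: cluster cl_ids[j] -> groups[pm[j]] (absent clusters ignored)
    map <- stats::setNames(groups[pm[seq_along(cl_ids)]], cl_ids)
    agree <- sum(map[as.character(clusters)] == true_groups)
    if (agree > best_agree) {
      best_agree <- agree
      best <- map
    }
  }

  inds <- unique(individuals)
  correct <- logical(length(inds))
  for (i in seq_along(inds)) {
    sel <- individuals == inds[i]
    votes <- table(best[as.character(clusters[sel])])
    assigned <- names(votes)[which.max(votes)]   # majority; ties -> first
    correct[i] <- assigned == true_groups[sel][1]
  }
  per_ind <- data.frame(individual = inds, correct = correct,
                        stringsAsFactors = FALSE)
  list(n_correct = sum(correct), n_total = length(inds),
       accuracy = mean(correct), mapping = best, per_individual = per_ind)
}

#' Row z-scores for heatmap display
#'
#' Per-row standardization (n-1 SD convention, as in the classic zscore
#' routines) clipped to \code{[-clip, clip]}; zero-variance rows map to all
#' zeros.
#'
#' @param mat numeric matrix.
#' @param clip positive clipping bound (default 3).
#' @return matrix of clipped z-scores, same dimensions.
#' @export
standardizeForHeatmap <- function(mat, clip = 3) {
  .assertScalarNumber(clip, "clip", lower = 0, strict_lower = TRUE)
  stopifnot(is.matrix(mat))
  z <- t(apply(mat, 1, .zscoreRow))
  dimnames(z) <- dimnames(mat)
  pmin(pmax(z, -clip), clip)
}
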