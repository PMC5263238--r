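#' @importFrom stats p.adjust pf phyper median
NULL

#' Assign samples to the three age groups
#'
#' Groups partition ages of 16 years and above: young 16-44, middle 45-74,
#' old 75 and older.
#'
#' @param age numeric vector of ages in years (all >= 16).
#' @return character vector in \code{c("young", "middle", "old")}.
#' @examples
#' assignAgeGroup(c(16, 44, 45, 74, 75, 106))
#' @export
assignAgeGroup <- function(age) {
  if (!is.numeric(age) || any(is.na(age)))
    stop("age must be numeric and non-missing", call. = FALSE)
  if (any(age < 16))
    stop("ages below 16 years are outside the cohort design", call. = FALSE)
  ifelse(age >= 75, "old", ifelse(age >= 45, "middle", "young"))
}

#' Collapse probe sets to gene-level signal
#'
#' Gene-level signal is the per-sample median over the probe sets
#' interrogating a transcript (the even-count convention is the mean of the
#' two middle values). Transcripts with no probe sets are skipped with a
#' warning.
#'
#' @param probe_matrix numeric matrix, probe sets x samples.
#' @param probe_to_transcript character vector mapping each row of
#'   \code{probe_matrix} to a transcript id.
#' @param transcripts transcripts to summarize (default: every transcript
#'   appearing in the mapping); requested transcripts with no probe sets are
#'   skipped with a warning.
#' @return numeric matrix, transcripts x samples.
#' @examples
#' m <- rbind(a1 = c(1, 2), a2 = c(5, 6), a3 = c(100, 0))
#' summarizeGeneLevel(m, c("tA", "tA", "tA"))
#' @export
summarizeGeneLevel <- function(probe_matrix, probe_to_transcript,
                               transcripts = NULL) {
  stopifnot(is.matrix(probe_matrix),
            length(probe_to_transcript) == nrow(probe_matrix))
  if (is.null(transcripts)) transcripts <- unique(probe_to_transcript)
  empty <- setdiff(transcripts, probe_to_transcript)
  if (length(empty)) {
    warning("skipping transcript(s) with no probe sets: ",
            paste(empty, collapse = ", "))
    transcripts <- setdiff(transcripts, empty)
  }
  out <- do.call(rbind, lapply(transcripts, function(tr) {
    apply(probe_matrix[probe_to_transcript == tr, , drop = FALSE], 2, median)
  }))
  rownames(out) <- transcripts
  colnames(out) <- colnames(probe_matrix)
  out
}

## Vectorized one-way fixed-effects ANOVA across matrix rows.
## Returns F and p per row; rows where fewer than 2 groups have >= 2 samples
## are NA (untestable). Groups with < 2 samples are dropped.
.rowAnova <- function(mat, groups) {
  groups <- as.character(groups)
  keep_groups <- names(which(table(groups) >= 2))
  use <- groups %in% keep_groups
  if (length(keep_groups) < 2) {
    return(data.frame(F = rep(NA_real_, nrow(mat)),
                      p = rep(NA_real_, nrow(mat)),
                      row.names = rownames(mat)))
  }
  m <- mat[, use, drop = FALSE]
  g <- factor(groups[use])
  n <- ncol(m)
  k <- nlevels(g)
  ng <- as.numeric(table(g))
  ## group sums per row via matrix multiply with the group indicator
  ind <- stats::model.matrix(~ g - 1)
  gs <- m %*% ind                       # row x group sums
  gm <- sweep(gs, 2, ng, `/`)           # group means
  grand <- rowSums(m) / n
  ss_between <- rowSums(sweep(sweep(gm, 1, grand)^2, 2, ng, `*`))
  ss_total <- rowSums((m - grand)^2)
  ss_within <- pmax(ss_total - ss_between, 0)
  df1 <- k - 1
  df2 <- n - k
  Fv <- (ss_between / df1) / (ss_within / df2)
  p <- pf(Fv, df1, df2, lower.tail = FALSE)
  ## zero within-group variance: equal means -> F = 0, p = 1; separated
  ## means -> F unbounded, p below machine floor
  degen <- ss_within == 0
  Fv[degen & ss_between == 0] <- 0
  p[degen & ss_between == 0] <- 1
  Fv[degen & ss_between > 0] <- Inf
  p[degen & ss_between > 0] <- 0
  data.frame(F = Fv, p = p, row.names = rownames(mat))
}

#' Per-gene one-way ANOVA of expression on age group within one region
#'
#' Fits a fixed-effects one-way ANOVA of log2 signal on the three age groups
#' for every gene, restricted to one region's samples. Age groups with fewer
#' than two samples are dropped; genes for which fewer than two groups remain
#' are returned with NA statistics (untestable).
#'
#' @param study an \linkS4class{ExpressionStudy}, or a numeric matrix
#'   (genes x samples) if \code{group_labels} is given.
#' @param region region label to restrict to (ignored for matrix input).
#' @param group_labels age-group labels per column (matrix input only).
#' @return data.frame with columns \code{gene}, \code{F}, \code{p}.
#' @export
anovaAging <- function(study, region = NULL, group_labels = NULL) {
  if (methods::is(study, "ExpressionStudy")) {
    cd <- SummarizedExperiment::colData(study)
    keep <- if (is.null(region)) rep(TRUE, ncol(study)) else
      cd$region == region
    if (!any(keep)) stop("no samples in region ", region, call. = FALSE)
    mat <- SummarizedExperiment::assay(study, "log2expr")[, keep,
                                                          drop = FALSE]
    group_labels <- assignAgeGroup(cd$age[keep])
  } else {
    mat <- study
    stopifnot(is.matrix(mat), !is.null(group_labels),
              length(group_labels) == ncol(mat))
  }
  res <- .rowAnova(mat, group_labels)
  data.frame(gene = rownames(mat), F = res$F, p = res$p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjustment; NA p-values are propagated as NA q-values and do
#' not count toward the family size.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return q-values, same length and order as \code{p}.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
fdrAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Old-vs-young log2 fold change per gene
#'
#' @param mat numeric matrix (genes x samples) of log2 signal.
#' @param group_labels age-group labels per column; both \code{"young"} and
#'   \code{"old"} must be present.
#' @return data.frame with columns \code{gene}, \code{delta_log2}
#'   (mean old - mean young) and \code{direction} (\code{"up"},
#'   \code{"down"}, or \code{"none"} on an exact tie).
#' @export
foldChange <- function(mat, group_labels) {
  stopifnot(is.matrix(mat), length(group_labels) == ncol(mat))
  if (!any(group_labels == "young") || !any(group_labels == "old"))
    stop("both young and old groups must be non-empty", call. = FALSE)
  d <- rowMeans(mat[, group_labels == "old", drop = FALSE]) -
    rowMeans(mat[, group_labels == "young", drop = FALSE])
  data.frame(gene = rownames(mat), delta_log2 = d,
             direction = ifelse(d > 0, "up", ifelse(d < 0, "down", "none")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-region differential expression across age groups
#'
#' Runs \code{\link{anovaAging}} and \code{\link{foldChange}} in every region
#' of a study and adjusts p-values with Benjamini-Hochberg per region
#' (untestable genes are excluded from each region's BH family).
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param regions regions to analyse (default: all in the study).
#' @return data.frame with one row per (gene, region): \code{gene},
#'   \code{region}, \code{F}, \code{p}, \code{q}, \code{delta_log2},
#'   \code{direction}.
#' @seealso \code{\link{classifyRegionalBreadth}}, \code{\link{selectTopGenes}}
#' @export
alteredGeneTable <- function(study, regions = NULL) {
  stopifnot(methods::is(study, "ExpressionStudy"))
  cd <- SummarizedExperiment::colData(study)
  if (is.null(regions)) regions <- unique(cd$region)
  mat <- SummarizedExperiment::assay(study, "log2expr")
  out <- lapply(regions, function(rg) {
    keep <- cd$region == rg
    labs <- assignAgeGroup(cd$age[keep])
    sub <- mat[, keep, drop = FALSE]
    an <- anovaAging(sub, group_labels = labs)
    fc <- foldChange(sub, labs)
    data.frame(gene = an$gene, region = rg, F = an$F, p = an$p,
               q = fdrAdjust(an$p), delta_log2 = fc$delta_log2,
               direction = fc$direction, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify aging-altered genes by regional breadth
#'
#' Genes significantly altered in exactly one region are "region_specific";
#' in two to seven regions "region_selective"; in eight or more
#' "multi_regional"; genes altered in all ten regions form the
#' "cross_regional" class. Genes significant nowhere are "uncategorized".
#'
#' @param sig_sets named list (by region) of significant gene character
#'   vectors, or an \code{\link{alteredGeneTable}} data.frame together with
#'   \code{fdr_threshold}.
#' @param n_regions_total total regions tested; the canonical taxonomy is
#'   defined for 10 regions. For other totals, explicit \code{thresholds}
#'   must be supplied.
#' @param thresholds optional list with elements \code{selective_max} and
#'   \code{multi_min} rescaling the 2-7 / >= 8 boundaries.
#' @param fdr_threshold significance cutoff on q when \code{sig_sets} is an
#'   altered-gene table (default 1e-3).
#' @return data.frame with columns \code{gene}, \code{n_regions},
#'   \code{category}, covering every gene significant in >= 1 region plus
#'   (for table input) uncategorized tested genes.
#' @examples
#' classifyRegionalBreadth(list(FCTX = "G1", CRBL = "G1", TCTX = "G2"),
#'                         n_regions_total = 10)
#' @export
classifyRegionalBreadth <- function(sig_sets, n_regions_total = 10,
                                    thresholds = NULL, fdr_threshold = 1e-3) {
  all_genes <- NULL
  if (is.data.frame(sig_sets)) {
    tab <- sig_sets
    stopifnot(all(c("gene", "region", "q") %in% colnames(tab)))
    all_genes <- unique(tab$gene)
    sig <- tab[!is.na(tab$q) & tab$q < fdr_threshold, ]
    sig_sets <- split(sig$gene, sig$region)
  }
  if (n_regions_total != 10 && is.null(thresholds))
    stop("breadth taxonomy is defined for 10 regions; supply explicit ",
         "'thresholds' to rescale", call. = FALSE)
  sel_max <- if (is.null(thresholds)) 7L else thresholds$selective_max
  multi_min <- if (is.null(thresholds)) 8L else thresholds$multi_min
  counts <- table(unlist(lapply(sig_sets, unique)))
  n_reg <- as.integer(counts)
  if (length(n_reg) && max(n_reg) > n_regions_total)
    stop("a gene is significant in more regions than n_regions_total",
         call. = FALSE)
  category <- ifelse(n_reg == n_regions_total, "cross_regional",
              ifelse(n_reg >= multi_min, "multi_regional",
              ifelse(n_reg > 1, "region_selective", "region_specific")))
  out <- data.frame(gene = names(counts), n_regions = n_reg,
                    category = category, stringsAsFactors = FALSE,
                    row.names = NULL)
  if (!is.null(all_genes)) {
    rest <- setdiff(all_genes, out$gene)
    if (length(rest))
      out <- rbind(out, data.frame(gene = rest, n_regions = 0L,
                                   category = "uncategorized"))
    out <- out[match(sort(out$gene), out$gene), ]
    rownames(out) <- NULL
  }
  out
}

#' Top significant genes in one region
#'
#' @param altered an \code{\link{alteredGeneTable}} data.frame.
#' @param region region label.
#' @param k number of genes; ties in q are broken by smaller p, then by
#'   lexical gene id. If fewer than \code{k} genes pass
#'   \code{fdr_threshold}, all passing genes are returned with a message.
#' @param fdr_threshold significance cutoff (default 1e-3); \code{NULL}
#'   ranks all testable genes.
#' @return character vector of gene ids.
#' @export
selectTopGenes <- function(altered, region, k, fdr_threshold = 1e-3) {
  .assertScalarNumber(k, "k", lower = 1)
  tab <- altered[altered$region == region & !is.na(altered$q), ]
  if (!is.null(fdr_threshold)) tab <- tab[tab$q < fdr_threshold, ]
  if (nrow(tab) < k)
    message(sprintf("region %s: only %d significant genes for k = %d",
                    region, nrow(tab), k))
  tab <- tab[order(tab$q, tab$p, tab$gene), ]
  utils::head(tab$gene, k)
}

#' One-sided hypergeometric over-representation test
#'
#' Probability of observing at least the given overlap between a gene set and
#' a category when drawing from a finite universe.
#'
#' @param gene_set,category_genes character vectors, subsets of
#'   \code{universe}.
#' @param universe character vector of all tested genes (non-empty).
#' @return list with \code{p}, \code{overlap}, \code{expected} and
#'   \code{odds_ratio} (sample odds ratio of the 2x2 overlap table,
#'   \code{Inf} when a margin is exhausted).
#' @examples
#' overrepresentationTest(letters[1:10], letters[1:10], letters[1:20])$p
#' @export
overrepresentationTest <- function(gene_set, category_genes, universe) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  gene_set <- unique(gene_set)
  category_genes <- unique(category_genes)
  if (!all(gene_set %in% universe) || !all(category_genes %in% universe))
    stop("gene_set and category_genes must be subsets of the universe",
         call. = FALSE)
  N <- length(universe)
  m <- length(gene_set)
  k <- length(category_genes)
  x <- length(intersect(gene_set, category_genes))
  p <- phyper(x - 1, m, N - m, k, lower.tail = FALSE)
  a <- x; b <- m - x; c <- k - x; d <- N - m - k + x
  or <- if (b * c == 0) Inf else (a * d) / (b * c)
  if (a == 0) or <- 0
  list(p = p, overlap = x, expected = m * k / N, odds_ratio = or)
}
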