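#' @importFrom stats var
NULL

#' Pooled-variance two-sample t statistic
#'
#' Sign convention: positive when the first group's mean is larger (young
#' minus old in the aging comparisons, so a positive t means a higher count
#' in young samples). Zero pooled variance gives t = 0 when the means are
#' equal and a signed infinity otherwise.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return the t statistic.
#' @examples
#' twoSampleT(c(1, 2, 3), c(4, 5, 6))
#' @export
twoSampleT <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each group needs >= 2 values", call. = FALSE)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  md <- mean(x) - mean(y)
  if (sp2 == 0) {
    if (md == 0) return(0)
    return(sign(md) * Inf)
  }
  md / sqrt(sp2 * (1 / nx + 1 / ny))
}

## Vectorized pooled t for B shuffled assignments of n1-out-of-n labels.
## v: pooled values; idx: n1 x B matrix of group-1 indices.
.permTs <- function(v, idx) {
  n <- length(v)
  n1 <- nrow(idx)
  n2 <- n - n1
  tot <- sum(v); tot2 <- sum(v^2)
  s1 <- colSums(matrix(v[idx], nrow = n1))
  q1 <- colSums(matrix(v[idx]^2, nrow = n1))
  m1 <- s1 / n1
  m2 <- (tot - s1) / n2
  ss1 <- q1 - n1 * m1^2
  ss2 <- (tot2 - q1) - n2 * m2^2
  sp2 <- pmax(ss1 + ss2, 0) / (n - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  t[sp2 == 0 & m1 == m2] <- 0
  t
}

#' Describe a shuffled-label permutation scheme
#'
#' Null distributions are built by shuffling group labels over the tiles.
#' Schemes mirror the imaging workflows: many rounds of moderate shuffle
#' counts with per-round tile subsampling (e.g. 100 rounds x 500 shuffles),
#' or one round of many shuffles (e.g. 10,000 or 100,000).
#'
#' @param n_iterations resampling rounds (>= 1).
#' @param n_permutations label shuffles per round (>= 1).
#' @param tail \code{"right"}, \code{"left"} or \code{"two"}.
#' @param subsample_size optional per-group tile subsample drawn each round
#'   (NULL = use all tiles).
#' @param seed integer seed.
#' @return a list of class \code{PermutationScheme}.
#' @export
permutationScheme <- function(n_iterations = 1L, n_permutations = 10000L,
                              tail = c("right", "left", "two"),
                              subsample_size = NULL, seed = 0L) {
  tail <- match.arg(tail)
  .assertScalarNumber(n_iterations, "n_iterations", lower = 1)
  .assertScalarNumber(n_permutations, "n_permutations", lower = 1)
  if (!is.null(subsample_size))
    .assertScalarNumber(subsample_size, "subsample_size", lower = 2)
  structure(list(n_iterations = as.integer(n_iterations),
                 n_permutations = as.integer(n_permutations),
                 tail = tail,
                 subsample_size = if (is.null(subsample_size)) NULL
                 else as.integer(subsample_size),
                 seed = as.integer(seed)),
            class = "PermutationScheme")
}

#' Shuffled-label permutation test on per-tile counts
#'
#' Per round: optionally subsample tiles per group, compute the true-label
#' pooled t (first group minus second), then shuffle the labels
#' \code{n_permutations} times recomputing t. Nulls are pooled across
#' rounds; the reported observed statistic is the mean true-label t over
#' rounds. The p-value uses the add-one convention
#' \code{(1 + exceedances) / (1 + N_null)} (right tail; mirrored for left;
#' doubled smaller tail, capped at 1, for two-sided), so it can never be 0.
#'
#' @param counts numeric vector of per-tile counts.
#' @param group_labels vector with exactly two distinct labels; the first
#'   level (by the order given in \code{levels}, default
#'   \code{c("young", "old")} when applicable, otherwise first appearance)
#'   is the positive side of the t statistic.
#' @param scheme a \code{\link{permutationScheme}}.
#' @param levels optional length-2 character vector fixing group order.
#' @return a \linkS4class{PermutationResult}.
#' @examples
#' set.seed(1)
#' pr <- permutationTest(c(rnorm(10, 5), rnorm(10, 3)),
#'                       rep(c("young", "old"), each = 10),
#'                       permutationScheme(n_permutations = 999, seed = 2))
#' permPValue(pr)
#' @export
permutationTest <- function(counts, group_labels, scheme = permutationScheme(),
                            levels = NULL) {
  stopifnot(inherits(scheme, "PermutationScheme"),
            length(counts) == length(group_labels))
  group_labels <- as.character(group_labels)
  if (is.null(levels)) {
    levels <- if (all(sort(unique(group_labels)) == c("old", "young")))
      c("young", "old") else unique(group_labels)
  }
  if (length(unique(group_labels)) != 2 ||
      !setequal(levels, unique(group_labels)))
    stop("exactly two non-empty groups are required", call. = FALSE)
  x_all <- counts[group_labels == levels[1]]
  y_all <- counts[group_labels == levels[2]]
  if (length(x_all) < 2 || length(y_all) < 2)
    stop("each group needs >= 2 tiles", call. = FALSE)

  .withSeed(scheme$seed, {
    obs <- numeric(scheme$n_iterations)
    nulls <- vector("list", scheme$n_iterations)
    for (it in seq_len(scheme$n_iterations)) {
      x <- x_all; y <- y_all
      if (!is.null(scheme$subsample_size)) {
        ks <- scheme$subsample_size
        x <- x_all[sample.int(length(x_all), min(ks, length(x_all)))]
        y <- y_all[sample.int(length(y_all), min(ks, length(y_all)))]
      }
      obs[it] <- twoSampleT(x, y)
      v <- c(x, y)
      idx <- replicate(scheme$n_permutations,
                       sample.int(length(v), length(x)))
      nulls[[it]] <- .permTs(v, matrix(idx, nrow = length(x)))
    }
    nulls <- unlist(nulls)
    n_null <- length(nulls)
    if (n_null == 0) stop("empty null distribution", call. = FALSE)
    obs_mean <- mean(obs)
    p_right <- (1 + sum(nulls >= obs_mean)) / (1 + n_null)
    p_left <- (1 + sum(nulls <= obs_mean)) / (1 + n_null)
    p <- switch(scheme$tail,
                right = p_right,
                left = p_left,
                two = min(1, 2 * min(p_right, p_left)))
    methods::new("PermutationResult", observed = obs_mean, nulls = nulls,
                 p = p, nullSd = sd(nulls), scheme = unclass(scheme))
  })
}

#' Permutation comparisons of young vs old tile counts per measure
#'
#' Runs \code{\link{permutationTest}} (young minus old, tiles as units) for
#' each requested measure of a tidy case-summary table.
#'
#' @param summary long-format table from \code{\link{summarizeCase}}
#'   (per-tile rows; case-total rows are ignored).
#' @param measures measures to test (default: total, stained, other and the
#'   four size bins). Absent measures are skipped with a warning.
#' @param scheme a \code{\link{permutationScheme}}.
#' @return data.frame with one row per measure: \code{measure},
#'   \code{mean_t}, \code{p}, \code{null_sd}, \code{n_young},
#'   \code{n_old}, plus the scheme fields; the fitted
#'   \linkS4class{PermutationResult} objects are attached as the
#'   \code{"results"} attribute.
#' @export
runCountComparisons <- function(summary,
                                measures = c("total", "stained", "other",
                                             "small", "medium", "large",
                                             "very_large"),
                                scheme = permutationScheme()) {
  stopifnot(all(c("age_group", "tile_id", "measure", "count") %in%
                  colnames(summary)))
  summary <- summary[summary$tile_id != "(case total)", ]
  rows <- list(); fits <- list()
  for (m in measures) {
    sub <- summary[summary$measure == m, ]
    if (nrow(sub) == 0) {
      warning("measure absent from summary, skipped: ", m)
      next
    }
    res <- permutationTest(sub$count, sub$age_group, scheme,
                           levels = c("young", "old"))
    rows[[m]] <- data.frame(
      measure = m, mean_t = observedT(res), p = permPValue(res),
      null_sd = res@nullSd,
      n_young = sum(sub$age_group == "young"),
      n_old = sum(sub$age_group == "old"),
      n_iterations = scheme$n_iterations,
      n_permutations = scheme$n_permutations,
      tail = scheme$tail, stringsAsFactors = FALSE)
    fits[[m]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- fits
  out
}
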