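#' @importFrom stats quantile
NULL

#' Shannon entropy of a tile's grayscale histogram
#'
#' Entropy (bits) of the 256-bin histogram of integer gray levels (Rec.601
#' luma of the RGB channels). Constant tiles score 0; a uniform use of all
#' 256 levels scores 8. Tiles with entropy at or below the exclusion
#' threshold (5 bits by convention) carry too little structure to quantify.
#'
#' @param tile a \linkS4class{StainedTile} or an RGB array on the 0..255
#'   scale.
#' @return entropy in bits, in [0, 8].
#' @export
computeTileEntropy <- function(tile) {
  px <- if (methods::is(tile, "StainedTile")) tilePixels(tile) else tile
  g <- .luma(px)
  counts <- tabulate(as.integer(g) + 1L, nbins = 256L)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Flag tiles passing the entropy quality-control criterion
#'
#' @param tiles list of \linkS4class{StainedTile} objects.
#' @param min_entropy exclusion threshold in bits (default 5; tiles with
#'   entropy strictly above it are kept).
#' @return data.frame with \code{tile_id}, \code{entropy}, \code{keep}.
#' @export
entropyQC <- function(tiles, min_entropy = 5) {
  ent <- vapply(tiles, computeTileEntropy, numeric(1))
  ids <- vapply(tiles, function(t) t@tileId, character(1))
  data.frame(tile_id = ids, entropy = ent, keep = ent > min_entropy,
             stringsAsFactors = FALSE)
}

## Exact 8-connected labeling: 4-connected bwlabel plus a diagonal-merge
## pass on the label adjacency graph.
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  nl <- max(lab)
  if (nl < 2) return(lab)
  a <- lab[-nrow(lab), -ncol(lab)]; b <- lab[-1, -1]       # down-right
  c <- lab[-1, -ncol(lab)];        d <- lab[-nrow(lab), -1] # up-right
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c), as.vector(d)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0) return(lab)
  g <- igraph::graph_from_edgelist(
    matrix(as.character(pairs), ncol = 2), directed = FALSE)
  orphan <- setdiff(as.character(seq_len(nl)), igraph::V(g)$name)
  if (length(orphan))
    g <- igraph::add_vertices(g, length(orphan), name = orphan)
  comp <- igraph::components(g)$membership
  remap <- integer(nl)
  remap[as.integer(names(comp))] <- comp
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Segmentation parameters for the two imaging dialects
#'
#' \code{"olig2"}: the 1,600 x 1,200 glial workflow (min area 50 px);
#' \code{"neun"}: the 10,000 x 10,000 neuronal workflow (min area 500 px,
#' matching the smallest size bin).
#'
#' @param dialect \code{"olig2"} or \code{"neun"}.
#' @param min_area minimum object area in pixels.
#' @param opening_radius radius of the morphological opening brush (px);
#'   0 disables opening.
#' @param stain_delta foreground pixels with red minus blue above this value
#'   are chromogen ("stained"); the rest are counterstain ("other").
#' @param threshold \code{"otsu"} (default) or a fixed grayscale cut in
#'   [0, 255]; foreground is darker than the cut.
#' @return a list of class \code{SegmentationParams}.
#' @export
segmentationParams <- function(dialect = c("olig2", "neun"),
                               min_area = NULL, opening_radius = 2,
                               stain_delta = 20, threshold = "otsu") {
  dialect <- match.arg(dialect)
  if (is.null(min_area)) min_area <- if (dialect == "olig2") 50 else 500
  .assertScalarNumber(min_area, "min_area", lower = 1)
  .assertScalarNumber(opening_radius, "opening_radius", lower = 0)
  .assertScalarNumber(stain_delta, "stain_delta", lower = 0)
  if (!identical(threshold, "otsu"))
    .assertScalarNumber(threshold, "threshold", lower = 0, upper = 255)
  structure(list(dialect = dialect, min_area = min_area,
                 opening_radius = opening_radius, stain_delta = stain_delta,
                 threshold = threshold),
            class = "SegmentationParams")
}

#' Detect and classify stained cells in a tile
#'
#' Pipeline: grayscale foreground mask by thresholding against the pale
#' background (Otsu by default); per-pixel stain classification on the
#' foreground by channel comparison (red-dominant with low blue = chromogen
#' "stained", blue-dominant = counterstain "other"); morphological opening;
#' 8-connected component labeling; small components dropped. Each object is
#' classified by its majority pixel class.
#'
#' @param tile a \linkS4class{StainedTile} or an RGB array on the 0..255
#'   scale.
#' @param params a \code{\link{segmentationParams}} list.
#' @return data.frame of detected objects: \code{x}, \code{y} (0-based
#'   centroid, origin top-left, x rightward, y downward), \code{area}
#'   (pixels), \code{class} (\code{"stained"}/\code{"other"}), and mean
#'   channel intensities \code{mean_r}, \code{mean_g}, \code{mean_b}.
#' @examples
#' tl <- generateTile(tileConfig(width = 300, height = 200, n_stained = 3,
#'                               n_counterstained = 4, seed = 11))
#' table(segmentCells(tl)$class)
#' @export
segmentCells <- function(tile, params = segmentationParams()) {
  px <- if (methods::is(tile, "StainedTile")) tilePixels(tile) else tile
  stopifnot(inherits(params, "SegmentationParams"))
  g <- .luma(px)
  cut <- if (identical(params$threshold, "otsu")) {
    255 * EBImage::otsu(EBImage::Image(t(g) / 255), range = c(0, 1))
  } else {
    params$threshold
  }
  mask <- g < cut
  if (!any(mask)) return(.emptyObjects())

  if (params$opening_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(params$opening_radius) + 1L,
                                shape = "disc")
    mask <- EBImage::opening(mask * 1, brush) > 0
  }
  if (!any(mask)) return(.emptyObjects())

  lab <- .label8(mask * 1)
  nl <- max(lab)
  if (nl == 0) return(.emptyObjects())

  idx <- which(lab > 0)
  labv <- lab[idx]
  areas <- tabulate(labv, nbins = nl)
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  r <- px[, , 1][idx]; gg <- px[, , 2][idx]; b <- px[, , 3][idx]
  stained_px <- (r - b) > params$stain_delta

  cy <- rowsum(as.numeric(rows), labv)[, 1] / areas - 1
  cx <- rowsum(as.numeric(cols), labv)[, 1] / areas - 1
  n_stained <- rowsum(as.numeric(stained_px), labv)[, 1]
  mr <- rowsum(r, labv)[, 1] / areas
  mg <- rowsum(gg, labv)[, 1] / areas
  mb <- rowsum(b, labv)[, 1] / areas

  keep <- areas >= params$min_area
  data.frame(x = cx[keep], y = cy[keep], area = areas[keep],
             class = ifelse(n_stained[keep] > areas[keep] / 2,
                            "stained", "other"),
             mean_r = mr[keep], mean_g = mg[keep], mean_b = mb[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

.emptyObjects <- function() {
  data.frame(x = numeric(), y = numeric(), area = numeric(),
             class = character(), mean_r = numeric(), mean_g = numeric(),
             mean_b = numeric(), stringsAsFactors = FALSE)
}

#' Size-bin boundaries for cell-body areas
#'
#' Four bins partition areas of at least 500 pixels: small [500, 3000),
#' medium [3000, 6000), large [6000, 9000], very_large (9000, Inf). The
#' large/very_large boundary is upper-inclusive at 9,000 because very large
#' is defined as strictly above 9,000 pixels.
#' @export
sizeBins <- function() {
  data.frame(label = c("small", "medium", "large", "very_large"),
             lower = c(500, 3000, 6000, 9000),
             upper = c(3000, 6000, 9000, Inf),
             stringsAsFactors = FALSE)
}

#' Bin detected objects by cell-body area
#'
#' Objects below 500 pixels are excluded from binning (but remain in object
#' totals elsewhere).
#'
#' @param objects data.frame with an \code{area} column, or a numeric vector
#'   of areas.
#' @return named integer vector of counts for \code{small}, \code{medium},
#'   \code{large}, \code{very_large}.
#' @examples
#' binByArea(c(499, 500, 3500, 7000, 9000, 9001))
#' @export
binByArea <- function(objects) {
  areas <- if (is.data.frame(objects)) objects$area else objects
  stopifnot(is.numeric(areas), all(areas >= 0))
  c(small = sum(areas >= 500 & areas < 3000),
    medium = sum(areas >= 3000 & areas < 6000),
    large = sum(areas >= 6000 & areas <= 9000),
    very_large = sum(areas > 9000))
}

#' Per-tile quantification statistics
#'
#' @param tile a \linkS4class{StainedTile}.
#' @param params a \code{\link{segmentationParams}} list.
#' @param min_entropy entropy exclusion threshold in bits.
#' @return one-row data.frame: identifiers, \code{entropy}, \code{keep}
#'   (entropy QC), \code{total}, \code{stained}, \code{other}, and the four
#'   size-bin counts.
#' @export
tileStats <- function(tile, params = segmentationParams(),
                      min_entropy = 5) {
  stopifnot(methods::is(tile, "StainedTile"))
  ent <- computeTileEntropy(tile)
  obj <- segmentCells(tile, params)
  bins <- binByArea(obj)
  data.frame(tile_id = tile@tileId, case_id = tile@caseId,
             age_group = tile@ageGroup, entropy = ent,
             keep = ent > min_entropy,
             total = nrow(obj),
             stained = sum(obj$class == "stained"),
             other = sum(obj$class == "other"),
             small = bins[["small"]], medium = bins[["medium"]],
             large = bins[["large"]], very_large = bins[["very_large"]],
             stringsAsFactors = FALSE)
}

#' Split tiles into density classes and select extremes per case
#'
#' Tiles are classed low/mid/high by pooled quantiles of the total nucleus
#' count (terciles by default, proxying white vs gray matter). Within each
#' extreme class, the \code{k} most extreme tiles per case are selected
#' (lowest counts among the low class, highest among the high class); ties
#' and class boundaries are resolved by tile id order, so selection is
#' deterministic.
#'
#' @param stats data.frame with columns \code{tile_id}, \code{case_id},
#'   \code{total} (e.g. rows of \code{\link{tileStats}}).
#' @param k tiles to select per case per extreme class (default 50).
#' @param probs two pooled quantile cut points (default terciles).
#' @return \code{stats} with added \code{density_class}
#'   (\code{"low"}/\code{"mid"}/\code{"high"}) and logical \code{selected};
#'   shortfalls (cases with fewer than \code{k} tiles in a class) are
#'   messaged.
#' @export
classifyDensity <- function(stats, k = 50, probs = c(1 / 3, 2 / 3)) {
  stopifnot(all(c("tile_id", "case_id", "total") %in% colnames(stats)))
  .assertScalarNumber(k, "k", lower = 1)
  stats <- stats[order(stats$case_id, stats$tile_id), , drop = FALSE]
  qs <- quantile(stats$total, probs = probs, type = 7, names = FALSE)
  cls <- ifelse(stats$total <= qs[1], "low",
                ifelse(stats$total > qs[2], "high", "mid"))
  stats$density_class <- cls
  stats$selected <- FALSE
  for (case in unique(stats$case_id)) {
    for (side in c("low", "high")) {
      i <- which(stats$case_id == case & stats$density_class == side)
      if (length(i) == 0) next
      ord <- if (side == "low")
        i[order(stats$total[i], stats$tile_id[i])]
      else i[order(-stats$total[i], stats$tile_id[i])]
      if (length(ord) < k)
        message(sprintf("case %s: only %d %s-density tiles for k = %d",
                        case, length(ord), side, k))
      stats$selected[utils::head(ord, k)] <- TRUE
    }
  }
  rownames(stats) <- NULL
  stats
}

#' Top-k tiles by nucleus density across all cases
#'
#' @param stats data.frame with columns \code{tile_id}, \code{total}.
#' @param k number of tiles (ties broken stably by tile id).
#' @return \code{stats} rows for the k highest-count tiles.
#' @export
rankTilesByDensity <- function(stats, k) {
  stopifnot(all(c("tile_id", "total") %in% colnames(stats)))
  .assertScalarNumber(k, "k", lower = 1)
  ord <- order(-stats$total, stats$tile_id)
  out <- stats[utils::head(ord, k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tidy case-level summary of tile counts
#'
#' @param stats per-tile statistics (rows of \code{\link{tileStats}});
#'   only rows passing QC/selection should be passed in.
#' @return long-format data.frame keyed (case_id, age_group, tile_id,
#'   measure, count) for measures total, stained, other and the four size
#'   bins, plus per-case totals with \code{tile_id = "(case total)"}.
#' @export
summarizeCase <- function(stats) {
  stopifnot(nrow(stats) >= 1)
  measures <- c("total", "stained", "other", "small", "medium", "large",
                "very_large")
  long <- do.call(rbind, lapply(measures, function(m)
    data.frame(case_id = stats$case_id, age_group = stats$age_group,
               tile_id = stats$tile_id, measure = m, count = stats[[m]],
               stringsAsFactors = FALSE)))
  totals <- stats::aggregate(count ~ case_id + age_group + measure,
                             data = long, FUN = sum)
  totals$tile_id <- "(case total)"
  out <- rbind(long, totals[, colnames(long)])
  rownames(out) <- NULL
  out
}
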