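#' Configure a synthetic stained tile
#'
#' Emulates a crop of a chromogen-stained, counterstained section: disk-shaped
#' cells of two stain classes ("stained" = brown chromogen, "other" = blue
#' counterstain) on a pale background, plus Gaussian pixel noise. Two tile
#' dialects are used in practice: 1,600 x 1,200 pixels for the
#' oligodendrocyte workflow and 10,000 x 10,000 for the pan-neuronal
#' workflow; the default is the small dialect.
#'
#' @param width,height tile size in pixels.
#' @param n_stained,n_counterstained disk counts per class.
#' @param radius_range min/max disk radius in pixels (min >= 2).
#' @param stained_color,counterstained_color,background_color RGB triples in
#'   [0, 255]; defaults approximate DAB brown, hematoxylin blue and a pale
#'   slide background.
#' @param overlap_allowed if \code{FALSE}, disks are placed pairwise disjoint
#'   by rejection sampling (bounded attempts), with a 2-pixel margin between
#'   boundaries so that rasterized disks never share adjacent pixels.
#' @param noise_sd per-channel Gaussian noise SD in intensity units.
#' @param seed integer seed.
#' @return a list of class \code{TileConfig}.
#' @export
tileConfig <- function(width = 1600, height = 1200,
                       n_stained = 10, n_counterstained = 15,
                       radius_range = c(12, 25),
                       stained_color = c(150, 95, 45),
                       counterstained_color = c(70, 85, 150),
                       background_color = c(232, 228, 222),
                       overlap_allowed = FALSE,
                       noise_sd = 3,
                       seed = 1L) {
  .assertScalarNumber(width, "width", lower = 1)
  .assertScalarNumber(height, "height", lower = 1)
  .assertScalarNumber(n_stained, "n_stained", lower = 0)
  .assertScalarNumber(n_counterstained, "n_counterstained", lower = 0)
  if (length(radius_range) != 2L || radius_range[1] < 2 ||
      radius_range[1] > radius_range[2])
    stop("radius_range must be c(min, max) with min >= 2", call. = FALSE)
  for (col in list(stained_color, counterstained_color, background_color))
    if (length(col) != 3L || any(col < 0) || any(col > 255))
      stop("colors must be RGB triples in [0, 255]", call. = FALSE)
  .assertScalarNumber(noise_sd, "noise_sd", lower = 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_stained = as.integer(n_stained),
                 n_counterstained = as.integer(n_counterstained),
                 radius_range = as.numeric(radius_range),
                 stained_color = as.numeric(stained_color),
                 counterstained_color = as.numeric(counterstained_color),
                 background_color = as.numeric(background_color),
                 overlap_allowed = isTRUE(overlap_allowed),
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "TileConfig")
}

## Paint a solid disk into a h x w x 3 array (1-based center row/col).
.paintDisk <- function(px, cr, cc, r, color) {
  h <- dim(px)[1]; w <- dim(px)[2]
  rows <- max(1L, floor(cr - r)):min(h, ceiling(cr + r))
  cols <- max(1L, floor(cc - r)):min(w, ceiling(cc + r))
  dr <- rows - cr
  dc <- cols - cc
  inside <- outer(dr^2, dc^2, `+`) <= r^2
  for (ch in 1:3) {
    sub <- px[rows, cols, ch]
    sub[inside] <- color[ch]
    px[rows, cols, ch] <- sub
  }
  px
}

#' Generate a synthetic stained tile with ground truth
#'
#' @param config a \code{\link{tileConfig}}.
#' @param tile_id,case_id,age_group identifiers stored on the tile.
#' @return a \linkS4class{StainedTile}; \code{\link{groundTruth}} lists every
#'   disk (0-based x/y center, radius, class).
#' @examples
#' tl <- generateTile(tileConfig(width = 200, height = 150, n_stained = 2,
#'                               n_counterstained = 3, seed = 5))
#' table(groundTruth(tl)$class)
#' @export
generateTile <- function(config, tile_id = "tile1", case_id = "case1",
                         age_group = "young") {
  if (!inherits(config, "TileConfig"))
    stop("config must come from tileConfig()", call. = FALSE)
  n_total <- config$n_stained + config$n_counterstained
  .withSeed(config$seed, {
    classes <- rep(c("stained", "other"),
                   c(config$n_stained, config$n_counterstained))
    radii <- if (n_total)
      runif(n_total, config$radius_range[1], config$radius_range[2])
    else numeric()
    cx <- numeric(n_total); cy <- numeric(n_total)
    max_attempts <- max(200L * n_total, 1000L)
    attempts <- 0L
    placed <- 0L
    while (placed < n_total) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf(
          "could not place %d disjoint disks (placed %d after %d attempts)",
          n_total, placed, attempts - 1L), call. = FALSE)
      r <- radii[placed + 1L]
      x <- runif(1, r + 1, config$width - r)
      y <- runif(1, r + 1, config$height - r)
      if (!config$overlap_allowed && placed > 0L) {
        ## 2 px margin: tangent disks would rasterize into touching pixels
        d2 <- (cx[seq_len(placed)] - x)^2 + (cy[seq_len(placed)] - y)^2
        if (any(d2 < (radii[seq_len(placed)] + r + 2)^2)) next
      }
      placed <- placed + 1L
      cx[placed] <- x; cy[placed] <- y
    }

    px <- array(rep(config$background_color,
                    each = config$height * config$width),
                dim = c(config$height, config$width, 3))
    for (i in seq_len(n_total)) {
      color <- if (classes[i] == "stained") config$stained_color
               else config$counterstained_color
      ## +1: ground truth is 0-based, the array is 1-based
      px <- .paintDisk(px, cy[i] + 1, cx[i] + 1, radii[i], color)
    }
    if (config$noise_sd > 0)
      px <- px + array(rnorm(length(px), sd = config$noise_sd), dim = dim(px))
    px <- pmin(pmax(px, 0), 255)

    gt <- data.frame(x = cx, y = cy, radius = radii, class = classes,
                     stringsAsFactors = FALSE)
    methods::new("StainedTile", pixels = px, tileId = tile_id,
                 caseId = case_id, ageGroup = age_group, groundTruth = gt)
  })
}

#' Write / read a tile as PNG (plus JSON ground truth)
#'
#' @param tile a \linkS4class{StainedTile}.
#' @param path PNG file path; ground truth, when present, is written next to
#'   it as \code{<path>.truth.json}.
#' @return \code{readTilePNG}: a \linkS4class{StainedTile} (ground truth
#'   restored if the JSON sidecar exists).
#' @export
writeTilePNG <- function(tile, path) {
  stopifnot(methods::is(tile, "StainedTile"))
  png::writePNG(tilePixels(tile) / 255, path)
  gt <- groundTruth(tile)
  if (nrow(gt)) {
    jsonlite::write_json(
      list(tile_id = tile@tileId, case_id = tile@caseId,
           age_group = tile@ageGroup, objects = gt),
      paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname writeTilePNG
#' @export
readTilePNG <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3))
  px <- px[, , 1:3, drop = FALSE] * 255
  tf <- paste0(path, ".truth.json")
  gt <- data.frame(x = numeric(), y = numeric(), radius = numeric(),
                   class = character())
  tid <- sub("\\.png$", "", basename(path)); cid <- "unknown"; ag <- "unknown"
  if (file.exists(tf)) {
    j <- jsonlite::read_json(tf, simplifyVector = TRUE)
    gt <- as.data.frame(j$objects)
    tid <- j$tile_id; cid <- j$case_id; ag <- j$age_group
  }
  methods::new("StainedTile", pixels = px, tileId = tid, caseId = cid,
               ageGroup = ag, groundTruth = gt)
}
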