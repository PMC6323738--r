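#' Run the automatic CSA segmentation pipeline on one image
#'
#' Deterministic composition of the automated pipeline stages:
#' Huang threshold, binarization (fiber interiors become particles),
#' binary opening, hole filling, 8-connected labeling, per-particle
#' morphometry, and size/circularity/edge filtering. The result records the
#' configuration, the threshold used and one ROI per kept particle with
#' `origin = "automatic"`. Two runs on identical inputs are identical: the
#' pipeline is a pure function of (image, config).
#'
#' @param image a [muscle_image()].
#' @param config a [pipeline_config()].
#' @param threshold optional fixed gray threshold; when `NULL` (default) the
#'   Huang threshold is computed from the image. Fixing it is useful when
#'   several tiles of one section must share a single global threshold.
#' @return A `segmentation_result`.
#' @examples
#' sec <- generate_section(section_preset("uninjured", n_seeds = 40))
#' res <- run_pipeline(sec$image, pipeline_preset("D0"))
#' res
#' @export
run_pipeline <- function(image, config = pipeline_config(),
                         threshold = NULL) {
  stopifnot(inherits(image, "muscle_image"),
            inherits(config, "pipeline_config"))
  thr <- if (is.null(threshold)) huang_threshold(image) else {
    as.integer(threshold)
  }
  mask <- binarize_fibers(image, thr, config)
  mask <- morphological_open(mask, config$open_radius_px,
                             config$open_iterations)
  mask <- fill_holes(mask)
  lab <- label_connected(mask)
  morph <- .measure_all_regions(lab, image$pixel_size_um)
  flt <- filter_regions(morph, config)
  rois <- lapply(seq_along(flt$kept), function(i) {
    m <- flt$kept[[i]]
    .fiber_roi(fiber_id = i, polygon = m$polygon, origin = "automatic",
               area_um2 = m$area_um2, perimeter_um = m$perimeter_um,
               circularity = m$circularity, centroid = m$centroid,
               touches_edge = m$touches_edge)
  })
  reason_counts <- table(unlist(lapply(flt$rejected, `[[`, "reasons")))
  .segmentation_result(
    rois = rois,
    image_name = image$name,
    image_size = c(ncol(image$pixels), nrow(image$pixels)),
    pixel_size_um = image$pixel_size_um,
    config = config,
    threshold_used = thr,
    filter_counts = list(
      n_particles = length(morph),
      n_kept = length(flt$kept),
      n_rejected = length(flt$rejected),
      rejected_by_reason = as.list(reason_counts)))
}

#' Split an image into overlapping tiles
#'
#' Whole-section images too large to process at once are split into two or
#' four parts. Two parts split along the longer axis; four parts split into
#' quadrants. Adjacent tiles share `overlap_px` rows/columns (the earlier
#' tile is extended across the seam), and each tile carries the offset
#' mapping its coordinates back to the whole image exactly; the union of
#' tiles covers the image.
#'
#' @param image a [muscle_image()].
#' @param n_parts 1, 2 or 4.
#' @param overlap_px seam overlap in pixels (>= 0). For seamless merging it
#'   should exceed the largest fiber diameter.
#' @return A list of tiles, each a list with `image` (the tile as a
#'   [muscle_image()]) and `offset` (`c(x, y)`, 0-based pixel offset of the
#'   tile origin in the whole image).
#' @export
split_into_tiles <- function(image, n_parts = 1L, overlap_px = 0L) {
  stopifnot(inherits(image, "muscle_image"))
  if (!n_parts %in% c(1L, 2L, 4L)) stop("n_parts must be 1, 2 or 4")
  if (overlap_px < 0) stop("overlap_px must be >= 0")
  px <- image$pixels
  h <- nrow(px); w <- ncol(px)
  cut1 <- function(len) {
    c0 <- len %/% 2L
    if (c0 + overlap_px > len || c0 == 0L) {
      stop("overlap_px larger than a tile dimension")
    }
    list(a = c(1L, c0 + overlap_px), b = c(c0 + 1L, len), off = c0)
  }
  spans_x <- list(c(1L, w)); offs_x <- 0L
  spans_y <- list(c(1L, h)); offs_y <- 0L
  if (n_parts == 2L) {
    if (w >= h) {
      s <- cut1(w); spans_x <- list(s$a, s$b); offs_x <- c(0L, s$off)
    } else {
      s <- cut1(h); spans_y <- list(s$a, s$b); offs_y <- c(0L, s$off)
    }
  } else if (n_parts == 4L) {
    sx <- cut1(w); sy <- cut1(h)
    spans_x <- list(sx$a, sx$b); offs_x <- c(0L, sx$off)
    spans_y <- list(sy$a, sy$b); offs_y <- c(0L, sy$off)
  }
  tiles <- list()
  k <- 0L
  for (iy in seq_along(spans_y)) {
    for (ix in seq_along(spans_x)) {
      k <- k + 1L
      sub <- px[spans_y[[iy]][1]:spans_y[[iy]][2],
                spans_x[[ix]][1]:spans_x[[ix]][2], drop = FALSE]
      timg <- muscle_image(sub, bit_depth = image$bit_depth,
                           pixel_size_um = image$pixel_size_um,
                           name = sprintf("%s[tile%d]", image$name, k))
      tiles[[k]] <- list(image = timg,
                         offset = c(offs_x[ix], offs_y[iy]))
    }
  }
  tiles
}

#' Merge per-tile segmentation results into a whole-image result
#'
#' Shifts every ROI by its tile offset and reconciles the seams: two ROIs
#' from different tiles are duplicates when the centroid of one falls inside
#' the polygon of the other; of each duplicate group the copy farthest from
#' its own tile's internal seams is kept (a copy cut by a seam is never
#' preferred over an intact one). With a tile overlap exceeding the largest
#' fiber diameter, the merged result matches the whole-image pipeline.
#'
#' @param tile_results list of per-tile entries, each a list with `result`
#'   (a `segmentation_result` from [run_pipeline()] on the tile) and
#'   `offset` (`c(x, y)` as produced by [split_into_tiles()]).
#' @param image_name name recorded in the merged result.
#' @return A merged `segmentation_result` in whole-image coordinates.
#' @export
merge_tile_results <- function(tile_results, image_name = NULL) {
  stopifnot(length(tile_results) >= 1L)
  cfgs <- lapply(tile_results, function(t) t$result$config)
  for (cfg in cfgs[-1]) {
    if (!identical(unclass(cfg), unclass(cfgs[[1]]))) {
      stop("inconsistent configs across tiles")
    }
  }
  ps <- tile_results[[1]]$result$pixel_size_um
  # whole-image extent from tile offsets + sizes
  W <- max(vapply(tile_results, function(t)
    t$offset[1] + t$result$image_size[1], numeric(1)))
  H <- max(vapply(tile_results, function(t)
    t$offset[2] + t$result$image_size[2], numeric(1)))

  entries <- list()
  for (ti in seq_along(tile_results)) {
    tr <- tile_results[[ti]]
    tw <- tr$result$image_size[1]; th <- tr$result$image_size[2]
    ox <- tr$offset[1]; oy <- tr$offset[2]
    # internal seams: tile edges that are not whole-image borders
    seam_left <- ox > 0; seam_right <- ox + tw < W
    seam_top <- oy > 0; seam_bottom <- oy + th < H
    for (roi in tr$result$rois) {
      p <- roi$polygon
      bb <- c(min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2]))
      dists <- c(if (seam_left) bb[1] else Inf,
                 if (seam_right) tw - bb[2] else Inf,
                 if (seam_top) bb[3] else Inf,
                 if (seam_bottom) th - bb[4] else Inf)
      seam_dist <- min(dists)
      roi$polygon <- cbind(p[, 1] + ox, p[, 2] + oy)
      roi$centroid <- roi$centroid + c(ox, oy)
      roi$tile_id <- ti
      entries[[length(entries) + 1L]] <-
        list(roi = roi, tile = ti, seam_dist = seam_dist,
             bbox = c(bb[1] + ox, bb[2] + ox, bb[3] + oy, bb[4] + oy))
    }
  }
  n <- length(entries)
  keep <- rep(TRUE, n)
  if (n > 1L) {
    # union-find over duplicate pairs
    parent <- seq_len(n)
    find <- function(x) {
      while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }
      x
    }
    bb <- t(vapply(entries, `[[`, numeric(4), "bbox"))
    tile_of <- vapply(entries, `[[`, numeric(1), "tile")
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (tile_of[i] == tile_of[j]) next
        if (bb[i, 2] < bb[j, 1] || bb[j, 2] < bb[i, 1] ||
            bb[i, 4] < bb[j, 3] || bb[j, 4] < bb[i, 3]) next
        ci <- entries[[i]]$roi$centroid; cj <- entries[[j]]$roi$centroid
        dup <- .points_in_polygon(ci[1], ci[2], entries[[j]]$roi$polygon) ||
               .points_in_polygon(cj[1], cj[2], entries[[i]]$roi$polygon)
        if (dup) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    groups <- split(seq_len(n), vapply(seq_len(n), find, integer(1)))
    for (g in groups) {
      if (length(g) == 1L) next
      sd <- vapply(entries[g], `[[`, numeric(1), "seam_dist")
      ar <- vapply(entries[g], function(e) e$roi$area_um2, numeric(1))
      best <- g[order(-sd, -ar, g)][1L]
      keep[setdiff(g, best)] <- FALSE
    }
  }
  rois <- lapply(entries[keep], `[[`, "roi")
  # stable whole-image numbering: raster order of centroids
  if (length(rois)) {
    cx <- vapply(rois, function(r) r$centroid[1], numeric(1))
    cy <- vapply(rois, function(r) r$centroid[2], numeric(1))
    rois <- rois[order(cy, cx)]
    for (i in seq_along(rois)) rois[[i]]$fiber_id <- i
  }
  thr <- unique(vapply(tile_results, function(t)
    as.numeric(t$result$threshold_used), numeric(1)))
  .segmentation_result(
    rois = rois,
    image_name = if (is.null(image_name))
      sub("\\[tile[0-9]+\\]$", "", tile_results[[1]]$result$image_name)
    else image_name,
    image_size = c(W, H),
    pixel_size_um = ps,
    config = cfgs[[1]],
    threshold_used = if (length(thr) == 1L) thr else thr,
    filter_counts = list(tiles_merged = length(tile_results),
                         n_kept = length(rois)))
}
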