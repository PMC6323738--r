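# Fiber ROI model: each detected or hand-added myofiber is a polygon in
# whole-image pixel coordinates with its morphometrics, collected in a
# segmentation_result together with the configuration used and an ordered,
# replayable correction log.

# construct a single fiber ROI record
.fiber_roi <- function(fiber_id, polygon, origin, area_um2, perimeter_um,
                       circularity, centroid, touches_edge = FALSE,
                       tile_id = NA_integer_) {
  structure(list(fiber_id = as.integer(fiber_id),
                 polygon = polygon,
                 origin = match.arg(origin, c("automatic", "manual")),
                 area_um2 = as.numeric(area_um2),
                 perimeter_um = as.numeric(perimeter_um),
                 circularity = as.numeric(circularity),
                 centroid = as.numeric(centroid),
                 touches_edge = isTRUE(touches_edge),
                 tile_id = as.integer(tile_id)),
            class = "fiber_roi")
}

# construct a segmentation result
.segmentation_result <- function(rois, image_name, image_size, pixel_size_um,
                                 config, threshold_used,
                                 correction_log = list(),
                                 filter_counts = NULL) {
  ids <- vapply(rois, function(r) r$fiber_id, integer(1))
  if (anyDuplicated(ids)) stop("fiber ids must be unique")
  structure(list(rois = rois,
                 image_name = image_name,
                 image_size = as.integer(image_size),   # (width, height)
                 pixel_size_um = as.numeric(pixel_size_um),
                 config = config,
                 threshold_used = threshold_used,
                 correction_log = correction_log,
                 filter_counts = filter_counts),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  n <- length(x$rois)
  orig <- vapply(x$rois, function(r) r$origin, character(1))
  cat(sprintf("<segmentation_result> '%s': %d fibers (%d automatic, %d manual)\n",
              x$image_name, n, sum(orig == "automatic"),
              sum(orig == "manual")))
  cat(sprintf("  image %d x %d px @ %.4g um/px, threshold %s, %d correction(s)\n",
              x$image_size[1], x$image_size[2], x$pixel_size_um,
              format(x$threshold_used), length(x$correction_log)))
  if (n > 0) {
    a <- fiber_areas(x)
    cat(sprintf("  CSA: mean %.1f um^2, median %.1f um^2, range [%.1f, %.1f]\n",
                mean(a), median(a), min(a), max(a)))
  }
  invisible(x)
}

#' @export
summary.segmentation_result <- function(object, ...) {
  print(object)
  if (length(object$rois)) {
    print(summary(fiber_areas(object)))
  }
  invisible(object)
}

#' Per-fiber areas of a segmentation result
#'
#' @param result a segmentation result.
#' @return Numeric vector of fiber areas in um^2.
#' @export
fiber_areas <- function(result) {
  stopifnot(inherits(result, "segmentation_result"))
  vapply(result$rois, function(r) r$area_um2, numeric(1))
}

#' Convert a segmentation result to a per-fiber data frame
#'
#' @param x a segmentation result.
#' @param ... unused.
#' @return A data.frame with columns `fiber_id`, `origin`, `area_um2`,
#'   `perimeter_um`, `circularity`, `centroid_x`, `centroid_y`, `tile_id`.
#' @export
as.data.frame.segmentation_result <- function(x, ...) {
  if (!length(x$rois)) {
    return(data.frame(fiber_id = integer(0), origin = character(0),
                      area_um2 = numeric(0), perimeter_um = numeric(0),
                      circularity = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), tile_id = integer(0)))
  }
  data.frame(
    fiber_id = vapply(x$rois, `[[`, integer(1), "fiber_id"),
    origin = vapply(x$rois, `[[`, character(1), "origin"),
    area_um2 = vapply(x$rois, `[[`, numeric(1), "area_um2"),
    perimeter_um = vapply(x$rois, `[[`, numeric(1), "perimeter_um"),
    circularity = vapply(x$rois, `[[`, numeric(1), "circularity"),
    centroid_x = vapply(x$rois, function(r) r$centroid[1], numeric(1)),
    centroid_y = vapply(x$rois, function(r) r$centroid[2], numeric(1)),
    tile_id = vapply(x$rois, `[[`, integer(1), "tile_id"))
}

#' Delete fibers from a segmentation result
#'
#' Removes the given fiber ids (false myofibers created by the automation)
#' and appends the deletion to the correction log. Deleting an empty id set
#' is a recorded no-op.
#'
#' @param result a segmentation result.
#' @param ids integer vector of fiber ids to remove; all must exist.
#' @return The corrected segmentation result.
#' @export
delete_fibers <- function(result, ids) {
  stopifnot(inherits(result, "segmentation_result"))
  ids <- as.integer(ids)
  have <- vapply(result$rois, function(r) r$fiber_id, integer(1))
  missing <- setdiff(ids, have)
  if (length(missing)) {
    stop("unknown fiber id(s): ", paste(missing, collapse = ", "))
  }
  result$rois <- result$rois[!have %in% ids]
  result$correction_log <- c(result$correction_log,
                             list(list(op = "delete", ids = ids)))
  result
}

#' Add a hand-drawn fiber to a segmentation result
#'
#' Appends a manually drawn polygon as a new fiber with `origin = "manual"`
#' and a fresh id. The area comes from the continuous shoelace geometry of
#' the polygon times `pixel_size_um^2`. Manual fibers are exempt from the
#' size and circularity filters: the experimenter overrides the automation,
#' remaining the authority on what a myofiber is. Circularity is not
#' computed for manual fibers (it plays no role in CSA) and is `NA`.
#'
#' @param result a segmentation result.
#' @param polygon `n x 2` matrix of `(x, y)` vertices in whole-image pixel
#'   coordinates; must be simple and lie within the image bounds.
#' @param pixel_size_um calibration; defaults to the result's.
#' @return The corrected segmentation result.
#' @export
add_fiber <- function(result, polygon, pixel_size_um = NULL) {
  stopifnot(inherits(result, "segmentation_result"))
  if (is.null(pixel_size_um)) pixel_size_um <- result$pixel_size_um
  p <- .check_polygon(polygon)
  w <- result$image_size[1]; h <- result$image_size[2]
  if (min(p[, 1]) < 0 || max(p[, 1]) > w ||
      min(p[, 2]) < 0 || max(p[, 2]) > h) {
    stop("polygon lies outside the image bounds (", w, " x ", h, ")")
  }
  have <- vapply(result$rois, function(r) r$fiber_id, integer(1))
  new_id <- if (length(have)) max(have) + 1L else 1L
  area_px <- abs(.shoelace_signed(p))
  roi <- .fiber_roi(fiber_id = new_id, polygon = p, origin = "manual",
                    area_um2 = area_px * pixel_size_um^2,
                    perimeter_um = .polygon_perimeter(p) * pixel_size_um,
                    circularity = NA_real_,
                    centroid = .polygon_centroid(p))
  result$rois <- c(result$rois, list(roi))
  result$correction_log <- c(result$correction_log,
                             list(list(op = "add", id = new_id,
                                       polygon = p,
                                       pixel_size_um = pixel_size_um)))
  result
}

#' Replay a correction log onto an automatic result
#'
#' Applies an ordered list of add/delete events to a segmentation result.
#' Replaying a result's own log from its automatic state reproduces the
#' corrected state exactly.
#'
#' @param result a segmentation result (typically the uncorrected,
#'   automatic one).
#' @param log a correction log as stored in `result$correction_log`.
#' @return The segmentation result after applying all events.
#' @export
replay_corrections <- function(result, log) {
  stopifnot(inherits(result, "segmentation_result"))
  for (ev in log) {
    result <- switch(ev$op,
      delete = delete_fibers(result, ev$ids),
      add = add_fiber(result, ev$polygon, ev$pixel_size_um),
      stop("unknown correction op: ", ev$op))
  }
  result
}
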