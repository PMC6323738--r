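#' Pipeline configuration
#'
#' Holds the particle-analysis thresholds and morphology settings applied by
#' [run_pipeline()]. Size filtering is performed in calibrated um^2, so the
#' image calibration matters; circularity is the dimensionless shape score
#' `4*pi*area / perimeter^2` (1 for a perfect circle).
#'
#' @param size_min_um2 minimum fiber area in um^2 (>= 0).
#' @param circularity_min minimum circularity, in `[0, 1]`.
#' @param exclude_edges drop particles touching the image border (only entire
#'   myofibers are analyzed). Default `TRUE`.
#' @param open_radius_px structuring-element radius for the binary opening;
#'   the element is a square of side `2 * open_radius_px + 1`.
#' @param open_iterations number of opening passes (>= 0; 0 disables).
#' @param invert_after_threshold if `TRUE` (default), pixels at or below the
#'   threshold - the dark fiber interiors - become foreground particles;
#'   otherwise the bright laminin network is the foreground.
#' @param tile_overlap_px seam overlap used when an image is processed in
#'   tiles (>= 0).
#' @return An object of class `pipeline_config`.
#' @seealso [pipeline_preset()] for the recommended per-condition thresholds.
#' @examples
#' pipeline_config(size_min_um2 = 100, circularity_min = 0.4)
#' @export
pipeline_config <- function(size_min_um2 = 0, circularity_min = 0,
                            exclude_edges = TRUE, open_radius_px = 1L,
                            open_iterations = 1L,
                            invert_after_threshold = TRUE,
                            tile_overlap_px = 64L) {
  stopifnot(is.numeric(size_min_um2), length(size_min_um2) == 1L,
            size_min_um2 >= 0)
  if (!is.numeric(circularity_min) || circularity_min < 0 ||
      circularity_min > 1) {
    stop("circularity_min must lie in [0, 1]")
  }
  if (open_iterations < 0) stop("open_iterations must be >= 0")
  if (open_radius_px < 1) stop("open_radius_px must be >= 1")
  if (tile_overlap_px < 0) stop("tile_overlap_px must be >= 0")
  structure(list(size_min_um2 = as.numeric(size_min_um2),
                 circularity_min = as.numeric(circularity_min),
                 exclude_edges = isTRUE(exclude_edges),
                 open_radius_px = as.integer(open_radius_px),
                 open_iterations = as.integer(open_iterations),
                 invert_after_threshold = isTRUE(invert_after_threshold),
                 tile_overlap_px = as.integer(tile_overlap_px)),
            class = "pipeline_config")
}

# recommended starting thresholds per muscle condition
.preset_table <- data.frame(
  name = c("D0", "D8", "D14", "D28", "Fib-mdx"),
  size_min_um2 = c(200, 50, 100, 150, 50),
  circularity_min = rep(0.4, 5),
  stringsAsFactors = FALSE
)

#' Recommended size and circularity thresholds per muscle condition
#'
#' Starting thresholds for uninjured muscle (`"D0"`, young and old),
#' regenerating muscle at 8, 14 and 28 days post cardiotoxin injury (`"D8"`,
#' `"D14"`, `"D28"`) and fibrotic dystrophic muscle (`"Fib-mdx"`). All
#' presets use a circularity minimum of 0.4; size minima are 200, 50, 100,
#' 150 and 50 um^2 respectively. For regenerating conditions the size
#' threshold is a starting point to be adjusted: if too many small myofibers
#' are missed, decrease it progressively on a few representative pictures.
#'
#' @param name one of `"D0"`, `"D8"`, `"D14"`, `"D28"`, `"Fib-mdx"`.
#' @param ... overrides passed to [pipeline_config()].
#' @return A [pipeline_config()].
#' @examples
#' pipeline_preset("D0")
#' pipeline_preset("D8", exclude_edges = FALSE)
#' @export
pipeline_preset <- function(name, ...) {
  i <- match(name, .preset_table$name)
  if (is.na(i)) {
    stop("unknown preset '", name, "'; available: ",
         paste(.preset_table$name, collapse = ", "))
  }
  args <- modifyList(list(size_min_um2 = .preset_table$size_min_um2[i],
                          circularity_min = .preset_table$circularity_min[i]),
                     list(...))
  do.call(pipeline_config, args)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  size_min: %g um^2, circularity_min: %g, exclude_edges: %s\n",
              x$size_min_um2, x$circularity_min, x$exclude_edges))
  cat(sprintf("  opening: radius %d px x %d iteration(s); invert: %s; tile overlap: %d px\n",
              x$open_radius_px, x$open_iterations, x$invert_after_threshold,
              x$tile_overlap_px))
  invisible(x)
}
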