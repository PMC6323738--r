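#' Distribution bin specification for CSA histograms
#'
#' @param edges_um2 strictly increasing bin edges in um^2. Bins are
#'   right-open (`[e_i, e_{i+1})`), with an underflow bin below the first
#'   edge and an overflow bin above the last. The default edges include the
#'   500 um^2 cut separating "small" myofibers.
#' @return An object of class `distribution_spec`.
#' @export
distribution_spec <- function(edges_um2 = c(500, 1000, 1500, 2000, 2500,
                                            3000, 3500, 4000)) {
  edges_um2 <- as.numeric(edges_um2)
  if (length(edges_um2) < 1L || any(diff(edges_um2) <= 0)) {
    stop("bin edges must be strictly increasing")
  }
  structure(list(edges_um2 = edges_um2), class = "distribution_spec")
}

#' Mean cross-sectional area of a segmentation result
#'
#' @param result a `segmentation_result`, or a numeric vector of areas.
#' @return Arithmetic mean CSA in um^2.
#' @export
mean_csa <- function(result) {
  a <- if (inherits(result, "segmentation_result")) fiber_areas(result)
       else as.numeric(result)
  if (length(a) == 0L) stop("empty result: mean CSA is undefined")
  mean(a)
}

#' CSA distribution over declared bins
#'
#' @param result a `segmentation_result` or numeric vector of areas (um^2).
#' @param spec a [distribution_spec()].
#' @return A data.frame with `bin` labels, `lower`, `upper`, `count` and
#'   `fraction` (fractions sum to 1 for non-empty input).
#' @export
csa_distribution <- function(result, spec = distribution_spec()) {
  stopifnot(inherits(spec, "distribution_spec"))
  a <- if (inherits(result, "segmentation_result")) fiber_areas(result)
       else as.numeric(result)
  edges <- spec$edges_um2
  breaks <- c(-Inf, edges, Inf)
  counts <- as.integer(table(cut(a, breaks, right = FALSE)))
  lower <- c(0, edges)
  upper <- c(edges, Inf)
  data.frame(
    bin = paste0("[", lower, ",", ifelse(is.finite(upper), upper, "Inf"),
                 ")"),
    lower = lower, upper = upper, count = counts,
    fraction = if (length(a)) counts / length(a) else rep(0, length(counts)))
}

#' Match a segmentation to ground truth by intersection over union
#'
#' One-to-one greedy matching of predicted fibers to ground-truth fibers:
#' candidate pairs with IoU at or above `iou_min` are accepted in order of
#' descending IoU, each fiber matching at most once. Unmatched truth fibers
#' are missed; unmatched predictions are false. Predictions are rasterized
#' from their polygons, which is exact for pipeline-traced contours.
#'
#' Recall is additionally reported over the *eligible* truth subset -
#' fibers at least `eligible_min_um2` large and (when
#' `eligible_exclude_edge`) not touching the image border - since fibers the
#' configuration deliberately filters out (too small, cut by the border)
#' cannot be recovered by design.
#'
#' The truth-area convention is declared per report: `"boundary_inclusive"`
#' compares predicted CSA against full territory areas (interior plus the
#' basal-lamina band), `"interior"` against the area inside the stained
#' band; the automatic pipeline measures inside the basal lamina, so the
#' boundary-inclusive comparison shows a slight systematic underestimation.
#'
#' @param result a `segmentation_result` in the truth's image frame.
#' @param truth a `ground_truth_section`.
#' @param iou_min matching threshold in `(0, 1]`, default 0.5.
#' @param convention truth-area convention (see above).
#' @param eligible_min_um2 minimum truth area counted in `recall`; defaults
#'   to the result's configured `size_min_um2`.
#' @param eligible_exclude_edge exclude border-touching truth fibers from
#'   `recall`; defaults to the result's `exclude_edges` flag.
#' @param spec a [distribution_spec()] for the per-bin counts.
#' @return An object of class `comparison_report`; see Details.
#' @export
match_to_truth <- function(result, truth, iou_min = 0.5,
                           convention = c("boundary_inclusive", "interior"),
                           eligible_min_um2 = NULL,
                           eligible_exclude_edge = NULL,
                           spec = distribution_spec()) {
  stopifnot(inherits(result, "segmentation_result"),
            inherits(truth, "ground_truth_section"))
  convention <- match.arg(convention)
  if (!(iou_min > 0 && iou_min <= 1)) stop("iou_min must lie in (0, 1]")
  h <- nrow(truth$labels); w <- ncol(truth$labels)
  if (result$image_size[1] != w || result$image_size[2] != h ||
      abs(result$pixel_size_um - truth$image$pixel_size_um) > 1e-9) {
    stop("frame mismatch between result and truth (size or calibration)")
  }
  if (is.null(eligible_min_um2)) {
    eligible_min_um2 <- if (!is.null(result$config))
      result$config$size_min_um2 else 0
  }
  if (is.null(eligible_exclude_edge)) {
    eligible_exclude_edge <- if (!is.null(result$config))
      result$config$exclude_edges else FALSE
  }
  ps <- result$pixel_size_um
  n_truth <- nrow(truth$truth)
  n_pred <- length(result$rois)
  truth_px <- truth$truth$area_um2 / ps^2

  # candidate pairs via rasterized overlap with the truth raster
  cand <- list()
  pred_px <- numeric(n_pred)
  for (i in seq_len(n_pred)) {
    pix <- .rasterize_polygon(result$rois[[i]]$polygon, h, w)
    pred_px[i] <- nrow(pix)
    if (!nrow(pix)) next
    labs <- truth$labels[cbind(pix[, 1], pix[, 2])]
    tb <- table(labs[labs > 0L])
    for (k in seq_along(tb)) {
      L <- as.integer(names(tb)[k])
      inter <- as.numeric(tb[k])
      iou <- inter / (pred_px[i] + truth_px[L] - inter)
      if (iou >= iou_min) {
        cand[[length(cand) + 1L]] <- c(i, L, iou)
      }
    }
  }
  matched_pred <- integer(0); matched_truth <- integer(0)
  pairs <- NULL
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(-cm[, 3], cm[, 1], cm[, 2]), , drop = FALSE]
    used_p <- logical(n_pred); used_t <- logical(n_truth)
    sel <- logical(nrow(cm))
    for (k in seq_len(nrow(cm))) {
      i <- cm[k, 1]; L <- cm[k, 2]
      if (!used_p[i] && !used_t[L]) {
        used_p[i] <- TRUE; used_t[L] <- TRUE; sel[k] <- TRUE
      }
    }
    pairs <- cm[sel, , drop = FALSE]
    matched_pred <- as.integer(pairs[, 1])
    matched_truth <- as.integer(pairs[, 2])
  }

  truth_area <- switch(convention,
                       boundary_inclusive = truth$truth$area_um2,
                       interior = truth$truth$area_interior_um2)
  eligible <- truth$truth$area_um2 >= eligible_min_um2
  if (eligible_exclude_edge) eligible <- eligible & !truth$truth$touches_edge
  n_eligible <- sum(eligible)
  matched_eligible <- sum(eligible[matched_truth])
  pred_areas <- if (n_pred) fiber_areas(result) else numeric(0)
  mean_truth <- if (n_eligible) mean(truth_area[eligible]) else NA_real_
  mean_pred <- if (n_pred) mean(pred_areas) else NA_real_

  matched_area_pairs <- if (length(matched_pred)) {
    data.frame(pred_id = vapply(result$rois[matched_pred], `[[`,
                                integer(1), "fiber_id"),
               truth_id = matched_truth,
               area_pred_um2 = pred_areas[matched_pred],
               area_truth_um2 = truth_area[matched_truth],
               iou = pairs[, 3])
  } else {
    data.frame(pred_id = integer(0), truth_id = integer(0),
               area_pred_um2 = numeric(0), area_truth_um2 = numeric(0),
               iou = numeric(0))
  }

  structure(list(
    n_truth = n_truth,
    n_predicted = n_pred,
    n_matched = length(matched_truth),
    n_missed = n_truth - length(matched_truth),
    n_false = n_pred - length(matched_pred),
    n_truth_eligible = n_eligible,
    n_matched_eligible = matched_eligible,
    recall = if (n_eligible) matched_eligible / n_eligible else NA_real_,
    iou_min = iou_min,
    convention = convention,
    eligible_min_um2 = eligible_min_um2,
    eligible_exclude_edge = eligible_exclude_edge,
    mean_csa_truth = mean_truth,
    mean_csa_predicted = mean_pred,
    percent_mean_csa_error = 100 * (mean_pred - mean_truth) / mean_truth,
    bins_truth = csa_distribution(truth_area[eligible], spec),
    bins_predicted = csa_distribution(pred_areas, spec),
    matched_pairs = matched_area_pairs), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat(sprintf("  truth: %d (eligible %d)  predicted: %d\n",
              x$n_truth, x$n_truth_eligible, x$n_predicted))
  cat(sprintf("  matched: %d  missed: %d  false: %d  (IoU >= %.2f)\n",
              x$n_matched, x$n_missed, x$n_false, x$iou_min))
  cat(sprintf("  recall (eligible truth): %.1f%%\n", 100 * x$recall))
  cat(sprintf("  mean CSA: truth %.1f vs predicted %.1f um^2 (%+.1f%%, %s truth convention)\n",
              x$mean_csa_truth, x$mean_csa_predicted,
              x$percent_mean_csa_error, x$convention))
  invisible(x)
}

#' Identity-line correlation between two per-image CSA series
#'
#' Least-squares line and squared Pearson correlation of paired per-image
#' mean CSA values from two methods (e.g. automatic vs manual), the way
#' method-agreement panels plot each image as one dot against the identity
#' line.
#'
#' @param a,b numeric vectors of per-image mean CSA, same length >= 3.
#' @param spearman also report Spearman's rank correlation.
#' @return A list with `r_squared` (Pearson squared), `slope`, `intercept`,
#'   `n`, and optionally `spearman_rho`.
#' @export
correlation_identity <- function(a, b, spearman = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("a and b must have the same length")
  if (length(a) < 3L) stop("at least 3 pairs are required")
  if (sd(a) == 0) stop("zero variance in reference series 'a'")
  fit <- lm(b ~ a)
  out <- list(r_squared = unname(cor(a, b)^2),
              slope = unname(coef(fit)[2]),
              intercept = unname(coef(fit)[1]),
              n = length(a))
  if (spearman) {
    out$spearman_rho <- unname(cor(a, b, method = "spearman"))
  }
  out
}

#' Manual-correction burden
#'
#' Quantifies how much manual correction the automation needed: the
#' percentage of false fibers deleted and of missed fibers hand-added,
#' relative to the corrected fiber count, and the percent change of mean
#' CSA caused by correction,
#' `(mean_auto - mean_corrected) / mean_corrected * 100`.
#'
#' @param auto the uncorrected automatic `segmentation_result`.
#' @param corrected the result after corrections; it must derive from
#'   `auto` via its own correction log.
#' @return A list with `n_deleted`, `n_added`, `n_corrected`,
#'   `percent_false_deleted`, `percent_missed_added`,
#'   `percent_csa_change`.
#' @export
correction_burden <- function(auto, corrected) {
  stopifnot(inherits(auto, "segmentation_result"),
            inherits(corrected, "segmentation_result"))
  log <- corrected$correction_log
  replayed <- replay_corrections(auto, log)
  same <- identical(
    lapply(replayed$rois, function(r) r[c("fiber_id", "polygon", "origin")]),
    lapply(corrected$rois, function(r) r[c("fiber_id", "polygon", "origin")]))
  if (!same) {
    stop("corrected result does not derive from 'auto' via its correction log")
  }
  n_deleted <- sum(vapply(log, function(e)
    if (e$op == "delete") length(e$ids) else 0L, numeric(1)))
  n_added <- sum(vapply(log, function(e)
    as.numeric(e$op == "add"), numeric(1)))
  n_corr <- length(corrected$rois)
  if (n_corr == 0L) stop("corrected result has no fibers")
  mean_auto <- if (length(auto$rois)) mean_csa(auto) else NA_real_
  mean_corr <- mean_csa(corrected)
  list(n_deleted = as.integer(n_deleted),
       n_added = as.integer(n_added),
       n_corrected = n_corr,
       percent_false_deleted = 100 * n_deleted / n_corr,
       percent_missed_added = 100 * n_added / n_corr,
       percent_csa_change = 100 * (mean_auto - mean_corr) / mean_corr)
}

#' Whole-section versus spatial-subset bias of mean CSA
#'
#' Partitions the fibers of a section by centroid location and reports each
#' subset's percent deviation of mean CSA from the whole-section mean,
#' `(mean_subset - mean_whole) / mean_whole * 100`. On muscles regenerating
#' centripetally the peripheral subsets overestimate and the central
#' subsets underestimate the whole-section mean, which is why CSA should be
#' measured on the entire section.
#'
#' @param result a `segmentation_result` (automatic or corrected).
#' @param partition one of `"whole"` (single subset, deviation exactly 0),
#'   `"halves_x"`, `"halves_y"`, `"quadrants"`, or `"center_annulus"`
#'   (central disc holding half the image area vs the periphery).
#' @return A list with `partition`, a data.frame `subsets` (`subset`,
#'   `n_fibers`, `mean_csa_um2`, `percent_deviation`, `empty` flag),
#'   `mean_whole_um2`, `min_abs_deviation`, `max_abs_deviation`.
#' @export
subset_bias <- function(result, partition = c("halves_x", "halves_y",
                                              "quadrants", "center_annulus",
                                              "whole")) {
  stopifnot(inherits(result, "segmentation_result"))
  partition <- match.arg(partition)
  if (!length(result$rois)) stop("empty result: no fibers to partition")
  W <- result$image_size[1]; H <- result$image_size[2]
  cx <- vapply(result$rois, function(r) r$centroid[1], numeric(1))
  cy <- vapply(result$rois, function(r) r$centroid[2], numeric(1))
  grp <- switch(partition,
    whole = rep("whole", length(cx)),
    halves_x = ifelse(cx < W / 2, "left", "right"),
    halves_y = ifelse(cy < H / 2, "top", "bottom"),
    quadrants = paste0(ifelse(cy < H / 2, "top_", "bottom_"),
                       ifelse(cx < W / 2, "left", "right")),
    center_annulus = {
      r_half <- sqrt(W * H / (2 * pi))   # disc holding half the image area
      ifelse((cx - W / 2)^2 + (cy - H / 2)^2 <= r_half^2,
             "center", "periphery")
    })
  levels_all <- switch(partition,
    whole = "whole",
    halves_x = c("left", "right"),
    halves_y = c("top", "bottom"),
    quadrants = c("top_left", "top_right", "bottom_left", "bottom_right"),
    center_annulus = c("center", "periphery"))
  a <- fiber_areas(result)
  mean_whole <- mean(a)
  rows <- lapply(levels_all, function(g) {
    sel <- grp == g
    if (!any(sel)) {
      data.frame(subset = g, n_fibers = 0L, mean_csa_um2 = NA_real_,
                 percent_deviation = NA_real_, empty = TRUE)
    } else {
      m <- mean(a[sel])
      data.frame(subset = g, n_fibers = sum(sel), mean_csa_um2 = m,
                 percent_deviation = 100 * (m - mean_whole) / mean_whole,
                 empty = FALSE)
    }
  })
  subsets <- do.call(rbind, rows)
  dev <- abs(subsets$percent_deviation[!subsets$empty])
  list(partition = partition, subsets = subsets,
       mean_whole_um2 = mean_whole,
       min_abs_deviation = if (length(dev)) min(dev) else NA_real_,
       max_abs_deviation = if (length(dev)) max(dev) else NA_real_)
}
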