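#' Parameters of the synthetic muscle-section generator
#'
#' Describes a calibrated laminin-like section: tightly packed polygonal
#' fibers (uninjured muscle), small round fibers with interstitial space
#' (regenerating / fibrotic muscle) or a centripetal size gradient (late
#' regeneration, which finishes at the periphery first). Fiber target areas
#' follow a lognormal law (optionally a mixture, for the bimodal fibrotic
#' regime); fiber territories are a power-diagram (Laguerre) tessellation of
#' the image around packed seeds, with per-fiber weights iteratively
#' adjusted so realized areas track the sampled law. The laminin ridge is
#' rendered as a bright band of half-width `boundary_width_px` straddling
#' each fiber's edge; `roundness` erodes each territory so fibers become
#' round and stop touching.
#'
#' @param n_seeds number of fibers to place.
#' @param area_median_um2 median(s) of the lognormal fiber-area law in um^2;
#'   a vector describes a mixture.
#' @param area_sdlog log-scale standard deviation(s) of the law.
#' @param mix_prop mixture weights (same length as `area_median_um2`).
#' @param roundness interstitial erosion radius in px: 0 keeps tightly
#'   packed polygons; larger values give round fibers separated by
#'   interstitium of width about `2 * roundness`.
#' @param boundary_width_px half-width of the rendered laminin ridge (the
#'   band spans about `2 * boundary_width_px` across the fiber interface).
#' @param boundary_intensity,interior_intensity gray levels of the ridge and
#'   of fiber interiors / deep interstitium; must fit the bit depth.
#' @param noise_sd standard deviation of additive Gaussian noise (gray
#'   levels; 0 = clean).
#' @param faint_fraction fraction of fibers whose boundary carries a
#'   contiguous faint arc (spatially coherent weak staining), in `[0, 1]`.
#' @param faint_arc_frac fraction of an affected fiber's boundary covered by
#'   its faint arc.
#' @param faint_intensity gray level of faint ridge arcs; by default the
#'   interior intensity, i.e. the staining locally drops to background
#'   level, which is what makes faintly stained areas fail detection at a
#'   threshold set by the well-stained part of the section.
#' @param gradient_mode `"none"` or `"centripetal"` (small fibers centrally,
#'   large peripherally, by rank-matching sampled areas to seed distance
#'   from the section center; the area law's marginal is unchanged).
#' @param width,height image size in px; `NULL` (default) sizes the canvas
#'   to fit the sampled areas.
#' @param pixel_size_um calibration in um/pixel.
#' @param bit_depth 8 or 16.
#' @param seed RNG seed; the generator is a pure function of its parameters.
#' @return An object of class `section_params`.
#' @seealso [section_preset()], [generate_section()]
#' @export
section_params <- function(n_seeds = 500L,
                           area_median_um2 = 1500,
                           area_sdlog = 0.4,
                           mix_prop = NULL,
                           roundness = 0,
                           boundary_width_px = 2L,
                           boundary_intensity = 230,
                           interior_intensity = 25,
                           noise_sd = 0,
                           faint_fraction = 0,
                           faint_arc_frac = 0.5,
                           faint_intensity = NULL,
                           gradient_mode = c("none", "centripetal"),
                           width = NULL, height = NULL,
                           pixel_size_um = 1,
                           bit_depth = 8L,
                           seed = 1L) {
  gradient_mode <- match.arg(gradient_mode)
  k <- length(area_median_um2)
  if (length(area_sdlog) == 1L) area_sdlog <- rep(area_sdlog, k)
  if (is.null(mix_prop)) mix_prop <- rep(1 / k, k)
  stopifnot(length(area_sdlog) == k, length(mix_prop) == k,
            all(area_median_um2 > 0), all(area_sdlog >= 0),
            all(mix_prop > 0), n_seeds >= 1, pixel_size_um > 0,
            boundary_width_px >= 1, roundness >= 0, noise_sd >= 0)
  mix_prop <- mix_prop / sum(mix_prop)
  maxval <- 2^as.integer(bit_depth) - 1
  if (is.null(faint_intensity)) faint_intensity <- interior_intensity
  for (v in c(boundary_intensity, interior_intensity, faint_intensity)) {
    if (v < 0 || v > maxval) {
      stop("intensities must lie within the bit depth [0, ", maxval, "]")
    }
  }
  if (faint_fraction < 0 || faint_fraction > 1) {
    stop("faint_fraction must lie in [0, 1]")
  }
  if (faint_arc_frac <= 0 || faint_arc_frac > 1) {
    stop("faint_arc_frac must lie in (0, 1]")
  }
  structure(list(n_seeds = as.integer(n_seeds),
                 area_median_um2 = area_median_um2,
                 area_sdlog = area_sdlog, mix_prop = mix_prop,
                 roundness = roundness,
                 boundary_width_px = as.integer(boundary_width_px),
                 boundary_intensity = boundary_intensity,
                 interior_intensity = interior_intensity,
                 noise_sd = noise_sd,
                 faint_fraction = faint_fraction,
                 faint_arc_frac = faint_arc_frac,
                 faint_intensity = faint_intensity,
                 gradient_mode = gradient_mode,
                 width = width, height = height,
                 pixel_size_um = pixel_size_um,
                 bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "section_params")
}

#' Synthetic section presets for the biological regimes
#'
#' * `uninjured`: large polygonal, tightly packed fibers, clean bright
#'   boundaries (noise-free; the substrate for detection-recovery checks).
#' * `regenerating_d8`: small round fibers of highly variable size with wide
#'   interstitial space.
#' * `regenerating_d28_gradient`: centripetal size gradient - regeneration
#'   is finished at the periphery (large fibers) while small regenerating
#'   fibers remain central.
#' * `fibrotic`: bimodal sizes with many very small fibers (< 500 um^2) and
#'   wide interstitium, the hardest regime.
#'
#' @param name preset name.
#' @param ... overrides passed to [section_params()] (e.g. `seed`,
#'   `n_seeds`, `noise_sd`).
#' @return A [section_params()].
#' @export
section_preset <- function(name = c("uninjured", "regenerating_d8",
                                    "regenerating_d28_gradient", "fibrotic"),
                           ...) {
  if (!is.character(name) || !name[1] %in%
      c("uninjured", "regenerating_d8", "regenerating_d28_gradient",
        "fibrotic")) {
    stop("unknown preset '", name[1], "'; available: uninjured, ",
         "regenerating_d8, regenerating_d28_gradient, fibrotic")
  }
  name <- match.arg(name)
  base <- switch(name,
    uninjured = list(n_seeds = 500L, area_median_um2 = 1800,
                     area_sdlog = 0.35, roundness = 0, noise_sd = 0),
    regenerating_d8 = list(n_seeds = 600L, area_median_um2 = 350,
                           area_sdlog = 0.5, roundness = 2, noise_sd = 4,
                           pixel_size_um = 0.65),
    regenerating_d28_gradient = list(n_seeds = 500L,
                                     area_median_um2 = 1200,
                                     area_sdlog = 0.35, roundness = 1,
                                     noise_sd = 4,
                                     gradient_mode = "centripetal"),
    fibrotic = list(n_seeds = 500L, area_median_um2 = c(250, 1400),
                    area_sdlog = c(0.45, 0.35), mix_prop = c(0.6, 0.4),
                    roundness = 3, noise_sd = 4))
  do.call(section_params, modifyList(base, list(...)))
}

#' Generate a synthetic laminin-stained section with ground truth
#'
#' Places fiber seeds by size-aware dart throwing, tessellates the canvas
#' with a power diagram whose weights are iterated toward the sampled area
#' law, erodes each territory by the roundness radius, and renders the
#' image: `interior_intensity` inside fibers and in deep interstitium, a
#' bright laminin ridge of half-width `boundary_width_px` straddling each
#' fiber edge, optional contiguous faint arcs, and Gaussian noise.
#' Deterministic for a fixed `seed`.
#'
#' @param params a [section_params()].
#' @return An object of class `ground_truth_section`: a list with `image`
#'   (a [muscle_image()]), `labels` (integer truth raster, consecutive
#'   labels in raster order, attribute `region_count`), `truth` (data.frame
#'   with `fiber_id`, `area_um2` - exact label pixel count times
#'   `pixel_size_um^2` -, `area_interior_um2` - the part rendered at
#'   interior intensity, i.e. inside the basal-lamina band -, `centroid_x`,
#'   `centroid_y`, `touches_edge`) and `params`.
#' @export
generate_section <- function(params) {
  stopifnot(inherits(params, "section_params"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(params$seed)
  ps <- params$pixel_size_um
  n <- params$n_seeds

  # fiber target areas in px^2 (lognormal mixture)
  comp <- sample.int(length(params$mix_prop), n, replace = TRUE,
                     prob = params$mix_prop)
  A <- rlnorm(n, log(params$area_median_um2[comp]),
              params$area_sdlog[comp]) / ps^2
  r <- sqrt(A / pi)

  # canvas: sized to the sampled areas unless given
  if (is.null(params$width)) {
    side <- ceiling(sqrt(sum(A)))
    W <- side; H <- side
  } else {
    W <- as.integer(params$width)
    H <- as.integer(if (is.null(params$height)) params$width else
      params$height)
    if (sum(A) > 1.15 * W * H) {
      stop("fibers cannot fit: n_seeds too high for the size law ",
           "on a ", W, " x ", H, " canvas")
    }
  }

  # dart throwing, largest first. In centripetal-gradient mode a seed's
  # position must additionally match its size: the distance quantile of the
  # candidate position (empirical, over the canvas) has to agree with the
  # seed's area quantile, so small fibers settle centrally and large ones
  # peripherally while the area law's marginal is untouched.
  grad <- params$gradient_mode == "centripetal"
  if (grad) {
    qx <- runif(20000, 0, W); qy <- runif(20000, 0, H)
    Fd <- stats::ecdf(sqrt((qx - W / 2)^2 + (qy - H / 2)^2))
    area_q <- (rank(A, ties.method = "first") - 0.5) / n
  }
  o <- order(-r); A <- A[o]; r <- r[o]
  if (grad) area_q <- area_q[o]
  sx <- numeric(n); sy <- numeric(n); placed <- 0L
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(4000L)) {
      px <- runif(1, 0.3 * r[i], W - 0.3 * r[i])
      py <- runif(1, 0.3 * r[i], H - 0.3 * r[i])
      if (grad) {
        dq <- Fd(sqrt((px - W / 2)^2 + (py - H / 2)^2))
        tol <- 0.1 + 0.3 * (try / 4000)
        if (abs(dq - area_q[i]) > tol) next
      }
      if (placed == 0L) { ok <- TRUE; break }
      d2 <- (sx[1:placed] - px)^2 + (sy[1:placed] - py)^2
      if (all(d2 >= (0.68 * (r[1:placed] + r[i]))^2)) { ok <- TRUE; break }
    }
    if (!ok) stop("fibers cannot fit: n_seeds too high for the size law")
    placed <- placed + 1L
    sx[i] <- px; sy[i] <- py
  }

  # power-diagram assignment with area-matching weight iterations
  assign_cells <- function(w) {
    best <- matrix(Inf, H, W)
    lab <- matrix(0L, H, W)
    for (i in seq_len(n)) {
      R <- 3.2 * r[i] + 12
      c1 <- max(1L, floor(sx[i] - R)); c2 <- min(W, ceiling(sx[i] + R))
      r1 <- max(1L, floor(sy[i] - R)); r2 <- min(H, ceiling(sy[i] + R))
      if (c2 < c1 || r2 < r1) next
      xs <- (c1:c2) - 0.5; ys <- (r1:r2) - 0.5
      D <- outer((ys - sy[i])^2, (xs - sx[i])^2, "+") - w[i]
      sub <- best[r1:r2, c1:c2]
      m <- D < sub
      sub[m] <- D[m]
      best[r1:r2, c1:c2] <- sub
      lsub <- lab[r1:r2, c1:c2]
      lsub[m] <- i
      lab[r1:r2, c1:c2] <- lsub
    }
    lab
  }
  w <- r^2
  lab <- assign_cells(w)
  for (it in 1:4) {
    cur <- tabulate(lab, n)
    w <- w + (A - cur) / pi * 0.9
    lab <- assign_cells(w)
  }

  # distance of each pixel to the inter-cell interface
  h <- H; wd <- W
  diff_right <- lab[, -wd] != lab[, -1L]
  diff_down <- lab[-h, ] != lab[-1L, ]
  B <- matrix(FALSE, h, wd)
  B[, -wd] <- B[, -wd] | diff_right
  B[, -1L] <- B[, -1L] | diff_right
  B[-h, ] <- B[-h, ] | diff_down
  B[-1L, ] <- B[-1L, ] | diff_down
  D <- EBImage::distmap(matrix(as.numeric(!B), h, wd))
  if (inherits(D, "Image")) D <- EBImage::imageData(D)

  e <- params$roundness
  bw <- params$boundary_width_px
  truth_lab <- lab
  if (e > 0) truth_lab[D < e] <- 0L

  # relabel consecutively in raster-scan order of first pixel
  fg <- which(truth_lab > 0L)
  rr <- (fg - 1L) %% h + 1L
  cc <- (fg - 1L) %/% h + 1L
  raster_pos <- (rr - 1L) * wd + cc
  first <- tapply(raster_pos, truth_lab[fg], min)
  old_ids <- as.integer(names(first))
  remap <- integer(n)
  remap[old_ids[order(first)]] <- seq_along(old_ids)
  truth_lab[fg] <- remap[truth_lab[fg]]
  n_fib <- length(old_ids)
  attr(truth_lab, "region_count") <- n_fib

  # render
  ridge <- abs(D - e) < bw
  img <- matrix(params$interior_intensity, h, wd)
  img[ridge] <- params$boundary_intensity

  # faint arcs: contiguous sectors of weak ridge staining
  lab_new <- truth_lab
  cnt <- tabulate(lab_new[fg], n_fib)
  cenx <- vapply(split(cc - 0.5, lab_new[fg]), mean, numeric(1))
  ceny <- vapply(split(rr - 0.5, lab_new[fg]), mean, numeric(1))
  n_faint <- round(params$faint_fraction * n_fib)
  if (n_faint > 0) {
    faint_ids <- sample.int(n_fib, n_faint)
    maxr2 <- rep(0, n_fib)
    dx <- (cc - 0.5) - cenx[lab_new[fg]]
    dy <- (rr - 0.5) - ceny[lab_new[fg]]
    d2 <- dx^2 + dy^2
    mx <- tapply(d2, lab_new[fg], max)
    maxr2[as.integer(names(mx))] <- mx
    half_arc <- pi * params$faint_arc_frac
    for (fid in faint_ids) {
      R <- sqrt(maxr2[fid]) + bw + 2
      cx <- cenx[fid]; cy <- ceny[fid]
      theta0 <- runif(1, 0, 2 * pi)
      c1 <- max(1L, floor(cx - R)); c2 <- min(wd, ceiling(cx + R))
      r1 <- max(1L, floor(cy - R)); r2 <- min(h, ceiling(cy + R))
      xs <- (c1:c2) - 0.5; ys <- (r1:r2) - 0.5
      ddx <- matrix(xs - cx, r2 - r1 + 1L, c2 - c1 + 1L, byrow = TRUE)
      ddy <- matrix(ys - cy, r2 - r1 + 1L, c2 - c1 + 1L)
      within <- ddx^2 + ddy^2 <= R^2
      ang <- atan2(ddy, ddx) - theta0
      ang <- atan2(sin(ang), cos(ang))        # wrap to (-pi, pi]
      sect <- within & abs(ang) <= half_arc
      sub_img <- img[r1:r2, c1:c2]
      sub_ridge <- ridge[r1:r2, c1:c2]
      sel <- sect & sub_ridge
      sub_img[sel] <- params$faint_intensity
      img[r1:r2, c1:c2] <- sub_img
    }
  }

  maxval <- 2^params$bit_depth - 1
  if (params$noise_sd > 0) {
    img <- img + rnorm(length(img), 0, params$noise_sd)
  }
  img <- matrix(as.integer(pmin(pmax(round(img), 0), maxval)), h, wd)

  interior_cnt <- rep(0L, n_fib)
  inner <- lab_new > 0L & D >= e + bw
  tin <- tabulate(lab_new[inner], n_fib)
  interior_cnt[seq_along(tin)] <- tin

  truth <- data.frame(
    fiber_id = seq_len(n_fib),
    area_um2 = cnt * ps^2,
    area_interior_um2 = interior_cnt * ps^2,
    centroid_x = as.numeric(cenx),
    centroid_y = as.numeric(ceny),
    touches_edge = vapply(split(rr == 1L | rr == h | cc == 1L | cc == wd,
                                lab_new[fg]), any, logical(1))[
                                  as.character(seq_len(n_fib))])
  rownames(truth) <- NULL

  image <- muscle_image(img, bit_depth = params$bit_depth,
                        pixel_size_um = ps,
                        name = sprintf("synthetic_seed%d", params$seed))
  structure(list(image = image, labels = truth_lab, truth = truth,
                 params = params),
            class = "ground_truth_section")
}

#' @export
print.ground_truth_section <- function(x, ...) {
  cat(sprintf("<ground_truth_section> %d fibers, %d x %d px @ %.4g um/px\n",
              nrow(x$truth), ncol(x$labels), nrow(x$labels),
              x$image$pixel_size_um))
  cat(sprintf("  truth CSA: median %.0f um^2, mean %.0f um^2\n",
              median(x$truth$area_um2), mean(x$truth$area_um2)))
  invisible(x)
}
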