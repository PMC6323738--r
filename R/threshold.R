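#' Huang minimum-fuzziness threshold
#'
#' Computes the automatic gray-level threshold of Huang and Wang: for each
#' candidate threshold `t` the pixels are partitioned into the classes
#' `<= t` and `> t` with class mean gray levels `mu0(t)` and `mu1(t)`; every
#' pixel of gray `g` receives a fuzzy membership to its class,
#' `u = 1 / (1 + |g - mu_class| / C)` with `C = g_max - g_min`, and the
#' image fuzziness is the histogram-weighted sum of the Shannon entropy
#' `S(u) = -u log(u) - (1-u) log(1-u)`. The returned threshold minimizes the
#' fuzziness; ties are broken toward the smallest gray level.
#'
#' The histogram uses one bin per gray level for 8-bit images and 256 equal
#' bins spanning `[min, max]` for 16-bit images (mirroring the usual
#' 8-bit-scaled behavior); in the 16-bit case the returned value is the
#' largest gray level falling in the minimizing bin, so that thresholding at
#' the returned value reproduces the bin partition.
#'
#' @param image a [muscle_image()].
#' @param n_bins number of histogram bins for 16-bit input (default 256;
#'   ignored for 8-bit).
#' @return Integer threshold `t` on the image's gray scale; pixels `<= t`
#'   form the dark class.
#' @examples
#' px <- matrix(c(rep(10L, 50), rep(200L, 50)), 10, 10)
#' huang_threshold(muscle_image(px, pixel_size_um = 1))
#' @export
huang_threshold <- function(image, n_bins = 256L) {
  stopifnot(inherits(image, "muscle_image"))
  g_min <- min(image$pixels)
  g_max <- max(image$pixels)
  if (g_min == g_max) {
    stop("degenerate image: single gray value, no threshold exists")
  }
  if (image$bit_depth == 8L) {
    counts <- tabulate(as.vector(image$pixels) + 1L, nbins = 256L)
    values <- 0:255
    t_star <- .huang_argmin(counts, values)
    return(as.integer(t_star))
  }
  # 16-bit: equal-width bins over [min, max]
  n_bins <- as.integer(n_bins)
  binw <- (g_max - g_min + 1) / n_bins
  idx <- floor((as.vector(image$pixels) - g_min) / binw)  # 0-based bin index
  counts <- tabulate(as.integer(idx) + 1L, nbins = n_bins)
  values <- g_min + (seq_len(n_bins) - 0.5) * binw        # bin centers
  b_star <- .huang_argmin(counts, values, bin_index = TRUE)
  # largest integer gray level in bin b_star
  thr <- g_min + ceiling((b_star + 1) * binw) - 1
  as.integer(min(thr, g_max))
}

# exhaustive minimization of the Huang-Wang fuzziness over histogram bins.
# counts: per-bin pixel counts; values: representative gray per bin.
# Returns the gray value of the minimizing bin, or its 0-based index when
# bin_index = TRUE.
.huang_argmin <- function(counts, values, bin_index = FALSE) {
  nz <- which(counts > 0L)
  first <- nz[1]; last <- nz[length(nz)]
  C <- values[last] - values[first]
  cum_n <- cumsum(counts)
  cum_s <- cumsum(counts * values)
  total_n <- cum_n[length(counts)]
  total_s <- cum_s[length(counts)]
  cand <- first:(last - 1L)         # both classes non-empty
  best_f <- Inf; best_t <- NA_integer_
  for (t in cand) {
    n0 <- cum_n[t]; n1 <- total_n - n0
    mu0 <- cum_s[t] / n0
    mu1 <- (total_s - cum_s[t]) / n1
    lo <- seq_len(t); hi <- (t + 1L):length(counts)
    u <- c(1 / (1 + abs(values[lo] - mu0) / C),
           1 / (1 + abs(values[hi] - mu1) / C))
    f <- sum(c(counts[lo], counts[hi]) * .shannon_fuzz(u))
    if (f < best_f - 1e-12) { best_f <- f; best_t <- t }
  }
  if (bin_index) best_t - 1L else values[best_t]
}

# entropy of a fuzzy membership, with 0 log 0 := 0
.shannon_fuzz <- function(u) {
  s <- numeric(length(u))
  ok <- u > 0 & u < 1
  s[ok] <- -u[ok] * log(u[ok]) - (1 - u[ok]) * log(1 - u[ok])
  s
}

#' Binarize an image into fiber-interior particles
#'
#' Applies a threshold to produce a binary mask. With
#' `invert_after_threshold` set (the default) pixels at or below the
#' threshold - the dark fiber interiors enclosed by the bright laminin
#' network - become foreground, so that particles correspond to myofibers;
#' otherwise pixels above the threshold (the laminin staining itself) are
#' the foreground.
#'
#' @param image a [muscle_image()].
#' @param threshold integer gray level in `[0, 2^bit_depth - 1]`.
#' @param config a [pipeline_config()]; only `invert_after_threshold` is
#'   consulted.
#' @return An integer 0/1 matrix of the same shape as the image.
#' @export
binarize_fibers <- function(image, threshold, config = pipeline_config()) {
  stopifnot(inherits(image, "muscle_image"))
  maxval <- 2^image$bit_depth - 1
  if (threshold < 0 || threshold > maxval) {
    stop(sprintf("threshold must lie in [0, %d]", maxval))
  }
  m <- if (isTRUE(config$invert_after_threshold)) {
    image$pixels <= threshold
  } else {
    image$pixels > threshold
  }
  mask <- matrix(as.integer(m), nrow(image$pixels), ncol(image$pixels))
  mask
}
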