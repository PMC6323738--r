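#' Binary opening with a square structuring element
#'
#' Erosion followed by dilation with a square element of side
#' `2 * radius_px + 1`, repeated `iterations` times. Opening removes
#' protrusions and specks narrower than the element and is used to adjust
#' the myofiber contours after binarization. It is anti-extensive (never
#' adds foreground) and idempotent.
#'
#' @param mask integer/logical 0-1 matrix.
#' @param radius_px element radius (>= 1).
#' @param iterations number of opening passes; 0 returns the input.
#' @return An integer 0/1 matrix of the same shape.
#' @export
morphological_open <- function(mask, radius_px = 1L, iterations = 1L) {
  mask <- .as_mask(mask)
  if (radius_px < 1) stop("radius_px must be >= 1")
  if (iterations < 0) stop("iterations must be >= 0")
  if (iterations == 0L) return(mask)
  kern <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "box")
  out <- mask
  for (i in seq_len(iterations)) {
    out <- EBImage::dilate(EBImage::erode(out, kern), kern)
  }
  .as_mask(out)
}

#' Fill enclosed holes in a binary mask
#'
#' Every background component that is not 4-connected to the image border
#' becomes foreground; border-connected background (including cavities open
#' to the edge) is preserved. Applied after the opening so that each fiber
#' interior is a solid particle.
#'
#' @param mask integer/logical 0-1 matrix.
#' @return An integer 0/1 matrix of the same shape.
#' @export
fill_holes <- function(mask) {
  mask <- .as_mask(mask)
  # label the background 4-connectedly; components absent from the border
  # are enclosed holes
  bg <- 1L - mask
  lab <- EBImage::bwlabel(bg)          # 4-connectivity
  if (inherits(lab, "Image")) lab <- EBImage::imageData(lab)
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  border <- border[border > 0]
  hole <- bg == 1L & !(lab %in% border)
  out <- mask
  out[hole] <- 1L
  .as_mask(out)
}

#' Label connected foreground components
#'
#' Labels the 8-connected components of the foreground, numbered
#' `1..region_count` in raster-scan order (row by row, left to right) of
#' each component's first pixel. Background is 0.
#'
#' @param mask integer/logical 0-1 matrix.
#' @return An integer matrix of labels with attribute `region_count`.
#' @export
label_connected <- function(mask) {
  mask <- .as_mask(mask)
  lab <- EBImage::bwlabel(mask)        # 4-connected pass
  if (inherits(lab, "Image")) lab <- EBImage::imageData(lab)
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n > 0L) {
    # merge labels that touch diagonally to obtain 8-connectivity
    h <- nrow(lab); w <- ncol(lab)
    a1 <- lab[-h, -w]; b1 <- lab[-1L, -1L]        # down-right neighbors
    a2 <- lab[-h, -1L]; b2 <- lab[-1L, -w]        # down-left neighbors
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]),
                          cbind(a2[sel2], b2[sel2])))
    if (nrow(pairs)) {
      parent <- seq_len(n)
      find <- function(x) {
        while (parent[x] != x) {
          parent[x] <<- parent[parent[x]]
          x <- parent[x]
        }
        x
      }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(n), find, integer(1))
      lab[] <- c(0L, root)[lab + 1L]
    }
    # renumber consecutively in raster-scan order of first pixel
    h <- nrow(lab); w <- ncol(lab)
    fg <- which(lab > 0L)
    if (length(fg)) {
      r <- (fg - 1L) %% h + 1L
      c <- (fg - 1L) %/% h + 1L
      raster <- (r - 1L) * w + c                  # row-major position
      first <- tapply(raster, lab[fg], min)
      old <- as.integer(names(first))
      new <- integer(max(old))
      new[old[order(first)]] <- seq_along(old)
      lab[fg] <- new[lab[fg]]
    }
  }
  attr(lab, "region_count") <- max(lab)
  lab
}

# coerce to a plain integer 0/1 matrix, preserving shape
.as_mask <- function(mask) {
  if (inherits(mask, "Image")) mask <- EBImage::imageData(mask)
  if (!is.matrix(mask)) stop("mask must be a matrix")
  out <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  out
}
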