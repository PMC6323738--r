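# Boundary geometry: crack-edge contour tracing, polygon simplification,
# shoelace areas, point-in-polygon rasterization.
#
# Contours are traced along the "cracks" between pixels, so vertices are
# integer lattice corners: pixel (row r, col c) covers [c-1, c] x [r-1, r].
# The shoelace area of a traced contour therefore equals the pixel count of
# a hole-free region exactly, and a pixel belongs to the region iff its
# center (c - 0.5, r - 0.5) lies inside the polygon.

# Trace the outer boundary of the region labelled `value` in the integer
# matrix `lab`. Works for 8-connected regions: at a diagonal pinch the trace
# passes through the shared corner, keeping a single closed loop. Returns an
# n x 2 matrix of (x, y) lattice corners.
.trace_boundary <- function(lab, value) {
  h <- nrow(lab); w <- ncol(lab)
  # pad with background so neighbor lookups need no bounds checks
  M <- matrix(FALSE, h + 2L, w + 2L)
  M[2:(h + 1L), 2:(w + 1L)] <- lab == value
  # first region pixel in raster-scan (row-major) order
  idx <- which(M, arr.ind = TRUE)
  if (!nrow(idx)) stop("no pixels with label ", value)
  o <- order(idx[, 1L], idx[, 2L])
  r0 <- idx[o[1L], 1L]; c0 <- idx[o[1L], 2L]    # padded coordinates
  # corner (x, y) in unpadded corner coordinates; start at the pixel's
  # top-left corner heading east, region on the right
  x <- c0 - 2L; y <- r0 - 2L
  dir <- 1L                                     # 1 E, 2 S, 3 W, 4 N
  dx <- c(1L, 0L, -1L, 0L); dy <- c(0L, 1L, 0L, -1L)
  # around corner (x, y): NE = pixel (y, x+1), SE = (y+1, x+1),
  # SW = (y+1, x), NW = (y, x) in unpadded 1-based pixel indices.
  # front-left / front-right pixel per direction:
  fl_pick <- c(1L, 2L, 3L, 4L)                  # E->NE, S->SE, W->SW, N->NW
  fr_pick <- c(2L, 3L, 4L, 1L)
  cap <- 256L
  X <- integer(cap); Y <- integer(cap); n <- 0L
  sx <- x; sy <- y
  limit <- 4L * (h + 1L) * (w + 1L)
  repeat {
    # the four pixels around the corner, as padded-matrix logicals
    ne <- M[y + 1L, x + 2L]; se <- M[y + 2L, x + 2L]
    sw <- M[y + 2L, x + 1L]; nw <- M[y + 1L, x + 1L]
    q <- c(ne, se, sw, nw)
    if (q[fl_pick[dir]]) {
      dir <- (dir - 2L) %% 4L + 1L              # turn left
    } else if (!q[fr_pick[dir]]) {
      dir <- dir %% 4L + 1L                     # turn right
    }
    n <- n + 1L
    if (n > cap) {
      cap <- cap * 2L
      length(X) <- cap; length(Y) <- cap
    }
    X[n] <- x; Y[n] <- y
    x <- x + dx[dir]; y <- y + dy[dir]
    if (x == sx && y == sy) break
    if (n > limit) stop("boundary tracing failed to close")
  }
  cbind(x = X[seq_len(n)], y = Y[seq_len(n)])
}

# Douglas-Peucker simplification of a closed polygon. The closed curve is
# split at vertex 1 and its farthest vertex, and each open chain is
# simplified to the given tolerance (in pixels).
.simplify_polygon <- function(p, tol = 1.0) {
  n <- nrow(p)
  if (n <= 4L) return(p)
  d1 <- (p[, 1L] - p[1L, 1L])^2 + (p[, 2L] - p[1L, 2L])^2
  k <- which.max(d1)
  keep <- logical(n); keep[c(1L, k)] <- TRUE
  getp <- function(i) p[(i - 1L) %% n + 1L, ]
  stack <- list(c(1L, k), c(k, n + 1L))         # index n+1 wraps to 1
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    if (j - i < 2L) next
    ids <- (i + 1L):(j - 1L)
    pts <- p[(ids - 1L) %% n + 1L, , drop = FALSE]
    a <- getp(i); b <- getp(j)
    v <- b - a; L2 <- sum(v * v)
    if (L2 == 0) {
      dd <- sqrt((pts[, 1L] - a[1L])^2 + (pts[, 2L] - a[2L])^2)
    } else {
      tt <- pmin(1, pmax(0, ((pts[, 1L] - a[1L]) * v[1L] +
                             (pts[, 2L] - a[2L]) * v[2L]) / L2))
      dd <- sqrt((pts[, 1L] - a[1L] - tt * v[1L])^2 +
                 (pts[, 2L] - a[2L] - tt * v[2L])^2)
    }
    m <- which.max(dd)
    if (dd[m] > tol) {
      mid <- ids[m]
      keep[(mid - 1L) %% n + 1L] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, mid)
      stack[[length(stack) + 1L]] <- c(mid, j)
    }
  }
  p[keep, , drop = FALSE]
}

# signed shoelace area (positive for counter-clockwise in y-up coordinates)
.shoelace_signed <- function(p) {
  n <- nrow(p); j <- c(2:n, 1L)
  sum(p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L]) / 2
}

# perimeter of a closed polygon
.polygon_perimeter <- function(p) {
  n <- nrow(p); j <- c(2:n, 1L)
  sum(sqrt((p[j, 1L] - p[, 1L])^2 + (p[j, 2L] - p[, 2L])^2))
}

# area-weighted centroid of a simple polygon (falls back to the vertex mean
# for degenerate input)
.polygon_centroid <- function(p) {
  n <- nrow(p); j <- c(2:n, 1L)
  cr <- p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(p[, 1L]), mean(p[, 2L])))
  cx <- sum((p[, 1L] + p[j, 1L]) * cr) / (6 * a)
  cy <- sum((p[, 2L] + p[j, 2L]) * cr) / (6 * a)
  c(cx, cy)
}

#' Area of a simple polygon
#'
#' Absolute shoelace area in squared pixel units, independent of vertex
#' orientation. Used for the area of hand-drawn fiber polygons; multiply by
#' `pixel_size_um^2` for a calibrated area.
#'
#' @param polygon an `n x 2` matrix (or data.frame) of `(x, y)` vertices,
#'   `n >= 3`, describing a simple (non-self-intersecting) polygon.
#' @return Area in px^2.
#' @examples
#' polygon_area(rbind(c(0, 0), c(4, 0), c(0, 3)))  # 6
#' @export
polygon_area <- function(polygon) {
  p <- .check_polygon(polygon)
  abs(.shoelace_signed(p))
}

# validate a polygon: matrix form, >= 3 distinct vertices, non-degenerate,
# simple (no proper self-intersections)
.check_polygon <- function(polygon) {
  p <- as.matrix(polygon)
  if (!is.numeric(p) || ncol(p) != 2L) {
    stop("polygon must be an n x 2 numeric matrix of (x, y) vertices")
  }
  # drop an explicitly repeated closing vertex
  n <- nrow(p)
  if (n >= 2L && all(p[1L, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  if (nrow(p) < 3L) stop("degenerate polygon: fewer than 3 vertices")
  if (anyNA(p)) stop("polygon contains missing coordinates")
  if (abs(.shoelace_signed(p)) < 1e-12) {
    stop("degenerate polygon: zero area")
  }
  if (.self_intersects(p)) {
    stop("self-intersecting polygon is not a valid fiber outline")
  }
  p
}

# proper segment-crossing test over all non-adjacent edge pairs; O(n^2) but
# hand-drawn outlines are short
.self_intersects <- function(p) {
  n <- nrow(p)
  a <- p; b <- p[c(2:n, 1L), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]              # skip edges sharing vertex 1
    for (j in js) {
      d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
      d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
      d3 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
      d4 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# even-odd point-in-polygon test, vectorized over query points
.points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  xj <- poly[n, 1L]; yj <- poly[n, 2L]
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    hit <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, hit)
    xj <- xi; yj <- yi
  }
  inside
}

# rasterize a polygon to pixel (row, col) indices within an h x w frame:
# a pixel is inside iff its center lies inside the polygon. Exact for
# crack-traced contours since centers are at half-integers.
.rasterize_polygon <- function(poly, h, w) {
  c1 <- max(1L, floor(min(poly[, 1L])) + 1L)
  c2 <- min(w, ceiling(max(poly[, 1L])))
  r1 <- max(1L, floor(min(poly[, 2L])) + 1L)
  r2 <- min(h, ceiling(max(poly[, 2L])))
  if (c2 < c1 || r2 < r1) return(cbind(row = integer(0), col = integer(0)))
  cc <- rep(c1:c2, each = r2 - r1 + 1L)
  rr <- rep(r1:r2, times = c2 - c1 + 1L)
  keep <- .points_in_polygon(cc - 0.5, rr - 0.5, poly)
  cbind(row = rr[keep], col = cc[keep])
}
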