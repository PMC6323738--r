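# Independent oracles and fixture builders used across the suite. Every
# oracle is written as plainly as possible (loops, enumeration) and shares
# no code path with the implementation it checks.

# ---- Huang threshold: exhaustive fuzziness minimizer ----------------------

# counts: per-gray-level histogram; values: gray level of each bin.
# Scans every candidate threshold and recomputes the fuzziness from the
# definition, scalar loops throughout.
oracle_huang <- function(counts, values) {
  nz <- which(counts > 0)
  C <- values[max(nz)] - values[min(nz)]
  best_f <- Inf
  best_v <- NA
  for (t in min(nz):(max(nz) - 1)) {
    mu0_num <- 0; mu0_den <- 0; mu1_num <- 0; mu1_den <- 0
    for (i in seq_along(counts)) {
      if (i <= t) {
        mu0_num <- mu0_num + counts[i] * values[i]
        mu0_den <- mu0_den + counts[i]
      } else {
        mu1_num <- mu1_num + counts[i] * values[i]
        mu1_den <- mu1_den + counts[i]
      }
    }
    mu0 <- mu0_num / mu0_den
    mu1 <- mu1_num / mu1_den
    f <- 0
    for (i in seq_along(counts)) {
      if (counts[i] == 0) next
      mu <- if (i <= t) mu0 else mu1
      u <- 1 / (1 + abs(values[i] - mu) / C)
      s <- if (u <= 0 || u >= 1) 0 else -u * log(u) - (1 - u) * log(1 - u)
      f <- f + counts[i] * s
    }
    if (f < best_f - 1e-12) {
      best_f <- f
      best_v <- values[t]
    }
  }
  best_v
}

# build an 8-bit muscle_image realizing a given histogram
image_from_histogram <- function(counts, values) {
  px <- rep(values, counts)
  n <- length(px)
  h <- floor(sqrt(n))
  w <- ceiling(n / h)
  px <- c(px, rep(values[1], h * w - n))
  muscle_image(matrix(as.integer(px), h, w), bit_depth = 8L,
               pixel_size_um = 1)
}

# ---- connected components: BFS flood fill ---------------------------------

# 8-connectivity, labels assigned in raster-scan (row-major) order
oracle_flood_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (mask[r, c] == 0 || lab[r, c] != 0) next
    nxt <- nxt + 1L
    queue <- list(c(r, c))
    lab[r, c] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr < 1 || rr > h || cc < 1 || cc > w) next
        if (mask[rr, cc] == 1 && lab[rr, cc] == 0) {
          lab[rr, cc] <- nxt
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  attr(lab, "region_count") <- nxt
  lab
}

# ---- matching: brute-force assignment -------------------------------------

# iou: matrix [pred x truth]. Enumerates every one-to-one assignment of
# predictions to truth over pairs with iou >= iou_min, maximizing matched
# count then total IoU. Feasible for <= 8 x 8.
oracle_match <- function(iou, iou_min) {
  np <- nrow(iou); nt <- ncol(iou)
  best <- list(count = -1, total = -Inf)
  recurse <- function(i, used_t, count, total) {
    if (i > np) {
      if (count > best$count ||
          (count == best$count && total > best$total + 1e-12)) {
        best <<- list(count = count, total = total)
      }
      return(invisible())
    }
    recurse(i + 1, used_t, count, total)          # leave prediction i out
    for (t in seq_len(nt)) {
      if (!used_t[t] && iou[i, t] >= iou_min) {
        used_t[t] <- TRUE
        recurse(i + 1, used_t, count + 1, total + iou[i, t])
        used_t[t] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, nt), 0, 0)
  best
}

# ---- geometry helpers ------------------------------------------------------

# independent even-odd membership test (crossing count, scalar)
oracle_point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  crossings <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    x1 <- poly[i, 1]; y1 <- poly[i, 2]
    x2 <- poly[j, 1]; y2 <- poly[j, 2]
    if ((y1 > y) != (y2 > y)) {
      xint <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
      if (x < xint) crossings <- crossings + 1
    }
  }
  crossings %% 2 == 1
}

# star-shaped simple polygon around a center; jittered evenly spread angles
# keep every angular gap below pi, which guarantees simplicity
random_simple_polygon <- function(n_vertices = 8, center = c(20, 20),
                                  radius = 10) {
  ang <- (seq_len(n_vertices) - runif(n_vertices)) * 2 * pi / n_vertices
  rad <- runif(n_vertices, 0.35 * radius, radius)
  cbind(x = center[1] + rad * cos(ang), y = center[2] + rad * sin(ang))
}

random_mask <- function(h = 30, w = 30, p = 0.5) {
  matrix(as.integer(runif(h * w) < p), h, w)
}

# rasterized disc of given radius (pixel centers within radius of center)
disc_mask <- function(radius, pad = 3) {
  n <- 2 * radius + 2 * pad
  ctr <- n / 2
  m <- matrix(0L, n, n)
  for (r in seq_len(n)) for (c in seq_len(n)) {
    if ((r - 0.5 - ctr)^2 + (c - 0.5 - ctr)^2 <= radius^2) m[r, c] <- 1L
  }
  m
}

# ---- ImageJ ROI record built byte-by-byte ---------------------------------

# polygon record per the published layout: magic "Iout", version, type at
# byte 6, bounding box int16 at 8..15, point count at 16, coordinates
# (int16, relative to left/top) from byte 64.
imagej_roi_record <- function(xs, ys) {
  stopifnot(length(xs) == length(ys))
  be16 <- function(v) as.raw(c((v %/% 256) %% 256, v %% 256))
  top <- min(ys); left <- min(xs); bottom <- max(ys); right <- max(xs)
  hdr <- c(charToRaw("Iout"),
           be16(228),                  # version
           as.raw(c(0, 0)),            # type 0 = polygon, unused byte
           be16(top), be16(left), be16(bottom), be16(right),
           be16(length(xs)))
  hdr <- c(hdr, raw(64 - length(hdr)))
  coords <- c(unlist(lapply(xs - left, be16)),
              unlist(lapply(ys - top, be16)))
  c(hdr, coords)
}

# build a small segmentation result from scratch (no pipeline run)
make_result <- function(n_rois = 3, image_size = c(64, 64),
                        pixel_size_um = 1, origin = "automatic") {
  rois <- lapply(seq_len(n_rois), function(i) {
    p <- random_simple_polygon(n_vertices = sample(4:9, 1),
                               center = runif(2, 15, 45), radius = 8)
    fibercsa:::.fiber_roi(
      fiber_id = i, polygon = p, origin = origin,
      area_um2 = polygon_area(p) * pixel_size_um^2,
      perimeter_um = fibercsa:::.polygon_perimeter(p) * pixel_size_um,
      circularity = if (origin == "automatic") 0.8 else NA_real_,
      centroid = fibercsa:::.polygon_centroid(p))
  })
  fibercsa:::.segmentation_result(
    rois = rois, image_name = "fixture", image_size = image_size,
    pixel_size_um = pixel_size_um, config = pipeline_config(),
    threshold_used = 42L)
}

# build a result whose ROIs are the traced ground-truth regions themselves
result_from_truth <- function(sec) {
  lab <- sec$labels
  ps <- sec$image$pixel_size_um
  n <- attr(lab, "region_count")
  rois <- lapply(seq_len(n), function(L) {
    m <- region_morphometry(lab, L, pixel_size_um = ps)
    fibercsa:::.fiber_roi(
      fiber_id = L, polygon = m$polygon, origin = "automatic",
      area_um2 = m$area_um2, perimeter_um = m$perimeter_um,
      circularity = m$circularity, centroid = m$centroid,
      touches_edge = m$touches_edge)
  })
  fibercsa:::.segmentation_result(
    rois = rois, image_name = sec$image$name,
    image_size = c(ncol(lab), nrow(lab)), pixel_size_um = ps,
    config = pipeline_config(size_min_um2 = 0, circularity_min = 0,
                             exclude_edges = FALSE),
    threshold_used = NA_integer_)
}

# ---- shared expensive fixtures (computed once per test run) ---------------

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

uninjured_section <- function() {
  cached("uninjured500", generate_section(section_preset("uninjured",
                                                         seed = 11)))
}

uninjured_result <- function() {
  cached("uninjured500_result",
         run_pipeline(uninjured_section()$image, pipeline_preset("D0")))
}

small_section <- function() {
  cached("small60", generate_section(section_preset("uninjured",
                                                    n_seeds = 60,
                                                    seed = 3)))
}

small_result <- function() {
  cached("small60_result",
         run_pipeline(small_section()$image, pipeline_preset("D0")))
}
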