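# whole-section tiling and seam-aware merging

test_that("splitting follows the documented layout", {
  img <- muscle_image(matrix(seq_len(6000) %% 251, 60, 100),
                      pixel_size_um = 1)
  one <- split_into_tiles(img, 1, 0)
  expect_length(one, 1)
  expect_identical(one[[1]]$offset, c(0L, 0L))
  expect_identical(one[[1]]$image$pixels, img$pixels)

  two <- split_into_tiles(img, 2, 0)   # 100 wide x 60 high: split along x
  expect_length(two, 2)
  expect_identical(dim(two[[1]]$image$pixels), c(60L, 50L))
  expect_identical(dim(two[[2]]$image$pixels), c(60L, 50L))
  expect_identical(two[[1]]$offset, c(0L, 0L))
  expect_identical(two[[2]]$offset, c(50L, 0L))

  expect_error(split_into_tiles(img, 3, 0), "n_parts")
  expect_error(split_into_tiles(img, 2, 60), "overlap")
})

test_that("tile pixels map back to whole-image pixels exactly", {
  set.seed(12)
  img <- muscle_image(matrix(sample(0:255, 31 * 22, TRUE), 22, 31),
                      pixel_size_um = 1)
  for (parts in c(1L, 2L, 4L)) for (ov in c(0L, 3L)) {
    tiles <- split_into_tiles(img, parts, ov)
    covered <- matrix(FALSE, 22, 31)
    for (t in tiles) {
      tp <- t$image$pixels
      for (r in seq_len(nrow(tp))) for (c in seq_len(ncol(tp))) {
        R <- r + t$offset[2]; C <- c + t$offset[1]
        expect_identical(tp[r, c], img$pixels[R, C])
        covered[R, C] <- TRUE
      }
    }
    expect_true(all(covered), info = paste(parts, ov))
  }
})

test_that("merging a single tile returns it unchanged", {
  res <- small_result()
  merged <- merge_tile_results(list(list(result = res, offset = c(0, 0))))
  expect_identical(length(merged$rois), length(res$rois))
  expect_equal(sum(fiber_areas(merged)), sum(fiber_areas(res)))
})

test_that("disjoint fibers from two tiles land at whole-image coordinates", {
  px <- matrix(200L, 40, 40)
  px[10:18, 10:18] <- 10L
  imgA <- muscle_image(px, pixel_size_um = 1, name = "A")
  pxB <- matrix(200L, 40, 40)
  pxB[20:28, 22:30] <- 10L
  imgB <- muscle_image(pxB, pixel_size_um = 1, name = "B")
  cfg <- pipeline_config(size_min_um2 = 10, circularity_min = 0.2)
  ra <- run_pipeline(imgA, cfg, threshold = 100)
  rb <- run_pipeline(imgB, cfg, threshold = 100)
  expect_length(ra$rois, 1)
  merged <- merge_tile_results(list(list(result = ra, offset = c(0, 0)),
                                    list(result = rb, offset = c(40, 0))))
  expect_length(merged$rois, 2)
  cx <- sort(vapply(merged$rois, function(r) r$centroid[1], numeric(1)))
  expect_equal(cx, c(13.5, 65.5))      # second fiber shifted by tile offset
  expect_identical(merged$image_size, c(80L, 40L))
})

test_that("tiled analysis reproduces the whole-image run through the overlap", {
  sec <- small_section()
  cfg <- pipeline_preset("D0")
  thr <- huang_threshold(sec$image)
  whole <- run_pipeline(sec$image, cfg, threshold = thr)
  maxdiam <- 2 * sqrt(max(sec$truth$area_um2) / pi)
  ov <- as.integer(ceiling(maxdiam) + 10)
  tiles <- split_into_tiles(sec$image, 2, ov)
  tr <- lapply(tiles, function(t) {
    list(result = run_pipeline(t$image, cfg, threshold = thr),
         offset = t$offset)
  })
  merged <- merge_tile_results(tr)
  expect_identical(length(merged$rois), length(whole$rois))
  expect_lt(abs(sum(fiber_areas(merged)) - sum(fiber_areas(whole))) /
              sum(fiber_areas(whole)), 0.001)
  expect_error(merge_tile_results(list(
    list(result = whole, offset = c(0, 0)),
    list(result = run_pipeline(sec$image, pipeline_preset("D8"),
                               threshold = thr), offset = c(0, 0)))),
    "inconsistent configs")
})
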