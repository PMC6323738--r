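# ROI archives: native round trip, ImageJ interoperability, CSV export

test_that("export/import round-trips vertices, ids and origins exactly", {
  set.seed(88)
  for (i in 1:6) {
    res <- make_result(sample(2:8, 1))
    res <- add_fiber(res, random_simple_polygon(center = c(40, 40),
                                                radius = 6))
    path <- tempfile(fileext = ".zip")
    export_rois(res, path)
    back <- import_rois(path)
    expect_identical(length(back$rois), length(res$rois))
    for (k in seq_along(res$rois)) {
      expect_identical(back$rois[[k]]$fiber_id, res$rois[[k]]$fiber_id)
      expect_identical(back$rois[[k]]$origin, res$rois[[k]]$origin)
      expect_identical(unname(back$rois[[k]]$polygon[, 1]),
                       unname(res$rois[[k]]$polygon[, 1]))
      expect_identical(unname(back$rois[[k]]$polygon[, 2]),
                       unname(res$rois[[k]]$polygon[, 2]))
    }
    expect_identical(back$image_size, res$image_size)
    expect_identical(back$pixel_size_um, res$pixel_size_um)
    unlink(path)
  }
})

test_that("archives are byte-reproducible and empty results round-trip", {
  res <- make_result(4)
  p1 <- tempfile(fileext = ".zip"); p2 <- tempfile(fileext = ".zip")
  export_rois(res, p1); export_rois(res, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  empty <- fibercsa:::.segmentation_result(
    rois = list(), image_name = "empty", image_size = c(10L, 10L),
    pixel_size_um = 1, config = pipeline_config(), threshold_used = 1L)
  pe <- tempfile(fileext = ".zip")
  export_rois(empty, pe)
  back <- import_rois(pe)
  expect_length(back$rois, 0)
  unlink(c(p1, p2, pe))
})

test_that("a hand-constructed ImageJ polygon record parses to its vertices", {
  xs <- c(12L, 30L, 30L, 12L)
  ys <- c(5L, 5L, 22L, 22L)
  rec <- imagej_roi_record(xs, ys)
  path <- tempfile(fileext = ".roi")
  writeBin(rec, path)
  res <- import_rois(path, pixel_size_um = 2)
  expect_length(res$rois, 1)
  roi <- res$rois[[1]]
  expect_identical(roi$origin, "manual")
  expect_identical(unname(roi$polygon[, 1]), as.numeric(xs))
  expect_identical(unname(roi$polygon[, 2]), as.numeric(ys))
  expect_identical(roi$area_um2, 18 * 17 * 4)   # shoelace x calibration
  unlink(path)
})

test_that("ImageJ zip archives of polygon ROIs import as manual fibers", {
  files <- list(
    "a.roi" = imagej_roi_record(c(2L, 9L, 9L, 2L), c(2L, 2L, 8L, 8L)),
    "b.roi" = imagej_roi_record(c(20L, 28L, 24L), c(4L, 4L, 12L)))
  path <- tempfile(fileext = ".zip")
  fibercsa:::.write_zip(files, path)
  res <- import_rois(path)
  expect_length(res$rois, 2)
  expect_true(all(vapply(res$rois, `[[`, character(1), "origin") ==
                    "manual"))
  unlink(path)
})

test_that("malformed files raise parse errors naming a byte offset", {
  bad <- tempfile(fileext = ".roi")
  writeBin(charToRaw("Inot-a-roi-file-at-all-padding-padding-padding-xyz"),
           bad)
  expect_error(import_rois(bad), "byte offset 0")
  unlink(bad)
})

test_that("the results CSV has the documented columns", {
  res <- make_result(3)
  path <- tempfile(fileext = ".csv")
  write_results_csv(res, path)
  df <- read.csv(path)
  expect_identical(names(df),
                   c("fiber_id", "origin", "area_um2", "perimeter_um",
                     "circularity", "centroid_x", "centroid_y", "tile_id"))
  expect_identical(nrow(df), 3L)
  unlink(path)
})
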