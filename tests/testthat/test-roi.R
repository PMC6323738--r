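# fiber ROI model and programmatic manual correction

test_that("polygon areas follow the shoelace formula", {
  expect_identical(polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1)
  expect_identical(polygon_area(rbind(c(0, 0), c(4, 0), c(0, 3))), 6)
  # orientation independent
  expect_identical(polygon_area(rbind(c(0, 0), c(0, 3), c(4, 0))), 6)
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))), "degenerate")
  expect_error(polygon_area(rbind(c(0, 0), c(4, 0), c(1, 3), c(3, 3))),
               "self-intersecting")
})

test_that("polygon area agrees with a rasterized pixel count oracle", {
  set.seed(55)
  for (i in 1:10) {
    p <- random_simple_polygon(n_vertices = sample(5:12, 1))
    a <- polygon_area(p)
    # count pixel centers inside with the independent crossing test
    cnt <- 0
    for (r in 1:40) for (c in 1:40) {
      if (oracle_point_in_polygon(c - 0.5, r - 0.5, p)) cnt <- cnt + 1
    }
    per <- fibercsa:::.polygon_perimeter(p)
    # discrepancy bounded by a one-pixel band along the boundary
    expect_lt(abs(a - cnt), per + 1, label = paste("polygon", i))
  }
})

test_that("deleting fibers removes exactly the named ids and logs the event", {
  res <- make_result(10)
  out <- delete_fibers(res, c(2L, 5L))
  expect_length(out$rois, 8)
  expect_false(any(c(2L, 5L) %in% vapply(out$rois, `[[`, integer(1),
                                         "fiber_id")))
  expect_identical(out$correction_log[[1]],
                   list(op = "delete", ids = c(2L, 5L)))
  # empty deletion: unchanged fibers, one no-op log entry
  noop <- delete_fibers(res, integer(0))
  expect_identical(noop$rois, res$rois)
  expect_length(noop$correction_log, 1)
  expect_error(delete_fibers(res, 99L), "99")
})

test_that("added fibers are manual, unfiltered, and correctly measured", {
  res <- make_result(3)
  sq <- rbind(c(10, 10), c(20, 10), c(20, 20), c(10, 20))
  out <- add_fiber(res, sq)
  expect_length(out$rois, 4)
  roi <- out$rois[[4]]
  expect_identical(roi$origin, "manual")
  expect_identical(roi$area_um2, 100)
  expect_true(is.na(roi$circularity))
  # a sliver far below the D8 size threshold is still accepted: manual
  # origin bypasses the filters
  res8 <- make_result(3)
  res8$config <- pipeline_preset("D8")
  sliver <- rbind(c(5, 5), c(8, 5), c(8, 7), c(5, 7))   # 6 um^2
  out8 <- add_fiber(res8, sliver)
  expect_length(out8$rois, 4)
  expect_lt(out8$rois[[4]]$area_um2, res8$config$size_min_um2)
  expect_error(add_fiber(res, rbind(c(-5, 0), c(5, 0), c(0, 5))),
               "outside the image")
})

test_that("add-then-delete restores the mean CSA exactly", {
  res <- make_result(6)
  before <- mean_csa(res)
  out <- add_fiber(res, rbind(c(30, 30), c(40, 30), c(40, 40), c(30, 40)))
  new_id <- out$rois[[length(out$rois)]]$fiber_id
  out <- delete_fibers(out, new_id)
  expect_identical(mean_csa(out), before)
})

test_that("replaying the correction log reproduces the corrected state", {
  set.seed(66)
  auto <- make_result(8)
  cur <- delete_fibers(auto, c(1L, 4L))
  cur <- add_fiber(cur, random_simple_polygon(center = c(30, 30)))
  cur <- delete_fibers(cur, 7L)
  cur <- add_fiber(cur, random_simple_polygon(center = c(45, 40),
                                              radius = 6))
  replayed <- replay_corrections(auto, cur$correction_log)
  expect_identical(replayed, cur)
})
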