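# evaluation: truth matching, CSA statistics, correlation, burden, bias

test_that("a prediction equal to the truth matches perfectly", {
  sec <- generate_section(section_preset("regenerating_d8", n_seeds = 40,
                                         seed = 10))
  res <- result_from_truth(sec)
  rep <- match_to_truth(res, sec, iou_min = 0.5)
  expect_identical(rep$n_missed, 0L)
  expect_identical(rep$n_false, 0L)
  expect_identical(rep$n_matched, rep$n_truth)
  expect_true(all(rep$matched_pairs$iou == 1))
  # conservation identities
  expect_identical(rep$n_matched + rep$n_missed, rep$n_truth)
  expect_identical(rep$n_matched + rep$n_false, rep$n_predicted)
  # perfect self-prediction survives even iou_min = 1
  rep1 <- match_to_truth(res, sec, iou_min = 1)
  expect_identical(rep1$n_missed, 0L)
})

test_that("an empty prediction misses every truth fiber", {
  sec <- generate_section(section_preset("uninjured", n_seeds = 30,
                                         seed = 12))
  empty <- fibercsa:::.segmentation_result(
    rois = list(), image_name = sec$image$name,
    image_size = c(ncol(sec$labels), nrow(sec$labels)),
    pixel_size_um = 1, config = pipeline_config(), threshold_used = 1L)
  rep <- match_to_truth(empty, sec)
  expect_identical(rep$n_missed, rep$n_truth)
  expect_identical(rep$n_false, 0L)
  mismatched <- empty
  mismatched$image_size <- c(5L, 5L)
  expect_error(match_to_truth(mismatched, sec), "frame mismatch")
})

test_that("greedy matching agrees with the brute-force assignment oracle", {
  set.seed(123)
  for (trial in 1:8) {
    sec <- generate_section(section_params(n_seeds = 7,
                                           area_median_um2 = 900,
                                           area_sdlog = 0.3,
                                           roundness = 2, seed = trial))
    # degrade the prediction: drop a fiber, shrink another by erosion
    res <- result_from_truth(sec)
    drop <- sample(length(res$rois), 1)
    res$rois <- res$rois[-drop]
    rep <- match_to_truth(res, sec, iou_min = 0.3)
    # recompute the IoU matrix independently and enumerate assignments
    h <- nrow(sec$labels); w <- ncol(sec$labels)
    np <- length(res$rois); nt <- nrow(sec$truth)
    iou <- matrix(0, np, nt)
    for (i in seq_len(np)) {
      pix <- fibercsa:::.rasterize_polygon(res$rois[[i]]$polygon, h, w)
      pl <- sec$labels[cbind(pix[, 1], pix[, 2])]
      for (t in seq_len(nt)) {
        inter <- sum(pl == t)
        iou[i, t] <- inter / (nrow(pix) + sum(sec$labels == t) - inter)
      }
    }
    want <- oracle_match(iou, 0.3)
    expect_identical(rep$n_matched, as.integer(want$count))
    expect_equal(sum(rep$matched_pairs$iou), want$total, tolerance = 1e-9)
  }
})

test_that("mean CSA and binned distributions follow their definitions", {
  expect_identical(mean_csa(c(100, 300)), 200)
  expect_error(mean_csa(numeric(0)), "empty")
  d <- csa_distribution(c(100, 600), distribution_spec(500))
  expect_identical(d$count, c(1L, 1L))
  expect_identical(sum(d$fraction), 1)
  set.seed(3)
  a <- runif(200, 0, 5000)
  dd <- csa_distribution(a)
  expect_identical(sum(dd$count), 200L)
  expect_equal(sum(dd$fraction), 1)
  expect_equal(mean_csa(a), sum(a) / length(a))
  expect_error(distribution_spec(c(500, 400)), "strictly increasing")
})

test_that("identity correlation matches the closed-form Pearson oracle", {
  a <- c(100, 200, 300, 400)
  r <- correlation_identity(a, a)
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0)
  r2 <- correlation_identity(a, 2 * a)
  expect_equal(r2$r_squared, 1)
  expect_equal(r2$slope, 2)
  set.seed(31)
  x <- rnorm(20, 1500, 300); y <- 0.9 * x + rnorm(20, 0, 80)
  got <- correlation_identity(x, y, spearman = TRUE)
  # direct formula cross-check
  num <- sum((x - mean(x)) * (y - mean(y)))
  expect_equal(got$r_squared,
               num^2 / (sum((x - mean(x))^2) * sum((y - mean(y))^2)))
  expect_equal(got$slope, num / sum((x - mean(x))^2))
  expect_error(correlation_identity(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(correlation_identity(1:2, 1:2), "3 pairs")
})

test_that("correction burden counts events against the corrected total", {
  auto <- make_result(10)
  none <- correction_burden(auto, auto)
  expect_identical(none$percent_false_deleted, 0)
  expect_identical(none$percent_missed_added, 0)
  expect_identical(none$percent_csa_change, 0)
  cur <- delete_fibers(auto, 3L)
  cur <- add_fiber(cur, rbind(c(30, 30), c(40, 30), c(40, 40), c(30, 40)))
  got <- correction_burden(auto, cur)
  expect_identical(got$n_corrected, 10L)
  expect_identical(got$percent_false_deleted, 10)
  expect_identical(got$percent_missed_added, 10)
  expect_equal(got$percent_csa_change,
               100 * (mean_csa(auto) - mean_csa(cur)) / mean_csa(cur))
  unrelated <- make_result(5)
  unrelated$correction_log <- cur$correction_log
  expect_error(correction_burden(make_result(7), unrelated),
               "does not derive")
})

test_that("randomized correction sequences agree with a recount oracle", {
  set.seed(99)
  for (i in 1:5) {
    auto <- make_result(12)
    cur <- auto
    n_del <- 0; n_add <- 0
    for (step in 1:4) {
      if (runif(1) < 0.5 && length(cur$rois) > 2) {
        id <- vapply(cur$rois, `[[`, integer(1), "fiber_id")[
          sample(length(cur$rois), 1)]
        cur <- delete_fibers(cur, id)
        n_del <- n_del + 1
      } else {
        cur <- add_fiber(cur, random_simple_polygon(center = c(40, 40),
                                                    radius = 7))
        n_add <- n_add + 1
      }
    }
    got <- correction_burden(auto, cur)
    expect_identical(got$n_deleted, as.integer(n_del))
    expect_identical(got$n_added, as.integer(n_add))
    expect_equal(got$percent_false_deleted,
                 100 * n_del / length(cur$rois))
  }
})

test_that("subset bias is zero for the whole partition and flags empties", {
  res <- make_result(8)
  whole <- subset_bias(res, "whole")
  expect_identical(whole$subsets$percent_deviation, 0)
  # all fibers sit in the upper-left region of the 64 x 64 frame at times;
  # force an empty subset with a tiny frame split
  res2 <- make_result(5)
  for (k in seq_along(res2$rois)) {
    res2$rois[[k]]$centroid <- c(10 + k, 10)    # all on the left half
  }
  sb <- subset_bias(res2, "halves_x")
  expect_true(sb$subsets$empty[sb$subsets$subset == "right"])
  expect_identical(sb$subsets$n_fibers[sb$subsets$subset == "left"], 5L)
})

test_that("gradient sections bias peripheral subsets up and central down", {
  g <- cached("gradient500",
              generate_section(section_preset("regenerating_d28_gradient",
                                              seed = 2)))
  res <- result_from_truth(g)
  sb <- subset_bias(res, "center_annulus")
  dev <- setNames(sb$subsets$percent_deviation, sb$subsets$subset)
  expect_gt(dev["periphery"], 0)
  expect_lt(dev["center"], 0)
})
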