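# synthetic section generator and its presets

test_that("generation is a pure function of its parameters", {
  p <- section_preset("regenerating_d8", n_seeds = 40, seed = 9)
  a <- generate_section(p)
  b <- generate_section(p)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(as.vector(a$labels), as.vector(b$labels))
  expect_identical(a$truth, b$truth)
})

test_that("at roundness 0 the background is exactly the boundary band", {
  sec <- generate_section(section_preset("uninjured", n_seeds = 50,
                                         seed = 4))
  img <- sec$image$pixels
  p <- sec$params
  # noise-free two-level rendering
  expect_identical(sort(unique(as.vector(img))),
                   as.integer(c(p$interior_intensity,
                                p$boundary_intensity)))
  # every pixel belongs to a tessellation cell and truth areas are the
  # exact cell pixel counts
  expect_true(all(sec$labels > 0))
  counts <- tabulate(sec$labels, nrow(sec$truth))
  expect_identical(sec$truth$area_um2, as.numeric(counts))
})

test_that("truth labels are consecutive connected regions matching the raster", {
  sec <- generate_section(section_preset("regenerating_d8", n_seeds = 60,
                                         seed = 14))
  lab <- sec$labels
  n <- attr(lab, "region_count")
  expect_identical(sort(unique(as.vector(lab[lab > 0]))), seq_len(n))
  expect_identical(nrow(sec$truth), n)
  # relabeling through label_connected preserves each region unsplit
  relab <- label_connected(matrix(as.integer(lab > 0), nrow(lab)))
  for (L in sample(n, 10)) {
    pix <- which(lab == L)
    expect_identical(length(unique(relab[pix])), 1L, info = paste(L))
  }
})

test_that("sampled truth areas follow the declared lognormal law", {
  sec <- generate_section(section_params(n_seeds = 500,
                                         area_median_um2 = 1500,
                                         area_sdlog = 0.4, seed = 7))
  med <- median(sec$truth$area_um2)
  expect_lt(abs(med - 1500) / 1500, 0.15)
})

test_that("presets realize their regimes", {
  u <- section_preset("uninjured")
  expect_identical(u$roundness, 0)
  expect_gte(u$area_median_um2, 1000)
  expect_identical(u$noise_sd, 0)

  fb <- generate_section(section_preset("fibrotic", seed = 2))
  expect_gte(mean(fb$truth$area_um2 < 500), 0.30)

  g <- generate_section(section_preset("regenerating_d28_gradient",
                                       seed = 2))
  W <- ncol(g$labels); H <- nrow(g$labels)
  r_half <- sqrt(W * H / (2 * pi))
  central <- (g$truth$centroid_x - W / 2)^2 +
    (g$truth$centroid_y - H / 2)^2 <= r_half^2
  expect_gt(mean(g$truth$area_um2[!central]),
            mean(g$truth$area_um2[central]))

  expect_error(section_preset("normal"), "unknown preset")
})

test_that("impossible packings raise an explicit error", {
  p <- section_params(n_seeds = 500, area_median_um2 = 1500,
                      width = 120, height = 120, seed = 1)
  expect_error(generate_section(p), "cannot fit")
})

test_that("the 16-bit path renders and segments", {
  p <- section_params(n_seeds = 35, area_median_um2 = 1200,
                      boundary_intensity = 58000,
                      interior_intensity = 6000,
                      noise_sd = 300, bit_depth = 16L, seed = 6)
  sec <- generate_section(p)
  expect_identical(sec$image$bit_depth, 16L)
  expect_lte(max(sec$image$pixels), 65535L)
  res <- run_pipeline(sec$image, pipeline_config(size_min_um2 = 100,
                                                 circularity_min = 0.4))
  rep <- match_to_truth(res, sec)
  expect_gte(rep$recall, 0.9)
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(section_params(faint_fraction = 1.2), "faint_fraction")
  expect_error(section_params(boundary_intensity = 300, bit_depth = 8),
               "bit depth")
})
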