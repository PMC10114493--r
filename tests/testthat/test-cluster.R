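two_plateau_image <- function() {
  m <- matrix(0.1, 5, 5)
  m[1:2, 1:2] <- 0.9
  m[4:5, 4:5] <- 0.9
  make_proj(m)
}

test_that("gaussian smoothing: identity, normalization, impulse kernel", {
  set.seed(2)
  img <- make_proj(matrix(runif(64), 8, 8))
  expect_equal(gaussian_smooth(img, smoothing_params(5L, 0))$pixels,
               img$pixels)
  const <- make_proj(matrix(0.37, 8, 8))
  expect_equal(gaussian_smooth(const, smoothing_params(9L, 2))$pixels,
               const$pixels, tolerance = 1e-12)

  # unit impulse: centre equals the closed-form normalized kernel centre
  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  sm <- gaussian_smooth(make_proj(imp), smoothing_params(5L, 1))
  d <- -2:2
  k <- outer(exp(-d^2 / 2), exp(-d^2 / 2))
  expect_equal(sm$pixels[8, 8], (k / sum(k))[3, 3], tolerance = 1e-12)

  expect_error(smoothing_params(4L, 1), "odd")
  expect_error(smoothing_params(5L, -1), ">= 0")
})

test_that("detect_clusters resolves separated plateaus like a flood fill", {
  img <- two_plateau_image()
  fr <- detect_clusters(img, full_mask(5, 5),
                        cluster_params(0.4, min_cluster_px = 1L))
  expect_equal(fr$n_clusters, 2L)
  expect_equal(sort(fr$clusters$pixel_count), c(4L, 4L))
  oracle <- flood_fill_label(img$pixels > 0.4, 8L)
  expect_equal(max(oracle), 2L)
  expect_equal(fr$total_area_um2, 8 * 0.0526^2)
  expect_equal(fr$clusters$mean_intensity, c(0.9, 0.9))
})

test_that("threshold above the ROI maximum yields zero clusters", {
  img <- two_plateau_image()
  fr <- detect_clusters(img, full_mask(5, 5), cluster_params(0.95))
  expect_equal(fr$n_clusters, 0L)
  expect_equal(fr$total_area_um2, 0)
  expect_true(is.na(fr$mean_in_cluster_intensity))
})

test_that("a uniform suprathreshold ROI is one cluster filling the mask", {
  mask <- matrix(0, 9, 9); mask[3:7, 2:8] <- 1
  img <- make_proj(matrix(0.5, 9, 9))
  fr <- detect_clusters(img, roi_mask(mask), cluster_params(0.4))
  expect_equal(fr$n_clusters, 1L)
  expect_equal(fr$clusters$pixel_count, sum(mask))
})

test_that("cluster area is monotone in threshold and pixels are conserved", {
  set.seed(14)
  img <- make_proj(matrix(runif(400), 20, 20))
  mask <- full_mask(20, 20)
  params <- function(th) cluster_params(th, min_cluster_px = 1L)
  areas <- vapply(seq(0.1, 0.9, by = 0.1), function(th) {
    detect_clusters(img, mask, params(th))$total_area_um2
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))

  fr <- detect_clusters(img, mask, params(0.5))
  expect_equal(sum(fr$clusters$pixel_count), sum(img$pixels > 0.5))
  # 8-connectivity merges at least as much as 4-connectivity
  fr4 <- detect_clusters(img, mask, cluster_params(0.5, connectivity = 4L,
                                                   min_cluster_px = 1L))
  expect_lte(fr$n_clusters, fr4$n_clusters)
  # without smoothing, cluster pixels all exceed the threshold
  expect_true(all(fr$clusters$mean_intensity > 0.5))
})

test_that("min_cluster_px drops small components and smoothing agglomerates", {
  m <- matrix(0.1, 9, 9)
  m[5, 3] <- 0.9; m[5, 5] <- 0.9  # two isolated bright pixels
  img <- make_proj(m)
  fr <- detect_clusters(img, full_mask(9, 9),
                        cluster_params(0.4, min_cluster_px = 2L))
  expect_equal(fr$n_clusters, 0L)
  frs <- detect_clusters(img, full_mask(9, 9),
                         cluster_params(0.05, min_cluster_px = 2L),
                         smoothing = smoothing_params(5L, 1.5))
  expect_equal(frs$n_clusters, 1L)  # bridged by the blur
})

test_that("time series normalizes to the baseline window", {
  # frames engineered so baseline areas are equal and a later frame is 1.5x
  base <- matrix(0.1, 6, 6); base[3:4, 3:4] <- 0.9      # 4 px
  late <- base; late[3:4, 2] <- 0.9                      # 6 px
  frames <- lapply(list(base, base, base, late), make_proj)
  ts <- analyze_timeseries(frames, full_mask(6, 6),
                           cluster_params(0.4, min_cluster_px = 1L),
                           treatment_frame = 4L)
  expect_equal(mean(ts$frames$relative_total_area[1:3]), 1, tolerance = 1e-9)
  expect_equal(mean(ts$frames$relative_n_clusters[1:3]), 1, tolerance = 1e-9)
  expect_equal(ts$frames$relative_total_area[4], 1.5)
  expect_equal(ts$frames$time_min, c(-6, -3, 0, 3))

  expect_error(analyze_timeseries(frames, full_mask(6, 6),
                                  treatment_frame = 2L), "at least")
})

test_that("all-zero series flags the relative metrics as undefined", {
  frames <- replicate(5, make_proj(matrix(0, 6, 6)), simplify = FALSE)
  ts <- analyze_timeseries(frames, full_mask(6, 6), cluster_params(0.4),
                           treatment_frame = 4L)
  expect_setequal(ts$undefined_relative,
                  c("relative_total_area", "relative_n_clusters"))
  expect_true(all(is.na(ts$frames$relative_total_area)))
})

test_that("before/after summary picks the post-treatment peak in-window", {
  mk <- function(npx) {
    m <- matrix(0.1, 8, 20); m[4:5, seq_len(npx)] <- 0.9
    make_proj(m)
  }
  # mean sizes: baseline 2x3=6 px clusters ... construct single clusters
  frames <- lapply(c(3, 3, 3, 5, 7, 6, 9), mk)
  ts <- analyze_timeseries(frames, full_mask(8, 20),
                           cluster_params(0.4, min_cluster_px = 1L),
                           treatment_frame = 4L, frame_time_min = 3)
  s <- summarize_before_after(ts, after_window_min = 10)
  px2 <- 0.0526^2
  expect_equal(s$before_um2, 6 * px2)
  expect_equal(s$after_um2, 14 * px2)  # peak among frames at +3, +6, +9 min
  # constant series: before equals after
  frames2 <- lapply(c(3, 3, 3, 3, 3), mk)
  ts2 <- analyze_timeseries(frames2, full_mask(8, 20),
                            cluster_params(0.4, min_cluster_px = 1L),
                            treatment_frame = 4L)
  s2 <- summarize_before_after(ts2)
  expect_equal(s2$before_um2, s2$after_um2)
  expect_equal(s2$ratio, 1)
})
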