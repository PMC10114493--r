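test_that("the generator is deterministic under (config, seed)", {
  cfg <- preset_config("bicuculline", seed = 99, width_px = 128L,
                       height_px = 128L, n_clusters = 4L)
  a <- generate_projection(cfg)
  b <- generate_projection(cfg)
  expect_identical(a$projection$pixels, b$projection$pixels)
  s1 <- generate_timelapse(cfg, render = FALSE)
  s2 <- generate_timelapse(cfg, render = FALSE)
  expect_identical(s1$truth$births, s2$truth$births)
  expect_identical(s1$truth$tracks, s2$truth$tracks)
  # a different seed changes the noise field
  c2 <- generate_projection(preset_config("bicuculline", seed = 100,
                                          width_px = 128L, height_px = 128L,
                                          n_clusters = 4L))
  expect_false(identical(a$projection$pixels, c2$projection$pixels))
})

test_that("noiseless cluster-free image equals the analytic band profile", {
  cfg <- preset_config("baseline", seed = 1, width_px = 96L, height_px = 96L,
                       n_clusters = 0L, noise_sd = 0)
  g <- generate_projection(cfg)
  px <- g$projection$pixels
  vals <- sort(unique(as.vector(px)))
  expect_equal(vals, c(cfg$background_level, cfg$diffuse_level))
  half <- floor(cfg$dendrite_width_um / cfg$pixel_size_um / 2)
  expect_equal(sum(px == cfg$diffuse_level), 96 * (2 * half + 1))
})

test_that("programmed clusters are recovered exactly without noise", {
  cfg <- preset_config("baseline", seed = 2, n_clusters = 5L, noise_sd = 0)
  g <- generate_projection(cfg)
  mask <- grow_skeleton(g$skeleton, 95L)
  fr <- detect_clusters(g$projection, mask, cluster_params(cfg$threshold))
  expect_equal(fr$n_clusters, 5L)
  # measured areas agree with the analytic supra-threshold disk areas
  expect_equal(fr$total_area_um2, sum(g$truth$clusters$area_um2),
               tolerance = 0.03)
  # cluster x-positions match the layout
  got <- sort(fr$clusters$centroid_x)
  want <- sort(g$truth$clusters$position_um / cfg$pixel_size_um + 1)
  expect_equal(got, want, tolerance = 0.02 * max(want))
})

test_that("noiseless time-lapse conserves summed intensity while clusters grow", {
  cfg <- preset_config("bicuculline", seed = 3, noise_sd = 0)
  sim <- generate_timelapse(cfg)
  sums <- vapply(sim$frames, function(f) sum(f$pixels), numeric(1))
  expect_lt(diff(range(sums)) / mean(sums), 0.005)
  # diffuse pool shrinks as clusters grow
  expect_lt(sim$truth$diffuse[cfg$n_frames], sim$truth$diffuse[1])
  # area factor schedule hits the programmed marks
  tf <- sim$treatment_frame
  fac <- sim$truth$area_factor
  expect_equal(fac[tf - 1], 1)     # onset
  expect_equal(fac[tf + 1], 1.5)   # +6 min
  expect_equal(fac[tf + 2], 2.0)   # +9 min peak
})

test_that("flat program with zero rate yields identical frames up to noise", {
  cfg <- preset_config("baseline", seed = 4, noise_sd = 0,
                       spine_gain_per_h = 0)
  sim <- generate_timelapse(cfg)
  expect_identical(sim$frames[[1]]$pixels, sim$frames[[20]]$pixels)
  expect_equal(nrow(sim$truth$births), 0L)
})

test_that("ground-truth precedence fraction matches the programmed probability", {
  births <- dplyr::bind_rows(lapply(1:120, function(s) {
    generate_timelapse(preset_config("bicuculline", seed = 7000 + s),
                       render = FALSE)$truth$births
  }))
  n <- nrow(births)
  expect_gte(n, 200)
  phat <- mean(births$from_cluster)
  expect_lt(abs(phat - 0.85), 3 * sqrt(0.85 * 0.15 / n))
})

test_that("spine tables honour the class mix and classify diagonally", {
  cfg <- preset_config("baseline", seed = 10)
  expect_equal(nrow(generate_spine_table(cfg, 0)), 0L)
  mush <- generate_spine_table(cfg, 50, c(stubby = 0, thin = 0, mushroom = 1))
  expect_true(all(classify_spines(mush)$spine_class == "mushroom"))

  tab <- generate_spine_table(cfg, 1000,
                              c(stubby = 0.3, thin = 0.4, mushroom = 0.3))
  cls <- classify_spines(tab)
  conf <- table(truth = tab$true_class, got = cls$spine_class)
  for (k in c("stubby", "thin", "mushroom")) {
    expect_equal(unname(conf[k, k]), sum(tab$true_class == k))
  }
  expect_error(generate_spine_table(cfg, 10, c(stubby = 0.5, thin = 0.2,
                                               mushroom = 0.2)), "sum to 1")
})

test_that("colocalization pairs deliver the programmed correlation", {
  cfg <- preset_config("baseline", seed = 12)
  perfect <- generate_coloc_pair(cfg, 1)
  expect_equal(pearson_cc(perfect$ch1, perfect$ch2, perfect$roi), 1)
  inv <- generate_coloc_pair(cfg, -1)
  expect_equal(pearson_cc(inv$ch1, inv$ch2, inv$roi), -1)

  null <- generate_coloc_pair(preset_config("baseline", seed = 13), 0)
  n <- length(null$ch1$pixels)
  expect_lt(abs(pearson_cc(null$ch1, null$ch2, null$roi)), 3 / sqrt(n))

  strong <- generate_coloc_pair(preset_config("baseline", seed = 14), 0.8)
  tol <- 3 * (1 - 0.8^2) / sqrt(length(strong$ch1$pixels))
  expect_lt(abs(pearson_cc(strong$ch1, strong$ch2, strong$roi) - 0.8), tol)
  expect_error(generate_coloc_pair(cfg, 1.2), "<= 1")
})

test_that("spine-gain cohorts are unbiased for the programmed gain", {
  gains <- vapply(1:30, function(s) {
    mean(simulate_spine_gain(preset_config("bicuculline", seed = 300 + s),
                             12)$gain_percent)
  }, numeric(1))
  se <- sd(gains) / sqrt(length(gains))
  expect_lt(abs(mean(gains) - 14.0), 3 * se)
})
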