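test_that("new-protrusion detection emits births only on appearance", {
  same <- lapply(1:5, function(i) c(1.0, 3.5, 7.2))
  expect_equal(nrow(detect_new_protrusions(same)), 0L)

  ev <- detect_new_protrusions(list(numeric(0), 4.2))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$birth_frame, 2L)
  expect_equal(ev$position_um, 4.2)

  # persistent protrusion with slight drift within the radius: one event total
  drift <- list(c(2.0), c(2.2), c(2.4))
  expect_equal(nrow(detect_new_protrusions(drift, match_radius_um = 0.5)), 0L)
  expect_error(detect_new_protrusions(list(1.0)), "at least 2")
})

test_that("detection recovers the generator's birth schedule exactly", {
  cfg <- preset_config("bicuculline", seed = 33)
  sim <- generate_timelapse(cfg, render = FALSE)
  ev <- detect_new_protrusions(sim$truth$protrusions)
  expect_equal(nrow(ev), nrow(sim$truth$births))
  expect_equal(ev$birth_frame, sim$truth$births$birth_frame)
  expect_equal(sort(ev$position_um), sort(sim$truth$births$position_um))
  # event count invariant to within-frame ordering
  shuf <- sim$truth$protrusions
  shuf <- shuf[sample(nrow(shuf)), ]
  shuf <- shuf[order(shuf$frame), ]
  expect_equal(nrow(detect_new_protrusions(shuf)), nrow(ev))
})

test_that("protrusion rate and spine gain are the documented arithmetic", {
  expect_equal(protrusion_rate(3, 30, 10), 0.1)
  expect_equal(protrusion_rate(0, 30, 10), 0)
  expect_error(protrusion_rate(3, 0, 10), "> 0")
  expect_equal(spine_gain_percent(13, 100), 13)
  expect_equal(spine_gain_percent(0, 40), 0)
  expect_equal(spine_gain_percent(7, 50), 14)
  expect_error(spine_gain_percent(1, 0), "> 0")
})

test_that("rate recovery over many videos matches the configured intensity", {
  rates <- vapply(1:40, function(s) {
    cfg <- preset_config("gas7_oe", seed = 5000 + s)
    sim <- generate_timelapse(cfg, render = FALSE)
    ev <- detect_new_protrusions(sim$truth$protrusions)
    protrusion_rate(ev, sim$dendrite_length_um,
                    (cfg$n_frames - 1) * cfg$frame_time_min)
  }, numeric(1))
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 0.150), 3 * se)
})

test_that("cluster association links preceding nearby tracks only", {
  tracks <- tibble::tibble(cluster_id = 1L, frame = 1:5, position_um = 10)
  ev <- tibble::tibble(birth_frame = 3L, position_um = 10.4)
  res <- associate_with_clusters(ev, tracks, radius_um = 1.0)
  expect_equal(res$events$linked_cluster_id, 1L)
  expect_equal(res$percent_from_clusters, 100)

  # too far, or cluster not yet present at the preceding frame
  far <- associate_with_clusters(
    tibble::tibble(birth_frame = 3L, position_um = 12.5), tracks)
  expect_true(is.na(far$events$linked_cluster_id))
  late_track <- tibble::tibble(cluster_id = 1L, frame = 4:6, position_um = 10)
  late <- associate_with_clusters(ev, late_track)
  expect_true(is.na(late$events$linked_cluster_id))

  none <- associate_with_clusters(ev, tracks[0, ])
  expect_equal(none$percent_from_clusters, 0)
  empty <- associate_with_clusters(ev[0, ], tracks)
  expect_true(is.na(empty$percent_from_clusters))
})

test_that("linked percentage is monotone in radius and complements sum to 100", {
  cfg <- preset_config("bicuculline", seed = 77)
  sim <- generate_timelapse(cfg, render = FALSE)
  ev <- detect_new_protrusions(sim$truth$protrusions)
  pcts <- vapply(c(0.2, 0.5, 1.0, 2.0), function(r) {
    associate_with_clusters(ev, sim$truth$tracks,
                            radius_um = r)$percent_from_clusters
  }, numeric(1))
  expect_true(all(diff(pcts) >= 0))
  p <- pcts[3]
  expect_equal(p + (100 - p), 100)
})

test_that("epoch pooling counts events in 15-frame windows", {
  # 45-min epochs at 3-min frames are 15 frames each
  expect_equal(45 / 3, 15)
  ev <- tibble::tibble(birth_frame = c(2L, 5L, 14L),
                       linked_cluster_id = c(1L, NA, 2L))
  ep <- pool_epochs(ev, treatment_frame = 16L, epoch_n_frames = 15L,
                    n_frames = 30L)
  expect_equal(ep$n_events, c(3L, 0L))
  expect_equal(ep$n_linked, c(2L, 0L))

  set.seed(6)
  bf <- sample(1:30, 40, replace = TRUE)
  ep2 <- pool_epochs(tibble::tibble(birth_frame = bf), 16L, 15L, 30L)
  expect_equal(ep2$n_events,
               c(sum(bf >= 1 & bf <= 15), sum(bf >= 16 & bf <= 30)))
  expect_error(pool_epochs(ev, treatment_frame = 10L, epoch_n_frames = 15L),
               "before the series")
})
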