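#' Preset configurations for the synthetic dendrite generator
#'
#' Returns the full parameter set of the seeded synthetic-image generator.
#' Preset values encode the measured effects the generator emulates:
#' treatment-induced total-cluster-area growth reaching 1.5-fold at +6 min
#' with peak mean cluster size doubling within the first 10 min
#' (`bicuculline`), an 85 % cluster-precedence probability for new spines
#' (`bicuculline`), spine gains of 14.0 %/h (`bicuculline`) vs 1.0 %/h
#' (`baseline`), and new-protrusion rates of 0.150 (`gas7_oe`) vs 0.078
#' (`control_oe`) per 10 um per min.
#'
#' @param name One of `"baseline"`, `"bicuculline"`, `"gas7_oe"`,
#'   `"control_oe"`, `"latrunculin"`.
#' @param seed Integer seed; fixes all randomness of the generator.
#' @param ... Named overrides of any config field.
#' @return A `spq_preset` list. Fields include image geometry
#'   (`width_px`, `height_px`, `pixel_size_um`, `dendrite_width_um`),
#'   cluster layout (`n_clusters`, `cluster_sigma_um`, `diffuse_level`,
#'   `blob_amplitude`, `background_level`, `noise_sd`, `threshold`),
#'   timing (`frame_time_min`, `epoch_frames`, `n_frames`), treatment
#'   effects (`cluster_area_growth_factor`, `cluster_size_factor`,
#'   `precedence_prob`, `spine_gain_per_h`,
#'   `protrusion_rate_per_10um_min`) and the spine population
#'   (`n_existing_spines`).
#' @export
preset_config <- function(name = c("baseline", "bicuculline", "gas7_oe",
                                   "control_oe", "latrunculin"),
                          seed = 1L, ...) {
  name <- match.arg(name)
  cfg <- list(
    name = name,
    seed = as.integer(seed),
    width_px = 512L, height_px = 512L,
    pixel_size_um = 0.0526,
    dendrite_width_um = 2,
    n_clusters = 8L,
    cluster_sigma_um = 0.30,
    diffuse_level = 0.25,
    blob_amplitude = 0.45,
    background_level = 0.05,
    noise_sd = 0.02,
    threshold = 0.4,
    frame_time_min = 3,
    epoch_frames = 15L,
    n_frames = 30L,
    baseline_n_frames = 3L,
    cluster_area_growth_factor = 1,
    cluster_size_factor = 1,
    growth_ramp_min = 6,
    size_peak_min = 9,
    precedence_prob = NA_real_,
    spine_gain_per_h = 1.0,
    protrusion_rate_per_10um_min = NA_real_,
    n_existing_spines = 16L,
    cluster_count_decay_per_frame = 0)
  over <- switch(
    name,
    baseline = list(),
    bicuculline = list(cluster_area_growth_factor = 1.5,
                       cluster_size_factor = 2.0,
                       precedence_prob = 0.85,
                       spine_gain_per_h = 14.0),
    gas7_oe = list(protrusion_rate_per_10um_min = 0.150,
                   precedence_prob = 0.759,
                   n_frames = 16L, epoch_frames = NA_integer_),
    control_oe = list(protrusion_rate_per_10um_min = 0.078,
                      precedence_prob = 0,
                      n_frames = 16L, epoch_frames = NA_integer_),
    latrunculin = list(cluster_area_growth_factor = 0.85,
                       cluster_size_factor = 0.85,
                       baseline_n_frames = 4L,
                       epoch_frames = 10L, n_frames = 20L))
  cfg[names(over)] <- over
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  if (!is.na(cfg$precedence_prob) &&
      (cfg$precedence_prob < 0 || cfg$precedence_prob > 1)) {
    stop("precedence_prob must lie in [0, 1]")
  }
  if (cfg$cluster_area_growth_factor <= 0 || cfg$cluster_size_factor <= 0) {
    stop("growth factors must be > 0")
  }
  structure(cfg, class = "spq_preset")
}

#' @export
print.spq_preset <- function(x, ...) {
  cat(sprintf("<spq_preset> %s (seed %d): %dx%d px, %d clusters, %d frames\n",
              x$name, x$seed, x$width_px, x$height_px, x$n_clusters,
              x$n_frames))
  invisible(x)
}

# piecewise-linear total-cluster-area ramp: 1 at onset (t = 0), reaching
# cluster_area_growth_factor at growth_ramp_min, then cluster_size_factor
# at size_peak_min, then flat. t in minutes after treatment onset.
area_ramp <- function(cfg, t_min) {
  g <- cfg$cluster_area_growth_factor
  s2 <- cfg$cluster_size_factor
  t1 <- cfg$growth_ramp_min
  t2 <- cfg$size_peak_min
  vapply(t_min, function(t) {
    if (t <= 0) 1
    else if (t <= t1) 1 + (g - 1) * t / t1
    else if (t <= t2) g + (s2 - g) * (t - t1) / (t2 - t1)
    else s2
  }, numeric(1))
}

# closed-form diffuse level conserving band+blob intensity while the
# supra-threshold blob area scales by `fac`; amplitude is recomputed so
# amplitude / (threshold - diffuse) stays fixed, which makes the measured
# area ramp exact.
diffuse_schedule <- function(cfg, fac) {
  sigma_px <- cfg$cluster_sigma_um / cfg$pixel_size_um
  band_px <- cfg$width_px *
    (2 * floor(cfg$dendrite_width_um / cfg$pixel_size_um / 2) + 1)
  k <- cfg$blob_amplitude / (cfg$threshold - cfg$diffuse_level)
  mass0 <- cfg$n_clusters * cfg$blob_amplitude * 2 * pi * sigma_px^2
  C <- band_px * cfg$diffuse_level + mass0
  M <- cfg$n_clusters * k * 2 * pi * sigma_px^2 * fac
  d <- (C - M * cfg$threshold) / (band_px - M)
  list(diffuse = d, amplitude = k * (cfg$threshold - d),
       sigma_px = sigma_px * sqrt(fac))
}

# deterministic layout of cluster arclength positions (um): evenly spaced
# with sub-pixel jitter, clear of the image margins
cluster_layout <- function(cfg) {
  len_um <- (cfg$width_px - 1) * cfg$pixel_size_um
  margin <- 2
  base <- seq(margin, len_um - margin, length.out = cfg$n_clusters)
  jitter <- stats::runif(cfg$n_clusters, -0.4, 0.4)
  pos <- base + jitter
  tibble::tibble(cluster_id = seq_len(cfg$n_clusters), position_um = pos)
}

render_frame <- function(cfg, clusters, sched, noise = TRUE) {
  h <- cfg$height_px; w <- cfg$width_px
  y0 <- (h + 1) / 2
  half <- floor(cfg$dendrite_width_um / cfg$pixel_size_um / 2)
  img <- matrix(cfg$background_level, h, w)
  band_rows <- (round(y0) - half):(round(y0) + half)
  img[band_rows, ] <- sched$diffuse
  sig <- sched$sigma_px
  ext <- ceiling(4 * sig)
  for (i in seq_len(nrow(clusters))) {
    cx <- clusters$position_um[i] / cfg$pixel_size_um + 1
    cy <- y0
    xs <- max(1, floor(cx - ext)):min(w, ceiling(cx + ext))
    ys <- max(1, floor(cy - ext)):min(h, ceiling(cy + ext))
    blob <- sched$amplitude *
      exp(-outer((ys - cy)^2, (xs - cx)^2, "+") / (2 * sig^2))
    img[ys, xs] <- img[ys, xs] + blob
  }
  if (noise && cfg$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(h * w, 0, cfg$noise_sd), h, w)
  }
  img <- pmin(pmax(img, 0), 1)
  projection(img, pixel_size_um = cfg$pixel_size_um, unit_scaled = TRUE)
}

dendrite_skeleton <- function(cfg) {
  sk <- matrix(0, cfg$height_px, cfg$width_px)
  sk[round((cfg$height_px + 1) / 2), ] <- 1
  skeleton_image(sk, pixel_size_um = cfg$pixel_size_um)
}

#' Generate a single synthetic dendrite projection with ground truth
#'
#' Renders a straight dendrite band at the diffuse cytoplasmic level with
#' `n_clusters` Gaussian blobs on it plus Gaussian photon-like noise,
#' clipped to \[0, 1\]. All randomness flows from `config$seed`.
#'
#' @param config A [preset_config()].
#' @return List with `projection` (unit-scaled), `skeleton`
#'   (one-pixel dendrite curve) and `truth` (cluster layout tibble with the
#'   analytic supra-threshold area of each blob, the diffuse level, and the
#'   noiseless image).
#' @export
generate_projection <- function(config) {
  stopifnot(inherits(config, "spq_preset"))
  sigma_px <- config$cluster_sigma_um / config$pixel_size_um
  if (6 * sigma_px > min(config$width_px, config$height_px)) {
    stop("cluster sigma larger than the image")
  }
  set.seed(config$seed)
  clusters <- cluster_layout(config)
  sched <- diffuse_schedule(config, 1)
  noiseless <- render_frame(config, clusters, sched, noise = FALSE)
  proj <- render_frame(config, clusters, sched, noise = TRUE)
  r_px <- sched$sigma_px *
    sqrt(2 * log(sched$amplitude / (config$threshold - sched$diffuse)))
  clusters$area_um2 <- pi * r_px^2 * config$pixel_size_um^2
  list(projection = proj,
       skeleton = dendrite_skeleton(config),
       truth = list(clusters = clusters, diffuse = sched$diffuse,
                    amplitude = sched$amplitude, noiseless = noiseless))
}

#' Generate a ground-truthed synthetic time-lapse
#'
#' Baseline frames hold stationary clusters; from the treatment frame
#' onward the supra-threshold total cluster area follows a piecewise-linear
#' ramp reaching `cluster_area_growth_factor` at +6 min and
#' `cluster_size_factor` at +9 min (within the first 10 min), with the
#' diffuse pool shrinking so the summed band intensity is conserved —
#' emulating diffuse-to-cluster redistribution under stable overall image
#' intensity. Protrusion births are drawn per frame as a Poisson process at
#' the configured spine-gain or protrusion-rate program; each birth is
#' placed at an existing cluster (present at least one frame earlier,
#' within 1 um) with probability `precedence_prob`, else at a cluster-free
#' site.
#'
#' @param config A [preset_config()].
#' @param render If `FALSE`, skip image rendering and return ground-truth
#'   tables only (event/track analyses need no pixels).
#' @return List: `frames` (list of unit-scaled projections, or `NULL`),
#'   `skeleton`, `treatment_frame`, `dendrite_length_um`, and `truth` with
#'   `tracks` (cluster_id, frame, position_um, area_um2), `births`
#'   (birth_frame, position_um, from_cluster, cluster_id), `protrusions`
#'   (frame, position_um for every frame), `existing` positions, and the
#'   per-frame `area_factor` / `diffuse` schedules.
#' @export
generate_timelapse <- function(config, render = TRUE) {
  stopifnot(inherits(config, "spq_preset"))
  set.seed(config$seed)
  n_frames <- config$n_frames
  tf <- if (!is.na(config$epoch_frames)) config$epoch_frames + 1L else NA_integer_
  len_um <- (config$width_px - 1) * config$pixel_size_um
  clusters <- cluster_layout(config)
  t_post <- if (is.na(tf)) rep(0, n_frames) else
    (seq_len(n_frames) - tf + 1) * config$frame_time_min
  fac <- area_ramp(config, t_post)

  # birth program
  lambda <- birth_lambda(config, t_post, len_um)
  existing <- sort(stats::runif(config$n_existing_spines, 0.5, len_um - 0.5))
  pos_now <- existing
  births <- list()
  for (i in 2:n_frames) {
    nb <- stats::rpois(1, lambda[i])
    for (b in seq_len(nb)) {
      from_cluster <- !is.na(config$precedence_prob) &&
        stats::runif(1) < config$precedence_prob
      p <- place_birth(clusters$position_um, pos_now, len_um, from_cluster)
      if (is.null(p)) next  # no admissible site; skip this birth
      births[[length(births) + 1]] <- tibble::tibble(
        birth_frame = i, position_um = p$pos,
        from_cluster = from_cluster,
        cluster_id = p$cluster_id)
      pos_now <- c(pos_now, p$pos)
    }
  }
  births <- if (length(births)) dplyr::bind_rows(births) else
    tibble::tibble(birth_frame = integer(0), position_um = numeric(0),
                   from_cluster = logical(0), cluster_id = integer(0))
  protrusions <- protrusion_table(existing, births, n_frames)

  # cluster tracks with the analytic supra-threshold areas
  scheds <- lapply(fac, function(f) diffuse_schedule(config, f))
  tracks <- dplyr::bind_rows(lapply(seq_len(n_frames), function(i) {
    s <- scheds[[i]]
    r_px <- s$sigma_px *
      sqrt(2 * log(s$amplitude / (config$threshold - s$diffuse)))
    tibble::tibble(cluster_id = clusters$cluster_id, frame = i,
                   position_um = clusters$position_um,
                   area_um2 = pi * r_px^2 * config$pixel_size_um^2)
  }))

  frames <- NULL
  if (render) {
    frames <- lapply(seq_len(n_frames), function(i) {
      render_frame(config, clusters, scheds[[i]], noise = TRUE)
    })
  }
  list(frames = frames,
       skeleton = dendrite_skeleton(config),
       treatment_frame = tf,
       dendrite_length_um = len_um,
       frame_time_min = config$frame_time_min,
       truth = list(tracks = tracks, births = births,
                    protrusions = protrusions, existing = existing,
                    area_factor = fac,
                    diffuse = vapply(scheds, `[[`, numeric(1), "diffuse")))
}

# expected births per frame interval
birth_lambda <- function(config, t_post, len_um) {
  ft <- config$frame_time_min
  if (!is.na(config$protrusion_rate_per_10um_min)) {
    rep(config$protrusion_rate_per_10um_min * (len_um / 10) * ft,
        length(t_post))
  } else {
    gain <- ifelse(t_post > 0, config$spine_gain_per_h, 1.0)
    config$n_existing_spines * (gain / 100) * (ft / 60)
  }
}

# place one birth: at a cluster (within the association radius, clear of
# current protrusions) or at a cluster-free site; NULL when rejection
# sampling finds no admissible position. Clearance only enforces physical
# distinctness; frame-to-frame identification is exact for persistent
# protrusions because matching consumes zero-distance pairs first.
place_birth <- function(cluster_pos, pos_now, len_um, from_cluster,
                        clearance_um = 0.2, free_margin_um = 1.2) {
  for (try in 1:200) {
    if (from_cluster) {
      cid <- sample.int(length(cluster_pos), 1)
      p <- cluster_pos[cid] + stats::runif(1, -0.5, 0.5)
    } else {
      cid <- NA_integer_
      p <- stats::runif(1, 0.3, len_um - 0.3)
      if (length(cluster_pos) &&
          min(abs(p - cluster_pos)) < free_margin_um) next
    }
    if (length(pos_now) && min(abs(p - pos_now)) < clearance_um) next
    return(list(pos = p, cluster_id = cid))
  }
  NULL
}

protrusion_table <- function(existing, births, n_frames) {
  dplyr::bind_rows(lapply(seq_len(n_frames), function(i) {
    pos <- c(existing, births$position_um[births$birth_frame <= i])
    tibble::tibble(frame = i, position_um = sort(pos))
  }))
}

#' Generate a ground-truthed table of spine geometries
#'
#' Samples per-class geometry from ranges guaranteed to satisfy the class's
#' retention and classification rules, with the intended class stored as
#' ground truth.
#'
#' @param config A [preset_config()] (supplies the seed).
#' @param n_spines Number of rows.
#' @param class_mix Named numeric vector of class proportions over
#'   `stubby`, `thin`, `mushroom`; must sum to 1.
#' @return Tibble with geometry columns, plus `true_class`.
#' @export
generate_spine_table <- function(config, n_spines,
                                 class_mix = c(stubby = 0.3, thin = 0.4,
                                               mushroom = 0.3)) {
  stopifnot(inherits(config, "spq_preset"))
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (any(class_mix < 0)) stop("class_mix proportions must be >= 0")
  set.seed(config$seed)
  if (n_spines == 0) {
    return(tibble::tibble(length_um = numeric(0),
                          head_diameter_um = numeric(0),
                          neck_diameter_um = numeric(0),
                          max_width_um = numeric(0),
                          volume_um3 = numeric(0),
                          true_class = character(0)))
  }
  cls <- sample(names(class_mix), n_spines, replace = TRUE,
                prob = class_mix)
  n <- n_spines
  head <- numeric(n); neck <- numeric(n); vol <- numeric(n)
  len <- numeric(n); wid <- numeric(n)
  is_m <- cls == "mushroom"; is_s <- cls == "stubby"; is_t <- cls == "thin"
  head[is_m] <- stats::runif(sum(is_m), 0.40, 0.80)
  neck[is_m] <- head[is_m] / stats::runif(sum(is_m), 1.2, 2.0)
  vol[is_m] <- stats::runif(sum(is_m), 0.05, 0.30)
  len[is_m] <- stats::runif(sum(is_m), 0.5, 2.0)
  head[is_s] <- stats::runif(sum(is_s), 0.15, 0.30)
  neck[is_s] <- NA_real_  # neck often unresolvable for stubby morphology
  vol[is_s] <- stats::runif(sum(is_s), 0.045, 0.20)
  len[is_s] <- stats::runif(sum(is_s), 0.15, 0.8)
  head[is_t] <- stats::runif(sum(is_t), 0.15, 0.30)
  neck[is_t] <- head[is_t] / stats::runif(sum(is_t), 1.0, 1.05)
  vol[is_t] <- stats::runif(sum(is_t), 0.021, 0.0395)
  len[is_t] <- stats::runif(sum(is_t), 0.8, 3.0)
  wid <- stats::runif(n, 0.3, 1.5)
  tibble::tibble(length_um = len, head_diameter_um = head,
                 neck_diameter_um = neck, max_width_um = wid,
                 volume_um3 = vol, true_class = cls)
}

#' Simulate a cohort of spine-gain measurements
#'
#' One-hour new-spine program of a preset: per neuron the number of new
#' spines is Poisson with mean `n_existing x gain/100 x hours`, and the
#' gain is reported as percent of existing spines.
#'
#' @param config A [preset_config()] (uses `spine_gain_per_h`,
#'   `n_existing_spines` and the seed).
#' @param n_neurons Number of neurons.
#' @param duration_min Observation window (default 60 min).
#' @return Tibble: `neuron`, `n_existing`, `n_new`, `gain_percent`.
#' @export
simulate_spine_gain <- function(config, n_neurons, duration_min = 60) {
  stopifnot(inherits(config, "spq_preset"))
  set.seed(config$seed)
  n_ex <- sample(30:50, n_neurons, replace = TRUE)
  lam <- n_ex * (config$spine_gain_per_h / 100) * (duration_min / 60)
  n_new <- stats::rpois(n_neurons, lam)
  tibble::tibble(neuron = seq_len(n_neurons), n_existing = n_ex,
                 n_new = n_new,
                 gain_percent = spine_gain_percent(n_new, n_ex))
}

#' Generate a channel pair with a programmed Pearson correlation
#'
#' Pixels are jointly Gaussian with correlation `true_pcc`, then each
#' channel is affinely rescaled to \[0, 1\] (which preserves the
#' correlation).
#'
#' @param config A [preset_config()] (supplies the seed and image size).
#' @param true_pcc Target correlation in \[-1, 1\].
#' @param side Image side length in pixels (default 100).
#' @return List with projections `ch1`, `ch2` and a full-image `roi`.
#' @export
generate_coloc_pair <- function(config, true_pcc, side = 100L) {
  stopifnot(inherits(config, "spq_preset"))
  if (abs(true_pcc) > 1) stop("|true_pcc| must be <= 1")
  set.seed(config$seed)
  n <- side * side
  z1 <- stats::rnorm(n)
  z2 <- true_pcc * z1 + sqrt(1 - true_pcc^2) * stats::rnorm(n)
  unit <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) v * 0 else (v - r[1]) / diff(r)
  }
  ch1 <- projection(matrix(unit(z1), side, side),
                    pixel_size_um = config$pixel_size_um, unit_scaled = TRUE)
  ch2 <- projection(matrix(unit(z2), side, side),
                    pixel_size_um = config$pixel_size_um, unit_scaled = TRUE)
  roi <- roi_mask(matrix(1, side, side),
                  pixel_size_um = config$pixel_size_um)
  list(ch1 = ch1, ch2 = ch2, roi = roi)
}
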