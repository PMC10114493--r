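#' Detect new-protrusion events between consecutive frames
#'
#' Compares each frame with the previous one: a protrusion position with no
#' match within `match_radius_um` in the previous frame is a birth event.
#' Matching is greedy nearest-first (ties broken by lower arclength), so a
#' persistent protrusion produces at most one event. Nothing can be born in
#' the first observed frame.
#'
#' @param protrusions Per-frame protrusion positions: either a data frame
#'   with columns `frame` (1-based, consecutive) and `position_um`
#'   (arclength along the dendrite skeleton), or a list of numeric position
#'   vectors, one per frame.
#' @param match_radius_um Maximum displacement identifying the same
#'   protrusion across frames (default 0.5 um).
#' @return Tibble of events: `birth_frame`, `position_um`,
#'   `curvature_flag` (always `"unannotated"`; membrane curvature is a
#'   manual annotation, not computed).
#' @export
detect_new_protrusions <- function(protrusions, match_radius_um = 0.5) {
  fr <- as_frame_list(protrusions)
  if (length(fr) < 2) stop("need at least 2 frames")
  out <- list()
  for (t in 2:length(fr)) {
    cur <- sort(fr[[t]])
    prev <- fr[[t - 1]]
    born <- cur[!greedy_match(cur, prev, match_radius_um)]
    if (length(born)) {
      out[[length(out) + 1]] <- tibble::tibble(birth_frame = t,
                                               position_um = born)
    }
  }
  ev <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(birth_frame = integer(0), position_um = numeric(0))
  ev$curvature_flag <- factor(rep("unannotated", nrow(ev)),
                              levels = c("curved", "flat", "unannotated"))
  ev
}

as_frame_list <- function(protrusions) {
  if (is.data.frame(protrusions)) {
    stopifnot(all(c("frame", "position_um") %in% names(protrusions)))
    f <- protrusions$frame
    if (any(diff(order(f)) < 0)) stop("frames must be sorted")
    nmax <- max(f, 1L)
    lapply(seq_len(nmax), function(i) protrusions$position_um[f == i])
  } else if (is.list(protrusions)) {
    protrusions
  } else stop("protrusions must be a data frame or list of position vectors")
}

# TRUE for each element of `cur` that is matched to a distinct element of
# `prev` within `radius`, greedily by increasing distance
greedy_match <- function(cur, prev, radius) {
  matched <- logical(length(cur))
  if (length(cur) == 0 || length(prev) == 0) return(matched)
  d <- abs(outer(cur, prev, "-"))
  cand <- which(d <= radius, arr.ind = TRUE)
  if (nrow(cand) == 0) return(matched)
  ord <- order(d[cand], cur[cand[, 1]])
  cand <- cand[ord, , drop = FALSE]
  used_prev <- logical(length(prev))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!matched[i] && !used_prev[j]) {
      matched[i] <- TRUE
      used_prev[j] <- TRUE
    }
  }
  matched
}

#' New-protrusion rate per 10 um of dendrite per minute
#'
#' @param events Event tibble from [detect_new_protrusions()], or an event
#'   count.
#' @param dendrite_length_um Positive dendrite length.
#' @param duration_min Positive observation time in minutes.
#' @return Rate in protrusions / 10 um / min.
#' @export
protrusion_rate <- function(events, dendrite_length_um, duration_min) {
  if (dendrite_length_um <= 0) stop("dendrite_length_um must be > 0")
  if (duration_min <= 0) stop("duration_min must be > 0")
  n <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  n / (dendrite_length_um / 10) / duration_min
}

#' Spine gain as percent of existing spines
#'
#' New spines divided by the total number of existing spines, in percent
#' (e.g. 13 new per 100 existing = 13 %).
#'
#' @param n_new Number of new spines.
#' @param n_total_existing Positive total spine count.
#' @return Percentage.
#' @export
spine_gain_percent <- function(n_new, n_total_existing) {
  if (any(n_total_existing <= 0)) stop("n_total_existing must be > 0")
  100 * n_new / n_total_existing
}

#' Link birth events to spatiotemporally preceding clusters
#'
#' An event is linked iff some cluster track was already present at least
#' `min_precede_frames` before the birth frame and its centroid at frame
#' `birth_frame - min_precede_frames` lies within `radius_um` of the birth
#' position; the nearest qualifying track wins. Events and tracks must
#' share the frame clock and the arclength coordinate.
#'
#' @param events Tibble with `birth_frame`, `position_um`.
#' @param tracks Tibble of per-frame cluster positions with columns
#'   `cluster_id`, `frame`, `position_um` (and optionally `area_um2`);
#'   frames of a track are contiguous from its first frame.
#' @param radius_um Association radius (default 1.0 um, the spine-neck
#'   scale).
#' @param min_precede_frames Minimum number of frames the cluster must
#'   precede the birth (default 1).
#' @return A list: `events` (input plus `linked_cluster_id`, NA when
#'   unlinked) and `percent_from_clusters` (100 x linked / total; NA with a
#'   message when there are no events).
#' @export
associate_with_clusters <- function(events, tracks, radius_um = 1.0,
                                    min_precede_frames = 1L) {
  events <- tibble::as_tibble(events)
  tracks <- tibble::as_tibble(tracks)
  linked <- rep(NA_integer_, nrow(events))
  if (nrow(events) > 0 && nrow(tracks) > 0) {
    first_frame <- tapply(tracks$frame, tracks$cluster_id, min)
    for (i in seq_len(nrow(events))) {
      ref_frame <- events$birth_frame[i] - min_precede_frames
      cand <- tracks[tracks$frame == ref_frame, , drop = FALSE]
      if (nrow(cand) == 0) next
      ok <- first_frame[as.character(cand$cluster_id)] <= ref_frame
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) == 0) next
      dist <- abs(cand$position_um - events$position_um[i])
      j <- which.min(dist)
      if (dist[j] <= radius_um) linked[i] <- cand$cluster_id[j]
    }
  }
  events$linked_cluster_id <- linked
  pct <- if (nrow(events) > 0) 100 * mean(!is.na(linked)) else NA_real_
  list(events = events, percent_from_clusters = pct)
}

#' Pool birth events into pre- and post-treatment epochs
#'
#' Counts events (and cluster-linked events, when annotated) in the
#' `epoch_n_frames` frames before the treatment frame and the
#' `epoch_n_frames` frames from it onward. With 3-min frames the default 15
#' frames per epoch corresponds to 45-min epochs.
#'
#' @param events Tibble with `birth_frame` (and optionally
#'   `linked_cluster_id`).
#' @param treatment_frame 1-based index of the first post-treatment frame.
#' @param epoch_n_frames Frames per epoch (default 15).
#' @param n_frames Total frames in the series, used to check the epochs fit.
#' @return Tibble with one row per epoch: `epoch`, `frame_start`,
#'   `frame_end`, `n_events`, `n_linked`.
#' @export
pool_epochs <- function(events, treatment_frame, epoch_n_frames = 15L,
                        n_frames = NULL) {
  pre_lo <- treatment_frame - epoch_n_frames
  post_hi <- treatment_frame + epoch_n_frames - 1
  if (pre_lo < 1) stop("pre-treatment epoch extends before the series")
  if (!is.null(n_frames) && post_hi > n_frames) {
    stop("post-treatment epoch extends beyond the series")
  }
  bf <- events$birth_frame
  has_lk <- "linked_cluster_id" %in% names(events)
  lk <- if (has_lk) !is.na(events$linked_cluster_id) else logical(length(bf))
  pre <- bf >= pre_lo & bf < treatment_frame
  post <- bf >= treatment_frame & bf <= post_hi
  tibble::tibble(
    epoch = c("pre", "post"),
    frame_start = c(pre_lo, treatment_frame),
    frame_end = c(treatment_frame - 1, post_hi),
    n_events = c(sum(pre), sum(post)),
    n_linked = if (has_lk) c(sum(lk & pre), sum(lk & post)) else
      c(NA_integer_, NA_integer_))
}
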