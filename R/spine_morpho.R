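#' Retention filter for candidate spines
#'
#' A measured protrusion is retained as a spine iff its volume is at least
#' 0.020 um^3, its length lies between 0.1 and 5 um (inclusive) and its
#' maximal width is at most 3 um. Thresholds are read inclusively
#' ("minimum of x" means >= x). Volumes are taken in um^3 rather than voxel
#' counts so the rule is resolution-independent (see the methods vignette
#' for the voxel-count discrepancy this sidesteps).
#'
#' @param spines Data frame with numeric columns `length_um`,
#'   `max_width_um`, `volume_um3` (plus `head_diameter_um`,
#'   `neck_diameter_um` for classification). One row per protrusion.
#' @param min_volume_um3,min_length_um,max_length_um,max_width_um The
#'   retention thresholds.
#' @return The input as a tibble with a logical `retained` column added.
#' @export
retain_spines <- function(spines, min_volume_um3 = 0.020,
                          min_length_um = 0.1, max_length_um = 5,
                          max_width_um = 3) {
  spines <- tibble::as_tibble(spines)
  check_geometry(spines)
  spines$retained <- spines$volume_um3 >= min_volume_um3 &
    spines$length_um >= min_length_um &
    spines$length_um <= max_length_um &
    spines$max_width_um <= max_width_um
  spines
}

check_geometry <- function(spines) {
  geo <- intersect(c("length_um", "head_diameter_um", "neck_diameter_um",
                     "max_width_um", "volume_um3"), names(spines))
  for (col in geo) {
    v <- spines[[col]]
    if (any(!is.na(v) & v < 0)) stop("negative geometry in column ", col)
  }
  invisible(spines)
}

#' Classify retained spines as stubby, thin or mushroom
#'
#' A spine is a mushroom iff its head diameter is at least 0.35 um and its
#' head/neck diameter ratio is at least 1.1; an absent neck diameter leaves
#' the ratio undefined (not infinite) and disqualifies mushroom. Among
#' non-mushroom spines, those with volume at least 0.040 um^3 are stubby;
#' all others are thin. Rows failing the retention filter are labelled
#' `"rejected"`.
#'
#' @inheritParams retain_spines
#' @param min_head_um Mushroom head-diameter minimum (0.35 um).
#' @param min_head_neck_ratio Mushroom head/neck ratio minimum (1.1).
#' @param stubby_min_volume_um3 Stubby volume minimum (0.040 um^3).
#' @return The input as a tibble with `retained` and factor `spine_class`
#'   (`stubby`, `thin`, `mushroom`, `rejected`) columns added.
#' @export
classify_spines <- function(spines, min_volume_um3 = 0.020,
                            min_length_um = 0.1, max_length_um = 5,
                            max_width_um = 3, min_head_um = 0.35,
                            min_head_neck_ratio = 1.1,
                            stubby_min_volume_um3 = 0.040) {
  sp <- retain_spines(spines, min_volume_um3, min_length_um, max_length_um,
                      max_width_um)
  neck <- sp$neck_diameter_um
  ratio <- ifelse(!is.na(neck) & neck > 0, sp$head_diameter_um / neck,
                  NA_real_)
  mushroom <- !is.na(sp$head_diameter_um) &
    sp$head_diameter_um >= min_head_um &
    !is.na(ratio) & ratio >= min_head_neck_ratio
  stubby <- !mushroom & sp$volume_um3 >= stubby_min_volume_um3
  cls <- ifelse(!sp$retained, "rejected",
                ifelse(mushroom, "mushroom",
                       ifelse(stubby, "stubby", "thin")))
  sp$spine_class <- factor(cls, levels = c("stubby", "thin", "mushroom",
                                           "rejected"))
  sp
}

#' Spine densities per micrometre of dendrite
#'
#' Counts retained spines (total and per class) and divides by the dendrite
#' length, giving spines per 1 um of dendrite.
#'
#' @param spines Data frame already passed through [classify_spines()], or
#'   raw geometry which will be classified with default thresholds.
#' @param dendrite_length_um Positive dendrite length in micrometres.
#' @return A one-row tibble: `dendrite_length_um`, `n_spines`,
#'   `density_total`, `density_stubby`, `density_thin`, `density_mushroom`.
#' @export
spine_density <- function(spines, dendrite_length_um) {
  if (dendrite_length_um <= 0) stop("dendrite_length_um must be > 0")
  spines <- tibble::as_tibble(spines)
  if (!"spine_class" %in% names(spines)) spines <- classify_spines(spines)
  kept <- spines[!is.na(spines$spine_class) &
                   spines$spine_class != "rejected", ]
  cnt <- table(factor(kept$spine_class,
                      levels = c("stubby", "thin", "mushroom")))
  tibble::tibble(
    dendrite_length_um = dendrite_length_um,
    n_spines = nrow(kept),
    density_total = nrow(kept) / dendrite_length_um,
    density_stubby = unname(cnt["stubby"]) / dendrite_length_um,
    density_thin = unname(cnt["thin"]) / dendrite_length_um,
    density_mushroom = unname(cnt["mushroom"]) / dendrite_length_um)
}
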