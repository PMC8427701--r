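#' Full bone-measurement pipeline
#'
#' Runs threshold -> slice-wise clean-up -> 3D labelling -> volume filter
#' -> landmark resolution -> per-bone measurement on a calibrated volume
#' and returns one measurement record per resolved element. Landmarks that
#' resolve to one shared component are reported as a single composite
#' record whose bone name joins the members (e.g. `"TIBIA+FIBULA"`).
#'
#' @param volume a [ct_volume()] in HU (apply [gv_to_hu()] first if raw).
#' @param landmarks a `landmark_set` (see [landmarks()], [read_landmarks()]).
#' @param threshold_hu lower threshold in HU; alternatively give `stage`
#'   (+ `level`, `profile`) for a preset, or `"auto"` for the
#'   maximum-entropy threshold.
#' @param stage,level,profile preset lookup, see [preset_threshold()].
#' @param cleanup apply the 2D clean-up chain ([cleanup_mask()]); skipping
#'   it measures the raw thresholded mask.
#' @param connectivity 3D labelling connectivity (6, 18 or 26).
#' @param min_voxels component volume floor; `NULL` uses
#'   [default_min_voxels()] scaled to the volume's spacing.
#' @param specimen,batch,condition metadata copied into every record.
#' @param review print per-landmark resolution lines for auditing.
#' @param ... passed to [cleanup_mask()].
#' @return data.frame of measurement records (see [measure_component()]).
#' @export
measure_bones <- function(volume, landmarks, threshold_hu = NULL,
                          stage = NULL, level = "low",
                          profile = "mimics-style", cleanup = TRUE,
                          connectivity = 26, min_voxels = NULL,
                          specimen = "", batch = "", condition = "",
                          review = FALSE, ...) {
  stopifnot(inherits(volume, "ct_volume"))
  if (is.null(threshold_hu)) {
    if (!is.null(stage)) {
      threshold_hu <- preset_threshold(stage, level, profile)
    } else {
      threshold_hu <- max_entropy_threshold(compute_histogram(volume))
    }
  } else if (identical(threshold_hu, "auto")) {
    threshold_hu <- max_entropy_threshold(compute_histogram(volume))
  }
  mask <- apply_threshold(volume, threshold_hu)
  if (cleanup) mask <- cleanup_mask(mask, ...)
  labs <- label_components_3d(mask, connectivity)
  if (is.null(min_voxels)) min_voxels <- default_min_voxels(volume$spacing)
  labs <- filter_by_volume(labs, min_voxels)
  map <- assign_labels(labs, landmarks, review = review)
  ent <- map$entries
  rows <- lapply(unique(ent$label), function(lb) {
    members <- ent[ent$label == lb, , drop = FALSE]
    composite <- nrow(members) > 1
    bone <- paste(members$bone, collapse = "+")
    sides <- unique(members$side)
    side <- if (length(sides) == 1) sides else NA_character_
    comp <- bone_component(labs, lb, bone = bone, side = side,
                           composite = composite)
    measure_component(comp, specimen = specimen, batch = batch,
                      condition = condition, threshold_hu = threshold_hu)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
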