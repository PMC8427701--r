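#' Construct a calibrated CT volume
#'
#' A `ct_volume` wraps a 3D scalar grid indexed `[slice, row, column]`
#' (0-based in all user-facing coordinates) together with its physical voxel
#' spacing in micrometres and a linear Hounsfield calibration
#' `HU = GV * calib_slope + calib_intercept`.
#'
#' @param data 3D numeric array, dimension order (slice, row, column).
#' @param spacing numeric length-3, voxel edge lengths in um per axis
#'   (slice, row, column); all > 0.
#' @param calib_slope,calib_intercept linear HU calibration coefficients.
#' @param source_id free-text provenance string.
#' @return An object of class `ct_volume`.
#' @examples
#' v <- ct_volume(array(0, c(4, 4, 4)), spacing = c(20, 20, 20))
#' dim(v$data)
#' @export
ct_volume <- function(data, spacing, calib_slope = 1, calib_intercept = 0,
                      source_id = "") {
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3D array (slice, row, column)")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive values (um)")
  if (any(dim(data) < 1L)) stop("grid must have at least 1 voxel per axis")
  structure(
    list(data = data, spacing = spacing,
         calib_slope = as.numeric(calib_slope),
         calib_intercept = as.numeric(calib_intercept),
         source_id = as.character(source_id)),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ct_volume: %d x %d x %d voxels (slice x row x col)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  spacing: %.6g x %.6g x %.6g um\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  calibration: HU = GV * %.6g + %.6g\n",
              x$calib_slope, x$calib_intercept))
  if (nzchar(x$source_id)) cat("  source:", x$source_id, "\n")
  invisible(x)
}

#' Binary mask on a voxel grid
#'
#' @param data 3D logical array, same shape as the parent volume.
#' @param spacing voxel spacing in um, inherited from the parent volume.
#' @return An object of class `bone_mask`.
#' @export
bone_mask <- function(data, spacing) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array")
  storage.mode(data) <- "logical"
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 positive values (um)")
  structure(list(data = data, spacing = spacing), class = "bone_mask")
}

#' @export
print.bone_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bone_mask: %d x %d x %d, %d foreground voxels\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' Labelled connected components on a voxel grid
#'
#' Label values are consecutive integers `1..n_labels`; 0 is background.
#'
#' @param data 3D integer array of labels.
#' @param spacing voxel spacing in um.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array")
  storage.mode(data) <- "integer"
  if (any(data < 0L)) stop("labels must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  n <- if (any(data > 0L)) max(data) else 0L
  present <- sort(unique(data[data > 0L]))
  if (length(present) && !identical(as.integer(present), seq_len(n)))
    stop("label values must be 1..n_labels with no gaps")
  structure(list(data = data, spacing = spacing, n_labels = as.integer(n)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("label_volume: %d x %d x %d, %d labels\n",
              d[1], d[2], d[3], x$n_labels))
  invisible(x)
}

#' Convert raw gray values to Hounsfield units
#'
#' Applies the volume's linear calibration `HU = GV * slope + intercept`
#' voxel-wise. Scanner exports often store uncalibrated gray values; an
#' identity calibration is accepted with a warning so that empirically tuned
#' thresholds can still be applied on the raw scale.
#'
#' @param volume a [ct_volume()] holding gray values.
#' @return A `ct_volume` in HU with identity calibration recorded.
#' @examples
#' v <- ct_volume(array(1424, c(1, 1, 1)), 20, calib_slope = 1,
#'                calib_intercept = -1024)
#' gv_to_hu(v)$data[1, 1, 1]  # 400 HU
#' @seealso [hu_to_gv()]
#' @export
gv_to_hu <- function(volume) {
  stopifnot(inherits(volume, "ct_volume"))
  if (volume$calib_slope == 1 && volume$calib_intercept == 0)
    warning("identity calibration: gray values already equal HU")
  out <- volume
  out$data <- volume$data * volume$calib_slope + volume$calib_intercept
  out$calib_slope <- 1
  out$calib_intercept <- 0
  attr(out, "orig_calib") <- c(volume$calib_slope, volume$calib_intercept)
  out
}

#' Convert Hounsfield units back to gray values
#'
#' Inverse of [gv_to_hu()] under the calibration `(slope, intercept)`.
#'
#' @param volume a `ct_volume` in HU.
#' @param calib_slope,calib_intercept the calibration to invert.
#' @return A `ct_volume` holding gray values with that calibration attached.
#' @export
hu_to_gv <- function(volume, calib_slope = 1, calib_intercept = 0) {
  stopifnot(inherits(volume, "ct_volume"))
  if (calib_slope == 0) stop("calibration slope must be non-zero")
  out <- volume
  out$data <- (volume$data - calib_intercept) / calib_slope
  out$calib_slope <- calib_slope
  out$calib_intercept <- calib_intercept
  out
}

#' Emulate detector binning by block averaging
#'
#' Down-samples the volume by non-overlapping block means, emulating on-chip
#' detector binning (e.g. 2x2 for 20 um acquisitions re-binned to 40 um).
#' Voxel spacing is multiplied by the factor; trailing partial blocks are
#' dropped with a message.
#'
#' @param volume a [ct_volume()].
#' @param factor positive integer(s), one per axis (recycled from length 1).
#' @return The binned `ct_volume`.
#' @examples
#' v <- ct_volume(array(1, c(4, 4, 4)), 20)
#' downsample_binning(v, 2)$spacing  # 40 40 40
#' @export
downsample_binning <- function(volume, factor) {
  stopifnot(inherits(volume, "ct_volume"))
  factor <- as.integer(factor)
  if (length(factor) == 1L) factor <- rep(factor, 3L)
  if (length(factor) != 3L || any(is.na(factor)) || any(factor < 1L))
    stop("'factor' must be positive integers, one per axis")
  d <- dim(volume$data)
  if (any(factor > d))
    stop("binning factor exceeds grid extent (", paste(d, collapse = "x"), ")")
  keep <- (d %/% factor) * factor
  if (any(keep < d))
    message("downsample_binning: dropping trailing partial blocks (",
            paste(d - keep, collapse = ","), " voxels per axis)")
  x <- volume$data[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]),
                   drop = FALSE]
  nd <- keep %/% factor
  # block mean via one reshape per axis
  dim(x) <- c(factor[1], nd[1], keep[2], keep[3])
  x <- colMeans(x)                               # nd1 x keep2 x keep3
  dim(x) <- c(nd[1], factor[2], nd[2], keep[3])
  x <- aperm(x, c(2, 1, 3, 4))
  x <- colMeans(x)                               # nd1 x nd2 x keep3
  dim(x) <- c(nd[1], nd[2], factor[3], nd[3])
  x <- aperm(x, c(3, 1, 2, 4))
  x <- colMeans(x)                               # nd1 x nd2 x nd3
  dim(x) <- nd
  out <- volume
  out$data <- x
  out$spacing <- volume$spacing * factor
  out
}
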