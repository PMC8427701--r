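# TIFF stack I/O with a plain-text sidecar for physical metadata.
# Sidecar (YAML key-value): spacing_um (3 values, slice/row/col),
# calib_slope, calib_intercept, source_id.

.read_sidecar <- function(path) {
  if (!file.exists(path))
    stop("sidecar metadata file not found: ", path,
         " (physical voxel spacing is required for length measurement)")
  meta <- yaml::read_yaml(path)
  if (is.null(meta$spacing_um))
    stop("sidecar lacks 'spacing_um'; lengths are physical, spacing is mandatory")
  meta
}

#' Read a TIFF raster stack with sidecar metadata
#'
#' Accepts either one multi-page TIFF or a directory of per-slice TIFFs
#' (sorted by file name). Physical spacing and calibration come from a
#' sidecar YAML file (`spacing_um`, optional `calib_slope`,
#' `calib_intercept`, `value_scale`, `source_id`); absent spacing is a hard
#' error since exported lengths are physical.
#'
#' @param path multi-page TIFF file or directory of per-slice TIFFs.
#' @param sidecar path to the sidecar file; default `<path>.yml` for a file
#'   or `metadata.yml` inside a directory.
#' @return A [ct_volume()].
#' @export
read_raster_stack <- function(path, sidecar = NULL) {
  if (dir.exists(path)) {
    # a stack we wrote ourselves records its own value encoding
    own <- file.path(path, "metadata.yml")
    if (file.exists(own) &&
        !is.null(yaml::read_yaml(own)$value_offset))
      return(read_written_stack(path))
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stop("no TIFF files in ", path)
    if (is.null(sidecar)) sidecar <- file.path(path, "metadata.yml")
    pages <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
  } else {
    if (is.null(sidecar)) sidecar <- paste0(path, ".yml")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (is.matrix(pages)) pages <- list(pages)
  }
  meta <- .read_sidecar(sidecar)
  d <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d), TRUE)))
    stop("inconsistent slice dimensions across TIFF pages")
  arr <- array(0, c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  scale <- if (is.null(meta$value_scale)) 1 else meta$value_scale
  ct_volume(arr * scale, spacing = meta$spacing_um,
            calib_slope = meta$calib_slope %||% 1,
            calib_intercept = meta$calib_intercept %||% 0,
            source_id = meta$source_id %||% paste0("tiff:", path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a volume, mask or label volume as a per-slice TIFF stack
#'
#' Writes one 16-bit TIFF per slice (`slice_0001.tif`, ...) plus a
#' `metadata.yml` sidecar recording spacing, calibration and the value scale
#' needed to recover the original intensities. Masks are written as 0/1,
#' label volumes as integer labels.
#'
#' @param x a [ct_volume()], [bone_mask()] or [label_volume()].
#' @param directory output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_raster_stack <- function(x, directory) {
  stopifnot(inherits(x, c("ct_volume", "bone_mask", "label_volume")))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  arr <- x$data
  if (is.logical(arr)) arr <- arr * 1L
  lo <- min(arr); hi <- max(arr)
  # 16-bit container; store (v - lo) / scale, record both in the sidecar
  scale <- if (hi > lo) (hi - lo) / 65535 else 1
  meta <- list(spacing_um = as.numeric(x$spacing),
               value_scale = scale * 65535,  # multiply stored [0,1] by this
               value_offset = lo,
               integer_values = all(arr == round(arr)),
               kind = class(x)[1])
  if (inherits(x, "ct_volume")) {
    meta$calib_slope <- x$calib_slope
    meta$calib_intercept <- x$calib_intercept
    meta$source_id <- x$source_id
  }
  yaml::write_yaml(meta, file.path(directory, "metadata.yml"))
  n <- dim(arr)[1]
  for (i in seq_len(n)) {
    page <- (arr[i, , ] - lo) / (if (hi > lo) hi - lo else 1)
    tiff::writeTIFF(page, file.path(directory, sprintf("slice_%04d.tif", i)),
                    bits.per.sample = 16)
  }
  invisible(directory)
}

#' Re-read a stack written by [write_raster_stack()]
#'
#' Inverse of [write_raster_stack()]: applies the recorded value scale and
#' offset so the round trip reproduces the original values (exactly for
#' integer-valued data within 16-bit range).
#'
#' @param directory the stack directory.
#' @return A [ct_volume()], [bone_mask()] or [label_volume()] per the
#'   sidecar's `kind`.
#' @export
read_written_stack <- function(directory) {
  meta <- .read_sidecar(file.path(directory, "metadata.yml"))
  files <- sort(list.files(directory, pattern = "\\.tiff?$",
                           full.names = TRUE, ignore.case = TRUE))
  if (!length(files)) stop("no TIFF slices in ", directory)
  pages <- lapply(files, tiff::readTIFF)
  d <- dim(pages[[1]])
  arr <- array(0, c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  arr <- round(arr * 65535) / 65535 * (meta$value_scale %||% 1) +
    (meta$value_offset %||% 0)
  if (isTRUE(meta$integer_values)) arr <- round(arr)
  kind <- meta$kind %||% "ct_volume"
  switch(kind,
    bone_mask = bone_mask(arr > 0.5, meta$spacing_um),
    label_volume = label_volume(array(as.integer(round(arr)), dim(arr)),
                                meta$spacing_um),
    ct_volume(arr, meta$spacing_um,
              calib_slope = meta$calib_slope %||% 1,
              calib_intercept = meta$calib_intercept %||% 0,
              source_id = meta$source_id %||% ""))
}
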