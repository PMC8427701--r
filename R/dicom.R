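# Minimal single-frame DICOM series reader (explicit VR, little endian).
# Covers the subset produced by micro-CT reconstruction exports: one series of
# single-frame CT slices with consistent geometry, 16-bit pixel data.

.dcm_uint <- function(raw) sum(as.integer(raw) * 256^(seq_along(raw) - 1))

.dcm_read_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  while (pos + 7L <= length(raw)) {
    group <- .dcm_uint(raw[pos:(pos + 1L)])
    elem  <- .dcm_uint(raw[(pos + 2L):(pos + 3L)])
    vr    <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- .dcm_uint(raw[(pos + 8L):(pos + 11L)])
      val_at <- pos + 12L
    } else {
      len <- .dcm_uint(raw[(pos + 6L):(pos + 7L)])
      val_at <- pos + 8L
    }
    key <- sprintf("%04x,%04x", group, elem)
    val_raw <- if (len > 0) raw[val_at:(val_at + len - 1L)] else raw[0]
    tags[[key]] <- list(vr = vr, raw = val_raw)
    pos <- val_at + len
    if (key == "7fe0,0010") break
  }
  tags
}

.dcm_str <- function(tags, key, default = NULL) {
  t <- tags[[key]]
  if (is.null(t)) return(default)
  trimws(rawToChar(t$raw))
}

.dcm_num <- function(tags, key, default = NULL) {
  t <- tags[[key]]
  if (is.null(t)) return(default)
  if (t$vr %in% c("US", "SS")) {
    v <- .dcm_uint(t$raw[1:2])
    if (t$vr == "SS" && v >= 32768) v <- v - 65536
    return(v)
  }
  as.numeric(strsplit(trimws(rawToChar(t$raw)), "\\\\")[[1]])
}

.dcm_pixels <- function(tags, rows, cols) {
  t <- tags[["7fe0,0010"]]
  if (is.null(t)) stop("no PixelData element")
  bits <- .dcm_num(tags, "0028,0100", 16)
  if (bits != 16) stop("only 16-bit pixel data supported (got ", bits, ")")
  signed <- isTRUE(.dcm_num(tags, "0028,0103", 0) == 1)
  v <- readBin(t$raw, "integer", n = rows * cols, size = 2,
               signed = signed, endian = "little")
  if (!signed) v[v < 0] <- v[v < 0] + 65536  # readBin size=2 unsigned cap
  matrix(v, nrow = rows, ncol = cols, byrow = TRUE)  # row-major in file
}

#' Read a single-frame DICOM CT series
#'
#' Reads every `.dcm` file in a directory (explicit-VR little-endian,
#' single-frame slices of one series), sorts slices by position along the
#' stack axis, and assembles a calibrated [ct_volume()]. Pixel spacing and
#' slice increment (DICOM millimetres) are converted to micrometres; rescale
#' slope/intercept become the HU calibration. Missing rescale tags default to
#' slope 1, intercept 0 with a warning, matching uncalibrated micro-CT
#' exports whose thresholds are tuned empirically on the raw scale.
#'
#' @param directory path containing the slice files.
#' @param pattern filename regexp, default `"\\.dcm$"` (case-insensitive).
#' @return A [ct_volume()] holding gray values with calibration attached.
#' @details Errors on mixed SeriesInstanceUIDs, inconsistent in-plane
#'   dimensions, and slice gaps deviating more than 1\% from the median
#'   increment (the offending slice positions are named).
#' @export
read_dicom_series <- function(directory, pattern = "\\.dcm$") {
  files <- list.files(directory, pattern = pattern, full.names = TRUE,
                      ignore.case = TRUE)
  if (!length(files)) stop("no DICOM files found in ", directory)
  slices <- lapply(files, .dcm_read_file)

  uid <- unique(vapply(slices, function(t)
    .dcm_str(t, "0020,000e", ""), ""))
  if (length(uid) > 1)
    stop("mixed series: ", length(uid), " distinct SeriesInstanceUIDs")

  rows <- vapply(slices, function(t) .dcm_num(t, "0028,0010"), 0)
  cols <- vapply(slices, function(t) .dcm_num(t, "0028,0011"), 0)
  if (length(unique(rows)) > 1 || length(unique(cols)) > 1)
    stop("inconsistent in-plane dimensions across slices")

  pos <- vapply(slices, function(t) {
    ipp <- .dcm_num(t, "0020,0032")
    if (!is.null(ipp) && length(ipp) >= 3) return(ipp[3])
    sl <- .dcm_num(t, "0020,1041")
    if (!is.null(sl)) return(sl[1])
    stop("slice has neither ImagePositionPatient nor SliceLocation")
  }, 0)
  ord <- order(pos)
  slices <- slices[ord]
  pos <- pos[ord]
  files <- files[ord]

  n <- length(slices)
  if (n > 1) {
    gaps <- diff(pos)
    ref <- stats::median(gaps)
    bad <- which(abs(gaps - ref) > 0.01 * abs(ref))
    if (length(bad))
      stop("non-uniform slice spacing: gap(s) at position(s) ",
           paste(sprintf("%.6g->%.6g (%.6g mm)", pos[bad], pos[bad + 1],
                         gaps[bad]), collapse = ", "),
           " deviate >1% from the median increment ", signif(ref, 6), " mm")
    dz_mm <- ref
  } else {
    dz_mm <- .dcm_num(slices[[1]], "0018,0050", 1)[1]  # SliceThickness
  }

  ps_mm <- .dcm_num(slices[[1]], "0028,0030")
  if (is.null(ps_mm) || length(ps_mm) < 2)
    stop("PixelSpacing tag (0028,0030) missing: physical lengths undefined")

  slope <- .dcm_num(slices[[1]], "0028,1053")
  inter <- .dcm_num(slices[[1]], "0028,1052")
  if (is.null(slope) || is.null(inter)) {
    warning("rescale tags absent; defaulting to slope 1, intercept 0 ",
            "(uncalibrated gray values)")
    if (is.null(slope)) slope <- 1
    if (is.null(inter)) inter <- 0
  }

  arr <- array(0, c(n, rows[1], cols[1]))
  for (i in seq_len(n))
    arr[i, , ] <- .dcm_pixels(slices[[i]], rows[1], cols[1])

  ct_volume(arr,
            spacing = c(abs(dz_mm), ps_mm[1], ps_mm[2]) * 1000,
            calib_slope = slope[1], calib_intercept = inter[1],
            source_id = paste0("dicom:", normalizePath(directory)))
}
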