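# Minimal explicit-VR little-endian DICOM writer used only to build test
# fixtures at run time (fixtures are generated, never stored).

.u16le <- function(x) writeBin(as.integer(x), raw(), size = 2,
                               endian = "little")

dcm_element <- function(group, elem, vr, value) {
  if (vr %in% c("UI", "DS", "IS", "LO", "CS")) {
    v <- charToRaw(as.character(value))
    if (length(v) %% 2 == 1)
      v <- c(v, as.raw(if (vr == "UI") 0x00 else 0x20))
    c(.u16le(group), .u16le(elem), charToRaw(vr), .u16le(length(v)), v)
  } else if (vr == "US") {
    v <- .u16le(value)
    c(.u16le(group), .u16le(elem), charToRaw(vr), .u16le(length(v)), v)
  } else if (vr == "OW") {
    v <- value  # raw already
    c(.u16le(group), .u16le(elem), charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(v), raw(), size = 4, endian = "little"), v)
  } else stop("unsupported VR in fixture writer: ", vr)
}

# write one single-frame slice; pixels: integer matrix (rows x cols),
# values 0..32767 stored as unsigned 16-bit
write_dicom_slice <- function(path, pixels, z_mm, pixel_spacing_mm = 0.02,
                              series_uid = "1.2.3.4",
                              slope = NULL, intercept = NULL) {
  body <- c(
    dcm_element(0x0020, 0x000e, "UI", series_uid),
    dcm_element(0x0020, 0x0032, "DS", sprintf("0\\0\\%g", z_mm)),
    dcm_element(0x0028, 0x0010, "US", nrow(pixels)),
    dcm_element(0x0028, 0x0011, "US", ncol(pixels)),
    dcm_element(0x0028, 0x0030, "DS",
                sprintf("%g\\%g", pixel_spacing_mm, pixel_spacing_mm)),
    dcm_element(0x0028, 0x0100, "US", 16),
    dcm_element(0x0028, 0x0103, "US", 0))
  if (!is.null(intercept))
    body <- c(body, dcm_element(0x0028, 0x1052, "DS", sprintf("%g", intercept)))
  if (!is.null(slope))
    body <- c(body, dcm_element(0x0028, 0x1053, "DS", sprintf("%g", slope)))
  px <- writeBin(as.integer(t(pixels)), raw(), size = 2, endian = "little")
  body <- c(body, dcm_element(0x7fe0, 0x0010, "OW", px))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(rep(as.raw(0), 128), charToRaw("DICM"),
             dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
             body), con)
  invisible(path)
}

# write a whole synthetic series; data: 3D integer array (slice, row, col)
write_dicom_series <- function(dir, data, z0_mm = 0, dz_mm = 0.02,
                               pixel_spacing_mm = 0.02,
                               series_uid = "1.2.3.4",
                               slope = 1, intercept = -1024,
                               file_order = seq_len(dim(data)[1])) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (j in seq_along(file_order)) {
    i <- file_order[j]
    write_dicom_slice(file.path(dir, sprintf("slice_%03d.dcm", j)),
                      data[i, , ], z_mm = z0_mm + (i - 1) * dz_mm,
                      pixel_spacing_mm = pixel_spacing_mm,
                      series_uid = series_uid,
                      slope = slope, intercept = intercept)
  }
  invisible(dir)
}
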