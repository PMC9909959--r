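# Minimal explicit-VR little-endian DICOM writer for fixtures generated at
# test time (axial CT slices, 16-bit, uncompressed).

.u16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32_raw <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.dcm_elem <- function(group, elem, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(value)
    if (length(value) %% 2 == 1) value <- c(value, charToRaw(" "))
  }
  head <- c(.u16_raw(group), .u16_raw(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(head, as.raw(c(0, 0)), .u32_raw(length(value)), value)
  else
    c(head, .u16_raw(length(value)), value)
}

# mat is [x, y]; DICOM pixel data is row-major with Rows = y extent
write_dicom_slice <- function(path, mat, z, pixel_spacing = c(0.7, 0.5),
                              slope = 1, intercept = -1024,
                              uid = "1.2.3.4", signed = FALSE) {
  stored <- as.integer(round((mat - intercept) / slope))
  rows <- ncol(mat); cols <- nrow(mat)
  # transpose to row-major order (x fastest within each row)
  px <- writeBin(as.vector(stored), raw(), size = 2, endian = "little")
  body <- c(
    .dcm_elem(0x0020, 0x000E, "UI", uid),
    .dcm_elem(0x0020, 0x0032, "DS", sprintf("0\\0\\%g", z)),
    .dcm_elem(0x0028, 0x0010, "US", .u16_raw(rows)),
    .dcm_elem(0x0028, 0x0011, "US", .u16_raw(cols)),
    .dcm_elem(0x0028, 0x0030, "DS", sprintf("%g\\%g", pixel_spacing[1], pixel_spacing[2])),
    .dcm_elem(0x0028, 0x0100, "US", .u16_raw(16)),
    .dcm_elem(0x0028, 0x0103, "US", .u16_raw(as.integer(signed))),
    .dcm_elem(0x0028, 0x1052, "DS", sprintf("%g", intercept)),
    .dcm_elem(0x0028, 0x1053, "DS", sprintf("%g", slope)),
    .dcm_elem(0x7FE0, 0x0010, "OW", px)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  invisible(path)
}

write_dicom_series <- function(dir, vol_data, slice_pitch = 0.625,
                               pixel_spacing = c(0.7, 0.5), slope = 1,
                               intercept = -1024, uid = "1.2.3.4") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- dim(vol_data)[3]
  for (k in seq_len(nz))
    write_dicom_slice(file.path(dir, sprintf("slice%03d.dcm", k)),
                      vol_data[, , k], z = (k - 1) * slice_pitch,
                      pixel_spacing = pixel_spacing, slope = slope,
                      intercept = intercept, uid = uid)
  invisible(dir)
}
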