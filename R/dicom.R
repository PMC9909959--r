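# Minimal DICOM series reader.
#
# Supports the subset of DICOM needed to ingest an axial CT series: explicit
# VR little-endian transfer syntax, single-frame, 16-bit pixel data,
# uncompressed. Values are rescaled to HU with (0028,1052)/(0028,1053).
# Anything outside this subset raises an error naming the defect.

.dcm_tag <- function(group, elem) sprintf("%04X,%04X", group, elem)

.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path, call. = FALSE)
  pos <- 133L
  n <- length(raw)
  u16 <- function(at) readBin(raw[at:(at + 1L)], "integer", 1L, size = 2L,
                              signed = FALSE, endian = "little")
  u32 <- function(at) readBin(raw[at:(at + 3L)], "integer", 1L, size = 4L,
                              endian = "little")
  tags <- list()
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported (implicit VR?) DICOM encoding in ", path, call. = FALSE)
    if (vr %in% .dcm_long_vrs) {
      len <- u32(pos + 8L); val_at <- pos + 12L
    } else {
      len <- u16(pos + 6L); val_at <- pos + 8L
    }
    if (len < 0 || identical(len, -1L))
      stop("undefined-length DICOM element not supported in ", path, call. = FALSE)
    val <- if (len > 0) raw[val_at:(val_at + len - 1L)] else raw()
    tags[[.dcm_tag(group, elem)]] <- list(vr = vr, value = val)
    pos <- val_at + len
  }
  tags
}

.dcm_str <- function(tags, tag) {
  el <- tags[[tag]]
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$value))
}

.dcm_nums <- function(tags, tag) {
  s <- .dcm_str(tags, tag)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

.dcm_u16 <- function(tags, tag) {
  el <- tags[[tag]]
  if (is.null(el)) return(NULL)
  readBin(el$value, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
}

read_dicom_series <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) < 2L)
    stop("DICOM directory must contain a series of at least 2 slices (2D input rejected)",
         call. = FALSE)
  slices <- lapply(files, function(f) {
    tags <- read_dicom_slice(f)
    rows <- .dcm_u16(tags, "0028,0010"); cols <- .dcm_u16(tags, "0028,0011")
    if (is.null(rows) || is.null(cols)) stop("DICOM slice missing Rows/Columns: ", f, call. = FALSE)
    ps <- .dcm_nums(tags, "0028,0030")
    if (is.null(ps) || length(ps) != 2L || any(ps <= 0))
      stop("DICOM slice missing PixelSpacing: ", f, call. = FALSE)
    ipp <- .dcm_nums(tags, "0020,0032")
    if (is.null(ipp) || length(ipp) != 3L)
      stop("DICOM slice missing ImagePositionPatient: ", f, call. = FALSE)
    bits <- .dcm_u16(tags, "0028,0100") %||% 16L
    if (bits != 16L) stop("only 16-bit DICOM pixel data supported", call. = FALSE)
    signed <- identical(.dcm_u16(tags, "0028,0103"), 1L)
    slope <- (.dcm_nums(tags, "0028,1053") %||% 1)[1]
    intercept <- (.dcm_nums(tags, "0028,1052") %||% 0)[1]
    uid <- .dcm_str(tags, "0020,000E") %||% ""
    px <- tags[["7FE0,0010"]]
    if (is.null(px)) stop("DICOM slice missing PixelData: ", f, call. = FALSE)
    stored <- readBin(px$value, "integer", rows * cols, size = 2L,
                      signed = signed, endian = "little")
    # pixel data is row-major (x fastest): matrix(nrow = cols) yields [x, y]
    list(hu = matrix(slope * stored + intercept, nrow = cols),
         ps = ps, z = ipp[3], uid = uid, rows = rows, cols = cols)
  })
  uids <- unique(vapply(slices, `[[`, "", "uid"))
  if (length(uids) > 1L)
    stop("mixed DICOM series: multiple SeriesInstanceUIDs in one directory", call. = FALSE)
  dims <- unique(t(vapply(slices, function(s) c(s$rows, s$cols), numeric(2))))
  if (nrow(dims) > 1L) stop("mixed DICOM series: inconsistent matrix sizes", call. = FALSE)
  ord <- order(vapply(slices, `[[`, 0, "z"))
  slices <- slices[ord]
  zs <- vapply(slices, `[[`, 0, "z")
  dz <- diff(zs)
  if (any(dz <= 0) || (max(dz) - min(dz)) > 1e-3 * max(dz))
    stop("DICOM series has duplicate or non-uniform slice positions", call. = FALSE)
  ps <- slices[[1]]$ps  # (row spacing = y, column spacing = x)
  data <- array(0L, c(slices[[1]]$cols, slices[[1]]$rows, length(slices)))
  for (k in seq_along(slices)) data[, , k] <- round(slices[[k]]$hu)
  ct_volume(data, spacing_mm = c(ps[2], ps[1], dz[1]),
            origin_mm = c(0, 0, zs[1]))
}
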