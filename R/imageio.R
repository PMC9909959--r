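#' CT volume container
#'
#' A 3D scalar grid in Hounsfield units with voxel spacing and origin in mm.
#' The axis convention is fixed throughout the package: x runs
#' medial-lateral, y anterior-posterior (+y anterior), z inferior-superior
#' (+z superior). HU are stored as integers (CT semantics; makes interval
#' binning exact); values are clamped below at -1024 (air).
#'
#' @param data 3D numeric/integer array of HU values.
#' @param spacing_mm Per-axis voxel size in mm, length 3, all positive.
#' @param origin_mm Per-axis origin in mm, length 3.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("ct_volume requires a 3D array", call. = FALSE)
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0), length(origin_mm) == 3L)
  d <- round(data)
  if (any(d < -1024)) stop("HU values below -1024 are invalid", call. = FALSE)
  storage.mode(d) <- "integer"
  structure(list(data = d, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("CT volume %s voxels, spacing %s mm, HU range [%d, %d]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Read a CT volume from NIfTI or a DICOM series
#'
#' A NIfTI file (`.nii`/`.nii.gz`) is read with RNifti and, when the header
#' carries a complete orientation, reoriented to the canonical RAS-like axis
#' convention (the applied permutation is reported via `message()`). A
#' directory is treated as one DICOM series: slices are sorted by position,
#' the rescale slope/intercept is applied so values are true HU, and slice
#' pitch becomes the z spacing.
#'
#' @param path NIfTI file path or directory containing one DICOM series.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume, got ", length(dim(img)), "D input", call. = FALSE)
  ori <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (!is.na(ori) && nzchar(ori) && !identical(ori, "RAS")) {
    message("reorienting volume from ", ori, " to RAS")
    RNifti::orientation(img) <- "RAS"
  }
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("missing or invalid voxel spacing in NIfTI header", call. = FALSE)
  ct_volume(array(as.numeric(img), dim(img)), spacing_mm = sp)
}

#' Write a CT volume or binary mask as NIfTI
#'
#' Volumes are written as signed 16-bit integers (lossless for HU), masks as
#' unsigned 8-bit. Spacing goes into the header; files carry no timestamps,
#' so output is byte-deterministic.
#'
#' @param vol A [ct_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname write_volume
#' @param mask Logical array or [clip_to_epiphyseal()] result.
#' @param spacing_mm Voxel spacing, taken from the ROI when available.
#' @export
write_mask <- function(mask, path, spacing_mm = NULL) {
  if (inherits(mask, "subchondral_roi")) {
    spacing_mm <- spacing_mm %||% mask$spacing_mm
    mask <- mask$mask
  }
  spacing_mm <- spacing_mm %||% c(1, 1, 1)
  m <- array(as.integer(mask), dim(mask))
  img <- RNifti::asNifti(m)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#' @param path NIfTI path.
#' @return Logical array.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) != 0, dim(img))
}

#' Write a %BTV profile as CSV
#'
#' One data row per density interval, labelled `"100-200"` through
#' `"1201-maximum"`, with the density class, absolute volume and %BTV.
#'
#' @param profile A [btv_profile()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "btv_profile"))
  sc <- density_scheme()
  df <- data.frame(density_hu = sc$labels,
                   class = sc$class_of_bin,
                   volume_mm3 = profile$volumes_mm3,
                   pct_btv = profile$pct,
                   bone = profile$bone, side = profile$side)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a table (frequency, pattern, comparison) as CSV
#'
#' Plain deterministic CSV writer; an empty table yields a header-only file.
#'
#' @param table A data.frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_table_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write and re-read an articular-surface density map
#'
#' The lossless representation is CSV (one row per y index, `NA` outside the
#' articular footprint); [write_map_png()] renders the pseudo-colour
#' densitogram using the scheme colours, black outside the footprint.
#'
#' @param map A [project_density()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  write.table(map$values, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_map_csv
#' @param pixel_spacing_mm,bone,side Metadata to attach on re-read.
#' @export
read_map_csv <- function(path, pixel_spacing_mm = c(1, 1), bone = "distal_femur",
                         side = "right") {
  m <- as.matrix(read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  density_map(m, !is.na(m), pixel_spacing_mm, bone, side)
}

#' @rdname write_map_csv
#' @param scheme A [density_scheme()] supplying the 12 colours.
#' @export
write_map_png <- function(map, path, scheme = density_scheme()) {
  stopifnot(inherits(map, "density_map"))
  v <- map$values
  bin <- findInterval(as.numeric(v), scheme$lo)
  rgbm <- col2rgb(scheme$colors) / 255
  img <- array(0, c(ncol(v), nrow(v), 3))  # rows of the PNG = y axis
  ok <- which(!is.na(bin) & bin >= 1)
  if (length(ok)) {
    ix <- ((ok - 1) %% nrow(v)) + 1
    iy <- ((ok - 1) %/% nrow(v)) + 1
    for (ch in 1:3) {
      plane <- matrix(0, ncol(v), nrow(v))
      plane[cbind(iy, ix)] <- rgbm[ch, bin[ok]]
      img[, , ch] <- plane
    }
  }
  png::writePNG(img, path)
  invisible(path)
}
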