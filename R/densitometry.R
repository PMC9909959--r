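#' The twelve-interval CTOAM density scheme
#'
#' Subchondral bone is segmented into twelve Hounsfield-unit intervals:
#' `[100,200], [201,300], ..., [1101,1200], [1201,max]`. Intervals are closed
#' on integer HU and gapless; values below 100 HU are outside the bone tissue
#' of interest. Bins 1-4 form the *low*, 5-8 the *medium* and 9-12 the *high*
#' bone density class. Each bin carries a display colour for pseudo-colour
#' densitograms.
#'
#' @return An object of class `density_scheme` with fields `lo`, `hi`
#'   (integer interval bounds, `hi` is `NA` for the open-ended 12th bin),
#'   `labels` (`"100-200"` ... `"1201-maximum"`), `class_of_bin` and `colors`.
#' @export
#' @examples
#' density_scheme()$labels
density_scheme <- function() {
  lo <- c(100L, seq(201L, 1201L, by = 100L))
  hi <- c(seq(200L, 1200L, by = 100L), NA_integer_)
  labels <- c(paste0(lo[-12L], "-", hi[-12L]), "1201-maximum")
  structure(list(
    lo = lo, hi = hi, labels = labels,
    class_of_bin = rep(c("low", "medium", "high"), each = 4L),
    colors = colorRampPalette(c("#00007F", "#0000FF", "#007FFF", "#00FFFF",
                                "#7FFF7F", "#FFFF00", "#FF7F00", "#FF0000",
                                "#7F0000"))(12L)
  ), class = "density_scheme")
}

#' @export
print.density_scheme <- function(x, ...) {
  cat("CTOAM density scheme: 12 HU intervals\n")
  print(data.frame(bin = 1:12, interval = x$labels, class = x$class_of_bin))
  invisible(x)
}

#' Assign every ROI voxel to its density bin
#'
#' Labels each voxel of the bone tissue of interest with its density interval:
#' 0 for voxels outside the ROI or below 100 HU, 1-12 for the twelve scheme
#' intervals. Non-integer HU values are rounded to the nearest integer before
#' binning, so interval membership is exact.
#'
#' @param vol A [ct_volume()].
#' @param roi A [clip_to_epiphyseal()] result or a logical mask on the same grid.
#' @param scheme A [density_scheme()].
#' @return Integer array of bin labels with the volume's dimensions.
#' @export
bin_voxels <- function(vol, roi, scheme = density_scheme()) {
  stopifnot(inherits(vol, "ct_volume"))
  mask <- as_mask(roi)
  if (!identical(dim(mask), dim(vol$data)))
    stop("volume and ROI grids do not match", call. = FALSE)
  if (inherits(roi, "subchondral_roi") &&
      !isTRUE(all.equal(roi$spacing_mm, vol$spacing_mm, tolerance = 1e-6)))
    stop("volume and ROI voxel spacing do not match", call. = FALSE)
  labels <- array(0L, dim(vol$data))
  h <- as.integer(round(as.numeric(vol$data[mask])))
  b <- findInterval(h, scheme$lo)
  b[h < 100L] <- 0L
  labels[mask] <- b
  labels
}

#' Per-bin bone tissue volumes and %BTV
#'
#' Converts a bin-label grid into the bone-tissue-volume profile: absolute
#' volume per density interval (mm^3) and the percentage of the total bone
#' tissue of interest it represents, `%BTV_i = 100 * V_i / V_total`, where
#' `V_total` sums the twelve intervals. By construction the twelve
#' percentages sum to 100.
#'
#' @param labels Integer label grid from [bin_voxels()].
#' @param spacing_mm Per-axis voxel size in mm (length 3).
#' @param bone `"distal_femur"` or `"tibial_plateau"`.
#' @param side `"right"` or `"left"`.
#' @return An object of class `btv_profile` with `volumes_mm3` (length 12),
#'   `total_btoi_mm3`, `pct`, `bone`, `side`.
#' @export
btv_profile <- function(labels, spacing_mm, bone = "distal_femur", side = "right") {
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0))
  counts <- tabulate(labels[labels > 0L], nbins = 12L)
  if (sum(counts) == 0L) stop("empty BTOI: no voxel in any density bin", call. = FALSE)
  voxel_mm3 <- prod(spacing_mm)
  volumes <- counts * voxel_mm3
  structure(list(
    volumes_mm3 = volumes,
    total_btoi_mm3 = sum(volumes),
    pct = 100 * volumes / sum(volumes),
    voxel_counts = counts,
    bone = check_bone(bone), side = check_side(side)
  ), class = "btv_profile")
}

#' @export
print.btv_profile <- function(x, ...) {
  sc <- density_scheme()
  cat(sprintf("%%BTV profile: %s, %s side, total BTOI %.1f mm^3\n",
              x$bone, x$side, x$total_btoi_mm3))
  print(data.frame(interval = sc$labels, class = sc$class_of_bin,
                   volume_mm3 = round(x$volumes_mm3, 2),
                   pct_btv = round(x$pct, 3)))
  invisible(x)
}

#' Low / medium / high density class summary
#'
#' Aggregates a %BTV profile into the three density classes: low = bins 1-4
#' (100-500 HU), medium = bins 5-8 (501-900 HU), high = bins 9-12 (901 HU and
#' above). The three shares sum to 100.
#'
#' @param profile A [btv_profile()].
#' @return Named numeric vector `c(low=, medium=, high=)` in percent of BTOI.
#' @export
class_summary <- function(profile) {
  stopifnot(inherits(profile, "btv_profile"))
  c(low = sum(profile$pct[1:4]),
    medium = sum(profile$pct[5:8]),
    high = sum(profile$pct[9:12]))
}
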