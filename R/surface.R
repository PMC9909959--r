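#' Articular-surface density map container
#'
#' 2D grid of projected HU defined on the articular footprint (`NA`
#' elsewhere), with pixel spacing and bone/side metadata.
#'
#' @param values Numeric matrix (x by y) of projected HU, `NA` off-footprint.
#' @param footprint Logical matrix of the articular surface extent.
#' @param pixel_spacing_mm Length-2 in-plane pixel size (mm).
#' @param bone,side Anatomical metadata.
#' @return Object of class `density_map`.
#' @export
density_map <- function(values, footprint, pixel_spacing_mm, bone, side) {
  stopifnot(is.matrix(values), is.matrix(footprint),
            identical(dim(values), dim(footprint)),
            length(pixel_spacing_mm) == 2L, all(pixel_spacing_mm > 0))
  values[!footprint] <- NA_real_
  structure(list(values = values, footprint = footprint,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 bone = check_bone(bone), side = check_side(side)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density map: %s (%s), footprint %d px of %s\n", x$bone, x$side,
              sum(x$footprint), paste(dim(x$values), collapse = "x")))
  invisible(x)
}

#' Project subchondral density onto the articular surface
#'
#' Maximum-intensity projection along z: for every (x, y) column that
#' intersects the ROI the map value is the maximum HU over the ROI voxels of
#' that column. The footprint is the set of columns with at least one ROI
#' voxel. CTOAM densitograms conventionally show the maximal subchondral
#' density, and maxima are what drive high-density-area detection.
#'
#' @param vol A [ct_volume()].
#' @param roi A `subchondral_roi` (or logical mask on the same grid).
#' @return A [density_map()].
#' @export
project_density <- function(vol, roi) {
  stopifnot(inherits(vol, "ct_volume"))
  mask <- as_mask(roi)
  if (!identical(dim(mask), dim(vol$data)))
    stop("volume and ROI grids do not match", call. = FALSE)
  if (!any(mask)) stop("empty ROI: nothing to project", call. = FALSE)
  d <- dim(mask)
  v <- array(as.numeric(vol$data), d)
  v[!mask] <- NA_real_
  M <- matrix(v, nrow = d[1] * d[2])
  vals <- suppressWarnings(do.call(pmax, c(asplit(M, 2), list(na.rm = TRUE))))
  vals <- matrix(vals, d[1], d[2])
  bone <- if (inherits(roi, "subchondral_roi")) roi$bone else "distal_femur"
  side <- if (inherits(roi, "subchondral_roi")) roi$side else "right"
  density_map(vals, !is.na(vals), vol$spacing_mm[1:2], bone, side)
}

# split 1..w into three near-equal integer bands; symmetric under reversal
.band3 <- function(rel, w) {
  findInterval(rel, c(0, round(w / 3), round(2 * w / 3)) + 0.5)
}

.map_bbox <- function(footprint) {
  xs <- which(rowSums(footprint) > 0)
  ys <- which(colSums(footprint) > 0)
  c(x0 = min(xs), x1 = max(xs), y0 = min(ys), y1 = max(ys))
}

#' Partition the articular footprint into nine anatomical regions
#'
#' A 3x3 grid of equal-thirds bands over the footprint's bounding box. Rows
#' run anterior (row 1) to posterior (row 3); columns run medial (column 1)
#' to lateral (column 3), so the medial column sits at opposite pixel sides
#' for left and right knees and the numbering is anatomically mirrored.
#' Region index = (row - 1) * 3 + column; region 5 is central.
#'
#' @param map A [density_map()].
#' @return Object of class `region_grid` with `region_of_pixel` (integer
#'   matrix, `NA` off-footprint), `side`, `bone`, `bbox`.
#' @export
nine_regions <- function(map) {
  stopifnot(inherits(map, "density_map"))
  fp <- map$footprint
  if (!any(fp)) stop("degenerate footprint: empty map", call. = FALSE)
  bb <- .map_bbox(fp)
  wx <- bb["x1"] - bb["x0"] + 1L
  wy <- bb["y1"] - bb["y0"] + 1L
  if (wx < 3L || wy < 3L)
    stop("degenerate footprint: need at least 3 pixels extent per axis", call. = FALSE)
  idx <- which(fp, arr.ind = TRUE)
  bandx <- .band3(idx[, 1] - bb["x0"] + 1L, wx)
  # +y is anterior: row 1 (anterior) = largest y
  rowb <- .band3(bb["y1"] - idx[, 2] + 1L, wy)
  colpos <- if (map$side == "right") bandx else 4L - bandx
  reg <- matrix(NA_integer_, nrow(fp), ncol(fp))
  reg[idx] <- (rowb - 1L) * 3L + colpos
  structure(list(region_of_pixel = reg, side = map$side, bone = map$bone,
                 bbox = bb), class = "region_grid")
}

#' Detect high-density areas on a density map
#'
#' Thresholds the projected map at `threshold_hu` (default 901 HU, the start
#' of the high-density class), labels 8-connected pixel components and keeps
#' those covering at least `min_area_mm2`. Each component records its area,
#' centroid and every region it touches.
#'
#' @param map A [density_map()].
#' @param threshold_hu Integer HU cutoff (default 901).
#' @param min_area_mm2 Minimum component area in mm^2 (default 25).
#' @param regions A [nine_regions()] grid; computed from `map` when `NULL`.
#' @return Object of class `high_density_areas`: `components` (list with
#'   `pixels`, `area_mm2`, `centroid`, `regions`), `threshold_hu`,
#'   `min_area_mm2`, `bone`, `side`, `bbox`.
#' @export
detect_high_density <- function(map, threshold_hu = 901L, min_area_mm2 = 25,
                                regions = NULL) {
  stopifnot(inherits(map, "density_map"))
  if (is.null(regions)) regions <- nine_regions(map)
  hd <- map$footprint & !is.na(map$values) & map$values >= threshold_hu
  px_area <- prod(map$pixel_spacing_mm)
  comps <- list()
  if (any(hd)) {
    lab <- cc_label_2d8(hd)
    for (k in seq_len(max(lab))) {
      pix <- which(lab == k, arr.ind = TRUE)
      area <- nrow(pix) * px_area
      if (area < min_area_mm2) next
      comps[[length(comps) + 1L]] <- list(
        pixels = pix,
        area_mm2 = area,
        centroid = colMeans(pix),
        regions = sort(unique(regions$region_of_pixel[pix])))
    }
  }
  structure(list(components = comps, threshold_hu = as.integer(threshold_hu),
                 min_area_mm2 = min_area_mm2, bone = map$bone, side = map$side,
                 bbox = .map_bbox(map$footprint),
                 pixel_spacing_mm = map$pixel_spacing_mm),
            class = "high_density_areas")
}

#' @export
print.high_density_areas <- function(x, ...) {
  cat(sprintf("high-density areas: %s (%s), %d component(s) >= %g mm^2 at >= %d HU\n",
              x$bone, x$side, length(x$components), x$min_area_mm2, x$threshold_hu))
  invisible(x)
}

#' Per-region high-density frequency over a cohort of knees
#'
#' For each of the nine regions, counts the knees whose map has at least one
#' high-density component touching that region, and the integer percentage
#' of knees (halves rounded away from zero, see [percent_integer()]).
#'
#' @param cohort List of [detect_high_density()] results, one per knee.
#' @param n_knees Number of knees (defaults to `length(cohort)`).
#' @return data.frame with columns `region`, `count`, `percent`.
#' @export
region_frequency <- function(cohort, n_knees = length(cohort)) {
  stopifnot(n_knees >= 1, length(cohort) == n_knees)
  count <- integer(9)
  for (knee in cohort) {
    regs <- unique(unlist(lapply(knee$components, `[[`, "regions")))
    count[regs] <- count[regs] + 1L
  }
  data.frame(region = 1:9, count = count,
             percent = percent_integer(count, n_knees))
}
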