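#' Threshold bone from a CT volume
#'
#' Voxels at or above `threshold_hu` are bone. The default of 100 HU aligns
#' the extracted bone with the lowest interval of the density scheme, so the
#' ROI and the binning denominator agree.
#'
#' @param vol A [ct_volume()].
#' @param threshold_hu Integer HU cutoff (default 100).
#' @return Logical array.
#' @export
bone_mask <- function(vol, threshold_hu = 100L) {
  stopifnot(inherits(vol, "ct_volume"))
  m <- vol$data >= threshold_hu
  if (!any(m)) stop("empty mask: no voxel reaches ", threshold_hu, " HU", call. = FALSE)
  m
}

#' Region growing (26-connected component of a seed)
#'
#' Returns the 26-connected component of `mask` containing `seed_voxel` — the
#' functional equivalent of interactive area-growth extraction of a bone from
#' a thresholded mask.
#'
#' @param mask Logical 3D array.
#' @param seed_voxel Integer index triple `(x, y, z)`.
#' @return Logical array, a subset of `mask`.
#' @export
region_grow <- function(mask, seed_voxel) {
  mask <- as_mask(mask)
  stopifnot(length(dim(mask)) == 3L, length(seed_voxel) == 3L)
  seed_voxel <- as.integer(seed_voxel)
  if (any(seed_voxel < 1L) || any(seed_voxel > dim(mask)))
    stop("seed voxel outside the grid", call. = FALSE)
  if (!mask[seed_voxel[1], seed_voxel[2], seed_voxel[3]])
    stop("seed voxel is not inside the mask", call. = FALSE)
  lab <- cc_label_3d26(mask, dim(mask))
  lab == lab[seed_voxel[1], seed_voxel[2], seed_voxel[3]]
}

largest_component <- function(mask) {
  lab <- cc_label_3d26(mask, dim(mask))
  tab <- tabulate(lab[lab > 0L])
  lab == which.max(tab)
}

#' Clip a bone mask at the epiphyseal line
#'
#' Retains the subchondral side of a flat epiphyseal plane — the functional
#' equivalent of erasing, layer by layer, the mask outside the epiphyseal
#' line. For the distal femur the articular surface is inferior, so voxels
#' with `z <= plane_z` are kept; for the tibial plateau it is superior, so
#' `z >= plane_z` are kept. The result is re-grown from the largest
#' 26-connected component, giving the bone tissue of interest between
#' articular surface and epiphyseal line. The operation is idempotent.
#'
#' @param mask Logical 3D bone mask (e.g. from [bone_mask()]).
#' @param plane_z Epiphyseal plane slice index (within the grid).
#' @param bone `"distal_femur"` or `"tibial_plateau"`.
#' @param side `"right"` or `"left"` (metadata).
#' @param spacing_mm Voxel spacing to record on the ROI.
#' @return An object of class `subchondral_roi` with fields `mask`, `bone`,
#'   `side`, `epiphyseal_plane_z`, `spacing_mm`.
#' @export
clip_to_epiphyseal <- function(mask, plane_z, bone, side = "right",
                               spacing_mm = c(1, 1, 1)) {
  mask <- as_mask(mask)
  bone <- check_bone(bone)
  stopifnot(length(dim(mask)) == 3L)
  nz <- dim(mask)[3]
  if (plane_z < 1L || plane_z > nz)
    stop("epiphyseal plane_z outside the grid", call. = FALSE)
  zidx <- rep(seq_len(nz), each = prod(dim(mask)[1:2]))
  keep <- if (is_femur(bone)) zidx <= plane_z else zidx >= plane_z
  m <- mask & array(keep, dim(mask))
  if (!any(m))
    stop("clipping at the epiphyseal plane leaves an empty mask", call. = FALSE)
  m <- largest_component(m)
  structure(list(mask = m, bone = bone, side = check_side(side),
                 epiphyseal_plane_z = as.integer(plane_z),
                 spacing_mm = as.numeric(spacing_mm)),
            class = "subchondral_roi")
}

#' @export
print.subchondral_roi <- function(x, ...) {
  cat(sprintf("subchondral ROI: %s (%s), %d voxels, epiphyseal plane z=%d\n",
              x$bone, x$side, sum(x$mask), x$epiphyseal_plane_z))
  invisible(x)
}

#' Best-effort epiphyseal plane detection
#'
#' Heuristic locating the epiphyseal line as the z slice whose in-mask mean
#' HU is lowest (the growth-plate remnant is less dense than the surrounding
#' subchondral and metaphyseal bone). Slices containing fewer than 5% of the
#' largest slice's mask voxels are ignored. Always overridable by an explicit
#' plane.
#'
#' @param vol A [ct_volume()].
#' @param mask Logical bone mask.
#' @return Integer slice index.
#' @export
detect_epiphyseal_plane <- function(vol, mask) {
  stopifnot(inherits(vol, "ct_volume"))
  mask <- as_mask(mask)
  nz <- dim(mask)[3]
  counts <- vapply(seq_len(nz), function(z) sum(mask[, , z]), 0)
  ok <- counts >= 0.05 * max(counts)
  means <- rep(Inf, nz)
  for (z in which(ok)) means[z] <- mean(vol$data[, , z][mask[, , z]])
  which.min(means)
}
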