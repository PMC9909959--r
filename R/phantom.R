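#' Specification of a synthetic knee phantom
#'
#' Describes a stylized distal-femur or tibial-plateau CT phantom with a
#' known subchondral density composition. Geometry is deliberately schematic
#' (two condylar half-ellipsoids for the femur, a domed plateau slab for the
#' tibia): enough to exercise ROI extraction, projection, the nine-region
#' partition and %BTV quantification with voxel-exact ground truth. The
#' epiphyseal boundary is a flat plane at a known slice.
#'
#' Two density profiles mirror the qualitative contrast seen in trained vs
#' untrained knees: `control_like` is a laminar field that decays
#' monotonically with depth below the articular surface;
#' `judo_like` adds Gaussian high-density foci centred on configurable
#' anatomical regions (defaults: regions 4, 5, 6 for the femur — the
#' central, cruciate-ligament-insertion band — and regions 2, 4, 5, 7 for
#' the tibia).
#'
#' @param bone `"distal_femur"` or `"tibial_plateau"`.
#' @param side `"right"` or `"left"`.
#' @param profile `"control_like"` or `"judo_like"`.
#' @param grid_shape Voxels per axis (x, y, z), all >= 8.
#' @param spacing_mm Per-axis voxel size in mm (default isotropic 0.625, the
#'   slice thickness of thin-slice knee CT).
#' @param shell_thickness_mm Depth of the elevated subchondral shell (must
#'   exceed the slice spacing).
#' @param baseline_hu Background (deep trabecular) bone HU, placed mid-way
#'   inside a density interval so the deep field does not sit on a bin edge.
#' @param lam_amp_hu Amplitude of the laminar surface field above baseline.
#' @param lam_scale_mm Depth-decay length of the laminar field.
#' @param texture_amp_hu Half-width of the deterministic voxel-scale
#'   trabecular texture: every bone voxel is offset by an integer-hash value
#'   uniform in `[-texture_amp_hu, texture_amp_hu]`, spreading the bone HU
#'   into a flat continuous spectrum the way trabecular granularity does at
#'   sub-millimetre voxel sizes; 0 gives a spatially uniform field. The
#'   texture is a function of the voxel index only (not of the RNG seed).
#' @param remodel_gain Densification factor applied to the laminar
#'   amplitude in `judo_like` phantoms: habitual loading raises subchondral
#'   density across the plate, over and above the focal high-density areas.
#'   Kept moderate by default so that away from the foci the projected
#'   surface stays below the high-density detection class. 1 turns the
#'   broad effect off (foci only).
#' @param remodel_depth_gain Factor by which the densified plate deepens in
#'   `judo_like` phantoms. Thickening at depth is what shifts volume into
#'   the medium-density intervals without saturating the projected surface.
#' @param foci List of `list(region, amplitude_hu, sigma_mm)`; `NULL` means
#'   the profile default (none for `control_like`).
#' @param noise_sd_hu Additive Gaussian noise SD in HU (truncated at -1024).
#' @param seed Integer RNG seed; phantoms are bit-reproducible.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(bone = "distal_femur", side = "right",
                         profile = c("control_like", "judo_like"),
                         grid_shape = c(48, 48, 36),
                         spacing_mm = c(0.625, 0.625, 0.625),
                         shell_thickness_mm = 5,
                         baseline_hu = 280, lam_amp_hu = 200, lam_scale_mm = 3,
                         texture_amp_hu = 150, remodel_gain = 1.5,
                         remodel_depth_gain = 3,
                         foci = NULL, noise_sd_hu = 30, seed = 1L) {
  bone <- check_bone(bone); side <- check_side(side)
  profile <- match.arg(profile)
  grid_shape <- as.integer(grid_shape)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  stopifnot(length(grid_shape) == 3L, length(spacing_mm) == 3L)
  if (any(grid_shape < 8L)) stop("grid_shape must be >= 8 voxels per axis", call. = FALSE)
  if (any(spacing_mm <= 0)) stop("spacing_mm must be positive", call. = FALSE)
  if (shell_thickness_mm <= max(spacing_mm))
    stop("degenerate geometry: shell_thickness_mm (", shell_thickness_mm,
         " mm) must exceed the voxel spacing (shell thinner than one voxel)",
         call. = FALSE)
  if (noise_sd_hu < 0) stop("noise_sd_hu must be >= 0", call. = FALSE)
  if (texture_amp_hu < 0) stop("texture_amp_hu must be >= 0", call. = FALSE)
  if (remodel_gain <= 0) stop("remodel_gain must be positive", call. = FALSE)
  if (remodel_depth_gain <= 0) stop("remodel_depth_gain must be positive", call. = FALSE)
  if (baseline_hu < 100) stop("baseline_hu below the 100 HU bone threshold", call. = FALSE)
  if (baseline_hu - texture_amp_hu < 100)
    stop("texture_amp_hu too large: deep bone HU would fall below the 100 HU threshold",
         call. = FALSE)
  if (is.null(foci) && profile == "judo_like") foci <- default_foci(bone)
  if (is.null(foci)) foci <- list()
  for (f in foci) {
    if (!all(c("region", "amplitude_hu", "sigma_mm") %in% names(f)))
      stop("each focus needs region, amplitude_hu, sigma_mm", call. = FALSE)
    if (f$region < 1 || f$region > 9) stop("focus region must be in 1..9", call. = FALSE)
    if (f$amplitude_hu < 0) stop("focus amplitude must be >= 0", call. = FALSE)
    if (f$sigma_mm <= 0) stop("focus sigma_mm must be positive", call. = FALSE)
  }
  structure(list(bone = bone, side = side, profile = profile,
                 grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 shell_thickness_mm = shell_thickness_mm,
                 baseline_hu = baseline_hu, lam_amp_hu = lam_amp_hu,
                 lam_scale_mm = lam_scale_mm, texture_amp_hu = texture_amp_hu,
                 remodel_gain = remodel_gain,
                 remodel_depth_gain = remodel_depth_gain, foci = foci,
                 noise_sd_hu = noise_sd_hu, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_foci <- function(bone) {
  regions <- if (is_femur(check_bone(bone))) c(4L, 5L, 6L) else c(2L, 4L, 5L, 7L)
  lapply(regions, function(r) list(region = r, amplitude_hu = 450, sigma_mm = 3))
}

.grid_coords <- function(gs) {
  list(x = array(rep(seq_len(gs[1]), times = gs[2] * gs[3]), gs),
       y = array(rep(rep(seq_len(gs[2]), each = gs[1]), times = gs[3]), gs),
       z = array(rep(seq_len(gs[3]), each = gs[1] * gs[2]), gs))
}

# per-column extreme z of a mask: min (femur, surface inferior) or max (tibia)
.column_surface <- function(mask, zc, minimum) {
  d <- dim(mask)
  zz <- array(as.numeric(zc), d)
  zz[!mask] <- NA_real_
  M <- matrix(zz, nrow = d[1] * d[2])
  f <- if (minimum) pmin else pmax
  suppressWarnings(do.call(f, c(asplit(M, 2), list(na.rm = TRUE))))
}

.phantom_geometry <- function(spec) {
  gs <- spec$grid_shape
  co <- .grid_coords(gs)
  nx <- gs[1]; ny <- gs[2]; nz <- gs[3]
  if (is_femur(spec$bone)) {
    plane_z <- max(3L, round(0.7 * nz))
    cy <- 0.5 * (ny + 1)
    rx <- 0.26 * nx; ry <- 0.38 * ny; rz <- max(plane_z - 2, 3)
    cond <- function(cx) ((co$x - cx) / rx)^2 + ((co$y - cy) / ry)^2 +
      ((co$z - plane_z) / rz)^2 <= 1
    below <- (cond(0.5 * nx - 0.21 * nx) | cond(0.5 * nx + 0.21 * nx)) &
      co$z <= plane_z
    shaft <- co$z > plane_z &
      ((co$x - 0.5 * (nx + 1)) / (0.33 * nx))^2 + ((co$y - cy) / (0.30 * ny))^2 <= 1
    bone <- below | shaft
    roi <- below
    surf <- .column_surface(roi, co$z, minimum = TRUE)
    depth <- (co$z - array(rep(surf, nz), gs)) * spec$spacing_mm[3]
  } else {
    plane_z <- max(2L, round(0.35 * nz))
    cx <- 0.5 * (nx + 1); cy <- 0.5 * (ny + 1)
    e <- ((co$x - cx) / (0.42 * nx))^2 + ((co$y - cy) / (0.36 * ny))^2
    zsurf <- (nz - 3) - round(3 * e)
    bone <- e <= 1 & co$z >= 2 & co$z <= zsurf
    roi <- bone & co$z >= plane_z
    surf <- .column_surface(roi, co$z, minimum = FALSE)
    depth <- (array(rep(surf, nz), gs) - co$z) * spec$spacing_mm[3]
  }
  list(bone = bone, roi = roi, depth = depth, plane_z = as.integer(plane_z),
       coords = co)
}

# centroids (x, y) of the nine regions of a footprint, using the same
# equal-thirds convention as nine_regions()
.region_centers <- function(footprint, side) {
  bb <- .map_bbox(footprint)
  wx <- bb["x1"] - bb["x0"] + 1L; wy <- bb["y1"] - bb["y0"] + 1L
  idx <- which(footprint, arr.ind = TRUE)
  bandx <- .band3(idx[, 1] - bb["x0"] + 1L, wx)
  rowb <- .band3(bb["y1"] - idx[, 2] + 1L, wy)
  colpos <- if (side == "right") bandx else 4L - bandx
  reg <- (rowb - 1L) * 3L + colpos
  centers <- matrix(NA_real_, 9, 2)
  for (r in 1:9) {
    sel <- reg == r
    if (any(sel)) centers[r, ] <- colMeans(idx[sel, , drop = FALSE])
  }
  centers
}

#' Generate a synthetic knee phantom with ground truth
#'
#' Builds the HU volume described by a [phantom_spec()] and its exact ground
#' truth: the subchondral ROI between the articular surface and the
#' epiphyseal plane, and the per-interval voxel counts of the emitted volume
#' restricted to that ROI (computed by an exhaustive scan, independent of
#' the densitometry code path). Identical spec and seed give bit-identical
#' output.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `ctoam_phantom`: `volume` (a [ct_volume()]),
#'   `truth` (`roi_mask`, `per_bin_voxels`, `epiphyseal_plane_z`,
#'   `foci_regions`), `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- .phantom_geometry(spec)
  gs <- spec$grid_shape
  field <- array(-1024, gs)
  field[geo$bone] <- spec$baseline_hu
  if (spec$texture_amp_hu > 0) {
    # deterministic voxel-scale trabecular texture: an integer hash of the
    # voxel index mapped to a uniform offset, giving a flat atom-free HU
    # spectrum independent of the noise seed (exact in double arithmetic)
    u <- (geo$coords$x * 73856093 + geo$coords$y * 19349663 +
          geo$coords$z * 83492791) %% 100003 / 100003
    field[geo$bone] <- field[geo$bone] + spec$texture_amp_hu * (2 * u[geo$bone] - 1)
  }
  # laminar/foci elevation: shifted exponential in depth that reaches zero
  # continuously at shell_thickness_mm (a hard cutoff or an unshifted decay
  # would leave a discontinuity or a pile-up in the HU spectrum)
  in_shell <- geo$roi & !is.na(geo$depth)
  # judo-like remodeling raises the laminar amplitude and thickens the
  # densified plate
  judo <- spec$profile == "judo_like"
  gain <- if (judo) spec$remodel_gain else 1
  shell <- spec$shell_thickness_mm * (if (judo) spec$remodel_depth_gain else 1)
  floor_term <- exp(-shell / spec$lam_scale_mm)
  decay <- pmax(exp(-pmax(geo$depth, 0) / spec$lam_scale_mm) - floor_term, 0) /
    (1 - floor_term)
  lam_amp <- spec$lam_amp_hu * gain
  field[in_shell] <- field[in_shell] + lam_amp * decay[in_shell]
  if (length(spec$foci)) {
    foot <- matrix(FALSE, gs[1], gs[2])
    foot[unique(which(geo$roi, arr.ind = TRUE)[, 1:2, drop = FALSE])] <- TRUE
    centers <- .region_centers(foot, spec$side)
    for (f in spec$foci) {
      ctr <- centers[f$region, ]
      if (any(is.na(ctr))) next
      r2 <- ((geo$coords$x - ctr[1]) * spec$spacing_mm[1])^2 +
            ((geo$coords$y - ctr[2]) * spec$spacing_mm[2])^2
      g <- f$amplitude_hu * exp(-r2 / (2 * f$sigma_mm^2)) * decay
      field[in_shell] <- field[in_shell] + g[in_shell]
    }
  }
  hu <- with_seed(spec$seed, {
    if (spec$noise_sd_hu > 0) field + rnorm(length(field), sd = spec$noise_sd_hu)
    else field
  })
  vol <- ct_volume(pmax(array(hu, gs), -1024), spacing_mm = spec$spacing_mm)
  # exhaustive ground-truth scan over the emitted volume, restricted to the ROI
  h <- vol$data[geo$roi]
  brks <- c(99.5, seq(200.5, 1200.5, by = 100), Inf)
  per_bin <- tabulate(.bincode(h[h >= 100L], brks), nbins = 12L)
  structure(list(
    volume = vol,
    truth = list(roi_mask = geo$roi, per_bin_voxels = as.integer(per_bin),
                 epiphyseal_plane_z = geo$plane_z,
                 foci_regions = sort(unique(vapply(spec$foci, `[[`, 0, "region")))),
    spec = spec), class = "ctoam_phantom")
}

#' @export
print.ctoam_phantom <- function(x, ...) {
  cat(sprintf("knee phantom: %s (%s, %s), %d ROI voxels, plane z=%d\n",
              x$spec$bone, x$spec$side, x$spec$profile, sum(x$truth$roi_mask),
              x$truth$epiphyseal_plane_z))
  invisible(x)
}

# inter-subject jitter constants (multiplicative log-normal):
#   baseline sdlog 0.05, laminar amplitude sdlog 0.08, focus amplitude sdlog 0.25
.jitter_spec <- function(spec, seed) {
  with_seed(seed, {
    spec$baseline_hu <- max(100, spec$baseline_hu * rlnorm(1, 0, 0.05))
    spec$lam_amp_hu <- spec$lam_amp_hu * rlnorm(1, 0, 0.08)
    spec$foci <- lapply(spec$foci, function(f) {
      f$amplitude_hu <- f$amplitude_hu * rlnorm(1, 0, 0.25)
      f
    })
    spec
  })
}

#' Generate matched control-like and judo-like cohorts
#'
#' Produces `n_per_group` phantoms per profile from a shared base geometry.
#' Per-subject seeds are derived reproducibly from the master seed, and
#' inter-subject variability is applied as multiplicative log-normal jitter
#' on the baseline HU (sdlog 0.05), the laminar amplitude (sdlog 0.08) and
#' each focus amplitude (sdlog 0.25), creating group overlap so downstream
#' statistics are meaningful.
#'
#' @param n_per_group Subjects per group, >= 2 (default 15, the study size
#'   of an elite-athlete vs control comparison).
#' @param base_spec A [phantom_spec()]; its profile field is overridden.
#' @param seed Master seed.
#' @param profiles Which group(s) to generate (default both).
#' @return List with elements `control_like` and `judo_like` (or the subset
#'   requested), each a list of [make_phantom()] results.
#' @export
make_cohort <- function(n_per_group = 15, base_spec = phantom_spec(), seed = 1L,
                        profiles = c("control_like", "judo_like")) {
  stopifnot(inherits(base_spec, "phantom_spec"),
            all(profiles %in% c("control_like", "judo_like")))
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  out <- list()
  for (g in profiles) {
    base <- base_spec
    base$profile <- g
    base$foci <- if (g == "judo_like") {
      if (length(base_spec$foci)) base_spec$foci else default_foci(base$bone)
    } else list()
    gi <- if (g == "control_like") 1L else 2L
    out[[g]] <- lapply(seq_len(n_per_group), function(i) {
      sp <- .jitter_spec(base, derive_seed(seed, 1000L * gi + i))
      sp$seed <- derive_seed(seed, 1000L * gi + 500L + i)
      make_phantom(sp)
    })
  }
  out
}
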