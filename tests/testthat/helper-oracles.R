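# Independent brute-force oracles. These deliberately use different
# mechanisms (if-chains, explicit BFS, nested loops) from the package code
# paths they check.

# density bin of one integer HU value, as a literal if-chain
oracle_bin_one <- function(h) {
  if (h < 100) 0L
  else if (h <= 200) 1L
  else if (h <= 300) 2L
  else if (h <= 400) 3L
  else if (h <= 500) 4L
  else if (h <= 600) 5L
  else if (h <= 700) 6L
  else if (h <= 800) 7L
  else if (h <= 900) 8L
  else if (h <= 1000) 9L
  else if (h <= 1100) 10L
  else if (h <= 1200) 11L
  else 12L
}

oracle_bin_grid <- function(vol, mask) {
  out <- array(0L, dim(vol$data))
  for (i in which(mask)) out[i] <- oracle_bin_one(vol$data[i])
  out
}

# 26-connected flood fill from a seed, plain breadth-first scan
oracle_flood <- function(mask, seed) {
  d <- dim(mask)
  lab <- array(FALSE, d)
  queue <- matrix(seed, ncol = 3)
  lab[queue] <- TRUE
  while (nrow(queue) > 0) {
    v <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      w <- v + c(dx, dy, dz)
      if (any(w < 1) || any(w > d)) next
      if (mask[w[1], w[2], w[3]] && !lab[w[1], w[2], w[3]]) {
        lab[w[1], w[2], w[3]] <- TRUE
        queue <- rbind(queue, w)
      }
    }
  }
  lab
}

# per-column maximum over ROI voxels, nested loops
oracle_project <- function(vol, mask) {
  d <- dim(mask)
  out <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    col <- vol$data[i, j, ][mask[i, j, ]]
    if (length(col)) out[i, j] <- max(col)
  }
  out
}

# 8-connected 2D components by repeated flood fill; returns list of pixel
# index matrices, in scan order
oracle_cc2d <- function(hd) {
  d <- dim(hd)
  seen <- matrix(FALSE, d[1], d[2])
  comps <- list()
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!hd[i, j] || seen[i, j]) next
    queue <- matrix(c(i, j), ncol = 2)
    seen[i, j] <- TRUE
    pix <- queue
    while (nrow(queue) > 0) {
      v <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (dy in -1:1) for (dx in -1:1) {
        if (dx == 0 && dy == 0) next
        w <- v + c(dx, dy)
        if (any(w < 1) || w[1] > d[1] || w[2] > d[2]) next
        if (hd[w[1], w[2]] && !seen[w[1], w[2]]) {
          seen[w[1], w[2]] <- TRUE
          queue <- rbind(queue, w)
          pix <- rbind(pix, w)
        }
      }
    }
    comps[[length(comps) + 1]] <- pix
  }
  comps
}

# connected random blob: union of a few solid boxes plus salt, guaranteed
# non-empty
random_mask3d <- function(dims, p = 0.4) {
  m <- array(runif(prod(dims)) < p, dims)
  m
}

random_volume <- function(dims, lo = -200, hi = 1600) {
  ct_volume(array(sample(lo:hi, prod(dims), replace = TRUE), dims),
            spacing_mm = c(1, 1, 1))
}

# density map fixture: full rectangular footprint at a base HU
make_test_map <- function(nx = 30, ny = 30, base = 300, side = "right",
                          bone = "distal_femur", spacing = c(1, 1)) {
  density_map(matrix(base, nx, ny), matrix(TRUE, nx, ny), spacing, bone, side)
}

# paint a filled disc of given HU onto a map (pixel units)
add_disc <- function(map, cx, cy, r, value) {
  d <- dim(map$values)
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    if ((i - cx)^2 + (j - cy)^2 <= r^2) map$values[i, j] <- value
  map$values[!map$footprint] <- NA
  map
}

# mirror a map left-right (x axis), optionally flipping the side flag
mirror_map <- function(map, flip_side = TRUE) {
  v <- map$values[rev(seq_len(nrow(map$values))), , drop = FALSE]
  f <- map$footprint[rev(seq_len(nrow(map$footprint))), , drop = FALSE]
  side <- if (flip_side) setdiff(c("left", "right"), map$side) else map$side
  density_map(v, f, map$pixel_spacing_mm, map$bone, side)
}

noiseless_spec <- function(...) {
  phantom_spec(noise_sd_hu = 0, ...)
}
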