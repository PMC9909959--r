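#' Pattern taxonomy label sets
#'
#' Distribution patterns of high-density areas are bone-specific:
#' distal femur — Blank, Anterior-Lateral, Dual Center, Center Connections;
#' tibial plateau — Blank, Scatter, Multi-Center, Multi-Center Connections.
#'
#' @param bone `"distal_femur"` or `"tibial_plateau"`.
#' @return Character vector of admissible labels.
#' @export
pattern_labels <- function(bone) {
  if (is_femur(check_bone(bone)))
    c("Blank", "Anterior-Lateral", "Dual Center", "Center Connections")
  else
    c("Blank", "Scatter", "Multi-Center", "Multi-Center Connections")
}

# column (medial=1..lateral=3) of a region index
.region_col <- function(r) ((r - 1L) %% 3L) + 1L

#' Classify the high-density distribution pattern of one knee
#'
#' Deterministic rules over the detected components and the nine-region
#' grid. The taxonomy names and their bone-applicability follow the CTOAM
#' pattern classification; the decision geometry is an explicit,
#' parameterized convention of this package (the literature names the types
#' without operational rules).
#'
#' Distal femur, in precedence order:
#' \itemize{
#' \item \emph{Blank} — no component.
#' \item \emph{Center Connections} — one component bridges the central row's
#'   medial and lateral cells (touches both region 4 and region 6).
#' \item \emph{Anterior-Lateral} — every component centroid lies in the
#'   anterior-lateral quadrant of the footprint (quadrant defined
#'   anatomically, so it mirrors with `side`).
#' \item \emph{Dual Center} — otherwise (typically >= 2 disjoint components
#'   over distinct columns; also the total-function fallback).
#' }
#' Tibial plateau, in precedence order: \emph{Blank} (no component);
#' \emph{Multi-Center Connections} (one component touches >= 2 of the three
#' columns); \emph{Multi-Center} (>= 2 disjoint components each at least
#' `big_area_mm2`); \emph{Scatter} (otherwise).
#'
#' @param areas A [detect_high_density()] result.
#' @param grid The matching [nine_regions()] grid (unused fields tolerated).
#' @param bone Bone override; defaults to the bone recorded on `areas`.
#' @param big_area_mm2 Minimum area of a tibial "center" (default 100).
#' @return Object of class `pattern_label` with `bone`, `label`, `evidence`.
#' @export
classify_pattern <- function(areas, grid = NULL, bone = areas$bone,
                             big_area_mm2 = 100) {
  stopifnot(inherits(areas, "high_density_areas"))
  bone <- check_bone(bone)
  comps <- areas$components
  n <- length(comps)
  evidence <- list(n_components = n,
                   areas_mm2 = vapply(comps, `[[`, 0, "area_mm2"),
                   regions = lapply(comps, `[[`, "regions"))
  label <- if (is_femur(bone)) {
    if (n == 0L) "Blank"
    else if (any(vapply(comps, function(cp) all(c(4L, 6L) %in% cp$regions), TRUE)))
      "Center Connections"
    else if (all(vapply(comps, function(cp) .in_anterior_lateral(cp$centroid, areas), TRUE)))
      "Anterior-Lateral"
    else "Dual Center"
  } else {
    if (n == 0L) "Blank"
    else if (any(vapply(comps, function(cp) length(unique(.region_col(cp$regions))) >= 2L, TRUE)))
      "Multi-Center Connections"
    else if (sum(vapply(comps, `[[`, 0, "area_mm2") >= big_area_mm2) >= 2L)
      "Multi-Center"
    else "Scatter"
  }
  structure(list(bone = bone, label = label, evidence = evidence),
            class = "pattern_label")
}

# anterior-lateral quadrant of the footprint bounding box; +y is anterior,
# the lateral half flips with side (lateral = +x on the right knee)
.in_anterior_lateral <- function(centroid, areas) {
  bb <- areas$bbox
  xmid <- (bb["x0"] + bb["x1"]) / 2
  ymid <- (bb["y0"] + bb["y1"]) / 2
  anterior <- centroid[2] > ymid
  lateral <- if (areas$side == "right") centroid[1] > xmid else centroid[1] < xmid
  isTRUE(anterior && lateral)
}

#' @export
print.pattern_label <- function(x, ...) {
  cat(sprintf("pattern: %s (%s), %d component(s)\n", x$label, x$bone,
              x$evidence$n_components))
  invisible(x)
}

#' Cohort pattern-frequency table
#'
#' Counts each taxonomy label over a cohort of knees and computes the integer
#' percentage with the same rounding rule as [region_frequency()]. All knees
#' must share one bone; counts sum to `n_knees`.
#'
#' @param labels List of [classify_pattern()] results, one per knee.
#' @param n_knees Number of knees (defaults to `length(labels)`).
#' @return data.frame with columns `label`, `count`, `percent`.
#' @export
pattern_table <- function(labels, n_knees = length(labels)) {
  stopifnot(n_knees >= 1, length(labels) == n_knees)
  bones <- unique(vapply(labels, `[[`, "", "bone"))
  if (length(bones) != 1L) stop("pattern_table requires a single bone", call. = FALSE)
  lset <- pattern_labels(bones)
  got <- vapply(labels, `[[`, "", "label")
  if (!all(got %in% lset)) stop("label outside the bone-appropriate set", call. = FALSE)
  count <- vapply(lset, function(l) sum(got == l), 0L)
  data.frame(label = lset, count = as.integer(count),
             percent = percent_integer(count, n_knees), row.names = NULL)
}
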