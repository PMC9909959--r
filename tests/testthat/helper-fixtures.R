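# shared knee-map fixtures covering the full pattern taxonomy

stub_areas <- function(region_sets) {
  structure(list(components = lapply(region_sets, function(r) list(regions = r))),
            class = "high_density_areas")
}

classify_map <- function(map, big_area_mm2 = 100) {
  rg <- nine_regions(map)
  areas <- detect_high_density(map, regions = rg)
  classify_pattern(areas, rg, big_area_mm2 = big_area_mm2)
}

add_band <- function(map, x0, x1, y0, y1, value = 950) {
  map$values[x0:x1, y0:y1] <- value
  map$values[!map$footprint] <- NA
  map
}

femur_fixtures <- function() {
  base <- make_test_map(30, 30, bone = "distal_femur", side = "right")
  list(
    Blank = base,
    `Anterior-Lateral` = add_disc(base, 23, 23, 4, 950),
    `Dual Center` = add_disc(add_disc(base, 5, 15, 4, 950), 25, 15, 4, 950),
    `Center Connections` = add_band(base, 3, 27, 13, 17)
  )
}

tibia_fixtures <- function() {
  base <- make_test_map(45, 45, bone = "tibial_plateau", side = "right")
  list(
    Blank = base,
    Scatter = add_disc(add_disc(base, 5, 5, 4, 950), 5, 40, 4, 950),
    `Multi-Center` = add_disc(add_disc(base, 8, 23, 6, 950), 38, 23, 6, 950),
    `Multi-Center Connections` = add_band(base, 5, 40, 20, 26)
  )
}

make_label <- function(bone, label) {
  structure(list(bone = bone, label = label), class = "pattern_label")
}
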