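#' Default run configuration
#'
#' All pipeline knobs with their defaults, materialized so a manifest fully
#' determines a rerun. Any subset can be overridden by name, or loaded from
#' a YAML file with [read_run_config()].
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of class `ctoam_config`.
#' @export
ctoam_config <- function(...) {
  cfg <- list(
    n_per_group = 15L,
    bones = c("distal_femur", "tibial_plateau"),
    sides = c("right", "left"),
    grid_shape = c(48L, 48L, 36L),
    spacing_mm = 0.625,
    shell_thickness_mm = 5,
    baseline_hu = 280,
    lam_amp_hu = 200,
    lam_scale_mm = 3,
    texture_amp_hu = 150,
    remodel_gain = 1.5,
    remodel_depth_gain = 3,
    noise_sd_hu = 30,
    threshold_hu = 901L,
    min_area_mm2 = 25,
    big_area_mm2 = 100,
    alpha = 0.05,
    welch = FALSE,
    paired = FALSE,
    p_adjust = "none",
    seed = 1L,
    write_png = FALSE,
    write_volumes = FALSE,
    verbosity = 1L
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  cfg[names(ov)] <- ov
  structure(cfg, class = "ctoam_config")
}

#' @rdname ctoam_config
#' @param path YAML file of overrides.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  do.call(ctoam_config, yaml::read_yaml(path))
}

.log_factory <- function(log_path, verbosity) {
  function(...) {
    msg <- paste0(...)
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg, "\n", sep = "",
        file = log_path, append = TRUE)
    if (verbosity > 0) message(msg)
  }
}

.stage <- function(name, log, expr) {
  log("stage ", name, " ...")
  tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
}

# one knee through ROI -> binning -> profile -> map -> regions -> areas -> label
.process_knee <- function(phantom, cfg) {
  vol <- phantom$volume
  spec <- phantom$spec
  mask <- bone_mask(vol)
  roi <- clip_to_epiphyseal(mask, phantom$truth$epiphyseal_plane_z, spec$bone,
                            side = spec$side, spacing_mm = vol$spacing_mm)
  labels <- bin_voxels(vol, roi)
  profile <- btv_profile(labels, vol$spacing_mm, bone = spec$bone, side = spec$side)
  map <- project_density(vol, roi)
  regions <- nine_regions(map)
  areas <- detect_high_density(map, threshold_hu = cfg$threshold_hu,
                               min_area_mm2 = cfg$min_area_mm2, regions = regions)
  label <- classify_pattern(areas, regions, big_area_mm2 = cfg$big_area_mm2)
  list(profile = profile, map = map, regions = regions, areas = areas,
       label = label, phantom = phantom)
}

#' Run the full CTOAM pipeline on simulated cohorts
#'
#' Simulates control-like and judo-like cohorts for each configured bone and
#' side, extracts the subchondral ROI of every knee, computes its %BTV
#' profile and articular-surface density map, detects and classifies
#' high-density areas, and writes cohort frequency tables, pattern tables
#' and the gated group-comparison report, together with a manifest listing
#' every output file with its content hash. The run is deterministic given
#' the seed; data files contain no timestamps (run metadata goes to the
#' log).
#'
#' @param config A [ctoam_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; defaults to `config$seed`. Per-stage seeds are
#'   derived from it.
#' @return Invisibly, a list with the in-memory results (`knees`, `reports`,
#'   `tables`, `manifest_path`).
#' @export
ctoam_run <- function(config = ctoam_config(), out_dir, seed = config$seed) {
  stopifnot(inherits(config, "ctoam_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "profiles"), showWarnings = FALSE)
  if (config$write_png) dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
  if (config$write_volumes) dir.create(file.path(out_dir, "volumes"), showWarnings = FALSE)
  log <- .log_factory(file.path(out_dir, "run.log"), config$verbosity)
  config$seed <- as.integer(seed)
  log("ctoam run, seed ", seed)
  files <- character()
  emit <- function(obj, path, writer) {
    writer(obj, path)
    files <<- c(files, path)
    path
  }
  results <- list()
  tables <- list()
  for (bi in seq_along(config$bones)) {
    bone <- config$bones[bi]
    knees <- .stage(paste0("simulate[", bone, "]"), log, {
      kn <- list()
      for (si in seq_along(config$sides)) {
        side <- config$sides[si]
        base <- phantom_spec(bone = bone, side = side,
                             grid_shape = config$grid_shape,
                             spacing_mm = config$spacing_mm,
                             shell_thickness_mm = config$shell_thickness_mm,
                             baseline_hu = config$baseline_hu,
                             lam_amp_hu = config$lam_amp_hu,
                             lam_scale_mm = config$lam_scale_mm,
                             texture_amp_hu = config$texture_amp_hu,
                             remodel_gain = config$remodel_gain,
                             remodel_depth_gain = config$remodel_depth_gain,
                             noise_sd_hu = config$noise_sd_hu)
        coh <- make_cohort(config$n_per_group, base,
                           seed = derive_seed(seed, 100L * bi + si))
        for (g in names(coh)) for (i in seq_along(coh[[g]]))
          kn[[paste(g, side, i, sep = "_")]] <- coh[[g]][[i]]
      }
      kn
    })
    processed <- .stage(paste0("analyze[", bone, "]"), log,
                        lapply(knees, .process_knee, cfg = config))
    .stage(paste0("write[", bone, "]"), log, {
      for (nm in names(processed)) {
        p <- processed[[nm]]
        emit(p$profile, file.path(out_dir, "profiles",
                                  paste0(bone, "_", nm, ".csv")), write_profile_csv)
        if (config$write_png) {
          emit(p$map, file.path(out_dir, "maps", paste0(bone, "_", nm, ".png")),
               write_map_png)
          emit(p$map, file.path(out_dir, "maps", paste0(bone, "_", nm, ".csv")),
               write_map_csv)
        }
        if (config$write_volumes)
          emit(p$phantom$volume,
               file.path(out_dir, "volumes", paste0(bone, "_", nm, ".nii.gz")),
               write_volume)
      }
    })
    grp <- function(g) processed[grepl(paste0("^", g, "_"), names(processed))]
    for (g in c("control_like", "judo_like")) {
      n_knees <- config$n_per_group * length(config$sides)
      freq <- region_frequency(lapply(grp(g), `[[`, "areas"), n_knees)
      pat <- pattern_table(lapply(grp(g), `[[`, "label"), n_knees)
      tables[[paste(bone, "frequency", g, sep = "_")]] <- freq
      tables[[paste(bone, "patterns", g, sep = "_")]] <- pat
      emit(freq, file.path(out_dir, paste0(bone, "_frequency_", g, ".csv")),
           write_table_csv)
      emit(pat, file.path(out_dir, paste0(bone, "_patterns_", g, ".csv")),
           write_table_csv)
    }
    report <- .stage(paste0("compare[", bone, "]"), log,
      btv_report(lapply(grp("judo_like"), `[[`, "profile"),
                 lapply(grp("control_like"), `[[`, "profile"),
                 group_names = c("judo_like", "control_like"),
                 alpha = config$alpha, welch = config$welch,
                 p_adjust = config$p_adjust, paired = config$paired))
    tables[[paste0(bone, "_btv_group_comparison")]] <- report$group_comparison
    emit(report$group_comparison,
         file.path(out_dir, paste0(bone, "_btv_group_comparison.csv")),
         write_table_csv)
    if (!is.null(report$left_right))
      emit(report$left_right,
           file.path(out_dir, paste0(bone, "_btv_left_right.csv")),
           write_table_csv)
    results[[bone]] <- list(knees = processed, report = report)
  }
  manifest <- list(
    config = unclass(config),
    files = data.frame(path = sub(paste0("^", out_dir, "/?"), "", files),
                       md5 = unname(tools::md5sum(files))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log("run complete: ", length(files), " data files")
  invisible(list(results = results, tables = tables, manifest_path = manifest_path))
}
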