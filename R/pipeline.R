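#' Default run configuration for the melanin pipeline
#'
#' Central place for every threshold and kernel the pipeline uses; all values
#' are recorded in each report for provenance.
#'
#' @param frpe_pixel_threshold voxel-level F_RPE melanin threshold (0.15).
#' @param thickness_threshold_um lesion thickness threshold (70 um).
#' @param flow_threshold decorrelation threshold for binary flow (0.30).
#' @param mu_ref_mm1 attenuation normalization constant (10 mm^-1).
#' @param dopu_kernel,angio_kernel odd `(depth, aline)` windows.
#' @param s0_floor_factor validity floor = factor x total noise variance.
#' @param tail_cutoff_px bottom rows excluded from attenuation.
#' @param axial_length_mm optional axial length for Littmann scaling of the
#'   transverse pitches (`NULL` = nominal pitches).
#' @param seed seed recorded with the run.
#' @return A `run_config` list.
#' @export
run_config <- function(frpe_pixel_threshold = 0.15,
                       thickness_threshold_um = 70,
                       flow_threshold = 0.30,
                       mu_ref_mm1 = 10,
                       dopu_kernel = c(3L, 3L),
                       angio_kernel = c(3L, 3L),
                       s0_floor_factor = 3,
                       tail_cutoff_px = 16L,
                       axial_length_mm = NULL,
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full melanin pipeline on one volume
#'
#' Chains compositing, DOPU (measured or synthesized), attenuation,
#' angiography, F_RPE fusion, the thickness map, the lesion area and — when
#' ground-truth PED surfaces are available — the Cavalieri PED volume. All
#' thresholds come from the [run_config()] and are echoed in the returned
#' bundle together with a config hash.
#'
#' @param vol a `list(tomo, truth)` from [generate_phantom()] /
#'   [subject_volume()], or a path readable by [read_volume()]. `truth` may
#'   be `NULL` for non-phantom data.
#' @param config a [run_config()].
#' @param dopu_source `"measured"` (from the polarization channels) or
#'   `"synthesized"` (from intensity via `model`).
#' @param model trained [synth_model()], required when
#'   `dopu_source = "synthesized"`.
#' @param roi optional en-face logical ROI for the lesion area; defaults to
#'   the truth PED region (elevation > 0) when present.
#' @param keep_volumes keep the full derived volumes in the bundle (set
#'   `FALSE` to retain only en-face maps and scalars).
#' @return A `report_bundle` list.
#' @export
run_pipeline <- function(vol, config = run_config(),
                         dopu_source = c("measured", "synthesized"),
                         model = NULL, roi = NULL, keep_volumes = TRUE) {
  dopu_source <- match.arg(dopu_source)
  if (is.character(vol)) vol <- read_volume(vol)
  .assert(inherits(vol$tomo, "jones_tomogram"),
          "missing stage: no tomogram field data (run phantom generation or load a container)")
  tomo <- vol$tomo; truth <- vol$truth
  t0 <- proc.time()[["elapsed"]]
  comp <- coherent_composite(tomo)
  if (dopu_source == "measured") {
    st <- compute_stokes(tomo)
    noise <- tomo$noise_variance_per_channel
    dopu <- compute_dopu(st, noise = noise, kernel = config$dopu_kernel,
                         s0_floor = config$s0_floor_factor * sum(noise))
  } else {
    .assert(!is.null(model) && isTRUE(model$trained),
            "missing stage: dopu_source='synthesized' needs a trained synthesis model")
    dopu <- synthesize_dopu(model, comp,
                            intensity_floor =
                              config$s0_floor_factor *
                              sum(tomo$noise_variance_per_channel))
  }
  atten <- compute_attenuation(comp, mu_ref_mm1 = config$mu_ref_mm1,
                               tail_cutoff_px = config$tail_cutoff_px)
  angio <- compute_angiography(tomo, kernel = config$angio_kernel,
                               threshold = config$flow_threshold,
                               phases = comp$phase_offsets)
  frpe <- compute_frpe(dopu, atten, angio,
                       pixel_threshold = config$frpe_pixel_threshold)
  tmap <- thickness_map(frpe, tomo$axial_pitch_um)
  scale <- if (is.null(config$axial_length_mm)) 1
           else transverse_scale(config$axial_length_mm)
  ap <- tomo$aline_pitch_mm * scale
  bp <- tomo$bscan_pitch_mm * scale
  if (is.null(roi) && !is.null(truth)) roi <- truth$ped_elevation_um > 0
  if (!is.null(roi) && !any(roi)) roi <- NULL   # healthy eye: whole scan
  la <- lesion_area(tmap, ap, bp,
                    thickness_threshold_um = config$thickness_threshold_um,
                    roi = roi)
  pv <- NULL
  if (!is.null(truth))
    pv <- ped_volume(truth$ped_inner_boundary_px, truth$bruch_depth_px,
                     tomo$axial_pitch_um, ap, bp)
  bundle <- list(
    subject_id = tomo$subject_id,
    dopu_source = dopu_source,
    intensity_enface = enface_projection(comp$intensity, "mean"),
    thickness_map = tmap,
    mean_thickness_um = mean(tmap$thickness_um),
    lesion = la,
    ped = pv,
    truth_mean_thickness_um = if (!is.null(truth)) mean(truth$melanin_thickness_um),
    geometry = list(n_depth = dim(tomo$field)[1L],
                    n_alines = dim(tomo$field)[2L],
                    n_bscans = dim(tomo$field)[3L],
                    axial_pitch_um = tomo$axial_pitch_um,
                    aline_pitch_mm = ap, bscan_pitch_mm = bp,
                    transverse_scale = scale),
    config = config,
    config_hash = config_hash(config),
    elapsed_s = proc.time()[["elapsed"]] - t0
  )
  if (keep_volumes)
    bundle$volumes <- list(intensity = comp, dopu = dopu, attenuation = atten,
                           angiography = angio, frpe = frpe)
  structure(bundle, class = "report_bundle")
}

#' Cohort-level summary report
#'
#' Aggregates per-subject report bundles into group statistics: mean and SD
#' of the mean map thickness, paired original-versus-synthesized statistics
#' when both sources are present, and the lesion-area-versus-PED-volume
#' correlation.
#'
#' @param bundles list of `report_bundle`s (at least 2 subjects). Bundles
#'   from both DOPU sources may be mixed; they are paired by `subject_id`.
#' @return A `cohort_report`: `per_subject` data frame, `group` summary,
#'   optional `paired` statistics and `lesion_vs_ped` correlation.
#' @export
cohort_report <- function(bundles) {
  .assert(length(bundles) >= 1L, "no bundles")
  per <- do.call(rbind, lapply(bundles, function(b) data.frame(
    subject_id = b$subject_id,
    dopu_source = b$dopu_source,
    mean_thickness_um = b$mean_thickness_um,
    lesion_area_mm2 = b$lesion$area_mm2,
    ped_volume_mm3 = if (!is.null(b$ped)) b$ped$volume_mm3 else NA_real_,
    n_depth = b$geometry$n_depth, n_alines = b$geometry$n_alines,
    n_bscans = b$geometry$n_bscans,
    stringsAsFactors = FALSE)))
  .assert(length(unique(per$subject_id)) >= 2L, "cohort needs at least 2 subjects")
  geo <- unique(per[, c("n_depth", "n_alines", "n_bscans")])
  if (nrow(geo) > 1L) stop("mixed scan geometries in cohort", call. = FALSE)
  group <- do.call(rbind, lapply(split(per, per$dopu_source), function(g)
    data.frame(dopu_source = g$dopu_source[1L], n = nrow(g),
               mean_thickness_um = mean(g$mean_thickness_um),
               sd_thickness_um = stats::sd(g$mean_thickness_um),
               mean_lesion_area_mm2 = mean(g$lesion_area_mm2),
               stringsAsFactors = FALSE)))
  paired <- NULL
  if (all(c("measured", "synthesized") %in% per$dopu_source)) {
    m <- per[per$dopu_source == "measured", ]
    s <- per[per$dopu_source == "synthesized", ]
    s <- s[match(m$subject_id, s$subject_id), ]
    if (!anyNA(s$subject_id))
      paired <- list(
        thickness = compare_original_synthesized(m$mean_thickness_um,
                                                 s$mean_thickness_um),
        lesion_area = compare_original_synthesized(m$lesion_area_mm2,
                                                   s$lesion_area_mm2))
  }
  lesion_vs_ped <- NULL
  base <- per[per$dopu_source == per$dopu_source[1L], ]
  ok <- is.finite(base$ped_volume_mm3)
  if (sum(ok) >= 3L && stats::sd(base$lesion_area_mm2[ok]) > 0 &&
      stats::sd(base$ped_volume_mm3[ok]) > 0) {
    ct <- stats::cor.test(base$lesion_area_mm2[ok], base$ped_volume_mm3[ok])
    lesion_vs_ped <- list(pearson_r = unname(ct$estimate), p = ct$p.value,
                          n = sum(ok))
  }
  structure(list(per_subject = per, group = group, paired = paired,
                 lesion_vs_ped = lesion_vs_ped),
            class = "cohort_report")
}

#' Write a cohort report to CSV and JSON
#'
#' @param report a `cohort_report`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_subject, file.path(dir, "per_subject.csv"),
                   row.names = FALSE)
  utils::write.csv(report$group, file.path(dir, "group.csv"), row.names = FALSE)
  keep <- report[c("group", "paired", "lesion_vs_ped")]
  keep$paired <- lapply(keep$paired, function(p) p[setdiff(names(p), "data")])
  jsonlite::write_json(keep, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(dir)
}
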