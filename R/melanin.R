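#' Fuse DOPU, attenuation and flow into the RPE-melanin index F_RPE
#'
#' Pointwise `F_RPE = mu_norm * (1 - DOPU) * (1 - binary_flow)`. The index is
#' high only where tissue attenuates strongly, scrambles polarization
#' (melanin) and carries no flow — which singles out RPE melanin against the
#' vascular, equally depolarizing choroid. Voxels invalid in any input get
#' `F_RPE = 0`.
#'
#' @param dopu a `dopu_volume` (measured or synthesized).
#' @param atten an `attenuation_volume`.
#' @param angio an `angio_volume`.
#' @param pixel_threshold voxel-level melanin threshold stored with the
#'   volume (default 0.15).
#' @return An `frpe_volume`: `frpe` in [0, 1], `pixel_threshold`,
#'   `inputs_provenance`.
#' @export
compute_frpe <- function(dopu, atten, angio, pixel_threshold = 0.15) {
  .assert(inherits(dopu, "dopu_volume"), "dopu must be a dopu_volume")
  .assert(inherits(atten, "attenuation_volume"), "atten must be an attenuation_volume")
  .assert(inherits(angio, "angio_volume"), "angio must be an angio_volume")
  d <- dim(dopu$dopu)
  .assert(identical(d, dim(atten$mu_norm)) && identical(d, dim(angio$decorrelation)),
          "input volumes must have identical dimensions")
  dp <- dopu$dopu
  dp[!dopu$valid_mask] <- 1            # invalid DOPU contributes 0
  f <- atten$mu_norm * (1 - dp) * (1 - angio$binary_flow)
  f[!dopu$valid_mask | !atten$valid_mask] <- 0
  structure(list(frpe = f, pixel_threshold = pixel_threshold,
                 inputs_provenance = list(
                   dopu_source = dopu$source,
                   mu_ref_mm1 = atten$mu_ref_mm1,
                   flow_threshold = angio$threshold)),
            class = "frpe_volume")
}

#' En-face RPE-melanin thickness map
#'
#' Counts, along each A-line, the voxels with `F_RPE >= pixel_threshold`
#' (0.15 by default; contiguity is not required) and multiplies by the axial
#' pitch. Thickness is therefore always an integer multiple of the pitch.
#'
#' @param frpe an `frpe_volume`.
#' @param axial_pitch_um axial pitch in micrometres.
#' @param pixel_threshold override of the volume's stored threshold.
#' @param contiguous when `TRUE`, count only the longest contiguous
#'   suprathreshold run per A-line (sensitivity analysis).
#' @return A `melanin_thickness_map`: `thickness_um` `[aline, bscan]`,
#'   `axial_pitch_um`, `source`.
#' @export
thickness_map <- function(frpe, axial_pitch_um, pixel_threshold = NULL,
                          contiguous = FALSE) {
  .assert(inherits(frpe, "frpe_volume"), "frpe must be an frpe_volume")
  .assert(axial_pitch_um > 0, "axial pitch required")
  thr <- pixel_threshold %||% frpe$pixel_threshold
  supra <- frpe$frpe >= thr
  if (!contiguous) {
    counts <- apply(supra, c(2L, 3L), sum)
  } else {
    counts <- apply(supra, c(2L, 3L), function(v) {
      r <- rle(v)
      m <- r$lengths[r$values]
      if (length(m)) max(m) else 0L
    })
  }
  structure(list(thickness_um = counts * axial_pitch_um,
                 axial_pitch_um = axial_pitch_um,
                 pixel_threshold = thr,
                 source = frpe$inputs_provenance$dopu_source %||% "measured"),
            class = "melanin_thickness_map")
}

#' Area of thickened RPE-melanin lesions
#'
#' Thresholds the thickness map (70 um by default), optionally intersects
#' with a region of interest (e.g. the PED margin), and reports the area by
#' exact pixel counting: `area = count * aline_pitch * bscan_pitch`.
#'
#' @param map a `melanin_thickness_map`.
#' @param aline_pitch_mm,bscan_pitch_mm transverse pitches in mm (after any
#'   Littmann scaling).
#' @param thickness_threshold_um lesion threshold (default 70).
#' @param roi optional logical `[aline, bscan]` mask of the measurement
#'   region.
#' @return A `lesion_area_result`: `mask`, `area_mm2`, `pixel_area_mm2`,
#'   `thickness_threshold_um`.
#' @export
lesion_area <- function(map, aline_pitch_mm, bscan_pitch_mm,
                        thickness_threshold_um = 70, roi = NULL) {
  .assert(inherits(map, "melanin_thickness_map"), "map must be a melanin_thickness_map")
  .assert(aline_pitch_mm > 0 && bscan_pitch_mm > 0, "pitches must be positive")
  mask <- map$thickness_um >= thickness_threshold_um
  if (!is.null(roi)) {
    .assert(identical(dim(roi), dim(mask)), "roi does not match the scan grid")
    mask <- mask & roi
  }
  px <- aline_pitch_mm * bscan_pitch_mm
  structure(list(mask = mask, area_mm2 = sum(mask) * px,
                 pixel_area_mm2 = px,
                 thickness_threshold_um = thickness_threshold_um),
            class = "lesion_area_result")
}

#' PED volume by the Cavalieri principle
#'
#' Sums, per B-scan, the cross-sectional area between the detached RPE base
#' and Bruch's membrane (`sum over A-lines of (bruch - boundary) * axial
#' pitch * A-line pitch`), then multiplies by the B-scan spacing:
#' `V = sum(per-B-scan areas) * spacing`.
#'
#' @param inner_boundary_px,bruch_px `[aline, bscan]` depth indices of the
#'   detachment boundary and the Bruch reference surface; the boundary must
#'   not lie below Bruch's membrane anywhere (depth increases away from the
#'   vitreous).
#' @param axial_pitch_um,aline_pitch_mm,bscan_pitch_mm pixel pitches.
#' @return A `ped_volume_result`: `volume_mm3`, `per_bscan_area_mm2`,
#'   `bscan_spacing_mm`.
#' @export
ped_volume <- function(inner_boundary_px, bruch_px, axial_pitch_um,
                       aline_pitch_mm, bscan_pitch_mm) {
  .assert(identical(dim(inner_boundary_px), dim(bruch_px)),
          "boundary and reference surfaces must share dimensions")
  bad <- which(inner_boundary_px > bruch_px, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("boundary crosses Bruch reference at (aline=%d, bscan=%d)",
                 bad[1L, 1L], bad[1L, 2L]), call. = FALSE)
  elev_mm <- (bruch_px - inner_boundary_px) * axial_pitch_um / 1000
  areas <- colSums(elev_mm * aline_pitch_mm)
  structure(list(volume_mm3 = sum(areas * bscan_pitch_mm),
                 per_bscan_area_mm2 = areas,
                 bscan_spacing_mm = bscan_pitch_mm),
            class = "ped_volume_result")
}

#' Littmann/Bennett transverse magnification scale for an eye
#'
#' Bennett-style axial-length correction of transverse image scale:
#' `scale = (AL - 1.82) / (24.46 - 1.82)`, unity for the 24.46 mm reference
#' eye. Transverse pitches are multiplied by this factor; areas therefore
#' scale by its square.
#'
#' @param axial_length_mm measured axial length in [15, 35] mm.
#' @return The dimensionless scale factor.
#' @export
transverse_scale <- function(axial_length_mm) {
  .assert(axial_length_mm >= 15 && axial_length_mm <= 35,
          "axial length out of range [15, 35] mm")
  (0.01306 * (axial_length_mm - 1.82)) / (0.01306 * (24.46 - 1.82))
}

#' En-face projection of a volume
#'
#' @param volume `[depth, aline, bscan]` array.
#' @param reducer one of `"mean"`, `"max"`, `"sum"`.
#' @param depth_range integer range `c(z1, z2)` (default: full depth).
#' @return En-face `[aline, bscan]` matrix.
#' @export
enface_projection <- function(volume, reducer = c("mean", "max", "sum"),
                              depth_range = NULL) {
  reducer <- match.arg(reducer)
  d <- dim(volume)
  depth_range <- depth_range %||% c(1L, d[1L])
  .assert(depth_range[1L] >= 1L && depth_range[2L] <= d[1L] &&
            depth_range[1L] <= depth_range[2L], "empty or out-of-range depth range")
  z <- seq.int(depth_range[1L], depth_range[2L])
  m <- matrix(volume[z, , , drop = FALSE], length(z), d[2L] * d[3L])
  v <- switch(reducer,
              mean = colMeans(m),
              sum = colSums(m),
              max = do.call(pmax, c(asplit(m, 1L), list(na.rm = TRUE))))
  matrix(v, d[2L], d[3L])
}

#' Render a thickness map as a color-coded 8-bit image
#'
#' Deterministic mapping of thickness onto a color ramp; values at or below
#' `range_um[1]` map to the first palette color, values at or above
#' `range_um[2]` to the last.
#'
#' @param map a `melanin_thickness_map` (or bare numeric matrix).
#' @param palette character vector of colors (default: dark blue to yellow
#'   heat ramp).
#' @param range_um display range in micrometres.
#' @param file optional PNG path to write (lossless).
#' @return `[aline, bscan, 3]` array of RGB values in [0, 1] quantized to
#'   8 bits, with attributes `range_um` and `palette`.
#' @export
render_colormap <- function(map, palette = c("#000030", "#2040A0", "#00A0A0",
                                             "#30C030", "#E0E000", "#FF8000",
                                             "#FF2000"),
                            range_um = NULL, file = NULL) {
  m <- if (inherits(map, "melanin_thickness_map")) map$thickness_um else map
  range_um <- range_um %||% c(0, max(m, 1e-9))
  .assert(range_um[2L] > range_um[1L], "invalid display range")
  t01 <- pmin(pmax((m - range_um[1L]) / (range_um[2L] - range_um[1L]), 0), 1)
  ramp <- grDevices::colorRamp(palette)
  rgb <- ramp(as.vector(t01)) / 255
  rgb <- round(rgb * 255) / 255                      # 8-bit quantization
  img <- array(rgb, c(dim(m), 3L))
  attr(img, "range_um") <- range_um
  attr(img, "palette") <- palette
  if (!is.null(file)) png::writePNG(aperm(img, c(2L, 1L, 3L)), file)
  img
}
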