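#' Stokes parameters of a dual-polarization tomogram
#'
#' Computes per-voxel Stokes parameters from the two detection channels:
#' `S0 = |E_H|^2 + |E_V|^2`, `S1 = |E_H|^2 - |E_V|^2`,
#' `S2 = 2 Re(E_H conj(E_V))`, `S3 = -2 Im(E_H conj(E_V))`.
#' Repeats are computed individually and then averaged (the default), or a
#' single repeat can be selected for ablation.
#'
#' @param tomo a `jones_tomogram` (see [generate_phantom()]).
#' @param average_repeats average Stokes parameters over repeats (default) or
#'   keep a single repeat.
#' @param repeat_index repeat to use when `average_repeats = FALSE`.
#' @return A `stokes_volume`: list of arrays `S0, S1, S2, S3` indexed
#'   `[depth, aline, bscan]`, plus bookkeeping fields.
#' @export
compute_stokes <- function(tomo, average_repeats = TRUE, repeat_index = 1L) {
  .assert(inherits(tomo, "jones_tomogram"), "tomo must be a jones_tomogram")
  d <- dim(tomo$field)
  .assert(length(d) == 5L && d[4L] == 2L, "field must have two channels")
  reps <- if (average_repeats) seq_len(d[5L]) else repeat_index
  acc <- lapply(1:4, function(i) array(0, d[1:3]))
  for (r in reps) {
    eh <- array(tomo$field[, , , 1L, r], d[1:3])
    ev <- array(tomo$field[, , , 2L, r], d[1:3])
    ih <- Re(eh)^2 + Im(eh)^2
    iv <- Re(ev)^2 + Im(ev)^2
    cr <- eh * Conj(ev)
    acc[[1]] <- acc[[1]] + ih + iv
    acc[[2]] <- acc[[2]] + ih - iv
    acc[[3]] <- acc[[3]] + 2 * Re(cr)
    acc[[4]] <- acc[[4]] - 2 * Im(cr)
  }
  n <- length(reps)
  structure(list(S0 = acc[[1]] / n, S1 = acc[[2]] / n,
                 S2 = acc[[3]] / n, S3 = acc[[4]] / n,
                 n_repeats_used = n,
                 noise_variance_per_channel = tomo$noise_variance_per_channel),
            class = "stokes_volume")
}

#' Noise-bias-corrected degree of polarization uniformity (DOPU)
#'
#' Averages the Stokes parameters over a small spatial kernel inside each
#' B-scan and forms DOPU from the noise-bias-corrected means (Makita-style
#' correction): `<S0>c = <S0> - (s2H + s2V)`, `<S1>c = <S1> - (s2H - s2V)`,
#' `<S2>c = <S2>`, `<S3>c = <S3>`, and
#' `DOPU = sqrt(<S1>c^2 + <S2>c^2 + <S3>c^2) / <S0>c`, clipped to [0, 1].
#' Windows are truncated at volume borders (the mean runs over the voxels
#' that exist; nothing is padded in). Voxels whose corrected `<S0>` falls at
#' or below `s0_floor` are flagged invalid and excluded downstream.
#'
#' @param stokes a `stokes_volume` from [compute_stokes()].
#' @param noise per-channel additive-noise variances `c(s2H, s2V)`; defaults
#'   to the variances carried by the tomogram.
#' @param kernel odd `(depth, aline)` window, default `c(3, 3)`.
#' @param s0_floor validity floor on corrected `<S0>`; default
#'   `3 * (s2H + s2V)` (noise-dominated voxels give unstable DOPU).
#' @return A `dopu_volume`: `dopu` array in [0, 1] (NA where invalid),
#'   `valid_mask`, `kernel_shape`, `source = "measured"`.
#' @export
compute_dopu <- function(stokes, noise = NULL, kernel = c(3L, 3L),
                         s0_floor = NULL) {
  .assert(inherits(stokes, "stokes_volume"), "stokes must be a stokes_volume")
  .assert(length(kernel) == 2L && all(kernel %% 2L == 1L),
          "kernel must be odd in both dimensions")
  noise <- noise %||% stokes$noise_variance_per_channel %||% c(0, 0)
  .assert(all(noise >= 0), "noise variances must be >= 0")
  s0_floor <- s0_floor %||% (3 * sum(noise))
  d <- dim(stokes$S0)
  nd <- d[1L]; na <- d[2L]; nb <- d[3L]
  cnt <- box_count(nd, na, kernel)
  # guard against voxels whose windowed S0 is pure floating-point residue
  # (e.g. signal-free regions of a noise-free volume)
  s0_floor <- max(s0_floor, 64 * .Machine$double.eps * max(abs(stokes$S0)))
  dopu <- array(NA_real_, d)
  valid <- array(FALSE, d)
  for (b in seq_len(nb)) {
    m0 <- box_sum(stokes$S0[, , b], kernel) / cnt - (noise[1L] + noise[2L])
    m1 <- box_sum(stokes$S1[, , b], kernel) / cnt - (noise[1L] - noise[2L])
    m2 <- box_sum(stokes$S2[, , b], kernel) / cnt
    m3 <- box_sum(stokes$S3[, , b], kernel) / cnt
    ok <- m0 > s0_floor
    v <- sqrt(m1^2 + m2^2 + m3^2) / m0
    v[v > 1] <- 1; v[v < 0] <- 0
    v[!ok] <- NA_real_
    dopu[, , b] <- v
    valid[, , b] <- ok
  }
  if (!any(valid)) warning("all voxels invalid (corrected S0 below floor)")
  structure(list(dopu = dopu, valid_mask = valid, kernel_shape = kernel,
                 s0_floor = s0_floor, noise = noise, source = "measured"),
            class = "dopu_volume")
}

#' Coherent composite of repeated B-scans (standard OCT intensity)
#'
#' Estimates each repeat's bulk phase offset against the first repeat per
#' A-line (the argument of the complex inner product of their fields over
#' depth and both channels), removes it, averages the complex fields across
#' repeats per channel, and returns the intensity of the mean field
#' (`|E_H|^2 + |E_V|^2`). Coherent averaging of N repeats lowers the additive
#' noise floor by about 1/N while preserving the static signal.
#'
#' @param tomo a `jones_tomogram`.
#' @return An `intensity_volume`: linear `intensity` array
#'   `[depth, aline, bscan]`, `log_intensity` (dB, floored), `provenance`,
#'   the per-(repeat, aline, bscan) `phase_offsets`, and pixel pitches.
#' @export
coherent_composite <- function(tomo) {
  .assert(inherits(tomo, "jones_tomogram"), "tomo must be a jones_tomogram")
  d <- dim(tomo$field)
  nd <- d[1L]; na <- d[2L]; nb <- d[3L]; nr <- d[5L]
  phases <- array(0, c(nr, na, nb))
  if (nr == 1L) {
    eh <- array(tomo$field[, , , 1L, 1L], d[1:3])
    ev <- array(tomo$field[, , , 2L, 1L], d[1:3])
    intensity <- Re(eh)^2 + Im(eh)^2 + Re(ev)^2 + Im(ev)^2
    provenance <- "single"
  } else {
    accH <- array(tomo$field[, , , 1L, 1L], d[1:3])
    accV <- array(tomo$field[, , , 2L, 1L], d[1:3])
    refH <- accH; refV <- accV
    for (r in 2L:nr) {
      eh <- array(tomo$field[, , , 1L, r], d[1:3])
      ev <- array(tomo$field[, , , 2L, r], d[1:3])
      # inner product against repeat 1, summed over depth and channels
      ip <- colSums(matrix(eh * Conj(refH) + ev * Conj(refV), nd, na * nb))
      ph <- Arg(ip)
      rot <- exp(-1i * array(rep(ph, each = nd), c(nd, na, nb)))
      accH <- accH + eh * rot
      accV <- accV + ev * rot
      phases[r, , ] <- ph
    }
    mh <- accH / nr; mv <- accV / nr
    intensity <- Re(mh)^2 + Im(mh)^2 + Re(mv)^2 + Im(mv)^2
    provenance <- sprintf("composite-of-%d-repeats", nr)
  }
  floor_db <- max(intensity) * 1e-8
  structure(list(intensity = intensity,
                 log_intensity = 10 * log10(pmax(intensity, floor_db)),
                 provenance = provenance,
                 n_repeats = d[5L],
                 phase_offsets = phases,
                 axial_pitch_um = tomo$axial_pitch_um,
                 aline_pitch_mm = tomo$aline_pitch_mm,
                 bscan_pitch_mm = tomo$bscan_pitch_mm,
                 noise_variance_per_channel = tomo$noise_variance_per_channel),
            class = "intensity_volume")
}

#' Estimate per-channel additive-noise variance from a signal-free region
#'
#' @param tomo a `jones_tomogram`.
#' @param depth_range integer range `c(z1, z2)` of depth rows with no tissue
#'   signal (e.g. vitreous rows near the top of the scan).
#' @param truth optional `phantom_truth`; when given, a warning is issued if
#'   the region overlaps tissue (nonzero attenuation above vitreous level).
#' @return Named vector `c(H = s2H, V = s2V)`: mean `|E|^2` per channel.
#' @export
estimate_noise <- function(tomo, depth_range, truth = NULL) {
  .assert(inherits(tomo, "jones_tomogram"), "tomo must be a jones_tomogram")
  d <- dim(tomo$field)
  z <- seq.int(max(1L, depth_range[1L]), min(d[1L], depth_range[2L]))
  n_vox <- length(z) * d[2L] * d[3L]
  .assert(n_vox >= 1000L, "noise region must contain at least 1000 voxels")
  if (!is.null(truth) &&
      any(truth$mu_map_mm1[z, , ] > min(truth$mu_map_mm1) + 1e-9))
    warning("noise region overlaps tissue")
  e <- tomo$field[z, , , , , drop = FALSE]
  p <- Re(e)^2 + Im(e)^2
  c(H = mean(p[, , , 1L, ]), V = mean(p[, , , 2L, ]))
}
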