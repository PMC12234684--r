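# Minimal constructors for hand-built inputs used across tests.

make_tomo <- function(field, axial_pitch_um = 4, aline_pitch_mm = 6 / 128,
                      bscan_pitch_mm = 6 / 64, noise = c(H = 0, V = 0),
                      subject_id = "toy") {
  structure(list(field = field, axial_pitch_um = axial_pitch_um,
                 aline_pitch_mm = aline_pitch_mm,
                 bscan_pitch_mm = bscan_pitch_mm,
                 noise_variance_per_channel = noise,
                 subject_id = subject_id, config = NULL),
            class = "jones_tomogram")
}

# Tomogram with every voxel in a given pure Jones state (possibly repeated).
uniform_state_tomo <- function(jones, nd = 8, na = 8, nb = 2, nr = 2,
                               amp = NULL) {
  amp <- amp %||% array(1, c(nd, na, nb))
  field <- array(0i, c(nd, na, nb, 2, nr))
  for (r in seq_len(nr)) {
    field[, , , 1, r] <- amp * jones[1]
    field[, , , 2, r] <- amp * jones[2]
  }
  make_tomo(field)
}

make_dopu <- function(dopu, valid = NULL, source = "measured") {
  valid <- valid %||% !is.na(dopu)
  structure(list(dopu = dopu, valid_mask = valid, kernel_shape = c(3L, 3L),
                 s0_floor = 0, noise = c(0, 0), source = source),
            class = "dopu_volume")
}

make_atten <- function(mu_norm, mu_ref = 10, valid = NULL) {
  valid <- valid %||% array(TRUE, dim(mu_norm))
  structure(list(mu_mm1 = mu_norm * mu_ref, mu_norm = mu_norm,
                 valid_mask = valid, mu_ref_mm1 = mu_ref,
                 tail_cutoff_px = 0L),
            class = "attenuation_volume")
}

make_angio <- function(decorrelation, threshold = 0.3) {
  structure(list(decorrelation = decorrelation,
                 binary_flow = decorrelation >= threshold,
                 threshold = threshold, kernel_shape = c(3L, 3L),
                 valid_mask = array(TRUE, dim(decorrelation))),
            class = "angio_volume")
}

make_thickness_map <- function(thickness_um, pitch = 4) {
  structure(list(thickness_um = thickness_um, axial_pitch_um = pitch,
                 pixel_threshold = 0.15, source = "measured"),
            class = "melanin_thickness_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force windowed DOPU oracle: plain loops, no vectorized shortcuts.
dopu_oracle <- function(st, noise, kernel, s0_floor) {
  d <- dim(st$S0)
  hd <- (kernel[1] - 1) %/% 2; ha <- (kernel[2] - 1) %/% 2
  out <- array(NA_real_, d)
  for (b in seq_len(d[3])) for (a in seq_len(d[2])) for (z in seq_len(d[1])) {
    zi <- max(1, z - hd):min(d[1], z + hd)
    ai <- max(1, a - ha):min(d[2], a + ha)
    m0 <- mean(st$S0[zi, ai, b]) - (noise[1] + noise[2])
    m1 <- mean(st$S1[zi, ai, b]) - (noise[1] - noise[2])
    m2 <- mean(st$S2[zi, ai, b])
    m3 <- mean(st$S3[zi, ai, b])
    if (m0 > s0_floor)
      out[z, a, b] <- min(max(sqrt(m1^2 + m2^2 + m3^2) / m0, 0), 1)
  }
  out
}

# Small default phantom used by several tests.
small_phantom <- function(..., seed = 7) {
  args <- utils::modifyList(list(n_bscans = 12, n_alines = 64, n_depth = 128,
                                 rpe_thickness_um = 72, snr_db = 20,
                                 seed = seed), list(...))
  generate_phantom(do.call(phantom_config, args))
}
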