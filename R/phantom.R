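#' Configuration for the digital retinal phantom
#'
#' Builds a validated configuration for [generate_phantom()]. The phantom is a
#' layered retina (vitreous, inner retina, RPE melanin band, sub-RPE
#' fluid/Bruch's membrane, choroid) observed by a dual-polarization OCT system
#' with repeated B-scans. The melanin band depolarizes (polarization
#' scrambling), choroidal vessels decorrelate between repeats (flow), and each
#' repeat carries fresh additive detector noise.
#'
#' @param n_bscans,n_alines,n_depth grid size (all at least 8). The defaults
#'   (64 x 128 x 256) are a reduced version of the full-scale 256 B-scan x
#'   512 A-line raster over a 6.0 x 6.0 mm area; full scale is available by
#'   configuration.
#' @param axial_pitch_um depth sampling pitch in micrometres per pixel.
#' @param scan_width_mm,scan_height_mm nominal transverse scan extents (fast
#'   A-line axis, slow B-scan axis).
#' @param n_repeats repeated B-scans per location (4, as acquired by the
#'   modelled system; at least 2 are needed for angiography).
#' @param rpe_thickness_um baseline thickness of the RPE melanin band.
#' @param ped optional detachment: list with `center_xy` (mm, scan-centred),
#'   `radius_mm`, `height_um` and `shape` (`"spherical-cap"` or `"gaussian"`).
#' @param migration_foci optional list of intraretinal melanin foci, each a
#'   list with `center_xyz` (aline mm, bscan mm, depth um above the RPE band)
#'   and `radius_um`.
#' @param choroid_melanin logical; when `TRUE` the choroid also scrambles
#'   polarization (melanin outside the RPE, the confound F_RPE suppresses).
#' @param scramble_p polarization-scrambling strength of melanin voxels in
#'   [0, 1]: 0 leaves the global polarization state untouched, 1 draws a fully
#'   random (Haar) state per voxel.
#' @param choroid_scramble_p scrambling strength for choroidal melanin.
#' @param flow_fraction fraction of choroid voxels behaving as vessels.
#' @param snr_db signal-to-noise ratio of the RPE band in dB (`Inf` for a
#'   noise-free volume). Must be positive.
#' @param seed integer seed; fixes the volume bit-for-bit.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_bscans = 64L, n_alines = 128L, n_depth = 256L,
                           axial_pitch_um = 4.0,
                           scan_width_mm = 6.0, scan_height_mm = 6.0,
                           n_repeats = 4L,
                           rpe_thickness_um = 40.0,
                           ped = NULL,
                           migration_foci = list(),
                           choroid_melanin = TRUE,
                           scramble_p = 0.9,
                           choroid_scramble_p = 0.4,
                           flow_fraction = 0.25,
                           snr_db = 20.0,
                           seed = 1L) {
  .assert(all(c(n_bscans, n_alines, n_depth) >= 8L), "all grid counts must be >= 8")
  .assert(n_repeats >= 1L, "n_repeats must be >= 1")
  .assert(axial_pitch_um > 0 && scan_width_mm > 0 && scan_height_mm > 0,
          "pitches and scan extents must be positive")
  .assert(scramble_p >= 0 && scramble_p <= 1, "scramble_p must lie in [0, 1]")
  .assert(choroid_scramble_p >= 0 && choroid_scramble_p <= 1,
          "choroid_scramble_p must lie in [0, 1]")
  .assert(flow_fraction >= 0 && flow_fraction <= 1, "flow_fraction must lie in [0, 1]")
  .assert(is.finite(snr_db) || is.infinite(snr_db), "snr_db must be numeric")
  .assert(snr_db > 0, "snr_db must be positive")
  .assert(rpe_thickness_um >= 0, "rpe_thickness_um must be nonnegative")
  if (!is.null(ped)) {
    .assert(is.list(ped) && all(c("radius_mm", "height_um") %in% names(ped)),
            "ped needs radius_mm and height_um")
    ped$center_xy <- ped$center_xy %||% c(0, 0)
    ped$shape <- ped$shape %||% "spherical-cap"
    .assert(ped$shape %in% c("spherical-cap", "gaussian"), "unknown ped shape")
    .assert(ped$height_um >= 0, "ped height_um must be >= 0")
    .assert(ped$radius_mm > 0, "ped radius_mm must be > 0")
    if (abs(ped$center_xy[1L]) + ped$radius_mm > scan_width_mm / 2 ||
        abs(ped$center_xy[2L]) + ped$radius_mm > scan_height_mm / 2)
      stop("PED extends beyond the scan area", call. = FALSE)
  }
  structure(list(
    n_bscans = as.integer(n_bscans), n_alines = as.integer(n_alines),
    n_depth = as.integer(n_depth), axial_pitch_um = axial_pitch_um,
    scan_width_mm = scan_width_mm, scan_height_mm = scan_height_mm,
    n_repeats = as.integer(n_repeats), rpe_thickness_um = rpe_thickness_um,
    ped = ped, migration_foci = migration_foci,
    choroid_melanin = isTRUE(choroid_melanin),
    scramble_p = scramble_p, choroid_scramble_p = choroid_scramble_p,
    flow_fraction = flow_fraction, snr_db = snr_db, seed = as.integer(seed)
  ), class = "phantom_config")
}

# Layer attenuation coefficients (mm^-1). Backscattered power is taken
# proportional to the local attenuation so the single-scattering
# depth-resolved estimator is consistent with the ground-truth map. The
# scleral base is strongly scattering so the beam extinguishes inside the
# scan and the estimator's tail integral is essentially complete.
.mu_layers <- c(vitreous = 0.01, retina = 1.0, rpe = 6.0, fluid = 0.2,
                bruch = 3.0, choroid = 2.0, sclera = 12.0)

# Per-voxel SU(2) rotations: Haar-random rotation angle scaled by strength p,
# applied to the global Jones state. p = 0 -> identity, p = 1 -> Haar random
# (states uniform on the Poincare sphere).
.scramble_jones <- function(n, p, jones) {
  q <- matrix(stats::rnorm(4L * n), n, 4L)
  q <- q / sqrt(rowSums(q^2))
  ang <- acos(pmin(pmax(q[, 1L], -1), 1))        # half-angle in [0, pi]
  s <- sqrt(pmax(1 - q[, 1L]^2, 0))
  ax <- ifelse(s > 1e-12, 1 / s, 0) * q[, 2L:4L] # unit rotation axis
  a2 <- p * ang                                  # interpolate toward identity
  c0 <- cos(a2); sn <- sin(a2)
  n1 <- ax[, 1L] * sn; n2 <- ax[, 2L] * sn; n3 <- ax[, 3L] * sn
  # U = c0*I + i(n1 sx + n2 sy + n3 sz); rows: scrambled (J_H, J_V)
  jh <- (c0 + 1i * n3) * jones[1L] + (n2 + 1i * n1) * jones[2L]
  jv <- (-n2 + 1i * n1) * jones[1L] + (c0 - 1i * n3) * jones[2L]
  cbind(jh, jv)
}

#' Generate a synthetic multi-contrast PS-OCT volume with ground truth
#'
#' Builds the layered phantom described in [phantom_config()]: smooth layer
#' surfaces with optional PED elevation, per-voxel reflectivity attenuated by
#' the cumulative Beer-Lambert factor, fully developed speckle (circular
#' complex Gaussian fields), a shared global Jones state with per-voxel random
#' unitary scrambling in melanin, static speckle reused across repeats with
#' fresh additive detector noise, and independent speckle per repeat in flow
#' voxels. Ground-truth masks, surfaces, the attenuation map and noise
#' variances are returned alongside.
#'
#' @param config a [phantom_config()].
#' @return A list with `tomo` (a `jones_tomogram`: complex `field` array
#'   `[depth, aline, bscan, channel, repeat]`, pixel pitches, per-channel noise
#'   variances, `subject_id`, the config) and `truth` (a `phantom_truth`:
#'   `melanin_mask`, `melanin_thickness_um`, `ped_inner_boundary_px` (depth
#'   index of the detached RPE base, the RPE-fluid interface),
#'   `bruch_depth_px`, `flow_mask`, `mu_map_mm1`, `global_jones_state`,
#'   `noise_variance_per_channel`, `ped_elevation_um`).
#' @export
generate_phantom <- function(config) {
  .assert(inherits(config, "phantom_config"), "config must be a phantom_config")
  cfg <- config
  set.seed(cfg$seed)
  nd <- cfg$n_depth; na <- cfg$n_alines; nb <- cfg$n_bscans
  nr <- cfg$n_repeats
  pitch <- cfg$axial_pitch_um
  aline_pitch_mm <- cfg$scan_width_mm / na
  bscan_pitch_mm <- cfg$scan_height_mm / nb

  ## --- surfaces (en-face matrices [aline, bscan]) -------------------------
  x <- (seq_len(na) - 0.5) * aline_pitch_mm - cfg$scan_width_mm / 2
  y <- (seq_len(nb) - 0.5) * bscan_pitch_mm - cfg$scan_height_mm / 2
  X <- matrix(x, na, nb); Y <- matrix(y, na, nb, byrow = TRUE)
  und <- function(amp_px) {   # gentle smooth undulation
    ph <- stats::runif(4L, 0, 2 * pi)
    amp_px * (sin(2 * pi * X / cfg$scan_width_mm + ph[1L]) *
                cos(2 * pi * Y / cfg$scan_height_mm + ph[2L]) +
              0.5 * sin(4 * pi * X / cfg$scan_width_mm + ph[3L]) *
                cos(4 * pi * Y / cfg$scan_height_mm + ph[4L]))
  }
  bruch_z <- round(0.62 * nd + und(2))              # reference surface
  ilm_z <- round(0.20 * nd + und(3))
  choroid_bot <- pmin(round(0.86 * nd + und(2)), nd - 2L)

  elev_um <- matrix(0, na, nb)
  if (!is.null(cfg$ped) && cfg$ped$height_um > 0) {
    r2 <- (X - cfg$ped$center_xy[1L])^2 + (Y - cfg$ped$center_xy[2L])^2
    a <- cfg$ped$radius_mm; h <- cfg$ped$height_um
    if (cfg$ped$shape == "spherical-cap") {
      # cap of base radius a (mm) and apex height h (um)
      hm <- h / 1000
      R <- (a^2 + hm^2) / (2 * hm)                  # sphere radius, mm
      inside <- r2 < a^2
      elev_mm <- ifelse(inside, sqrt(pmax(R^2 - r2, 0)) - (R - hm), 0)
      elev_um <- elev_mm * 1000
    } else {
      elev_um <- h * exp(-r2 / (2 * (a / 2)^2))
      elev_um[elev_um < 0.5] <- 0
    }
  }
  elev_px <- round(elev_um / pitch)
  rpe_px <- max(0L, round(cfg$rpe_thickness_um / pitch))
  rpe_base_z <- bruch_z - elev_px                   # detached RPE base
  rpe_top_z <- rpe_base_z - rpe_px + 1L             # first melanin voxel
  .assert(all(rpe_top_z > ilm_z + 4L), "PED/RPE band collides with inner retina")

  ## --- layer labels -> mu and reflectivity --------------------------------
  Z <- array(seq_len(nd), c(nd, na, nb))
  expand <- function(m) array(rep(as.vector(m), each = nd), c(nd, na, nb))
  ilmE <- expand(ilm_z); bruE <- expand(bruch_z); botE <- expand(choroid_bot)
  topE <- expand(rpe_top_z); baseE <- expand(rpe_base_z)
  mu <- array(.mu_layers[["vitreous"]], c(nd, na, nb))
  mu[Z >= ilmE & Z < topE] <- .mu_layers[["retina"]]
  melanin <- Z >= topE & Z <= baseE & rpe_px > 0
  mu[melanin] <- .mu_layers[["rpe"]]
  fluid <- Z > baseE & Z < bruE
  mu[fluid] <- .mu_layers[["fluid"]]
  mu[Z == bruE] <- .mu_layers[["bruch"]]
  chor <- Z > bruE & Z <= botE
  mu[chor] <- .mu_layers[["choroid"]]
  mu[Z > botE] <- .mu_layers[["sclera"]]

  # intraretinal melanin migration foci (spheres above the RPE band)
  for (f in cfg$migration_foci) {
    cz <- expand(rpe_top_z) - f$center_xyz[3L] / pitch
    d2 <- ((Z - cz) * pitch / 1000)^2 +
      expand((X - f$center_xyz[1L])^2 + (Y - f$center_xyz[2L])^2)
    inside <- d2 < (f$radius_um / 1000)^2 & Z >= ilmE & Z < topE
    mu[inside] <- .mu_layers[["rpe"]]
    melanin <- melanin | inside
  }

  refl <- mu                                        # backscatter ~ mu
  refl[Z < ilmE] <- 0                               # vitreous: no signal
  dz_mm <- pitch / 1000
  att <- exp(-2 * dz_mm * (cumsum_depth(mu) - mu))  # attenuation to voxel top
  Imean <- refl * att                               # expected intensity

  ## --- choroidal vessels (contiguous ellipsoidal lumens) ------------------
  flow <- array(FALSE, c(nd, na, nb))
  n_chor <- sum(chor)
  if (cfg$flow_fraction > 0 && n_chor > 0) {
    target <- cfg$flow_fraction * n_chor
    zc_lo <- bruch_z + 1L; zc_hi <- choroid_bot
    for (it in seq_len(2000L)) {
      if (sum(flow) >= target) break
      a0 <- sample.int(na, 1L); b0 <- sample.int(nb, 1L)
      z0 <- sample(seq.int(zc_lo[a0, b0], max(zc_lo[a0, b0], zc_hi[a0, b0])), 1L)
      rz <- sample(8:16, 1L); ra <- sample(2:4, 1L); rb <- sample(1:2, 1L)
      zi <- pmax(1L, z0 - rz):pmin(nd, z0 + rz)
      ai <- pmax(1L, a0 - ra):pmin(na, a0 + ra)
      bi <- pmax(1L, b0 - rb):pmin(nb, b0 + rb)
      e2 <- outer(((zi - z0) / rz)^2, ((ai - a0) / ra)^2, `+`)
      ell <- outer(e2, ((bi - b0) / rb)^2, `+`) <= 1
      blk <- flow[zi, ai, bi, drop = FALSE]
      blk[ell & chor[zi, ai, bi, drop = FALSE]] <- TRUE
      flow[zi, ai, bi] <- blk
    }
  }

  ## --- polarization -------------------------------------------------------
  th <- stats::runif(1L, 0, pi / 2); ph <- stats::runif(1L, 0, 2 * pi)
  jones <- c(cos(th), sin(th) * exp(1i * ph))       # global unit Jones state
  JH <- array(jones[1L], c(nd, na, nb))
  JV <- array(jones[2L], c(nd, na, nb))
  scr_idx <- which(melanin)
  if (length(scr_idx) && cfg$scramble_p > 0) {
    sj <- .scramble_jones(length(scr_idx), cfg$scramble_p, jones)
    JH[scr_idx] <- sj[, 1L]; JV[scr_idx] <- sj[, 2L]
  }
  chor_scr <- which(chor & !flow)                   # stroma, not vessel lumen
  if (cfg$choroid_melanin && length(chor_scr) && cfg$choroid_scramble_p > 0) {
    sj <- .scramble_jones(length(chor_scr), cfg$choroid_scramble_p, jones)
    JH[chor_scr] <- sj[, 1L]; JV[chor_scr] <- sj[, 2L]
  }

  ## --- noise calibration ---------------------------------------------------
  rpe_sig <- mean(Imean[melanin])                   # both channels combined
  sigma_tot <- if (is.infinite(cfg$snr_db)) 0 else rpe_sig / 10^(cfg$snr_db / 10)
  sig2 <- c(H = sigma_tot / 2, V = sigma_tot / 2)   # per channel

  ## --- speckle and repeats -------------------------------------------------
  g0 <- .cgauss(Imean)                              # static speckle field
  flow_idx <- which(flow)
  nvox <- nd * na * nb
  field <- array(0i, c(nd, na, nb, 2L, nr))
  for (r in seq_len(nr)) {
    g <- g0
    if (length(flow_idx))                           # independent per repeat
      g[flow_idx] <- .cgauss(Imean[flow_idx])
    for (ch in 1L:2L) {
      e <- g * (if (ch == 1L) JH else JV)
      if (sigma_tot > 0) e <- e + .cgauss(sig2[ch], nvox)
      field[, , , ch, r] <- e
    }
  }

  tomo <- structure(list(
    field = field,
    axial_pitch_um = pitch,
    aline_pitch_mm = aline_pitch_mm,
    bscan_pitch_mm = bscan_pitch_mm,
    noise_variance_per_channel = sig2,
    subject_id = sprintf("phantom-%06d", cfg$seed),
    config = cfg
  ), class = "jones_tomogram")

  thick <- apply(melanin, c(2L, 3L), sum) * pitch
  truth <- structure(list(
    melanin_mask = melanin,
    melanin_thickness_um = thick,
    ped_inner_boundary_px = rpe_base_z,
    bruch_depth_px = bruch_z,
    ped_elevation_um = elev_px * pitch,
    flow_mask = flow,
    mu_map_mm1 = mu,
    global_jones_state = jones,
    noise_variance_per_channel = sig2,
    ilm_depth_px = ilm_z
  ), class = "phantom_truth")
  list(tomo = tomo, truth = truth)
}

#' Generate a reproducible cohort of phantom subjects
#'
#' Draws one randomized [phantom_config()] per subject from the given ranges.
#' Configurations (not volumes) are returned by default so that cohorts of
#' arbitrary size stream through downstream stages one volume at a time;
#' set `materialize = TRUE` to generate all volumes eagerly.
#'
#' @param n_subjects number of subjects (at least 2).
#' @param config_ranges named list of ranges; scalar parameters may be given
#'   as `c(lo, hi)` (drawn uniformly) or a single value. Recognised names:
#'   `rpe_thickness_um`, `scramble_p`, `snr_db`, `flow_fraction`,
#'   `ped_height_um`, `ped_radius_mm`. Any other [phantom_config()] argument
#'   may be supplied as a fixed value via `fixed`.
#' @param seed cohort seed; per-subject seeds are derived deterministically.
#' @param fixed named list of fixed [phantom_config()] arguments.
#' @param materialize generate the volumes now (`TRUE`) or return configs.
#' @return A list of subjects, each a list with `subject_id` and `config`
#'   (plus `tomo` and `truth` when materialized).
#' @export
generate_cohort <- function(n_subjects, config_ranges = list(), seed = 1L,
                            fixed = list(), materialize = FALSE) {
  .assert(n_subjects >= 2L, "n_subjects must be >= 2")
  .assert(is.list(config_ranges), "config_ranges must be a list")
  for (nm in names(config_ranges))
    .assert(length(config_ranges[[nm]]) >= 1L, sprintf("empty range for '%s'", nm))
  set.seed(seed)
  sub_seeds <- sample.int(2^30, n_subjects)
  draw <- function(rng) if (length(rng) == 1L) rng else stats::runif(1L, rng[1L], rng[2L])
  lapply(seq_len(n_subjects), function(i) {
    args <- fixed
    r <- config_ranges
    if (!is.null(r$rpe_thickness_um)) args$rpe_thickness_um <- draw(r$rpe_thickness_um)
    if (!is.null(r$scramble_p)) args$scramble_p <- draw(r$scramble_p)
    if (!is.null(r$snr_db)) args$snr_db <- draw(r$snr_db)
    if (!is.null(r$flow_fraction)) args$flow_fraction <- draw(r$flow_fraction)
    if (!is.null(r$ped_height_um) || !is.null(r$ped_radius_mm)) {
      h <- if (is.null(r$ped_height_um)) 0 else draw(r$ped_height_um)
      a <- if (is.null(r$ped_radius_mm)) 1.0 else draw(r$ped_radius_mm)
      args$ped <- if (h > 0) list(center_xy = c(0, 0), radius_mm = a,
                                  height_um = h, shape = "spherical-cap") else NULL
    }
    args$seed <- sub_seeds[i]
    cfg <- do.call(phantom_config, args)
    sub <- list(subject_id = sprintf("subject-%03d", i), config = cfg)
    if (materialize) {
      vol <- generate_phantom(cfg)
      sub$tomo <- vol$tomo; sub$tomo$subject_id <- sub$subject_id
      sub$truth <- vol$truth
    }
    sub
  })
}

#' Materialize one cohort subject
#'
#' @param subject an element of the list returned by [generate_cohort()].
#' @return The `list(tomo, truth)` volume for that subject.
#' @export
subject_volume <- function(subject) {
  vol <- generate_phantom(subject$config)
  vol$tomo$subject_id <- subject$subject_id
  vol
}
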