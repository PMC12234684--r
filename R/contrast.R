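#' Depth-resolved attenuation coefficient from OCT intensity
#'
#' Single-scattering depth-resolved estimator: for each A-line,
#' `mu[z] = I[z] / (2 * dz * sum(I[z'] for z' > z))` with `dz` the axial pitch
#' in mm. The estimate is scale-invariant in the intensity. Fully developed
#' speckle makes the single-voxel intensity exponentially distributed, so the
#' intensity is first averaged over a small `(depth, aline)` window within
#' each B-scan (truncated at borders; set `kernel = c(1, 1)` to disable);
#' without this the per-voxel estimate fluctuates with order-100% relative
#' error. The estimator diverges where the remaining tail carries no signal,
#' so the bottom `tail_cutoff_px` rows are masked invalid, as are voxels with
#' a nonpositive tail sum. `mu_norm = min(mu / mu_ref, 1)` provides the
#' dimensionless factor used by the melanin index.
#'
#' @param intensity an `intensity_volume` (linear scale) from
#'   [coherent_composite()], or a bare nonnegative `[depth, aline, bscan]`
#'   array (then `axial_pitch_um` must be given).
#' @param axial_pitch_um depth pitch in micrometres (taken from the volume if
#'   present).
#' @param mu_ref_mm1 normalization constant in mm^-1 (default 10).
#' @param tail_cutoff_px bottom rows excluded (default 16).
#' @param kernel odd `(depth, aline)` speckle-averaging window applied to the
#'   intensity before estimation (default `c(5, 15)`, about 75 speckles).
#' @param tail_extension complete the tail sum beyond the deepest pixel by
#'   geometric extrapolation of the terminal decay rate (default `TRUE`).
#' @param noise_floor additive intensity offset subtracted before estimation
#'   (the residual detector-noise floor of the composite). Defaults to
#'   `total noise variance / n_repeats` when the volume carries noise
#'   metadata.
#' @return An `attenuation_volume`: `mu_mm1` (NA where invalid), `mu_norm`
#'   (0 where invalid), `valid_mask`, `mu_ref_mm1`, `tail_cutoff_px`.
#' @export
compute_attenuation <- function(intensity, axial_pitch_um = NULL,
                                mu_ref_mm1 = 10, tail_cutoff_px = 16L,
                                kernel = c(5L, 15L), tail_extension = TRUE,
                                noise_floor = NULL) {
  if (inherits(intensity, "intensity_volume")) {
    axial_pitch_um <- axial_pitch_um %||% intensity$axial_pitch_um
    I <- intensity$intensity
    nv <- intensity$noise_variance_per_channel
    if (is.null(noise_floor) && !is.null(nv))
      noise_floor <- sum(nv) / (intensity$n_repeats %||% 1L)
  } else I <- intensity
  if (!is.null(noise_floor) && noise_floor > 0) I <- pmax(I - noise_floor, 0)
  .assert(!is.null(axial_pitch_um) && axial_pitch_um > 0, "axial pitch required")
  .assert(all(I >= 0), "intensity must be nonnegative (linear scale)")
  .assert(mu_ref_mm1 > 0, "mu_ref_mm1 must be positive")
  .assert(all(kernel >= 1L) && all(kernel %% 2L == 1L), "kernel must be odd")
  d <- dim(I)
  if (any(kernel > 1L)) {
    cnt <- box_count(d[1L], d[2L], kernel)
    for (b in seq_len(d[3L]))
      I[, , b] <- box_sum(I[, , b], kernel) / cnt
  }
  nd <- d[1L]
  dz <- axial_pitch_um / 1000
  m <- matrix(I, nd, prod(d[-1L]))
  # tail[z] = sum of I strictly below z, completed beyond the last pixel by
  # geometric extrapolation of the terminal decay (the truncated-tail bias
  # of this estimator otherwise inflates mu in the deepest layers)
  tot <- matrix(colSums(m), nd, ncol(m), byrow = TRUE)
  tail <- tot - apply(m, 2L, cumsum)
  if (tail_extension && nd >= 8L) {
    # terminal per-pixel decay rate from rows with full smoothing windows,
    # pooled across the volume (the deepest layer is shared); the remaining
    # signal beyond the last pixel is completed as a geometric series
    rr <- (m[nd - 2L, ] / pmax(m[nd - 6L, ], .Machine$double.xmin))^(1 / 4)
    rr <- rr[is.finite(rr) & rr > 0 & rr < 1]
    if (length(rr)) {
      r <- min(stats::median(rr), 0.995)
      tail <- tail + matrix(m[nd - 2L, ] * r^3 / (1 - r), nd, ncol(m),
                            byrow = TRUE)
    }
  }
  mu <- m / (2 * dz * tail)
  valid <- tail > 0 & is.finite(mu)
  if (tail_cutoff_px > 0) valid[seq.int(nd - tail_cutoff_px + 1L, nd), ] <- FALSE
  mu[!valid] <- NA_real_
  mu_norm <- pmin(mu / mu_ref_mm1, 1)
  mu_norm[!valid] <- 0
  structure(list(mu_mm1 = array(mu, d), mu_norm = array(mu_norm, d),
                 valid_mask = array(valid, d), mu_ref_mm1 = mu_ref_mm1,
                 tail_cutoff_px = as.integer(tail_cutoff_px)),
            class = "attenuation_volume")
}

#' Noise-corrected complex-correlation OCT angiography
#'
#' For each channel and adjacent repeat pair (k, k+1), computes over a small
#' spatial kernel the noise-corrected complex correlation
#' `c = |sum(E_k conj(E_k1))| / sqrt((sum|E_k|^2 - N s2)(sum|E_k1|^2 - N s2))`
#' where `N` is the (truncated) window voxel count and `s2` the channel noise
#' variance. Correlations are averaged over pairs and channels and clipped to
#' [0, 1]; decorrelation is `1 - c`. Bulk phase offsets estimated per A-line
#' (as in [coherent_composite()]) are removed before the pairwise products so
#' that axial bulk motion does not masquerade as flow. Voxels whose corrected
#' denominators are nonpositive are treated as static (decorrelation 0,
#' flagged invalid).
#'
#' @param tomo a `jones_tomogram` with at least 2 repeats.
#' @param kernel odd `(depth, aline)` window, default `c(3, 3)`.
#' @param threshold decorrelation threshold for the binary flow mask
#'   (default 0.30).
#' @param noise per-channel noise variances; defaults to the tomogram's.
#' @param noise_correction set `FALSE` to disable the bias correction.
#' @param phases optional precomputed bulk-phase offsets (from
#'   [coherent_composite()]); estimated here when `NULL`.
#' @return An `angio_volume`: `decorrelation` in [0, 1], `binary_flow`,
#'   `threshold`, `kernel_shape`, `valid_mask`.
#' @export
compute_angiography <- function(tomo, kernel = c(3L, 3L), threshold = 0.30,
                                noise = NULL, noise_correction = TRUE,
                                phases = NULL) {
  .assert(inherits(tomo, "jones_tomogram"), "tomo must be a jones_tomogram")
  d <- dim(tomo$field)
  nd <- d[1L]; na <- d[2L]; nb <- d[3L]; nr <- d[5L]
  .assert(nr >= 2L, "angiography requires at least 2 repeats")
  .assert(all(kernel %% 2L == 1L), "kernel must be odd")
  noise <- noise %||% tomo$noise_variance_per_channel %||% c(0, 0)
  if (!noise_correction) noise <- c(0, 0)
  phases <- phases %||% coherent_composite(tomo)$phase_offsets
  cnt <- box_count(nd, na, kernel)
  csum <- array(0, c(nd, na, nb))
  nsum <- array(0L, c(nd, na, nb))
  for (b in seq_len(nb)) {
    for (ch in 1L:2L) {
      s2 <- noise[ch]
      for (k in seq_len(nr - 1L)) {
        rot_k <- exp(-1i * phases[k, , b])
        rot_k1 <- exp(-1i * phases[k + 1L, , b])
        ek <- sweep(tomo$field[, , b, ch, k], 2L, rot_k, `*`)
        ek1 <- sweep(tomo$field[, , b, ch, k + 1L], 2L, rot_k1, `*`)
        num <- Mod(box_sum(ek * Conj(ek1), kernel))
        d1 <- Re(box_sum(ek * Conj(ek), kernel)) - cnt * s2
        d2 <- Re(box_sum(ek1 * Conj(ek1), kernel)) - cnt * s2
        ok <- d1 > 0 & d2 > 0
        cc <- ifelse(ok, num / sqrt(pmax(d1, 0) * pmax(d2, 0)), 1)
        csum[, , b] <- csum[, , b] + pmin(pmax(cc, 0), 1)
        nsum[, , b] <- nsum[, , b] + ok
      }
    }
  }
  corr <- csum / (2 * (nr - 1L))
  dec <- pmin(pmax(1 - corr, 0), 1)
  valid <- nsum > 0
  dec[!valid] <- 0                       # nonpositive denominators -> static
  structure(list(decorrelation = dec,
                 binary_flow = dec >= threshold,
                 threshold = threshold, kernel_shape = kernel,
                 valid_mask = valid),
            class = "angio_volume")
}

#' Re-threshold the binary flow mask of an angiography volume
#'
#' @param angio an `angio_volume`.
#' @param threshold new decorrelation threshold in (0, 1].
#' @return The `angio_volume` with `binary_flow = decorrelation >= threshold`.
#'   Idempotent at a fixed threshold.
#' @export
binarize_flow <- function(angio, threshold) {
  .assert(inherits(angio, "angio_volume"), "angio must be an angio_volume")
  .assert(threshold > 0 && threshold <= 1, "threshold must lie in (0, 1]")
  angio$binary_flow <- angio$decorrelation >= threshold
  angio$threshold <- threshold
  angio
}
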