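test_that("attenuation recovers a pure exponential decay within 1%", {
  mu <- 2; dz <- 0.004; nd <- 256
  z <- (seq_len(nd) - 1) * dz
  I <- 5 * exp(-2 * mu * z)
  vol <- array(rep(I, 8), c(nd, 4, 2))
  at <- compute_attenuation(vol, axial_pitch_um = 4, kernel = c(1, 1))
  top <- at$mu_mm1[1:(nd / 2), , ]
  expect_true(all(abs(top - mu) / mu < 0.01))
  # scale invariance: doubling intensity changes nothing
  at2 <- compute_attenuation(2 * vol, axial_pitch_um = 4, kernel = c(1, 1))
  expect_equal(at$mu_mm1, at2$mu_mm1, tolerance = 1e-12)
})

test_that("a single-term tail gives mu = I/(2*dz*I)", {
  vol <- array(0, c(32, 3, 1))
  vol[10, , ] <- 3; vol[20, , ] <- 3
  at <- compute_attenuation(vol, axial_pitch_um = 4, kernel = c(1, 1),
                            tail_extension = FALSE, tail_cutoff_px = 0)
  expect_equal(at$mu_mm1[10, 1, 1], 1 / (2 * 0.004))
  # below the last return the tail is empty: invalid
  expect_false(at$valid_mask[20, 1, 1])
  expect_false(at$valid_mask[25, 1, 1])
  expect_equal(at$mu_norm[25, 1, 1], 0)
  expect_error(compute_attenuation(-vol, axial_pitch_um = 4), "nonnegative")
})

test_that("attenuation matches the phantom truth map in static tissue", {
  v <- generate_phantom(phantom_config(n_bscans = 12, n_alines = 64,
                                       n_depth = 128, rpe_thickness_um = 72,
                                       flow_fraction = 0, snr_db = 15,
                                       seed = 7))
  at <- compute_attenuation(coherent_composite(v$tomo))
  mu <- v$truth$mu_map_mm1
  # interior: valid voxels in tissue, away from layer interfaces (the
  # speckle-averaging window straddles interfaces otherwise)
  d <- dim(mu)
  boundary <- array(FALSE, d)
  for (k in 1:3) {
    dd <- mu[1:(d[1] - k), , ] != mu[(1 + k):d[1], , ]
    boundary[1:(d[1] - k), , ] <- boundary[1:(d[1] - k), , ] | dd
    boundary[(1 + k):d[1], , ] <- boundary[(1 + k):d[1], , ] | dd
  }
  sel <- at$valid_mask & mu >= 1 & !boundary
  expect_gt(sum(sel), 5e4)
  relerr <- abs(at$mu_mm1[sel] - mu[sel]) / mu[sel]
  expect_lt(median(relerr), 0.10)
})

test_that("identical repeats give zero decorrelation without noise", {
  set.seed(4)
  base <- array(complex(real = rnorm(16 * 8 * 2), imaginary = rnorm(16 * 8 * 2)),
                c(16, 8, 2))
  f <- array(0i, c(16, 8, 2, 2, 3))
  for (r in 1:3) for (ch in 1:2) f[, , , ch, r] <- base / sqrt(2)
  an <- compute_angiography(make_tomo(f))
  expect_true(all(an$decorrelation == 0))
  expect_false(any(an$binary_flow))
  expect_error(compute_angiography(make_tomo(f[, , , , 1, drop = FALSE])),
               "2 repeats")
})

test_that("independent complex-Gaussian repeats decorrelate strongly", {
  set.seed(5)
  f <- array(complex(real = rnorm(32 * 32 * 4 * 2 * 3),
                     imaginary = rnorm(32 * 32 * 4 * 2 * 3)),
             c(32, 32, 4, 2, 3))
  an <- compute_angiography(make_tomo(f), kernel = c(7, 7))
  interior <- an$decorrelation[4:29, 4:29, ]
  expect_gt(mean(interior), 0.8)
  expect_true(all(an$decorrelation >= 0 & an$decorrelation <= 1))
})

test_that("noise correction lowers apparent decorrelation of a static scene", {
  set.seed(6)
  nd <- 24; na <- 32; nb <- 4; nr <- 3
  sig <- array(complex(real = rnorm(nd * na * nb),
                       imaginary = rnorm(nd * na * nb)), c(nd, na, nb))
  s2 <- 0.05                                # 10 dB below unit signal
  f <- array(0i, c(nd, na, nb, 2, nr))
  for (r in 1:nr) for (ch in 1:2)
    f[, , , ch, r] <- sig / sqrt(2) +
      array(complex(real = rnorm(nd * na * nb, sd = sqrt(s2 / 2)),
                    imaginary = rnorm(nd * na * nb, sd = sqrt(s2 / 2))),
            c(nd, na, nb))
  tomo <- make_tomo(f, noise = c(H = s2, V = s2))
  on_ <- compute_angiography(tomo, noise_correction = TRUE)
  off <- compute_angiography(tomo, noise_correction = FALSE)
  expect_lt(mean(on_$decorrelation), mean(off$decorrelation))
})

test_that("flow binarization recovers phantom vessels at high SNR", {
  v <- generate_phantom(phantom_config(n_bscans = 12, n_alines = 64,
                                       n_depth = 128, snr_db = 35,
                                       flow_fraction = 0.3, seed = 5))
  an <- compute_angiography(v$tomo, threshold = 0.3)
  fl <- v$truth$flow_mask
  mu <- v$truth$mu_map_mm1
  # dilate the vessel mask by the kernel radius: windows straddling a vessel
  # wall legitimately mix static and flowing speckle
  d <- dim(fl)
  dil <- fl
  dil[-1, , ] <- dil[-1, , ] | fl[-d[1], , ]
  dil[-d[1], , ] <- dil[-d[1], , ] | fl[-1, , ]
  dil[, -1, ] <- dil[, -1, ] | fl[, -d[2], ]
  dil[, -d[2], ] <- dil[, -d[2], ] | fl[, -1, ]
  static_tissue <- !dil & mu >= 1 & mu < 12
  expect_gt(mean(an$binary_flow[fl]), 0.9)
  expect_lt(mean(an$binary_flow[static_tissue]), 0.05)
})

test_that("binarize_flow is threshold-exact and idempotent", {
  dec <- array(runif(4 * 4 * 2), c(4, 4, 2))
  an <- make_angio(dec, 0.3)
  an2 <- binarize_flow(an, 0.5)
  expect_identical(an2$binary_flow, dec >= 0.5)
  expect_identical(binarize_flow(an2, 0.5)$binary_flow, an2$binary_flow)
  zero <- binarize_flow(make_angio(array(0, c(4, 4, 2))), 0.2)
  expect_false(any(zero$binary_flow))
  one <- binarize_flow(an, 1.0)
  expect_false(any(one$binary_flow))
  expect_error(binarize_flow(an, 0), "threshold")
})
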