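test_that("Stokes parameters of pure states match their textbook values", {
  f <- array(0i, c(1, 1, 1, 2, 1))
  f[, , , 1, 1] <- 1                       # horizontal
  st <- compute_stokes(make_tomo(f))
  expect_equal(c(st$S0, st$S1, st$S2, st$S3), c(1, 1, 0, 0))
  f[, , , 1, 1] <- 1 / sqrt(2); f[, , , 2, 1] <- 1 / sqrt(2)  # +45 linear
  st <- compute_stokes(make_tomo(f))
  expect_equal(c(st$S0, st$S1, st$S2, st$S3), c(1, 0, 1, 0))
  f[, , , 2, 1] <- 1i / sqrt(2)            # right circular: S3 = -2 Im(E_H conj(E_V)) = +1
  st <- compute_stokes(make_tomo(f))
  expect_equal(c(st$S0, st$S1, st$S2, st$S3), c(1, 0, 0, 1))
})

test_that("pointwise S0^2 equals S1^2+S2^2+S3^2 for any single-repeat field", {
  set.seed(1)
  f <- array(complex(real = rnorm(2 * 160), imaginary = rnorm(2 * 160)),
             c(5, 4, 4, 2, 1))
  st <- compute_stokes(make_tomo(f))
  expect_equal(st$S0^2, st$S1^2 + st$S2^2 + st$S3^2, tolerance = 1e-12)
  expect_error(compute_stokes(make_tomo(array(0i, c(2, 2, 2, 1, 1)))),
               "two channels")
})

test_that("uniform pure polarization gives DOPU exactly 1", {
  tomo <- uniform_state_tomo(c(0.8, 0.6i), nd = 10, na = 10)
  dp <- compute_dopu(compute_stokes(tomo), noise = c(0, 0))
  expect_true(all(dp$valid_mask))
  expect_lt(max(abs(dp$dopu - 1)), 1e-12)
})

test_that("balanced antipodal window gives DOPU exactly 0", {
  # 2 x 3 B-scan: row 1 horizontal (1,1,0,0), row 2 vertical (1,-1,0,0);
  # the truncated window at (1,2) holds three of each and the mean
  # polarization vector cancels
  f <- array(0i, c(2, 3, 1, 2, 1))
  f[1, , , 1, 1] <- 1
  f[2, , , 2, 1] <- 1
  dp <- compute_dopu(compute_stokes(make_tomo(f)), noise = c(0, 0))
  expect_equal(dp$dopu[1, 2, 1], 0)
  expect_equal(dp$dopu[2, 2, 1], 0)
})

test_that("vectorized DOPU equals the brute-force window oracle exactly", {
  set.seed(42)
  for (i in 1:3) {
    f <- array(complex(real = rnorm(16 * 12 * 2 * 2 * 2),
                       imaginary = rnorm(16 * 12 * 2 * 2 * 2)),
               c(16, 12, 2, 2, 2))
    tomo <- make_tomo(f, noise = c(H = 0.05, V = 0.08))
    st <- compute_stokes(tomo)
    dp <- compute_dopu(st)
    oracle <- dopu_oracle(st, c(0.05, 0.08), c(3, 3), dp$s0_floor)
    expect_equal(dp$dopu, oracle, tolerance = 1e-12)
  }
})

test_that("DOPU is invariant under a global polarization rotation", {
  v <- small_phantom(n_bscans = 8)
  dp1 <- compute_dopu(compute_stokes(v$tomo))
  th <- 0.7; ph <- 1.1
  u <- matrix(c(cos(th), -sin(th) * exp(-1i * ph),
                sin(th) * exp(1i * ph), cos(th)), 2, 2)
  rot <- v$tomo
  eh <- rot$field[, , , 1, , drop = FALSE]
  ev <- rot$field[, , , 2, , drop = FALSE]
  rot$field[, , , 1, ] <- u[1, 1] * eh + u[1, 2] * ev
  rot$field[, , , 2, ] <- u[2, 1] * eh + u[2, 2] * ev
  dp2 <- compute_dopu(compute_stokes(rot))
  sel <- dp1$valid_mask & dp2$valid_mask
  expect_gt(mean(sel), 0.4)
  expect_lt(max(abs(dp1$dopu[sel] - dp2$dopu[sel])), 1e-6)
})

test_that("noise correction shrinks the DOPU bias on a noisy uniform phantom", {
  set.seed(9)
  nd <- 32; na <- 48; nb <- 8
  s2 <- c(H = 0.05, V = 0.05)               # 10 dB below unit signal
  amp <- array(1, c(nd, na, nb))
  f <- array(0i, c(nd, na, nb, 2, 1))
  jones <- c(1 / sqrt(2), 1i / sqrt(2))
  f[, , , 1, 1] <- jones[1] * amp
  f[, , , 2, 1] <- jones[2] * amp
  noise <- array(complex(real = rnorm(nd * na * nb * 2, sd = sqrt(0.05 / 2)),
                         imaginary = rnorm(nd * na * nb * 2, sd = sqrt(0.05 / 2))),
                 c(nd, na, nb, 2))
  f[, , , , 1] <- f[, , , , 1] + noise
  tomo <- make_tomo(f, noise = s2)
  st <- compute_stokes(tomo)
  corrected <- compute_dopu(st, noise = s2)
  uncorrected <- compute_dopu(st, noise = c(0, 0), s0_floor = corrected$s0_floor)
  sel <- corrected$valid_mask
  expect_gt(sum(sel), 1e4)
  bias_c <- abs(mean(corrected$dopu[sel]) - 1)
  bias_u <- abs(mean(uncorrected$dopu[sel]) - 1)
  expect_lt(bias_c, bias_u)
})

test_that("coherent composite recovers constant per-repeat phase offsets", {
  set.seed(2)
  nd <- 16; na <- 8; nb <- 2; nr <- 4
  base <- array(complex(real = rnorm(nd * na * nb),
                        imaginary = rnorm(nd * na * nb)), c(nd, na, nb))
  f <- array(0i, c(nd, na, nb, 2, nr))
  phis <- c(0, 0.9, -2.1, 2.8)
  for (r in 1:nr) for (ch in 1:2)
    f[, , , ch, r] <- base * exp(1i * phis[r]) / sqrt(2)
  comp <- coherent_composite(make_tomo(f))
  single <- Mod(base)^2
  expect_equal(comp$intensity, single, tolerance = 1e-12)
  # identical repeats: composite equals single-repeat intensity too
  for (r in 1:nr) for (ch in 1:2) f[, , , ch, r] <- base / sqrt(2)
  comp2 <- coherent_composite(make_tomo(f))
  expect_equal(comp2$intensity, single, tolerance = 1e-12)
  expect_match(comp2$provenance, "composite-of-4")
  # single repeat passes through
  comp3 <- coherent_composite(make_tomo(f[, , , , 1, drop = FALSE]))
  expect_identical(comp3$provenance, "single")
})

test_that("compositing 4 repeats drops the noise floor by about 4x", {
  set.seed(3)
  nd <- 24; na <- 40; nb <- 6; nr <- 4
  sig <- array(complex(real = rnorm(nd * na * nb),
                       imaginary = rnorm(nd * na * nb)), c(nd, na, nb))
  sig[13:24, , ] <- 0                      # signal-free lower half
  f <- array(0i, c(nd, na, nb, 2, nr))
  for (r in 1:nr) for (ch in 1:2)
    f[, , , ch, r] <- sig / sqrt(2) +
      array(complex(real = rnorm(nd * na * nb, sd = sqrt(0.05)),
                    imaginary = rnorm(nd * na * nb, sd = sqrt(0.05))),
            c(nd, na, nb))
  comp <- coherent_composite(make_tomo(f))
  single <- Mod(f[, , , 1, 1])^2 + Mod(f[, , , 2, 1])^2
  ratio <- mean(single[13:24, , ]) / mean(comp$intensity[13:24, , ])
  expect_lt(abs(ratio - 4) / 4, 0.1)
})

test_that("noise estimation recovers the injected variance", {
  v <- generate_phantom(phantom_config(n_bscans = 8, n_alines = 64,
                                       n_depth = 128, snr_db = 20, seed = 13))
  est <- estimate_noise(v$tomo, c(1, 12), truth = v$truth)
  truth <- v$truth$noise_variance_per_channel
  expect_lt(abs(est[["H"]] - truth[["H"]]) / truth[["H"]], 0.05)
  expect_lt(abs(est[["V"]] - truth[["V"]]) / truth[["V"]], 0.05)
  # noise-free phantom gives exactly zero
  v0 <- generate_phantom(phantom_config(n_bscans = 8, n_alines = 64,
                                        n_depth = 128, snr_db = Inf, seed = 13))
  expect_equal(unname(estimate_noise(v0$tomo, c(1, 12))), c(0, 0))
  expect_error(estimate_noise(v$tomo, c(1, 1)), "1000")
  expect_warning(estimate_noise(v$tomo, c(1, 80), truth = v$truth), "tissue")
})
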