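test_that("F_RPE is the exact three-factor product with null annihilators", {
  d <- c(6, 5, 2)
  dopu <- make_dopu(array(0.7, d))
  atten <- make_atten(array(0.6, d))
  angio <- make_angio(array(0, d))
  fr <- compute_frpe(dopu, atten, angio)
  expect_equal(fr$frpe, array(0.6 * 0.3, d))
  expect_true(all(fr$frpe >= 0.15))        # counted as melanin
  # DOPU = 1 annihilates
  fr1 <- compute_frpe(make_dopu(array(1, d)), atten, angio)
  expect_true(all(fr1$frpe == 0))
  # flow annihilates locally
  dec <- array(0, d); dec[3, 2, 1] <- 1
  fr2 <- compute_frpe(dopu, atten, make_angio(dec))
  expect_equal(fr2$frpe[3, 2, 1], 0)
  expect_equal(fr2$frpe[1, 1, 1], 0.18)
  # mu_norm = 0 annihilates
  fr3 <- compute_frpe(dopu, make_atten(array(0, d)), angio)
  expect_true(all(fr3$frpe == 0))
  # invalid voxels are zeroed
  dv <- make_dopu(array(0.5, d)); dv$valid_mask[1, 1, 1] <- FALSE
  fr4 <- compute_frpe(dv, atten, angio)
  expect_equal(fr4$frpe[1, 1, 1], 0)
  expect_error(compute_frpe(make_dopu(array(1, c(2, 2, 2))), atten, angio),
               "dimensions")
})

test_that("thickness map counts suprathreshold voxels times the pitch", {
  d <- c(30, 4, 3)
  fr <- array(0, d)
  fr[6:23, 2, 2] <- 0.2                    # 18 voxels at 4 um = 72 um
  fr[c(2, 9), 3, 1] <- 0.16                # non-contiguous counting
  frv <- compute_frpe(make_dopu(array(1, d)), make_atten(array(0, d)),
                      make_angio(array(0, d)))
  frv$frpe <- fr
  tm <- thickness_map(frv, 4)
  expect_equal(tm$thickness_um[2, 2], 72)
  expect_equal(tm$thickness_um[3, 1], 8)
  expect_equal(tm$thickness_um[1, 1], 0)
  # contiguity flag keeps only the longest run
  tmc <- thickness_map(frv, 4, contiguous = TRUE)
  expect_equal(tmc$thickness_um[3, 1], 4)
  # idempotent / deterministic
  expect_identical(tm, thickness_map(frv, 4))
  # all-zero volume
  frv$frpe <- array(0, d)
  expect_true(all(thickness_map(frv, 4)$thickness_um == 0))
})

test_that("lesion area is exact pixel counting at full-scale pitches", {
  m <- matrix(0, 512, 256)
  m[sample(length(m), 100)] <- 80
  map <- make_thickness_map(m)
  la <- lesion_area(map, 6 / 512, 6 / 256, 70)
  expect_equal(la$area_mm2, 100 * (6 / 512) * (6 / 256), tolerance = 1e-12)
  expect_equal(la$area_mm2, 0.0275, tolerance = 2e-3)
  # empty mask
  expect_equal(lesion_area(make_thickness_map(matrix(0, 8, 8)), 0.1, 0.1)$area_mm2, 0)
  # ROI intersection is exact
  roi <- matrix(FALSE, 512, 256); roi[1:256, ] <- TRUE
  la2 <- lesion_area(map, 6 / 512, 6 / 256, 70, roi = roi)
  expect_equal(la2$area_mm2, sum(m[1:256, ] >= 70) * (6 / 512) * (6 / 256))
  expect_error(lesion_area(map, 6 / 512, 6 / 256, roi = matrix(TRUE, 2, 2)),
               "roi")
})

test_that("a thickened disc is measured within 5% of its analytic area", {
  na <- 512; nb <- 256
  x <- (seq_len(na) - 0.5) * 6 / na - 3
  y <- (seq_len(nb) - 0.5) * 6 / nb - 3
  m <- 100 * (outer(x^2, y^2, `+`) < 0.5^2)
  la <- lesion_area(make_thickness_map(m), 6 / na, 6 / nb, 70)
  expect_lt(abs(la$area_mm2 - pi * 0.25) / (pi * 0.25), 0.05)
})

test_that("Cavalieri volume is exact on a box and zero without elevation", {
  na <- 50
  bruch <- matrix(50, na, 1)
  bound <- bruch - 25                      # 100 um at 4 um pitch
  pv <- ped_volume(bound, bruch, 4, 1 / na, 0.0234)
  expect_equal(pv$volume_mm3, 0.1 * 1 * 0.0234, tolerance = 1e-12)
  expect_equal(pv$per_bscan_area_mm2, 0.1 * 1, tolerance = 1e-12)
  expect_equal(ped_volume(bruch, bruch, 4, 1 / na, 0.0234)$volume_mm3, 0)
  expect_error(ped_volume(bruch + 1, bruch, 4, 1 / na, 0.0234), "crosses")
})

test_that("spherical-cap phantom PED volume matches the closed form within 3%", {
  cfg <- phantom_config(n_bscans = 64, n_alines = 128, n_depth = 96,
                        n_repeats = 1, rpe_thickness_um = 40,
                        ped = list(radius_mm = 1.5, height_um = 100), seed = 8)
  v <- generate_phantom(cfg)
  pv <- ped_volume(v$truth$ped_inner_boundary_px, v$truth$bruch_depth_px,
                   4, v$tomo$aline_pitch_mm, v$tomo$bscan_pitch_mm)
  h <- 0.1; a <- 1.5
  cap <- pi * h * (3 * a^2 + h^2) / 6
  expect_lt(abs(pv$volume_mm3 - cap) / cap, 0.03)
})

test_that("Littmann scaling is unity at the reference eye and scales areas", {
  expect_equal(transverse_scale(24.46), 1)
  expect_equal(transverse_scale(22.4), (22.4 - 1.82) / (24.46 - 1.82))
  expect_equal(transverse_scale(22.4), 0.909, tolerance = 1e-3)
  expect_error(transverse_scale(40), "range")
  m <- matrix(0, 32, 32); m[10:14, 10:14] <- 100
  s <- transverse_scale(22.4)
  a1 <- lesion_area(make_thickness_map(m), 0.05, 0.05, 70)$area_mm2
  a2 <- lesion_area(make_thickness_map(m), 0.05 * s, 0.05 * s, 70)$area_mm2
  expect_equal(a2, a1 * s^2, tolerance = 1e-12)
})

test_that("en-face projections obey reducer semantics", {
  v <- array(3, c(6, 4, 2))
  expect_true(all(enface_projection(v, "mean") == 3))
  expect_true(all(enface_projection(v, "sum", c(2, 5)) == 12))
  set.seed(1)
  r <- array(rnorm(6 * 4 * 2), c(6, 4, 2))
  expect_true(all(enface_projection(r, "max") >= enface_projection(r, "mean")))
  expect_true(all(enface_projection(abs(r), "sum") >= 0))
  expect_error(enface_projection(r, "mean", c(5, 2)), "range")
})

test_that("colormap rendering is deterministic and round-trips through PNG", {
  m <- matrix(seq(0, 120, length.out = 48), 8, 6)
  img <- render_colormap(make_thickness_map(m), range_um = c(0, 120))
  pal <- attr(img, "palette")
  lo <- col2rgb(pal[1]) / 255
  hi <- col2rgb(pal[length(pal)]) / 255
  expect_equal(as.numeric(img[1, 1, ]), as.numeric(lo), tolerance = 1 / 255)
  expect_equal(as.numeric(img[8, 6, ]), as.numeric(hi), tolerance = 1 / 255)
  f <- tempfile(fileext = ".png")
  render_colormap(make_thickness_map(m), range_um = c(0, 120), file = f)
  back <- png::readPNG(f)
  expect_equal(aperm(back, c(2, 1, 3)), img, ignore_attr = TRUE,
               tolerance = 1e-9)
})
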