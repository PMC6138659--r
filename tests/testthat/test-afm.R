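# AFM mechanics: Hertz fits, grid averaging, tether steps and tensions,
# constant-height pressure, contact areas.

test_that("Hertz round trips are unbiased (<1%) across moduli and contact points", {
  for (E in c(100, 500, 1500, 5000, 10000)) {
    for (cp in c(-0.5e-6, 0, 0.4e-6)) {
      cur <- generate_force_data(force_curve_spec(
        "indentation", true_E = E, contact_point_m = cp, noise_sd = 0))
      fit <- fit_hertz_pyramidal(cur)
      expect_equal(fit$E_Pa, E, tolerance = 0.01)
      expect_lt(abs(fit$contact_point_m - cp), 0.05e-6)
    }
  }
})

test_that("Hertz fits tolerate realistic force noise", {
  cur <- generate_force_data(force_curve_spec(
    "indentation", true_E = 1500, noise_sd = 10e-12, seed = 5L))
  fit <- fit_hertz_pyramidal(cur)
  expect_equal(fit$E_Pa, 1500, tolerance = 0.05)
})

test_that("the pyramidal force law is quadratic in depth and linear in E", {
  expect_equal(hertz_force(1e-6, 1500), 0.515e-9, tolerance = 1e-3)
  d <- seq(0, 1e-6, length.out = 11)
  expect_equal(hertz_force(d, 3000), 2 * hertz_force(d, 1500))
  expect_equal(hertz_force(2e-6, 1500), 4 * hertz_force(1e-6, 1500))
  expect_equal(hertz_force(-1e-6, 1500), 0)   # no force before contact
})

test_that("grid modulus averages the centre and its four neighbours", {
  g <- matrix(1000, 8, 8)
  expect_equal(grid_modulus(g, c(4, 4)), 1000)
  g2 <- g; g2[4, 4] <- 2000
  expect_equal(grid_modulus(g2, c(4, 4)), 1200)
  expect_error(grid_modulus(g, c(1, 4)), "edge")
  expect_error(grid_modulus(g, c(8, 8)), "edge")
})

test_that("tether steps are recovered exactly at zero noise and scaled thresholds", {
  cur <- generate_force_data(force_curve_spec(
    "retraction_tethers", tether_forces_N = c(50e-12, 91e-12)))
  steps <- detect_tether_steps(cur)
  expect_length(steps, 2)
  expect_equal(sort(steps), c(50e-12, 91e-12), tolerance = 0.01)

  base <- data.frame(separation_m = seq(0, 5e-6, length.out = 400),
                     force_N = rep(0, 400))
  expect_length(detect_tether_steps(base), 0)

  set.seed(6)
  noisy <- generate_force_data(force_curve_spec(
    "retraction_tethers", tether_forces_N = 91e-12, noise_sd = 2e-12,
    seed = 6L))
  st <- detect_tether_steps(noisy)
  expect_length(st, 1)
  expect_equal(st, 91e-12, tolerance = 0.05)
})

test_that("tether tension follows F^2/(8 B pi^2) with the converted bending stiffness", {
  expect_equal(tether_tension(0), 0)
  # B = 3e-12 dyne cm = 3e-12 * 1e-5 N * 1e-2 m = 3e-19 N m
  expect_equal(3e-12 * 1e-5 * 1e-2, 3e-19)
  expect_equal(tether_tension(91e-12), 0.35e-3, tolerance = 2e-3)
  expect_equal(tether_tension(2 * 91e-12), 4 * tether_tension(91e-12))
  res <- tether_result(c(91e-12, 60e-12, 41e-12))
  expect_identical(res$normalized_tensions[1], 1)
  expect_true(all(diff(res$normalized_tensions) < 0))
})

test_that("constant-height pressure is force over area with reset stitching", {
  rec <- data.frame(time_s = 0:99, force_N = rep(1e-9, 100))
  out <- constant_height_pressure(rec, 100e-12)
  expect_equal(out$pressure_Pa, rep(10, 100))

  # stitching removes an injected -5 nN reset and restores monotonicity
  ramp <- seq(0, 20e-9, length.out = 200)
  raw <- ramp; raw[101:200] <- raw[101:200] - raw[100]
  out2 <- constant_height_pressure(
    data.frame(time_s = seq_len(200), force_N = raw), 100e-12)
  expect_true(all(diff(out2$stitched_force_N) >= -1e-15))
  expect_equal(out2$stitched_force_N, ramp, tolerance = 1e-6)

  # stitched force is invariant to the number and placement of resets
  prof <- data.frame(time_s = seq(0, 500, 1),
                     pressure_Pa = seq(0, 200, length.out = 501))
  mk <- function(resets) generate_force_data(force_curve_spec(
    "constant_height", pressure_profile = prof, contact_area_m2 = 100e-12,
    reset_times_s = resets, rupture = FALSE))
  s0 <- constant_height_pressure(mk(numeric()), 100e-12)$stitched_force_N
  s3 <- constant_height_pressure(mk(c(120, 260, 401)), 100e-12)$stitched_force_N
  # stitching restores the signal up to the one-sample growth increment
  # consumed by each reset
  expect_equal(s3, s0, tolerance = 1e-3)

  expect_error(constant_height_pressure(rec, 0), "> 0")
})

test_that("a generated swelling record recovers its pressure plateau and rupture", {
  prof <- data.frame(time_s = seq(0, 600, 2),
                     pressure_Pa = pmin(150, seq(0, 600, 2) * 0.5))
  cur <- generate_force_data(force_curve_spec(
    "constant_height", pressure_profile = prof, contact_area_m2 = 100e-12,
    reset_times_s = c(150, 250), noise_sd = 0.05e-9, seed = 9L))
  rec <- constant_height_pressure(cur, 100e-12)
  plateau <- rec$pressure_Pa[rec$time_s > 350 & rec$time_s <= 600]
  expect_equal(median(plateau, na.rm = TRUE), 150, tolerance = 2 / 150)
  expect_equal(attr(rec, "rupture_time_s"), 600, tolerance = 0.01)
  # measured band of swelling cells is 100-200 Pa; the plateau sits inside
  expect_true(median(plateau, na.rm = TRUE) > 100 &&
                median(plateau, na.rm = TRUE) < 200)
})

test_that("contact areas come from thresholded images and are intensity-invariant", {
  img <- disc_image(96, c(48, 48), 28.2)     # 28.2 px at 0.2 um/px: 100 um^2
  a <- contact_area_from_image(img, 0.2)
  expect_equal(m2_to_um2(a), 100, tolerance = 0.02)
  expect_equal(contact_area_from_image(img * 0.5, 0.2), a)
  expect_error(contact_area_from_image(matrix(0.3, 64, 64), 0.2), "empty mask")
})

test_that("force TSV round trips are bit-exact", {
  cur <- generate_force_data(force_curve_spec("indentation", noise_sd = 1e-12))
  tf <- tempfile(fileext = ".tsv")
  write_force_tsv(cur, tf)
  back <- read_force_tsv(tf)
  expect_identical(back$force_N, cur$force_N)
  expect_identical(back$separation_m, cur$separation_m)
  # malformed header is rejected
  writeLines(c("a\tb", "1\t2"), tf)
  expect_error(read_force_tsv(tf), "header")
})
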