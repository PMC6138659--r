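# Swelling biophysics: radius kinematics, diffusion fits, pressure chain,
# Arrhenius and Young-Laplace estimates, cohort delay analysis.

test_that("effective radius and radial rate follow their closed forms", {
  expect_equal(effective_radius(pi), 1)
  expect_equal(effective_radius(151), 6.932, tolerance = 1e-3)
  expect_equal(effective_radius(0), 0)
  expect_error(effective_radius(-1), ">= 0")

  expect_equal(radius_rate(5, 1200), 2.083e-3, tolerance = 1e-3)
  expect_error(radius_rate(5, 0), "> 0")
  # for R = sqrt(4Dt) the numeric derivative equals R/(2t)
  D <- 0.01; tt <- seq(100, 2000, 1); R <- sqrt(4 * D * tt)
  num <- diff(R) / diff(tt)
  expect_equal(num, radius_rate(R[-length(R)], tt[-length(tt)]),
               tolerance = 1e-3)
})

test_that("diffusion fits recover exact two-segment slopes and refuse population 2", {
  t <- 0:60
  a <- ifelse(t <= 10, 100,
       ifelse(t <= 30, 100 + 2.4 * (t - 10),
       ifelse(t <= 50, 148 + 1.2 * (t - 30), 172)))
  tr <- data.frame(t_min = t, area_um2 = a)
  ann <- fake_ann(t1 = 10, tD = 30, t2 = 50)
  D <- fit_diffusion(tr, ann)
  expect_equal(D$D1_um2_per_min, 0.6, tolerance = 1e-9)
  expect_equal(D$D2_um2_per_min, 0.3, tolerance = 1e-9)
  expect_equal(D$D1_um2_per_s, 0.01, tolerance = 1e-9)

  ann2 <- fake_ann(10, 30, 50, t3 = 50, population = 2L)
  expect_error(fit_diffusion(tr, ann2), "population 1")

  # constant segment gives D = 0
  flat <- data.frame(t_min = t, area_um2 = rep(100, 61))
  expect_equal(fit_diffusion(flat, ann)$D1_um2_per_min, 0, tolerance = 1e-12)
})

test_that("noiseless default-calibration trace returns the configured D within 1%", {
  cfg <- cohort_config(noise_sd = 0, seed = 3L)
  sim <- generate_cell_trace(cfg, 1)
  ann <- detect_phases(sim$trace)
  D <- fit_diffusion(sim$trace, ann)
  expect_equal(D$D1_um2_per_s, um2_per_min_to_um2_per_s(cfg$expansion_D),
               tolerance = 0.01)
  expect_equal(D$D1_um2_per_s, 0.0108, tolerance = 0.01)
})

test_that("mesh size follows the cubic-lattice rule and lands near 20 nm at cell scale", {
  p <- swelling_params()
  expect_equal(mesh_size(6.93e-6, p), 26.4e-9, tolerance = 2e-3)
  expect_equal(mesh_size(5e-6, p), 16.2e-9, tolerance = 2e-3)
  # quadrupling L halves l_p
  p4 <- swelling_params(genome_length_m = 8)
  expect_equal(mesh_size(5e-6, p4), mesh_size(5e-6, p) / 2)
  # lattice-edge convention is sqrt(3) larger
  p3 <- swelling_params(mesh_rule = "sqrt_3V_over_L")
  expect_equal(mesh_size(5e-6, p3), sqrt(3) * mesh_size(5e-6, p))
  # cell-scale radii give 15-30 nm, consistent with ~20 nm
  lp <- mesh_size(seq(5e-6, 7e-6, length.out = 10), p)
  expect_true(all(lp > 15e-9 & lp < 30e-9))
})

test_that("viscosity scales as (R0/R)^3 from eta0", {
  p <- swelling_params(R0_m = 3.5e-6)
  expect_equal(chromatin_viscosity(3.5e-6, p), 0.1)
  expect_equal(chromatin_viscosity(7e-6, p), 0.1 / 8)
  expect_equal(chromatin_viscosity(6e-6, p), 0.0199, tolerance = 1e-2)
})

test_that("the swelling pressure reproduces the direct arithmetic chain", {
  # oracle: R = 6 um at 600 s after onset, R0 = 3.5 um, default mesh rule
  eta <- 0.1 * (3.5 / 6)^3
  lp <- sqrt((4 / 3) * pi * (6e-6)^3 / 2)
  dRdt <- 6e-6 / (2 * 600)
  p_expected <- eta / lp^2 * dRdt * 6e-6
  expect_equal(p_expected, 1.31, tolerance = 0.01)

  # build a trace whose area reaches pi R^2 exactly 600 s after t1
  t1 <- 5; t <- 0:20
  a1 <- pi * 3.5^2; a2 <- pi * 6^2
  a <- ifelse(t <= t1, a1, pmin(a1 + (a2 - a1) * (t - t1) / 10, a2))
  tr <- data.frame(t_min = t, area_um2 = a)
  ann <- fake_ann(t1 = 5, tD = 12, t2 = 15)
  pt <- swelling_pressure(tr, ann)
  expect_equal(attr(pt, "R0_m"), 3.5e-6, tolerance = 1e-6)
  expect_equal(pt$pressure_Pa[pt$t_min == 15], p_expected, tolerance = 1e-6)
  expect_equal(attr(pt, "pressure_at_t2_Pa"), p_expected, tolerance = 1e-6)

  # scaling properties: p ~ eta0, p ~ 1/l_p^2 (quadrupling L halves l_p
  # twice over), p declines with the (R0/R)^3 viscosity
  pt_eta <- swelling_pressure(tr, ann, swelling_params(eta0 = 0.2))
  expect_equal(pt_eta$pressure_Pa, 2 * pt$pressure_Pa, tolerance = 1e-9)
  pt_lp <- swelling_pressure(tr, ann, swelling_params(genome_length_m = 8))
  expect_equal(pt_lp$pressure_Pa, 4 * pt$pressure_Pa, tolerance = 1e-9)
  # p is linear in dRdt and R by construction of the formula
  expect_equal(pt$pressure_Pa,
               pt$eta_Pa_s / pt$l_p_m^2 * pt$dRdt_m_per_s * pt$R_m,
               tolerance = 1e-12)
  # dR/dt = 0 gives p = 0
  expect_equal(0.05 / (2e-8)^2 * 0 * 6e-6, 0)
})

test_that("Arrhenius activation energy matches the printed temperature experiment", {
  expect_equal(arrhenius_activation_energy(10, 296.65, 10, 310.15), 0)
  ea <- arrhenius_activation_energy(227.5, 296.65, 55.0, 310.15)
  expect_equal(ea, 80, tolerance = 0.03)
  expect_equal(227.5 / 55.0, 4.14, tolerance = 1e-3)
  # log-linearity: squaring the ratio doubles Ea
  ea2 <- arrhenius_activation_energy(227.5^2 / 55.0, 296.65, 55.0, 310.15)
  expect_equal(ea2, 2 * ea, tolerance = 1e-9)
  # swapping the (slow, fast) pairs leaves the estimate unchanged
  expect_equal(arrhenius_activation_energy(55.0, 310.15, 227.5, 296.65), ea)
  expect_error(arrhenius_activation_energy(10, 300, 5, 300), "differ")
})

test_that("Young-Laplace pressure matches the printed late-P2 estimate", {
  expect_equal(laplace_pressure(0, 7e-6), 0)
  expect_equal(laplace_pressure(0.07e-3, 7e-6), 20, tolerance = 1e-9)
  expect_equal(laplace_pressure(0.35e-3, 7e-6), 100, tolerance = 1e-9)
  expect_error(laplace_pressure(0.1, 0), "> 0")
})

test_that("rupture-delay analysis normalises its KDE and recovers an exponential contour", {
  set.seed(4)
  n <- 120
  cells <- data.frame(area_um2 = runif(n, 100, 220),
                      pressure_Pa = runif(n, 0.3, 3),
                      delay_min = NA)
  # delays exactly on an exponential decay: binned maxima lie on it too
  a_true <- 60; b_true <- 1.1; c_true <- 8
  cells$delay_min <- a_true * exp(-b_true * cells$pressure_Pa) + c_true
  res <- rupture_delay_analysis(cells)
  dx <- diff(res$kde$x[1:2]); dy <- diff(res$kde$y[1:2])
  expect_equal(sum(res$kde$z) * dx * dy, 1, tolerance = 1e-3)
  expect_equal(res$exp_fit$a, a_true, tolerance = 0.05)
  expect_equal(res$exp_fit$b, b_true, tolerance = 0.05)

  expect_error(rupture_delay_analysis(cells[1:5, ]), "10")

  # size-delay coupling in a generated cohort gives a positive Spearman
  cfg <- small_cfg(n_cells = 40L, population1_fraction = 1,
                   size_delay_coupling = 0.5, cell_area_sd = 12)
  truths <- do.call(rbind, lapply(1:40, function(i)
    generate_cell_trace(cfg, i)$truth))
  cohort <- data.frame(area_um2 = truths$cell_area_um2,
                       pressure_Pa = runif(40, 0.5, 2),
                       delay_min = truths$t3_min - truths$t2_min)
  expect_gt(rupture_delay_analysis(cohort)$spearman, 0)
})

test_that("unit converters round-trip exactly", {
  x <- c(0.0108, 151, 56)
  expect_equal(s_to_min(min_to_s(x)), x, tolerance = 1e-15)
  expect_identical(m2_to_um2(um2_to_m2(x)), x)
  expect_identical(m_to_um(um_to_m(x)), x)
  expect_equal(um2_per_min_to_um2_per_s(0.648), 0.0108)
})
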