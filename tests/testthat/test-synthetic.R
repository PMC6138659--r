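# Synthetic-data generator: traces, cohorts, movies, ground truth.

test_that("noiseless generative trace grows at exactly 4D during free expansion", {
  cfg <- small_cfg(noise_sd = 0)
  sim <- generate_cell_trace(cfg, 1)
  tr <- sim$trace; tru <- sim$truth
  i <- which(tr$t_min > tru$t1_min + cfg$frame_interval &
               tr$t_min <= tru$tD_min)
  slopes <- diff(tr$area_um2[i]) / diff(tr$t_min[i])
  expect_equal(slopes, rep(4 * cfg$expansion_D, length(slopes)),
               tolerance = 1e-12)
})

test_that("activation phase scales by the closed-form Arrhenius factor", {
  # closed form: 80 kJ/mol between 23.5 and 37 degC gives x4.107
  fac <- exp((80000 / 8.314) * (1 / 296.65 - 1 / 310.15))
  expect_equal(fac, 4.107, tolerance = 1e-3)
  cold <- small_cfg(n_cells = 60L, temperature = 23.5, onset_sd_t1 = 2,
                    duration = 400, seed = 3L)
  warm <- small_cfg(n_cells = 60L, temperature = 37, onset_sd_t1 = 2,
                    seed = 3L)
  t1_cold <- vapply(1:60, function(i)
    generate_cell_trace(cold, i)$truth$t1_min, numeric(1))
  t1_warm <- vapply(1:60, function(i)
    generate_cell_trace(warm, i)$truth$t1_min, numeric(1))
  expect_equal(mean(t1_cold) / mean(t1_warm), fac, tolerance = 0.05)
  # P2 duration is temperature-invariant by construction
  p2 <- function(cfg, i) {
    tru <- generate_cell_trace(cfg, i)$truth
    tru$t2_min - tru$t1_min
  }
  expect_equal(mean(vapply(1:20, p2, numeric(1), cfg = cold)),
               mean(vapply(1:20, p2, numeric(1), cfg = warm)),
               tolerance = 0.05)
})

test_that("population structure and size-delay coupling behave as configured", {
  cfg <- small_cfg(n_cells = 50L, population1_fraction = 0)
  truths <- do.call(rbind, lapply(1:50, function(i)
    generate_cell_trace(cfg, i)$truth))
  expect_true(all(truths$t2_min == truths$t3_min))
  expect_true(all(truths$population == 2L))

  cfg2 <- small_cfg(n_cells = 60L, population1_fraction = 1,
                    size_delay_coupling = 0.5, cell_area_sd = 12)
  truths2 <- do.call(rbind, lapply(1:60, function(i)
    generate_cell_trace(cfg2, i)$truth))
  rho <- cor(truths2$cell_area_um2, truths2$t3_min - truths2$t2_min,
             method = "spearman")
  expect_gt(rho, 0)
  # time-point ordering invariant
  expect_true(all(truths2$t1_min < truths2$tD_min))
  expect_true(all(truths2$tD_min <= truths2$t2_min))
  expect_true(all(truths2$t2_min <= truths2$t3_min))
})

test_that("cohort onset spread matches the configured distribution", {
  cfg <- cohort_config(n_cells = 139L, seed = 5L)
  t1 <- vapply(1:139, function(i)
    generate_cell_trace(cfg, i)$truth$t1_min, numeric(1))
  expect_equal(sd(t1), cfg$onset_sd_t1, tolerance = 0.2)
  expect_equal(mean(t1), cfg$onset_mean_t1, tolerance = 0.1)
})

test_that("cohorts are deterministic under a fixed seed and change with it", {
  cfg <- small_cfg(n_cells = 2L, duration = 120, onset_mean_t1 = 30)
  a <- generate_cohort(cfg, movies = TRUE, t_pad_min = 5)
  b <- generate_cohort(cfg, movies = TRUE, t_pad_min = 5)
  expect_identical(a$truth, b$truth)
  expect_identical(a$stacks[[1]]$frames, b$stacks[[1]]$frames)
  c_ <- generate_cohort(small_cfg(n_cells = 2L, duration = 120,
                                  onset_mean_t1 = 30, seed = 99L),
                        movies = FALSE)
  expect_false(isTRUE(all.equal(a$truth$t1_min, c_$truth$t1_min)))
})

test_that("slow cells are flagged truncated and impossible configs rejected", {
  cfg <- small_cfg(n_cells = 30L, onset_mean_t1 = 60, onset_sd_t1 = 25,
                   duration = 130, plateau_mean = 40)
  truths <- do.call(rbind, lapply(1:30, function(i)
    generate_cell_trace(cfg, i)$truth))
  late <- truths$t3_min + cfg$spill_ramp_frames * cfg$frame_interval >
    cfg$duration
  expect_identical(truths$truncated, late)
  expect_error(small_cfg(onset_mean_t1 = 190, duration = 200),
               "duration")
})

test_that("rendered movies track the trace area and stay in [0, 1]", {
  cfg <- small_cfg(noise_sd = 0, seed = 21L)
  sim <- generate_cell_trace(cfg, 1)
  stk <- render_movie(sim$trace, sim$truth, cfg,
                      t_max = sim$truth$t3_min + 8)
  px2 <- cfg$pixel_size^2
  areas <- vapply(stk$frames, function(f) sum(f > 0.4) * px2, numeric(1))
  gen <- sim$trace$area_um2[seq_along(areas)]
  expect_lt(max(abs(areas - gen) / gen), 0.02)
  rng <- range(unlist(lapply(stk$frames, range)))
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
})

test_that("chromatin scales self-similarly about its centroid during free expansion", {
  cfg <- small_cfg(noise_sd = 0, seed = 31L)
  sim <- generate_cell_trace(cfg, 1)
  tru <- sim$truth
  stk <- render_movie(sim$trace, sim$truth, cfg, t_max = tru$tD_min)
  f_ref <- which(stk$times > tru$t1_min + 1)[1]
  f_lat <- max(which(stk$times <= tru$tD_min - 1))
  props <- function(f) {
    m <- stk$frames[[f]] > 0.4
    idx <- which(m)
    r <- (idx - 1) %% nrow(m) + 1; c <- (idx - 1) %/% nrow(m) + 1
    list(mask = m, area = length(idx), r = r, c = c,
         rg = sqrt(mean((r - mean(r))^2 + (c - mean(c))^2)))
  }
  a <- props(f_ref); b <- props(f_lat)
  s <- sqrt(b$area / a$area)
  expect_gt(s, 1.05)
  # radius of gyration scales with sqrt(area)
  expect_equal(b$rg / a$rg, s, tolerance = 0.02)
  # shrinking the later mask by s about the nucleus centre reproduces the
  # earlier boundary (overlap within a ~1 px rasterisation band)
  nc <- c(tru$nucleus_row_px, tru$nucleus_col_px)
  rm <- round(nc[1] + (b$r - nc[1]) / s)
  cm <- round(nc[2] + (b$c - nc[2]) / s)
  inside <- a$mask[cbind(pmin(pmax(rm, 1), nrow(a$mask)),
                         pmin(pmax(cm, 1), ncol(a$mask)))]
  expect_gt(mean(inside), 0.95)
})

test_that("the true rupture point lies on the membrane boundary", {
  cfg <- small_cfg(n_cells = 20L)
  for (i in 1:20) {
    tru <- generate_cell_trace(cfg, i)$truth
    centre <- (cfg$field_size + 1) / 2
    a <- sqrt(tru$cell_area_um2 / cfg$pixel_size^2 * tru$aspect_ratio / pi)
    b <- sqrt(tru$cell_area_um2 / cfg$pixel_size^2 / (tru$aspect_ratio * pi))
    br <- tru$beta_deg * pi / 180
    x <- (tru$rupture_col_px - centre) * cos(br) +
      (tru$rupture_row_px - centre) * sin(br)
    y <- -(tru$rupture_col_px - centre) * sin(br) +
      (tru$rupture_row_px - centre) * cos(br)
    expect_equal(sqrt((x / a)^2 + (y / b)^2), 1, tolerance = 1e-6)
  }
})

test_that("render errors when the field cannot contain the cell", {
  cfg <- small_cfg(cell_area_mean = 300, cell_area_sd = 0)
  sim <- generate_cell_trace(cfg, 1)
  expect_error(render_movie(sim$trace, sim$truth, cfg), "field_size")
})

test_that("synthetic force curves match their generative laws", {
  # indentation: Hertz force at 1 um depth for E = 1.5 kPa is 0.515 nN
  spec <- force_curve_spec("indentation", true_E = 1500, depth_m = 1.2e-6)
  cur <- generate_force_data(spec)
  f_at <- approx(cur$separation_m, cur$force_N, xout = 1e-6)$y
  expect_equal(f_at, 0.515e-9, tolerance = 0.005)

  # retraction: exactly one step of 91 pN at zero noise
  cur2 <- generate_force_data(force_curve_spec("retraction_tethers",
                                               tether_forces_N = 91e-12))
  steps <- detect_tether_steps(cur2)
  expect_length(steps, 1)
  expect_equal(steps, 91e-12, tolerance = 1e-9)

  # constant height: 150 Pa on 100 um^2 gives a 15 nN plateau after
  # reset stitching
  prof <- data.frame(time_s = seq(0, 600, 2),
                     pressure_Pa = pmin(150, seq(0, 600, 2)))
  cur3 <- generate_force_data(force_curve_spec(
    "constant_height", pressure_profile = prof,
    contact_area_m2 = 100e-12, reset_times_s = c(200, 400)))
  rec <- constant_height_pressure(cur3, 100e-12)
  plateau <- rec$stitched_force_N[rec$time_s > 300 & rec$time_s <= 600]
  expect_equal(median(plateau), 15e-9, tolerance = 0.01)
  expect_error(force_curve_spec("constant_height",
                                pressure_profile = data.frame()),
               "pressure_profile")
})
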