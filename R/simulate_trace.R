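#' Simulate one cell's chromatin area-time trace with ground truth
#'
#' Draws a single cell from the cohort distributions and builds its
#' generative projected chromatin-area trace: constant at the initial
#' (lobulated-nucleus) area during P1, linear growth A(t) = A0 + 4D (t - t1)
#' during the free expansion (t1..tD), slower linear growth while confined
#' by the membrane (tD..t2), a plateau at the cell area until rupture (t3),
#' and a ramped step increase after t3 as the NET spills beyond the
#' membrane. The onset t1 is Gaussian, scaled by the Arrhenius factor
#' exp[(Ea/R)(1/T - 1/Tref)] relative to 37 degC; the expansion and plateau
#' durations are temperature-invariant. The rupture delay is
#' max(0, plateau draw + size_delay_coupling * (cell area - mean)), zero for
#' population-2 cells.
#'
#' @param config a [cohort_config()].
#' @param cell_index cell index (0-based offsets are accepted; used for the
#'   derived per-cell seed and the cell id).
#' @return A list with elements `trace` (class `cell_trace`: data frame
#'   with `t_min`, `area_um2`, `norm_intensity`) and `truth` (one-row data
#'   frame of class `ground_truth` with the generative time points, areas,
#'   geometry and the per-cell seed).
#' @export
generate_cell_trace <- function(config, cell_index = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  if (cell_index > config$n_cells)
    stop("cell_index exceeds n_cells in the configuration")
  seed <- derive_seed(config$seed, cell_index)
  with_seed(seed, {
    fac <- arrhenius_time_factor(config$temperature, config$activation_energy)
    t1 <- -1
    while (t1 <= 0) t1 <- rnorm(1, config$onset_mean_t1, config$onset_sd_t1)
    t1 <- t1 * fac

    cell_area <- -1
    while (cell_area <= 0)
      cell_area <- rnorm(1, config$cell_area_mean, config$cell_area_sd)

    population <- if (runif(1) < config$population1_fraction) 1L else 2L
    delay <- if (population == 1L) {
      max(0, rnorm(1, config$plateau_mean, config$plateau_sd) +
            config$size_delay_coupling *
              (cell_area - config$cell_area_mean))
    } else 0

    a0 <- config$initial_area_fraction * cell_area
    a_touch <- config$touch_fraction * cell_area
    rate_free <- 4 * config$expansion_D
    rate_conf <- rate_free * config$confined_rate_ratio
    tD <- t1 + (a_touch - a0) / rate_free
    t2 <- tD + (cell_area - a_touch) / rate_conf
    t3 <- t2 + delay

    # cell outline geometry (ellipse) and rupture point, in pixels
    q <- runif(1, config$aspect_range[1], config$aspect_range[2])
    beta <- runif(1, 0, 180)
    area_px <- cell_area / config$pixel_size^2
    a_px <- sqrt(area_px * q / pi)
    b_px <- sqrt(area_px / (pi * q))
    off_d <- runif(1, 0, config$nucleus_offset_frac) * b_px
    off_th <- runif(1, 0, 2 * pi)
    centre <- (config$field_size + 1) / 2
    nuc_row <- centre + off_d * sin(off_th)
    nuc_col <- centre + off_d * cos(off_th)
    # rupture angle: von Mises about the major axis, either end
    phi <- rvonmises(1, 0, config$rupture_axis_kappa) +
      if (runif(1) < 0.5) 0 else pi
    br <- beta * pi / 180
    rup_row <- centre + a_px * cos(phi) * sin(br) + b_px * sin(phi) * cos(br)
    rup_col <- centre + a_px * cos(phi) * cos(br) - b_px * sin(phi) * sin(br)
    alpha <- (atan2(rup_row - centre, rup_col - centre) * 180 / pi) %% 360

    spill_ramp <- config$spill_ramp_frames * config$frame_interval
    truncated <- (t3 + spill_ramp) > config$duration

    t <- seq(0, config$duration, by = config$frame_interval)
    area <- ifelse(t <= t1, a0,
            ifelse(t <= tD, a0 + rate_free * (t - t1),
            ifelse(t <= t2, a_touch + rate_conf * (t - tD),
            ifelse(t <= t3, cell_area,
              cell_area * (1 + config$spill_fraction *
                             pmin(1, (t - t3) / spill_ramp))))))

    trace <- data.frame(t_min = t, area_um2 = area, norm_intensity = 1)
    attr(trace, "cell_id") <- cell_index
    attr(trace, "frame_interval") <- config$frame_interval
    class(trace) <- c("cell_trace", "data.frame")

    truth <- data.frame(
      cell_id = cell_index, t1_min = t1, tD_min = tD, t2_min = t2,
      t3_min = t3, population = population,
      cell_area_um2 = cell_area, initial_chromatin_area_um2 = a0,
      aspect_ratio = q, beta_deg = beta, alpha_deg = alpha,
      nucleus_row_px = nuc_row, nucleus_col_px = nuc_col,
      rupture_row_px = rup_row, rupture_col_px = rup_col,
      truncated = truncated, seed = seed)
    class(truth) <- c("ground_truth", "data.frame")

    list(trace = trace, truth = truth)
  })
}

#' @export
print.cell_trace <- function(x, ...) {
  cat(sprintf("<cell_trace> cell %s: %d frames, %.4g..%.4g min, area %.4g..%.4g um^2\n",
              as.character(attr(x, "cell_id") %||% NA), nrow(x),
              min(x$t_min), max(x$t_min),
              min(x$area_um2, na.rm = TRUE), max(x$area_um2, na.rm = TRUE)))
  invisible(x)
}

#' Plot a chromatin area-time trace
#'
#' @param x a `cell_trace`.
#' @param phases optional [detect_phases()] fit; its time points are drawn
#'   as vertical lines.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cell_trace <- function(x, phases = NULL, ...) {
  plot(x$t_min, x$area_um2, type = "l",
       xlab = "time since stimulation [min]",
       ylab = expression("projected chromatin area [" * mu * m^2 * "]"), ...)
  if (!is.null(phases)) {
    abline(v = unlist(phases[c("t1", "tD", "t2", "t3")]),
           lty = c(2, 3, 2, 2), col = c(2, 8, 4, 3))
    legend("topleft", bty = "n", lty = c(2, 3, 2, 2), col = c(2, 8, 4, 3),
           legend = c("t1", "tD", "t2", "t3"))
  }
  invisible(x)
}
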