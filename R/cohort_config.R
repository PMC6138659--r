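#' Configuration of a synthetic NETosis cohort
#'
#' Bundles every parameter of the synthetic time-lapse generator. The
#' defaults are the study conditions of the quantitative NETosis phase
#' analysis: chromatin decondensation starts on average 56 min after
#' stimulation (cohort SD 25 min), the chromatin area expands as a 2D
#' diffusion process with an effective diffusion constant of
#' 0.0108 um^2 s^-1 (0.648 um^2 min^-1) until it fills the ~151 um^2 cell,
#' and after a plateau of on average 42.5 min (population-1 cells, 80% of
#' the cohort) the membrane ruptures and the NET is released. With these
#' values the expected cohort means of the three characteristic time points
#' are t1 = 56, t2 = 82 and t3 = 116 min. The activation phase scales with
#' temperature following Arrhenius kinetics (default activation energy
#' 80 kJ/mol); the expansion and plateau phases are temperature-invariant.
#'
#' @param n_cells number of cells in the cohort.
#' @param field_size movie side length in pixels.
#' @param pixel_size pixel size in um/px.
#' @param frame_interval frame interval in minutes.
#' @param duration movie duration in minutes.
#' @param onset_mean_t1,onset_sd_t1 mean and SD (min) of the Gaussian
#'   chromatin-decondensation onset t1 at the reference temperature 37 degC;
#'   negative draws are redrawn.
#' @param expansion_D effective 2D diffusion constant of the free chromatin
#'   expansion in um^2/min (the slope of A(t) is 4D). 0.648 um^2/min equals
#'   0.0108 um^2/s.
#' @param touch_fraction fraction of the cell area at which the expanding
#'   chromatin first reaches the membrane (defines the truth tD).
#' @param confined_rate_ratio ratio of the confined (tD..t2) to the free
#'   (t1..tD) area growth rate.
#' @param initial_area_fraction initial (lobulated-nucleus) projected
#'   chromatin area as a fraction of the cell area.
#' @param plateau_mean,plateau_sd mean and SD (min) of the rupture-delay
#'   plateau t3 - t2 for population-1 cells.
#' @param cell_area_mean,cell_area_sd mean and SD of the projected cell
#'   area in um^2.
#' @param population1_fraction fraction of cells with a plateau between
#'   maximal expansion and rupture (t2 != t3); population-2 cells rupture at
#'   maximal expansion (plateau = 0).
#' @param size_delay_coupling slope linking cell area to rupture delay, in
#'   min/um^2 (larger cells rupture later).
#' @param temperature imaging temperature in degC.
#' @param activation_energy Arrhenius activation energy of the activation
#'   phase P1, kJ/mol.
#' @param noise_sd additive Gaussian imaging noise (relative intensity,
#'   image scale is [0, 1]).
#' @param aspect_range range of the cell's major/minor axis ratio; the cell
#'   outline is an ellipse of this eccentricity.
#' @param nucleus_offset_frac maximal offset of the nucleus centre from the
#'   cell centre, as a fraction of the minor semi-axis.
#' @param rupture_axis_kappa von Mises concentration of the rupture-point
#'   angle about the cell's major axis.
#' @param spill_fraction NET-spill area after rupture as a fraction of the
#'   cell area (drawn as a half-disc beyond the membrane).
#' @param spill_ramp_frames number of frames over which the post-rupture
#'   spill grows to its full area.
#' @param seed master seed; per-cell seeds are derived deterministically.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_cells = 139L,
                          field_size = 112L,
                          pixel_size = 0.3,
                          frame_interval = 1,
                          duration = 240,
                          onset_mean_t1 = 56,
                          onset_sd_t1 = 25,
                          expansion_D = 0.648,
                          touch_fraction = 0.9,
                          confined_rate_ratio = 0.5,
                          initial_area_fraction = 0.65,
                          plateau_mean = 42.5,
                          plateau_sd = 16,
                          cell_area_mean = 151,
                          cell_area_sd = 20,
                          population1_fraction = 0.8,
                          size_delay_coupling = 0.2,
                          temperature = 37,
                          activation_energy = 80,
                          noise_sd = 0.05,
                          aspect_range = c(1.05, 1.4),
                          nucleus_offset_frac = 0.35,
                          rupture_axis_kappa = 4,
                          spill_fraction = 0.3,
                          spill_ramp_frames = 6L,
                          seed = 1L) {
  cfg <- list(
    n_cells = as.integer(n_cells), field_size = as.integer(field_size),
    pixel_size = pixel_size, frame_interval = frame_interval,
    duration = duration, onset_mean_t1 = onset_mean_t1,
    onset_sd_t1 = onset_sd_t1, expansion_D = expansion_D,
    touch_fraction = touch_fraction,
    confined_rate_ratio = confined_rate_ratio,
    initial_area_fraction = initial_area_fraction,
    plateau_mean = plateau_mean, plateau_sd = plateau_sd,
    cell_area_mean = cell_area_mean, cell_area_sd = cell_area_sd,
    population1_fraction = population1_fraction,
    size_delay_coupling = size_delay_coupling,
    temperature = temperature, activation_energy = activation_energy,
    noise_sd = noise_sd, aspect_range = aspect_range,
    nucleus_offset_frac = nucleus_offset_frac,
    rupture_axis_kappa = rupture_axis_kappa,
    spill_fraction = spill_fraction,
    spill_ramp_frames = as.integer(spill_ramp_frames),
    seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(
    cfg$n_cells >= 1, cfg$field_size >= 16,
    cfg$pixel_size > 0, cfg$frame_interval > 0, cfg$duration > 0,
    cfg$onset_mean_t1 > 0, cfg$onset_sd_t1 >= 0,
    cfg$expansion_D > 0,
    cfg$touch_fraction > 0, cfg$touch_fraction <= 1,
    cfg$confined_rate_ratio > 0, cfg$confined_rate_ratio <= 1,
    cfg$initial_area_fraction > 0,
    cfg$initial_area_fraction < cfg$touch_fraction,
    cfg$plateau_mean >= 0, cfg$plateau_sd >= 0,
    cfg$cell_area_mean > 0, cfg$cell_area_sd >= 0,
    cfg$population1_fraction >= 0, cfg$population1_fraction <= 1,
    cfg$temperature > -273.15, cfg$activation_energy >= 0,
    cfg$noise_sd >= 0,
    length(cfg$aspect_range) == 2, all(cfg$aspect_range >= 1),
    cfg$spill_fraction >= 0, cfg$spill_ramp_frames >= 1)
  # Expansion must be able to reach the cell area within the movie: check
  # with the population-mean parameters (individual slow cells are flagged
  # `truncated` in the ground truth instead).
  fac <- arrhenius_time_factor(cfg$temperature, cfg$activation_energy)
  mean_expansion <- expansion_time(cfg$cell_area_mean, cfg)
  if (cfg$onset_mean_t1 * fac + mean_expansion > cfg$duration) {
    stop("invalid cohort_config: mean expansion cannot reach the cell ",
         "area within `duration` (needs > ",
         round(cfg$onset_mean_t1 * fac + mean_expansion, 1), " min)")
  }
  invisible(cfg)
}

# Duration (min) of the expansion phase t1 -> t2 for a cell of area A_cell.
expansion_time <- function(cell_area, cfg) {
  a0 <- cfg$initial_area_fraction * cell_area
  a_touch <- cfg$touch_fraction * cell_area
  rate_free <- 4 * cfg$expansion_D
  rate_conf <- rate_free * cfg$confined_rate_ratio
  (a_touch - a0) / rate_free + (cell_area - a_touch) / rate_conf
}

# Arrhenius scaling of the activation-phase duration relative to 37 degC:
# durations are inversely proportional to the rate constant
# k ~ exp(-Ea / (R T)).
arrhenius_time_factor <- function(temperature_c, activation_energy_kj) {
  t_k <- celsius_to_kelvin(temperature_c)
  exp((activation_energy_kj * 1000 / net_constants$R_gas) *
        (1 / t_k - 1 / net_constants$T_ref_K))
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic NETosis cohort configuration\n")
  cat(sprintf("  %d cells, %dx%d px @ %.2f um/px, %.3g min/frame, %g min\n",
              x$n_cells, x$field_size, x$field_size, x$pixel_size,
              x$frame_interval, x$duration))
  cat(sprintf("  onset t1 ~ N(%.3g, %.3g^2) min at %.1f degC (Ea %.3g kJ/mol)\n",
              x$onset_mean_t1, x$onset_sd_t1, x$temperature,
              x$activation_energy))
  cat(sprintf("  expansion D = %.4g um^2/min (%.3g um^2/s), cell area ~ N(%.3g, %.3g^2) um^2\n",
              x$expansion_D, um2_per_min_to_um2_per_s(x$expansion_D),
              x$cell_area_mean, x$cell_area_sd))
  cat(sprintf("  rupture delay ~ N(%.3g, %.3g^2) min, population-1 fraction %.2f\n",
              x$plateau_mean, x$plateau_sd, x$population1_fraction))
  cat(sprintf("  noise sd %.3g, seed %d\n", x$noise_sd, x$seed))
  invisible(x)
}
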