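#' Specification of a synthetic AFM signal
#'
#' @param mode `"indentation"` (extend curve following the pyramidal-tip
#'   Hertz law beyond a contact point), `"retraction_tethers"` (baseline
#'   with step-like force plateaus as membrane tethers detach) or
#'   `"constant_height"` (force-time record of a swelling cell pushing a
#'   fixed cantilever, with mirror-reset offsets and a terminal rupture
#'   collapse).
#' @param true_E Young's modulus, Pa (indentation).
#' @param poisson Poisson's ratio (fixed 0.5 for cells).
#' @param face_angle_deg pyramidal tip face angle, degrees.
#' @param contact_point_m tip-sample separation of the contact point, m.
#' @param depth_m maximal indentation depth, m.
#' @param tether_forces_N tether step forces, N (retraction mode).
#' @param bending_stiffness_Nm membrane bending stiffness B, N m
#'   (3e-19 N m = 3e-12 dyne cm).
#' @param pressure_profile data frame `time_s`, `pressure_Pa`
#'   (constant-height mode).
#' @param contact_area_m2 cell-cantilever contact area, m^2.
#' @param reset_times_s times at which the deflection mirror is reset
#'   (raw force drops to zero and continues).
#' @param rupture logical; append a terminal force collapse after the
#'   profile (membrane rupture ends the measurement).
#' @param n_points samples per sweep.
#' @param noise_sd force noise SD, N.
#' @param seed RNG seed.
#' @return A list of class `force_curve_spec`.
#' @export
force_curve_spec <- function(mode = c("indentation", "retraction_tethers",
                                      "constant_height"),
                             true_E = 1500, poisson = 0.5,
                             face_angle_deg = 20, contact_point_m = 0,
                             depth_m = 1.5e-6,
                             tether_forces_N = 91e-12,
                             bending_stiffness_Nm = 3e-19,
                             pressure_profile = NULL,
                             contact_area_m2 = 100e-12,
                             reset_times_s = numeric(),
                             rupture = TRUE,
                             n_points = 600, noise_sd = 0, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(true_E > 0, poisson >= 0, poisson < 1,
            face_angle_deg > 0, face_angle_deg < 90,
            bending_stiffness_Nm > 0, contact_area_m2 > 0, noise_sd >= 0)
  if (mode == "constant_height" &&
      (is.null(pressure_profile) || !nrow(pressure_profile)))
    stop("constant_height mode requires a non-empty pressure_profile")
  structure(list(mode = mode, true_E = true_E, poisson = poisson,
                 face_angle_deg = face_angle_deg,
                 contact_point_m = contact_point_m, depth_m = depth_m,
                 tether_forces_N = tether_forces_N,
                 bending_stiffness_Nm = bending_stiffness_Nm,
                 pressure_profile = pressure_profile,
                 contact_area_m2 = contact_area_m2,
                 reset_times_s = reset_times_s, rupture = rupture,
                 n_points = as.integer(n_points), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "force_curve_spec")
}

#' Pyramidal-tip Hertz force law
#'
#' `F = E / (1 - nu^2) * tan(alpha) / sqrt(2) * delta^2`.
#'
#' @param delta_m indentation depth, m (negative values give zero force).
#' @param E_Pa Young's modulus, Pa.
#' @param poisson Poisson's ratio.
#' @param face_angle_deg tip face angle, degrees.
#' @return Force in N.
#' @export
hertz_force <- function(delta_m, E_Pa, poisson = 0.5, face_angle_deg = 20) {
  E_Pa / (1 - poisson^2) * tan(face_angle_deg * pi / 180) / sqrt(2) *
    pmax(delta_m, 0)^2
}

#' Generate a synthetic AFM force curve
#'
#' @param spec a [force_curve_spec()].
#' @return A `force_curve`: data frame with the mode's abscissa
#'   (`separation_m` or `time_s`) and `force_N`, with attributes `mode` and
#'   `direction`, plus the generative truth as attribute `truth`.
#' @export
generate_force_data <- function(spec) {
  stopifnot(inherits(spec, "force_curve_spec"))
  with_seed(spec$seed, {
    out <- switch(spec$mode,
      indentation = {
        s <- seq(spec$contact_point_m - 2e-6,
                 spec$contact_point_m + spec$depth_m,
                 length.out = spec$n_points)
        f <- hertz_force(s - spec$contact_point_m, spec$true_E,
                         spec$poisson, spec$face_angle_deg)
        df <- data.frame(separation_m = s, force_N = f)
        attr(df, "direction") <- "extend"
        df
      },
      retraction_tethers = {
        k <- length(spec$tether_forces_N)
        n_seg <- k + 1L
        len <- spec$n_points %/% n_seg
        lev <- c(-rev(cumsum(rev(spec$tether_forces_N))), 0)
        f <- rep(lev, times = c(rep(len, n_seg - 1),
                                spec$n_points - len * (n_seg - 1)))
        df <- data.frame(separation_m = seq(0, 5e-6,
                                            length.out = spec$n_points),
                         force_N = f)
        attr(df, "direction") <- "retract"
        df
      },
      constant_height = {
        pp <- spec$pressure_profile
        t <- seq(min(pp$time_s), max(pp$time_s), length.out = spec$n_points)
        f <- approx(pp$time_s, pp$pressure_Pa, xout = t, rule = 2)$y *
          spec$contact_area_m2
        # mirror resets: the raw deflection is re-zeroed at each reset time
        offset <- numeric(length(t))
        for (rt in sort(spec$reset_times_s)) {
          i <- which(t >= rt)[1]
          if (!is.na(i) && i > 1) offset[i:length(t)] <-
              offset[i:length(t)] + f[i - 1] - offset[i - 1]
        }
        raw <- f - offset
        if (spec$rupture) {
          # membrane rupture: deflection collapses to the current baseline
          dt <- diff(t[1:2])
          tail_t <- max(t) + dt * seq_len(max(3, spec$n_points %/% 10))
          t <- c(t, tail_t)
          raw <- c(raw, rep(0, length(tail_t)))
        }
        df <- data.frame(time_s = t, force_N = raw)
        attr(df, "direction") <- "extend"
        attr(df, "rupture_time_s") <- if (spec$rupture)
          max(spec$pressure_profile$time_s) else NA_real_
        df
      })
    if (spec$noise_sd > 0)
      out$force_N <- out$force_N + rnorm(nrow(out), 0, spec$noise_sd)
    attr(out, "mode") <- spec$mode
    attr(out, "truth") <- spec
    class(out) <- c("force_curve", "data.frame")
    out
  })
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> mode %s, %d samples, force %.3g..%.3g nN\n",
              attr(x, "mode") %||% "?", nrow(x),
              min(x$force_N) * 1e9, max(x$force_N) * 1e9))
  invisible(x)
}
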