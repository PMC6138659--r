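#' Parameters of the entropic swelling-pressure model
#'
#' The decondensing chromatin is treated as a semiflexible polymer network
#' swelling against viscous resistance at the pore scale. The chain needs:
#' the nuclear viscosity before expansion `eta0` (0.1 Pa s), the genome
#' contour length `L` (~2 m of DNA), and a mesh-size rule that arranges the
#' genome in a cubic lattice inside a sphere of the current effective
#' radius: `l_p = sqrt(V/L)` (default) or the lattice-edge convention
#' `sqrt(3V/L)`. The DNA diameter `d` is recorded for completeness but is
#' not used by either mesh rule.
#'
#' @param eta0 nuclear viscosity before expansion, Pa s.
#' @param genome_length_m genome contour length L, metres.
#' @param dna_diameter_m DNA strand diameter, metres (recorded, unused).
#' @param mesh_rule `"sqrt_V_over_L"` or `"sqrt_3V_over_L"`.
#' @param R0_m reference chromatin radius (at t1) for the viscosity
#'   scaling, metres; usually set per cell by [swelling_pressure()].
#' @return A list of class `swelling_params`.
#' @export
swelling_params <- function(eta0 = 0.1, genome_length_m = 2,
                            dna_diameter_m = 2.2e-9,
                            mesh_rule = c("sqrt_V_over_L", "sqrt_3V_over_L"),
                            R0_m = NULL) {
  mesh_rule <- match.arg(mesh_rule)
  stopifnot(eta0 > 0, genome_length_m > 0, dna_diameter_m > 0,
            is.null(R0_m) || R0_m > 0)
  structure(list(eta0 = eta0, genome_length_m = genome_length_m,
                 dna_diameter_m = dna_diameter_m, mesh_rule = mesh_rule,
                 R0_m = R0_m),
            class = "swelling_params")
}

#' Effective chromatin radius from a projected area
#'
#' `R = sqrt(A / pi)`: the radius of the disc with the same projected area.
#'
#' @param area_um2 projected area in um^2 (vectorised).
#' @return Radius in um.
#' @export
effective_radius <- function(area_um2) {
  if (any(area_um2 < 0, na.rm = TRUE)) stop("area must be >= 0")
  sqrt(area_um2 / pi)
}

#' Radial expansion rate under square-root-of-time growth
#'
#' For diffusive area growth A = 4Dt the radius grows as sqrt(4Dt), whose
#' derivative is `dR/dt = R / (2t)` with t measured from the expansion
#' onset.
#'
#' @param R_um radius in um.
#' @param t_since_onset_s time since the expansion onset t1, seconds (> 0).
#' @return dR/dt in um/s.
#' @export
radius_rate <- function(R_um, t_since_onset_s) {
  if (any(t_since_onset_s <= 0)) stop("t_since_onset must be > 0")
  R_um / (2 * t_since_onset_s)
}

#' Chromatin mesh size from a cubic-lattice genome arrangement
#'
#' Arranges the genome (contour length L) evenly inside a sphere of radius
#' R: the volume per unit contour length is V/L, giving a characteristic
#' spacing `l_p = sqrt(V/L)` (default) or `sqrt(3V/L)` under the
#' lattice-edge convention.
#'
#' @param R_m chromatin radius in metres (vectorised).
#' @param params a [swelling_params()].
#' @return Mesh size in metres.
#' @export
mesh_size <- function(R_m, params = swelling_params()) {
  stopifnot(all(R_m > 0))
  V <- 4 / 3 * pi * R_m^3
  fac <- if (params$mesh_rule == "sqrt_3V_over_L") 3 else 1
  sqrt(fac * V / params$genome_length_m)
}

#' Chromatin viscosity scaling
#'
#' The viscosity of a semiflexible polymer network scales with the overall
#' radius as `eta(R) = eta0 (R0/R)^3`, anchored at the pre-expansion
#' nuclear viscosity `eta0`.
#'
#' @param R_m current radius, metres (vectorised).
#' @param params a [swelling_params()] with `R0_m` set.
#' @return Viscosity in Pa s.
#' @export
chromatin_viscosity <- function(R_m, params) {
  stopifnot(all(R_m > 0), !is.null(params$R0_m), params$R0_m > 0)
  params$eta0 * (params$R0_m / R_m)^3
}

#' Two-segment diffusion-constant fit of the chromatin expansion
#'
#' Interprets the linear area growth as a 2D diffusion process
#' `A - A(t1) = 4 D (t - t1)` and fits the slope by least squares on the
#' two expansion segments `(t1, tD]` and `(tD, t2]` separately, giving the
#' free-expansion constant D1 and the membrane-confined constant D2. The
#' frame adjacent to each segment boundary at tD is trimmed so that a
#' breakpoint falling between frames cannot contaminate the slopes. Only
#' population-1 cells are accepted.
#'
#' @param trace a `cell_trace`.
#' @param ann a `phase_fit` for that trace.
#' @param min_frames minimal number of frames per segment after trimming.
#' @return A list with `D1_um2_per_s`, `D2_um2_per_s`, the corresponding
#'   per-minute values, and the per-segment frame counts.
#' @export
fit_diffusion <- function(trace, ann, min_frames = 4) {
  if (ann$population != 1L)
    stop("population 1 required: diffusion constants are fitted only for ",
         "cells with a rupture-delay plateau (t2 != t3)")
  t <- trace$t_min; a <- trace$area_um2
  ok <- is.finite(t) & is.finite(a)
  t <- t[ok]; a <- a[ok]
  dt <- ann$frame_interval
  seg_fit <- function(lo, hi, trim_lo, trim_hi) {
    i <- which(t > lo + trim_lo * dt / 2 & t <= hi - trim_hi * dt + 1e-9)
    if (length(i) < min_frames)
      stop("too few frames in expansion segment [", round(lo, 2), ", ",
           round(hi, 2), "] for a diffusion fit")
    slope <- unname(coef(lm(a[i] ~ t[i]))[2])
    list(slope = slope, n = length(i))
  }
  s1 <- seg_fit(ann$t1, ann$tD, trim_lo = 0, trim_hi = 1)
  s2 <- seg_fit(ann$tD, ann$t2, trim_lo = 2, trim_hi = 1)
  list(D1_um2_per_min = s1$slope / 4,
       D2_um2_per_min = s2$slope / 4,
       D1_um2_per_s = um2_per_min_to_um2_per_s(s1$slope / 4),
       D2_um2_per_s = um2_per_min_to_um2_per_s(s2$slope / 4),
       n1 = s1$n, n2 = s2$n)
}

#' Entropic chromatin swelling pressure along a trace
#'
#' Evaluates the coarse-grained Stokes-flow pressure
#' `p(t) = eta(R) / l_p(R)^2 * dR/dt * R` per frame of the expansion phase
#' `(t1, t2]`, with `R = sqrt(A/pi)` from the measured areas,
#' `dR/dt = R / (2 (t - t1))` from the square-root growth law, the
#' viscosity scaling anchored at the radius at t1, and the cubic-lattice
#' mesh size. The value at t2 is exported as the cell's pressure at
#' maximal expansion. All mechanics are SI internally.
#'
#' @param trace a `cell_trace`.
#' @param ann a `phase_fit` (population 1).
#' @param params a [swelling_params()]; `R0_m`, if unset, is the effective
#'   radius at t1 interpolated from the trace.
#' @return A `pressure_trace`: data frame with `t_min`, `t_since_onset_s`,
#'   `R_m`, `dRdt_m_per_s`, `eta_Pa_s`, `l_p_m` and `pressure_Pa`, with
#'   attributes `pressure_at_t2_Pa`, `R0_m` and the diffusion fits.
#' @export
swelling_pressure <- function(trace, ann, params = swelling_params()) {
  if (ann$population != 1L)
    stop("population 1 required for the swelling-pressure analysis")
  t <- trace$t_min; a <- trace$area_um2
  ok <- is.finite(t) & is.finite(a)
  t <- t[ok]; a <- a[ok]
  if (is.null(params$R0_m)) {
    a_t1 <- approx(t, a, xout = ann$t1, rule = 2)$y
    params$R0_m <- um_to_m(effective_radius(a_t1))
  }
  sel <- which(t > ann$t1 & t <= ann$t2)
  if (!length(sel)) stop("no frames between t1 and t2")
  ts <- min_to_s(t[sel] - ann$t1)
  R <- um_to_m(effective_radius(a[sel]))
  dRdt <- um_to_m(radius_rate(m_to_um(R), ts))
  eta <- chromatin_viscosity(R, params)
  lp <- mesh_size(R, params)
  p <- eta / lp^2 * dRdt * R
  D <- tryCatch(fit_diffusion(trace, ann), error = function(e) NULL)
  out <- data.frame(t_min = t[sel], t_since_onset_s = ts, R_m = R,
                    dRdt_m_per_s = dRdt, eta_Pa_s = eta, l_p_m = lp,
                    pressure_Pa = p)
  attr(out, "pressure_at_t2_Pa") <- p[length(p)]
  attr(out, "R0_m") <- params$R0_m
  attr(out, "diffusion") <- D
  attr(out, "cell_id") <- attr(trace, "cell_id")
  class(out) <- c("pressure_trace", "data.frame")
  out
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("<pressure_trace> %d frames, R0 = %.3g um, p(t2) = %.3g Pa\n",
              nrow(x), m_to_um(attr(x, "R0_m")),
              attr(x, "pressure_at_t2_Pa")))
  invisible(x)
}

#' @export
plot.pressure_trace <- function(x, ...) {
  plot(x$t_min, x$pressure_Pa, type = "l",
       xlab = "time since stimulation [min]",
       ylab = "swelling pressure [Pa]", ...)
  invisible(x)
}
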