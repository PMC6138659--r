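#' Arrhenius activation energy from phase durations at two temperatures
#'
#' Assuming Arrhenius kinetics `k ~ exp(-Ea / (R T))` and durations
#' inversely proportional to the rate constant,
#' `Ea = R ln(tau_slow / tau_fast) / (1/T_slow - 1/T_fast)`. The estimate
#' is antisymmetric under swapping the (slow, fast) pairs and linear in the
#' log duration ratio.
#'
#' @param tau_slow,tau_fast phase durations (any common unit, e.g. min).
#' @param T_slow,T_fast absolute temperatures in kelvin (distinct).
#' @return Activation energy in kJ/mol.
#' @export
arrhenius_activation_energy <- function(tau_slow, T_slow, tau_fast, T_fast) {
  stopifnot(tau_slow > 0, tau_fast > 0, T_slow > 0, T_fast > 0)
  if (T_slow == T_fast) stop("temperatures must differ")
  ea_j <- net_constants$R_gas * log(tau_slow / tau_fast) /
    (1 / T_slow - 1 / T_fast)
  ea_j / 1000
}

#' Young-Laplace membrane pressure
#'
#' `p = 2 T / R` for a spherical membrane of tension T and radius R.
#'
#' @param tension_N_per_m membrane tension in N/m.
#' @param R_m radius in metres (> 0).
#' @return Pressure in Pa.
#' @export
laplace_pressure <- function(tension_N_per_m, R_m) {
  if (any(R_m <= 0)) stop("radius must be > 0")
  2 * tension_N_per_m / R_m
}

#' Cell-size, pressure and rupture-delay cohort analysis
#'
#' Two complementary views of why larger cells rupture later: (1) a
#' normalised 2D kernel density estimate over (cell area at t3, rupture
#' delay), and (2) an exponential contour of the maximal delays as a
#' function of the computed swelling pressure at t2: pressures are split
#' into equal-count bins, the maximal delay per bin is taken, and
#' `delay = a exp(-b p) + c` is fitted by least squares. Bandwidths follow
#' Scott's rule.
#'
#' @param cells data frame with columns `area_um2` (cell area at t3),
#'   `pressure_Pa` (swelling pressure at t2) and `delay_min` (t3 - t2);
#'   population-1 cells only, at least 10 rows.
#' @param n_bins number of equal-count pressure bins for the contour fit.
#' @param grid_n KDE evaluation grid size per axis.
#' @return A list with `kde` (MASS::kde2d-style grid, density normalised to
#'   integrate to 1), `exp_fit` (coefficients a, b, c and the binned
#'   maxima), and `spearman` (area-delay rank correlation).
#' @export
rupture_delay_analysis <- function(cells, n_bins = 8, grid_n = 64) {
  need <- c("area_um2", "pressure_Pa", "delay_min")
  stopifnot(all(need %in% names(cells)))
  cells <- cells[complete.cases(cells[, need]), ]
  if (nrow(cells) < 10)
    stop("at least 10 population-1 cells are required")
  scott <- function(v) 4 * sd(v) * nrow(cells)^(-1 / 6)  # kde2d sd = h/4
  kde <- MASS::kde2d(cells$area_um2, cells$delay_min,
                     h = c(scott(cells$area_um2),
                           max(scott(cells$delay_min), 1e-6)),
                     n = grid_n)
  cell_dx <- diff(kde$x[1:2]) * diff(kde$y[1:2])
  kde$z <- kde$z / (sum(kde$z) * cell_dx)

  q <- quantile(cells$pressure_Pa, probs = seq(0, 1, length.out = n_bins + 1))
  bin <- cut(cells$pressure_Pa, breaks = unique(q), include.lowest = TRUE)
  maxima <- do.call(rbind, lapply(split(cells, bin), function(d) {
    if (!nrow(d)) return(NULL)
    i <- which.max(d$delay_min)
    data.frame(pressure_Pa = d$pressure_Pa[i],
               max_delay_min = d$delay_min[i])
  }))
  fit <- tryCatch({
    st <- list(a = max(maxima$max_delay_min) - min(maxima$max_delay_min),
               b = 1 / max(diff(range(maxima$pressure_Pa)), 1e-6),
               c = min(maxima$max_delay_min))
    minpack.lm::nlsLM(max_delay_min ~ a * exp(-b * pressure_Pa) + c,
                      data = maxima, start = st,
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  }, error = function(e) NULL)
  cf <- if (is.null(fit)) c(a = NA_real_, b = NA_real_, c = NA_real_)
  else coef(fit)
  rho <- suppressWarnings(
    cor.test(cells$area_um2, cells$delay_min, method = "spearman"))
  list(kde = kde,
       exp_fit = list(a = unname(cf["a"]), b = unname(cf["b"]),
                      c = unname(cf["c"]), maxima = maxima, fit = fit),
       spearman = unname(rho$estimate))
}
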