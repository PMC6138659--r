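# Physical constants and small shared helpers. All mechanics are SI
# internally; I/O uses minutes and square micrometres.

#' Physical constants used by the swelling and kinetics models
#'
#' @format A list with elements `R_gas` (molar gas constant, J mol^-1 K^-1)
#'   and `T_ref_K` (reference body temperature 37 degC in kelvin).
#' @export
net_constants <- list(
  R_gas   = 8.314,
  T_ref_K = 310.15
)

#' Unit conversions between I/O units and SI
#'
#' Traces are handled in minutes and um^2 at the interface; the mechanics
#' work in seconds and metres. These converters are exact (pure
#' multiplications) and round-trip at double precision.
#'
#' @param x numeric vector.
#' @return Converted numeric vector.
#' @name unit-conversions
NULL

#' @rdname unit-conversions
#' @export
min_to_s <- function(x) x * 60

#' @rdname unit-conversions
#' @export
s_to_min <- function(x) x / 60

#' @rdname unit-conversions
#' @export
um2_to_m2 <- function(x) x / 1e12

#' @rdname unit-conversions
#' @export
m2_to_um2 <- function(x) x * 1e12

#' @rdname unit-conversions
#' @export
um_to_m <- function(x) x / 1e6

#' @rdname unit-conversions
#' @export
m_to_um <- function(x) x * 1e6

#' @rdname unit-conversions
#' @export
um2_per_min_to_um2_per_s <- function(x) x / 60

#' @rdname unit-conversions
#' @export
celsius_to_kelvin <- function(x) x + 273.15

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Fold an angle difference (degrees) into [0, 90]: axes are undirected.
fold_axis_deviation <- function(delta_deg) {
  d <- abs(delta_deg) %% 180
  ifelse(d > 90, 180 - d, d)
}

# von Mises sampler (Best & Fisher 1979 rejection method). mu in radians.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

# Deterministic per-cell seed derived from a master seed; kept < 2^31.
derive_seed <- function(master, index, stream = 0L) {
  as.integer((as.numeric(master) + 7919 * as.numeric(index) +
                104729 * as.numeric(stream)) %% .Machine$integer.max)
}

# Evaluate a computation under a local, restored RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
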