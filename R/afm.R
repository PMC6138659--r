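#' Read and write AFM force curves as TSV
#'
#' The dialect is a tab-separated table with a header of exactly two
#' columns: `separation_m` or `time_s`, and `force_N`. Values round-trip
#' at full double precision.
#'
#' @param path file path.
#' @param curve a `force_curve` data frame.
#' @return `read_force_tsv()` returns a `force_curve`;
#'   `write_force_tsv()` returns the path invisibly.
#' @export
read_force_tsv <- function(path) {
  if (!file.exists(path)) stop("force curve file not found: ", path)
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  ab <- intersect(c("separation_m", "time_s"), names(d))
  if (length(ab) != 1 || !"force_N" %in% names(d))
    stop("malformed force TSV header: need (separation_m|time_s, force_N), ",
         "got: ", paste(names(d), collapse = ", "))
  if (any(diff(d[[ab]]) <= 0))
    stop("non-monotone abscissa in ", path)
  class(d) <- c("force_curve", "data.frame")
  d
}

#' @rdname read_force_tsv
#' @export
write_force_tsv <- function(curve, path) {
  ab <- intersect(c("separation_m", "time_s"), names(curve))
  stopifnot(length(ab) == 1, "force_N" %in% names(curve))
  d <- data.frame(a = sprintf("%.17g", curve[[ab]]),
                  f = sprintf("%.17g", curve$force_N))
  names(d) <- c(ab, "force_N")
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fit the pyramidal-tip Hertz model to an extension force curve
#'
#' Locates the contact point as the changepoint of a two-piece
#' (flat + quadratic) least-squares model refined by a continuous search,
#' then extracts the Young's modulus from
#' `F = E / (1 - nu^2) * tan(alpha) / sqrt(2) * delta^2` beyond contact.
#' The baseline is corrected by a linear fit to the pre-contact 30% of the
#' sweep.
#'
#' @param curve a `force_curve` with `separation_m` and `force_N`
#'   (extension direction).
#' @param poisson Poisson's ratio (cells: 0.5).
#' @param face_angle_deg pyramidal face angle in degrees (20).
#' @param baseline_correct subtract a linear pre-contact baseline first.
#' @return An object of class `hertz_fit`: `E_Pa`, `contact_point_m`,
#'   `rss_N2`, the model constants, and the corrected curve.
#' @export
fit_hertz_pyramidal <- function(curve, poisson = 0.5, face_angle_deg = 20,
                                baseline_correct = TRUE) {
  s <- curve$separation_m
  f <- curve$force_N
  stopifnot(length(s) >= 20, all(is.finite(s)), all(is.finite(f)))
  if (baseline_correct) {
    nb <- max(5, floor(0.3 * length(s)))
    bl <- lm(f[seq_len(nb)] ~ s[seq_len(nb)])
    f <- f - (coef(bl)[1] + coef(bl)[2] * s)
  }
  rss_at <- function(c0) {
    q <- pmax(s - c0, 0)^2
    X <- cbind(1, q)
    sum(lm.fit(X, f)$residuals^2)
  }
  idx <- unique(round(seq(2, length(s) - 5, length.out = 200)))
  rss <- vapply(s[idx], rss_at, numeric(1))
  best <- idx[which.min(rss)]
  # the RSS dip at the true contact point is narrow; refine on a dense
  # local grid before the final continuous bracket
  lo <- s[max(best - 4, 1)]; hi <- s[min(best + 4, length(s))]
  grid <- seq(lo, hi, length.out = 160)
  gr <- vapply(grid, rss_at, numeric(1))
  gb <- which.min(gr)
  opt <- optimize(rss_at, c(grid[max(gb - 1, 1)],
                            grid[min(gb + 1, length(grid))]))
  c0 <- if (opt$objective < gr[gb]) opt$minimum else grid[gb]
  q <- pmax(s - c0, 0)^2
  cf <- lm.fit(cbind(1, q), f)$coefficients
  b <- max(cf[2], 0)
  if (b <= 0 || sum(s > c0) < 5) stop("no contact detected")
  E <- b * (1 - poisson^2) * sqrt(2) / tan(face_angle_deg * pi / 180)
  structure(list(E_Pa = unname(E), poisson = poisson,
                 face_angle_deg = face_angle_deg,
                 contact_point_m = c0, rss_N2 = opt$objective,
                 intercept_N = unname(cf[1]),
                 curve = data.frame(separation_m = s, force_N = f)),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("Hertz (pyramidal tip) fit: E = %.4g kPa, contact at %.3g um\n",
              x$E_Pa / 1000, x$contact_point_m * 1e6))
  cat(sprintf("  nu = %.2f, alpha = %.1f deg, RSS = %.3g N^2\n",
              x$poisson, x$face_angle_deg, x$rss_N2))
  invisible(x)
}

#' @export
coef.hertz_fit <- function(object, ...) {
  c(E_Pa = object$E_Pa, contact_point_m = object$contact_point_m)
}

#' @export
predict.hertz_fit <- function(object, separation_m = NULL, ...) {
  s <- separation_m %||% object$curve$separation_m
  hertz_force(s - object$contact_point_m, object$E_Pa, object$poisson,
              object$face_angle_deg)
}

#' @export
plot.hertz_fit <- function(x, ...) {
  plot(x$curve$separation_m * 1e6, x$curve$force_N * 1e9, pch = 16,
       cex = 0.4, xlab = "separation [um]", ylab = "force [nN]", ...)
  lines(x$curve$separation_m * 1e6, predict(x) * 1e9, col = 2, lwd = 2)
  abline(v = x$contact_point_m * 1e6, lty = 3)
  invisible(x)
}

#' Grid-averaged Young's modulus
#'
#' A force-curve map over the cell is summarised by the mean of the value
#' at the designated centre position and its four von Neumann neighbours,
#' avoiding edge effects.
#'
#' @param grid numeric matrix of per-position moduli (e.g. 8x8, Pa).
#' @param center integer `c(row, col)` of the centre position; must not lie
#'   on the grid edge.
#' @return Mean modulus (same units as `grid`).
#' @export
grid_modulus <- function(grid, center = NULL) {
  stopifnot(is.matrix(grid))
  if (is.null(center))
    center <- c(ceiling(nrow(grid) / 2), ceiling(ncol(grid) / 2))
  r <- center[1]; c <- center[2]
  if (r <= 1 || c <= 1 || r >= nrow(grid) || c >= ncol(grid))
    stop("center position lies on the grid edge: neighbors undefined")
  mean(c(grid[r, c], grid[r - 1, c], grid[r + 1, c],
         grid[r, c - 1], grid[r, c + 1]))
}

#' Detect tether detachment steps in a retraction curve
#'
#' Searches the baseline of a retraction curve for step-like deflection
#' changes that indicate tether detachment: a sharp force change with
#' constant plateaus before and after. Steps must exceed a noise-scaled
#' threshold (default 5x the MAD of the force increments) and both
#' plateaus must be flat to within a fraction of the step height.
#'
#' @param curve a `force_curve` (retraction, baseline-corrected).
#' @param window plateau window length in samples.
#' @param k_noise threshold in units of the increment MAD.
#' @param flatness maximal plateau slope per sample, as a fraction of the
#'   step height.
#' @return Numeric vector of step forces (N), possibly empty, ordered by
#'   position along the sweep.
#' @export
detect_tether_steps <- function(curve, window = 8, k_noise = 5,
                                flatness = 0.05) {
  f <- curve$force_N
  n <- length(f)
  if (n < 3 * window) return(numeric())
  d <- diff(f)
  noise <- mad(d)
  thr <- max(k_noise * noise, 1e-15)
  cand <- which(abs(d) > thr)
  if (!length(cand)) return(numeric())
  # merge candidates closer than `window` into single step locations
  grp <- cumsum(c(1, diff(cand) > window))
  steps <- numeric()
  for (g in unique(grp)) {
    ii <- cand[grp == g]
    i0 <- min(ii); i1 <- max(ii) + 1
    pre <- f[max(1, i0 - window):(i0 - 1)]
    post <- f[min(n, i1):min(n, i1 + window - 1)]
    if (length(pre) < 3 || length(post) < 3) next
    h <- abs(median(post) - median(pre))
    if (h <= thr) next
    slope_ok <- function(seg) {
      t <- seq_along(seg)
      abs(unname(coef(lm(seg ~ t))[2])) < flatness * h
    }
    if (slope_ok(pre) && slope_ok(post)) steps <- c(steps, h)
  }
  steps
}

#' Membrane tension from a tether force
#'
#' `T = F^2 / (8 B pi^2)` with B the membrane bending stiffness.
#'
#' @param F_N tether step force in N (vectorised).
#' @param B_Nm bending stiffness in N m; the default 3e-19 N m is the
#'   unit-converted 3e-12 dyne cm.
#' @return Tension in N/m.
#' @export
tether_tension <- function(F_N, B_Nm = 3e-19) {
  stopifnot(B_Nm > 0)
  F_N^2 / (8 * B_Nm * pi^2)
}

#' Tether-tension series with normalisation
#'
#' Converts a sequence of tether step forces into tensions and normalises
#' to the first value (so the normalised series always starts at 1),
#' enabling comparison across cells with different base tensions.
#'
#' @param step_forces_N tether forces in N, in temporal order.
#' @param B_Nm bending stiffness in N m.
#' @return A list of class `tether_result`: `step_forces_N`,
#'   `tensions_N_per_m`, `normalized_tensions`, `B_Nm`.
#' @export
tether_result <- function(step_forces_N, B_Nm = 3e-19) {
  stopifnot(length(step_forces_N) >= 1)
  tens <- tether_tension(step_forces_N, B_Nm)
  structure(list(step_forces_N = step_forces_N,
                 tensions_N_per_m = tens,
                 normalized_tensions = tens / tens[1],
                 B_Nm = B_Nm),
            class = "tether_result")
}

#' @export
print.tether_result <- function(x, ...) {
  cat(sprintf("<tether_result> %d steps, tensions %.3g..%.3g mN/m\n",
              length(x$step_forces_N), min(x$tensions_N_per_m) * 1e3,
              max(x$tensions_N_per_m) * 1e3))
  invisible(x)
}

#' Constant-height swelling-pressure record
#'
#' A cantilever held at constant height above a rounding cell is deflected
#' by the swelling force; when the sensor saturates the mirror is manually
#' reset, producing a sharp downward jump in the raw deflection. Resets
#' are detected as downward jumps exceeding `jump_k` times the
#' sample-to-sample MAD within one sample and removed by adding the jump
#' back to all later samples. A terminal collapse after which the force
#' stays near zero is flagged as the membrane rupture (end point of the
#' measurement) and is not stitched. The pressure is the stitched force
#' divided by the contact area.
#'
#' @param record a `force_curve` with `time_s` and `force_N`.
#' @param contact_area_m2 cell contact area in m^2 (> 0), e.g. from
#'   [contact_area_from_image()].
#' @param jump_k reset detection threshold in units of the increment MAD.
#' @param min_jump_frac absolute jump floor as a fraction of the force
#'   range (guards the noiseless case where the MAD vanishes).
#' @return An object of class `constant_height_record`: data frame with
#'   `time_s`, `raw_force_N`, `stitched_force_N`, `pressure_Pa`, and
#'   attributes `reset_times_s` and `rupture_time_s`.
#' @export
constant_height_pressure <- function(record, contact_area_m2,
                                     jump_k = 10, min_jump_frac = 0.02) {
  if (contact_area_m2 <= 0) stop("contact area must be > 0")
  t <- record$time_s; f <- record$force_N
  stopifnot(!is.null(t), length(f) >= 5)
  d <- diff(f)
  thr <- max(jump_k * mad(d), min_jump_frac * diff(range(f)), 1e-15)
  jumps <- which(d < -thr)
  rupture_i <- NA_integer_
  if (length(jumps)) {
    last <- jumps[length(jumps)]
    post <- f[(last + 1):length(f)]
    pre_level <- abs(f[last])
    if (pre_level > 0 &&
        max(abs(post - post[1])) < 0.1 * pre_level &&
        abs(median(post)) < 0.1 * pre_level) {
      rupture_i <- last
      jumps <- jumps[-length(jumps)]
    }
  }
  stitched <- f
  for (i in jumps) {
    stitched[(i + 1):length(stitched)] <-
      stitched[(i + 1):length(stitched)] - d[i]
  }
  out <- data.frame(time_s = t, raw_force_N = f,
                    stitched_force_N = stitched,
                    pressure_Pa = stitched / contact_area_m2)
  if (!is.na(rupture_i))
    out$pressure_Pa[(rupture_i + 1):nrow(out)] <- NA_real_
  attr(out, "reset_times_s") <- t[jumps + 1]
  attr(out, "rupture_time_s") <- if (is.na(rupture_i)) NA_real_ else
    t[rupture_i]
  attr(out, "contact_area_m2") <- contact_area_m2
  class(out) <- c("constant_height_record", "data.frame")
  out
}

#' @export
print.constant_height_record <- function(x, ...) {
  rt <- attr(x, "rupture_time_s")
  cat(sprintf("<constant_height_record> %d samples, peak pressure %.3g Pa%s\n",
              nrow(x), max(x$pressure_Pa, na.rm = TRUE),
              if (is.na(rt)) "" else sprintf(", rupture at %.3g s", rt)))
  invisible(x)
}

#' Cell contact area from a single-cell image
#'
#' Thresholds the visible cell (Otsu), keeps the largest connected
#' component, fills holes and converts the pixel count to square metres.
#'
#' @param image numeric intensity matrix.
#' @param pixel_size_um pixel size in um/px.
#' @return Contact area in m^2.
#' @export
contact_area_from_image <- function(image, pixel_size_um) {
  stopifnot(is.matrix(image), pixel_size_um > 0)
  rng <- range(image)
  if (diff(rng) <= 0) stop("empty mask: image has no contrast")
  norm <- (image - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm))
  m <- EBImage::fillHull(EBImage::Image((norm > th) * 1))
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  if (max(lab) == 0) stop("empty mask: no object above threshold")
  sizes <- tabulate(lab[lab > 0])
  um2_to_m2(max(sizes) * pixel_size_um^2)
}
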