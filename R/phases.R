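#' Phase-detection parameters
#'
#' @param k onset threshold in units of the baseline noise SD.
#' @param m number of consecutive qualifying frames required for the onset
#'   and slope tests.
#' @param slope_eps_frac plateau slope threshold as a fraction of the peak
#'   expansion slope.
#' @param smooth_k running-median window (frames, odd).
#' @param baseline_frames number of initial frames defining the baseline.
#' @return A list of class `phase_params`.
#' @export
phase_params <- function(k = 5, m = 5, slope_eps_frac = 0.02,
                         smooth_k = 5, baseline_frames = 10) {
  structure(list(k = k, m = m, slope_eps_frac = slope_eps_frac,
                 smooth_k = smooth_k, baseline_frames = baseline_frames),
            class = "phase_params")
}

# Sub-frame changepoint refinement: intersect a linear fit through the
# rising frames with a plateau level; fall back to the detected frame when
# the local slope is unusable.
refine_changepoint <- function(t, x, rise, level, fallback, lo, hi) {
  rise <- rise[rise >= 1 & rise <= length(x)]
  if (length(rise) < 2) return(fallback)
  fit <- lm(x[rise] ~ t[rise])
  sl <- coef(fit)[2]
  if (!is.finite(sl) || abs(sl) < 1e-12) return(fallback)
  clamp(unname((level - coef(fit)[1]) / sl), lo, hi)
}

run_start <- function(cond, m) {
  # index of the first position starting a run of >= m TRUEs, or NA
  if (!length(cond)) return(NA_integer_)
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  i <- which(r$values & r$lengths >= m)
  if (!length(i)) return(NA_integer_)
  ends[i[1]] - r$lengths[i[1]] + 1L
}

#' Detect the characteristic time points of a NETosis area trace
#'
#' Assigns the four characteristic time points on the median-smoothed
#' projected chromatin-area trace: `t1` (start of the first area increase;
#' the first run of `m` frames exceeding baseline + k*sigma, refined to the
#' baseline crossing of a local linear fit), `t2` (maximal intracellular
#' expansion; the first frame after `t1` where the forward slope stays
#' below `slope_eps` for `m` frames), `tD` (end of the uniform expansion;
#' the breakpoint of a two-segment least-squares fit on `[t1, t2]`) and
#' `t3` (NET release; the first frame after `t2` where the slope again
#' exceeds `slope_eps` for `m` frames). Cells without a plateau between
#' maximal expansion and rupture get `t3 = t2` and population 2. Detection
#' is translation-equivariant in time and scale-invariant in area: all
#' thresholds are relative (baseline MAD, fraction of the peak slope).
#'
#' @param trace a `cell_trace` (needs `t_min` and `area_um2`).
#' @param params a [phase_params()].
#' @return An object of class `phase_fit` with elements `t1`, `tD`, `t2`,
#'   `t3` (min), `population`, `P1_duration`, `P2_duration`,
#'   `rupture_delay`, diagnostic fields and the input trace.
#' @export
detect_phases <- function(trace, params = phase_params()) {
  ok <- is.finite(trace$t_min) & is.finite(trace$area_um2)
  t <- trace$t_min[ok]; a <- trace$area_um2[ok]
  if (length(t) < 20) stop("trace too short: need >= 20 frames")
  dt <- median(diff(t))
  m <- params$m
  x <- as.numeric(runmed(a, params$smooth_k))
  nb <- min(params$baseline_frames, length(x))
  baseline <- median(x[seq_len(nb)])
  # noise scale from the raw areas: median smoothing can null the MAD of
  # a discrete pixel-count trace, which would make the threshold hair-
  # trigger sensitive
  sig <- max(mad(a[seq_len(nb)]), mad(x[seq_len(nb)]),
             1e-8 * max(abs(baseline), 1))
  thr <- baseline + params$k * sig

  i1 <- run_start(x > thr, m)
  if (is.na(i1)) stop("no expansion detected")

  # refine t1: local linear fit through the first qualifying frames,
  # extrapolated back to the baseline crossing
  w <- i1:min(i1 + m - 1, length(x))
  fit <- lm(x[w] ~ t[w])
  slope1 <- coef(fit)[2]
  t1 <- if (is.finite(slope1) && slope1 > 0) {
    unname((baseline - coef(fit)[1]) / slope1)
  } else t[i1]
  t1 <- clamp(t1, t[max(1, i1 - m)], t[i1])

  # forward slope at frame j, median-smoothed: runmed preserves the
  # piecewise-constant slope structure (and hence noiseless changepoints)
  # while suppressing frame-to-frame segmentation jitter
  s <- diff(x) / diff(t)
  if (length(s) >= params$smooth_k)
    s <- as.numeric(runmed(s, params$smooth_k))
  peak <- max(s[i1:length(s)])
  if (!is.finite(peak) || peak <= 0) stop("no expansion detected")
  eps <- params$slope_eps_frac * peak
  # plateau/rise threshold: the larger of the relative slope_eps and a
  # noise floor estimated from the pre-onset slopes (zero for noiseless
  # traces, so exact changepoints are unaffected)
  sl_noise <- if (i1 > 6) mad(s[seq_len(i1 - 1)]) else 0
  eps_n <- max(eps, 3 * sl_noise)
  # pixel-count traces are quantised: one pixel per frame is the smallest
  # representable drift and must sit below the plateau threshold (applied
  # only when the quantum is small against the peak slope, so continuous
  # traces are unaffected)
  dq <- abs(diff(a)); dq <- dq[dq > 0]
  if (length(dq)) {
    sl_q <- min(dq) / dt
    if (sl_q <= 0.25 * peak) eps_n <- max(eps_n, 1.25 * sl_q)
  }

  # windowed-median slope tests: a window of m frames is "flat" when its
  # median slope is below the threshold. Medians tolerate the isolated
  # one-pixel quantisation spikes of segmented area traces that would
  # break an all-of-m run, and are exact on noiseless traces.
  nms <- length(s) - m + 1
  if (nms < 1) stop("trace too short: need >= 20 frames")
  ms <- vapply(seq_len(nms), function(j) median(s[j:(j + m - 1)]),
               numeric(1))
  j2 <- which(ms < eps_n & seq_len(nms) >= i1)[1]
  if (is.na(j2)) j2 <- NA_integer_

  # cells without a plateau (rupture at maximal expansion) show a
  # sustained slope *increase* instead -- the "second start of increase"
  # directly follows the expansion. Detect that kink as well and use
  # whichever changepoint comes first.
  # fire only from an established rising segment (med_prev well above the
  # plateau threshold) into a sustained >= 1.5x faster one
  jk <- NA_integer_
  for (j in seq(i1 + 5, max(i1 + 5, length(s) - m + 1))) {
    if (j > length(s) - m + 1) break
    if (!is.na(j2) && j >= j2) break
    med_prev <- median(s[max(i1, j - m):(j - 1)])
    nxt <- s[j:(j + m - 1)]
    if (med_prev > 3 * eps && median(nxt) > 1.5 * med_prev &&
        all(nxt > med_prev)) {
      jk <- j
      break
    }
  }
  if (is.na(j2) && is.na(jk))
    stop("truncated trace: ends before plateau resolution")

  if (!is.na(jk) && (is.na(j2) || jk < j2)) {
    # population 2: t2 = t3 at the slope kink (crossing of the expansion
    # and spill lines)
    pre <- max(i1, jk - m):(jk - 1)
    post <- jk:min(jk + m - 1, length(x))
    f1 <- lm(x[pre] ~ t[pre]); f2 <- lm(x[post] ~ t[post])
    denom <- coef(f2)[2] - coef(f1)[2]
    t2 <- if (is.finite(denom) && abs(denom) > 1e-12) {
      clamp(unname((coef(f1)[1] - coef(f2)[1]) / denom),
            t[max(i1, jk - 2)], t[min(jk + 1, length(t))])
    } else t[jk]
    t3 <- t2
    j2 <- jk
  } else {
    # anchor on the first genuinely flat frame of the detected window,
    # then refine t2 to the crossing of the final-rise linear fit with
    # the plateau level
    p2 <- j2 + which(s[j2:(j2 + m - 1)] < eps_n)[1] - 1
    rise <- (max(i1, p2 - m)):(p2 - 1)
    rise <- rise[s[rise] >= eps_n]
    t2 <- refine_changepoint(t, x, rise = rise,
                             level = median(x[p2:min(p2 + m - 1, length(x))]),
                             fallback = t[p2],
                             lo = t[max(i1, p2 - m)], hi = t[p2])
    j2 <- p2
    t3 <- NULL
  }

  # tD: two-segment piecewise-linear breakpoint on [t1, t2]
  seg <- which(t >= t1 & t <= t[j2])
  tD <- if (length(seg) >= 5) {
    best <- NULL; best_rss <- Inf
    for (b in seg[3:(length(seg) - 2)]) {
      i_lo <- seg[seg <= b]; i_hi <- seg[seg >= b]
      r1 <- sum(lm.fit(cbind(1, t[i_lo]), x[i_lo])$residuals^2)
      r2 <- sum(lm.fit(cbind(1, t[i_hi]), x[i_hi])$residuals^2)
      if (r1 + r2 < best_rss) { best_rss <- r1 + r2; best <- b }
    }
    t[best]
  } else t2
  tD <- clamp(tD, t1 + dt, t2)

  if (is.null(t3)) {
    j3 <- which(ms > eps_n & seq_len(nms) > j2)[1]
    t3 <- if (is.na(j3)) t2 else {
      # anchor on the first genuinely rising frame, refine t3 to the
      # crossing of the post-plateau rise with the plateau level
      p3 <- j3 + which(s[j3:(j3 + m - 1)] > eps_n)[1] - 1
      rise <- p3:min(p3 + m - 1, length(s))
      rise <- rise[s[rise] > eps_n]
      refine_changepoint(t, x, rise = rise,
                         level = median(x[j2:max(j2, p3 - 1)]),
                         fallback = t[p3],
                         lo = t[max(j2, p3 - 1)], hi = t[min(p3 + 1, length(t))])
    }
    if (t3 < t2) t3 <- t2
  }

  ann <- structure(list(
    t1 = t1, tD = tD, t2 = t2, t3 = t3,
    P1_duration = t1, P2_duration = t3 - t1, rupture_delay = t3 - t2,
    frame_interval = dt, baseline_area = baseline, noise_sd_area = sig,
    peak_slope = peak, slope_eps = eps, trace = trace),
    class = "phase_fit")
  ann$population <- classify_population(ann, dt)
  ann
}

#' Classify a cell into rupture populations
#'
#' Population 1 cells show a plateau between maximal chromatin expansion
#' and membrane rupture (`t3 - t2` greater than one frame interval);
#' population 2 cells rupture at maximal expansion (`t2 = t3`).
#'
#' @param ann a `phase_fit` (or any list with `t2` and `t3`).
#' @param frame_interval frame interval in minutes.
#' @return Integer 1 or 2.
#' @export
classify_population <- function(ann, frame_interval) {
  if (ann$t3 < ann$t2) stop("invalid annotation: t3 < t2")
  if ((ann$t3 - ann$t2) > frame_interval) 1L else 2L
}

#' @export
print.phase_fit <- function(x, ...) {
  cat("NETosis phase fit\n")
  cat(sprintf("  t1 = %.2f min, tD = %.2f min, t2 = %.2f min, t3 = %.2f min\n",
              x$t1, x$tD, x$t2, x$t3))
  cat(sprintf("  P1 = %.2f min, P2 = %.2f min, rupture delay = %.2f min, population %d\n",
              x$P1_duration, x$P2_duration, x$rupture_delay, x$population))
  invisible(x)
}

#' @export
coef.phase_fit <- function(object, ...) {
  c(t1 = object$t1, tD = object$tD, t2 = object$t2, t3 = object$t3)
}

#' @export
plot.phase_fit <- function(x, ...) {
  plot(x$trace, phases = x, ...)
}

#' Gaussian fit to a histogram of phase-onset times
#'
#' Bins the onset times and fits a Gaussian amplitude profile
#' `A * exp(-(x - mean)^2 / (2 sd^2))` to the bin counts by least squares,
#' mirroring the Gaussian distribution-function fits used for cohort onset
#' histograms. With fewer than 10 values the binned fit is unreliable and
#' the sample moments are returned with a warning; degenerate input (all
#' values equal) reports `sd = 0` with a warning.
#'
#' @param onsets numeric vector of onset times (min).
#' @param bin_width histogram bin width in minutes.
#' @return A list with `mean`, `sd`, `amplitude` (bin-count scale), and the
#'   histogram used for the fit (`NULL` when the moment fallback is used).
#' @export
fit_onset_histogram <- function(onsets, bin_width = 10) {
  onsets <- onsets[is.finite(onsets)]
  if (!length(onsets)) stop("no finite onset values")
  if (sd(onsets) == 0) {
    warning("degenerate onset sample: all values equal; sd = 0")
    return(list(mean = onsets[1], sd = 0, amplitude = length(onsets),
                histogram = NULL))
  }
  if (length(onsets) < 10) {
    warning("fewer than 10 onset values: returning sample moments, not a ",
            "histogram fit")
    return(list(mean = mean(onsets), sd = sd(onsets),
                amplitude = length(onsets), histogram = NULL))
  }
  breaks <- seq(floor(min(onsets) / bin_width) * bin_width,
                ceiling(max(onsets) / bin_width) * bin_width, by = bin_width)
  if (length(breaks) < 4)
    breaks <- seq(min(breaks) - bin_width, max(breaks) + bin_width,
                  by = bin_width)
  h <- graphics::hist(onsets, breaks = breaks, plot = FALSE)
  df <- data.frame(mid = h$mids, count = h$counts)
  fit <- minpack.lm::nlsLM(
    count ~ A * exp(-(mid - mu)^2 / (2 * s^2)), data = df,
    start = list(A = max(df$count), mu = mean(onsets), s = sd(onsets)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  list(mean = unname(cf["mu"]), sd = abs(unname(cf["s"])),
       amplitude = unname(cf["A"]), histogram = h)
}
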