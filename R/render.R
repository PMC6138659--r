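# Rasterisation of synthetic chromatin movies.
#
# Shapes are drawn with an analytic coverage model: each pixel's intensity
# is clamp(0.5 - signed_distance, 0, 1), i.e. a 1-px antialiasing ramp
# centred on the true boundary. Summed coverage then equals the geometric
# area to sub-pixel accuracy, which is what lets the segmentation recover
# the generative trace within a couple of percent.

# Lobe pattern in nucleus units (unit scale ~ one lobe radius cluster).
# 3-4 overlapping discs whose union approximates a lobulated nucleus.
make_lobe_pattern <- function(seed) {
  with_seed(derive_seed(seed, 0L, stream = 1L), {
    n <- sample(3:4, 1)
    ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)] +
      runif(n, -0.3, 0.3) + runif(1, 0, 2 * pi)
    rho <- runif(n, 0.35, 0.6)
    rad <- runif(n, 0.5, 0.7)
    data.frame(dr = rho * sin(ang), dc = rho * cos(ang), r = rad)
  })
}

# Signed distance (px) from each grid point to the ellipse boundary
# (negative inside). Uses the normalised-radius approximation scaled by the
# minor semi-axis, adequate for a 1-px antialiasing band.
ellipse_signed_distance <- function(rr, cc, centre_row, centre_col,
                                    a_px, b_px, beta_deg) {
  br <- beta_deg * pi / 180
  x <- (cc - centre_col) * cos(br) + (rr - centre_row) * sin(br)
  y <- -(cc - centre_col) * sin(br) + (rr - centre_row) * cos(br)
  rho <- sqrt((x / a_px)^2 + (y / b_px)^2)
  (rho - 1) * b_px
}

cov_from_sd <- function(sd) clamp(0.5 - sd, 0, 1)

# Coverage of the lobe union at scale sigma (px), about the nucleus centre.
lobe_union_sd <- function(rr, cc, nuc_row, nuc_col, lobes, sigma) {
  sd <- NULL
  for (i in seq_len(nrow(lobes))) {
    di <- sqrt((rr - (nuc_row + sigma * lobes$dr[i]))^2 +
                 (cc - (nuc_col + sigma * lobes$dc[i]))^2) -
      sigma * lobes$r[i]
    sd <- if (is.null(sd)) di else pmin(sd, di)
  }
  sd
}

#' Render a synthetic chromatin movie from a trace and its ground truth
#'
#' Draws the nucleus as 3-4 overlapping lobes whose union area follows the
#' generative trace; during the expansion phase the lobe pattern is scaled
#' self-similarly about the nucleus centroid (no re-shaping) and clipped by
#' the cell membrane (a convex elliptical boundary of the true cell area).
#' After t3 the chromatin spills beyond the membrane as a half-disc at the
#' rupture point. A faint membrane ring is drawn and additive Gaussian
#' noise of `config$noise_sd` is applied; intensities are clipped to [0, 1].
#'
#' @param trace,truth a trace/truth pair from [generate_cell_trace()].
#' @param config the [cohort_config()] used to generate them.
#' @param t_max optional last time point (min) to render; defaults to the
#'   full trace. Useful to stop acquisition shortly after NET release.
#' @return A `frame_stack`: list with `frames` (list of numeric matrices,
#'   row/column indexed), `times` (min), `pixel_size` (um/px),
#'   `frame_interval` (min) and `meta`.
#' @export
render_movie <- function(trace, truth, config, t_max = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n_field <- config$field_size
  px2 <- config$pixel_size^2
  keep <- if (is.null(t_max)) rep(TRUE, nrow(trace)) else trace$t_min <= t_max
  t <- trace$t_min[keep]
  area <- trace$area_um2[keep]

  a_px <- sqrt(truth$cell_area_um2 / px2 * truth$aspect_ratio / pi)
  b_px <- sqrt(truth$cell_area_um2 / px2 / (truth$aspect_ratio * pi))
  spill_total_px <- config$spill_fraction * truth$cell_area_um2 / px2
  spill_rad_max <- sqrt(2 * max(spill_total_px, 1) / pi)
  extent <- a_px + spill_rad_max + 3
  if (2 * extent > n_field) {
    stop("field too small for the cell: field_size must be at least ",
         ceiling(2 * extent), " px (is ", n_field, ")")
  }

  centre <- (n_field + 1) / 2
  rr <- matrix(seq_len(n_field), n_field, n_field)
  cc <- matrix(seq_len(n_field), n_field, n_field, byrow = TRUE)
  sd_ell <- ellipse_signed_distance(rr, cc, centre, centre, a_px, b_px,
                                    truth$beta_deg)
  cov_ell <- cov_from_sd(sd_ell)
  ell_area_px <- sum(cov_ell)
  ring_cov <- clamp(0.6 + 0.5 - abs(sd_ell), 0, 1)
  lobes <- make_lobe_pattern(truth$seed)

  # interior chromatin area in px for every frame (spill excluded)
  interior_px <- pmin(area, truth$cell_area_um2) / px2
  spill_px <- pmax(area - truth$cell_area_um2, 0) / px2

  interior_area_at <- function(sigma) {
    sd <- lobe_union_sd(rr, cc, truth$nucleus_row_px, truth$nucleus_col_px,
                        lobes, sigma)
    sum(pmin(cov_from_sd(sd), cov_ell))
  }
  # reference scale: free (unclipped) raster area of the unit pattern
  sd_unit <- lobe_union_sd(rr, cc, truth$nucleus_row_px,
                           truth$nucleus_col_px, lobes, 10)
  unit_area <- sum(cov_from_sd(sd_unit)) / 100  # area ~ sigma^2 * unit_area

  sigma_for_area <- function(target_px) {
    sig <- sqrt(target_px / unit_area)       # exact while inside membrane
    got <- interior_area_at(sig)
    if (abs(got - target_px) <= max(0.003 * target_px, 0.5)) return(sig)
    lo <- sig; hi <- sig                      # confined: bisect upward
    while (interior_area_at(hi) < target_px) {
      hi <- hi * 1.5
      if (hi > 4 * n_field) break
    }
    for (i in 1:18) {
      mid <- (lo + hi) / 2
      if (interior_area_at(mid) < target_px) lo <- mid else hi <- mid
      if (hi - lo < 0.02) break
    }
    (lo + hi) / 2
  }

  d_rup <- sqrt((rr - truth$rupture_row_px)^2 + (cc - truth$rupture_col_px)^2)
  cov_outside <- clamp(0.5 + sd_ell, 0, 1)
  spill_cov_at <- function(rs) pmin(cov_from_sd(d_rup - rs), cov_outside)
  spill_radius_for <- function(target_px) {
    lo <- 0; hi <- spill_rad_max + 3
    for (i in 1:18) {
      mid <- (lo + hi) / 2
      if (sum(spill_cov_at(mid)) < target_px) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }

  key <- paste(round(interior_px, 2), round(spill_px, 2))
  uniq <- !duplicated(key)
  imgs <- vector("list", sum(uniq))
  names(imgs) <- key[uniq]
  for (k in which(uniq)) {
    cov <- if (interior_px[k] >= 0.995 * ell_area_px) cov_ell
    else {
      sig <- sigma_for_area(interior_px[k])
      sd <- lobe_union_sd(rr, cc, truth$nucleus_row_px,
                          truth$nucleus_col_px, lobes, sig)
      pmin(cov_from_sd(sd), cov_ell)
    }
    if (spill_px[k] > 0.5)
      cov <- pmax(cov, spill_cov_at(spill_radius_for(spill_px[k])))
    imgs[[key[k]]] <- pmax(0.85 * cov, 0.12 * ring_cov)
  }

  frames <- vector("list", length(t))
  with_seed(derive_seed(truth$seed, 0L, stream = 2L), {
    for (k in seq_along(t)) {
      img <- imgs[[key[k]]]
      if (config$noise_sd > 0)
        img <- img + matrix(rnorm(length(img), 0, config$noise_sd),
                            nrow(img), ncol(img))
      frames[[k]] <- clamp(img, 0, 1)
    }
  })

  structure(list(frames = frames, times = t,
                 pixel_size = config$pixel_size,
                 frame_interval = config$frame_interval,
                 meta = list(cell_id = truth$cell_id, seed = truth$seed)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %dx%d px, %.3g um/px, %.3g min/frame\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' Draws `config$n_cells` independent cells (per-cell seeds are derived
#' deterministically from the master seed, so the cohort is reproducible
#' byte-for-byte) and optionally renders their movies.
#'
#' @param config a [cohort_config()].
#' @param movies logical; render the pixel movies (memory-heavy for large
#'   cohorts) or return only traces and ground truth.
#' @param t_pad_min when rendering, stop each movie this many minutes after
#'   the cell's NET release (plus the spill ramp); `Inf` renders the full
#'   configured duration.
#' @return A list with `traces` (list of `cell_trace`), `truth` (one row
#'   per cell) and, if requested, `stacks` (list of `frame_stack`).
#' @export
generate_cohort <- function(config, movies = TRUE, t_pad_min = Inf) {
  traces <- vector("list", config$n_cells)
  stacks <- if (movies) vector("list", config$n_cells) else NULL
  truths <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    sim <- generate_cell_trace(config, i)
    traces[[i]] <- sim$trace
    truths[[i]] <- sim$truth
    if (movies) {
      t_max <- if (is.finite(t_pad_min)) {
        min(config$duration,
            sim$truth$t3_min +
              config$spill_ramp_frames * config$frame_interval + t_pad_min)
      } else NULL
      stacks[[i]] <- render_movie(sim$trace, sim$truth, config, t_max = t_max)
    }
  }
  truth <- do.call(rbind, truths)
  out <- list(traces = traces, truth = truth)
  if (movies) out$stacks <- stacks
  out
}
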