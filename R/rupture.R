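# Rupture-point geometry. Masks are logical matrices in (row, col)
# indexing; angles are measured in degrees counterclockwise from the +col
# axis in the (col, row) plane and folded to [0, 90] for axis deviations.

mask_centroid <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) stop("empty mask")
  c(row = mean((idx - 1) %% nrow(mask) + 1),
    col = mean((idx - 1) %/% nrow(mask) + 1))
}

mask_boundary <- function(mask) {
  m <- EBImage::Image(mask * 1)
  er <- EBImage::imageData(EBImage::erode(m, EBImage::makeBrush(3, "box"))) > 0
  mask & !er
}

#' Chromatin velocity field over a grid of sub-windows
#'
#' Divides the frame into square sub-windows (default 15x15 px) and, for
#' every consecutive frame pair, measures the chromatin area gained or
#' lost per window. The signed area change is oriented along the outward
#' radial direction from the chromatin centroid, giving a growth/shrinking
#' vector per window; vectors are averaged over all frame pairs. The
#' residence density is the per-pixel sum of the binarised masks.
#'
#' @param masks list of logical matrices (one per frame, same shape).
#' @param frame_interval frame interval in minutes.
#' @param pixel_size pixel size in um/px.
#' @param window_px sub-window side length in pixels.
#' @return An object of class `velocity_field`: matrices `v_row`, `v_col`
#'   (mean vector components, um/min), `speed` (mean absolute rate,
#'   um/min), `residence` (pixel-wise frame counts), window centre
#'   coordinates and the grid geometry.
#' @export
velocity_field <- function(masks, frame_interval = 1, pixel_size = 1,
                           window_px = 15) {
  stopifnot(length(masks) >= 2)
  dims <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim(m), dims), logical(1))))
    stop("mask shape mismatch across frames")
  nwr <- ceiling(dims[1] / window_px)
  nwc <- ceiling(dims[2] / window_px)
  wrow <- pmin((seq_len(dims[1]) - 1) %/% window_px + 1, nwr)
  wcol <- pmin((seq_len(dims[2]) - 1) %/% window_px + 1, nwc)
  win_of <- matrix(wrow, dims[1], dims[2]) +
    nwr * (matrix(wcol, dims[1], dims[2], byrow = TRUE) - 1)
  centre_row <- (tapply(matrix(seq_len(dims[1]), dims[1], dims[2])[TRUE],
                        win_of[TRUE], mean))
  centre_col <- (tapply(matrix(seq_len(dims[2]), dims[1], dims[2],
                               byrow = TRUE)[TRUE], win_of[TRUE], mean))
  nwin <- nwr * nwc
  v_row <- v_col <- spd <- numeric(nwin)
  residence <- matrix(0, dims[1], dims[2])
  counts_prev <- tabulate(win_of[masks[[1]]], nwin)
  residence <- residence + masks[[1]]
  cent <- mask_centroid(masks[[1]])
  npairs <- length(masks) - 1
  for (f in 2:length(masks)) {
    counts <- tabulate(win_of[masks[[f]]], nwin)
    darea <- (counts - counts_prev) * pixel_size^2 / frame_interval
    mag <- darea / (window_px * pixel_size)     # um/min equivalent
    dr <- centre_row - cent["row"]; dc <- centre_col - cent["col"]
    nrm <- sqrt(dr^2 + dc^2); nrm[nrm == 0] <- 1
    v_row <- v_row + mag * dr / nrm
    v_col <- v_col + mag * dc / nrm
    spd <- spd + abs(mag)
    residence <- residence + masks[[f]]
    counts_prev <- counts
    if (any(masks[[f]])) cent <- mask_centroid(masks[[f]])
  }
  structure(list(
    v_row = matrix(v_row / npairs, nwr, nwc),
    v_col = matrix(v_col / npairs, nwr, nwc),
    speed = matrix(spd / npairs, nwr, nwc),
    residence = residence,
    centre_row = matrix(centre_row, nwr, nwc),
    centre_col = matrix(centre_col, nwr, nwc),
    window_px = window_px, pixel_size = pixel_size,
    frame_interval = frame_interval, dims = dims,
    win_of = win_of),
    class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %dx%d windows of %d px, max |v| = %.3g um/min\n",
              nrow(x$speed), ncol(x$speed), x$window_px, max(x$speed)))
  invisible(x)
}

#' Second-moment ellipse fit of a cell outline mask
#'
#' Fits the image-moment ellipse: centre of mass, semi-axes from the
#' eigenvalues of the pixel covariance (a solid ellipse with semi-axes a,
#' b has coordinate variances a^2/4, b^2/4) and the major-axis angle from
#' the principal eigenvector.
#'
#' @param mask logical matrix with a single connected component.
#' @param pixel_size pixel size in um/px.
#' @param circular_tol relative axis difference below which the cell is
#'   flagged circular (major-axis angle undefined).
#' @return An object of class `ellipse_fit`: `centre_row_px`,
#'   `centre_col_px`, `a_um`, `b_um`, `beta_deg` in [0, 180),
#'   `eccentricity`, `circular`.
#' @export
fit_cell_ellipse <- function(mask, pixel_size = 1, circular_tol = 0.01) {
  idx <- which(mask)
  if (length(idx) < 5) stop("degenerate mask: too few pixels")
  r <- (idx - 1) %% nrow(mask) + 1
  c <- (idx - 1) %/% nrow(mask) + 1
  mu <- c(mean(r), mean(c))
  S <- cov(cbind(r, c)) * (length(idx) - 1) / length(idx)
  e <- eigen(S, symmetric = TRUE)
  if (e$values[2] <= 0) stop("degenerate mask: line-like, no ellipse fit")
  a <- 2 * sqrt(e$values[1]) * pixel_size
  b <- 2 * sqrt(e$values[2]) * pixel_size
  v <- e$vectors[, 1]                       # (row, col) components
  beta <- (atan2(v[1], v[2]) * 180 / pi) %% 180
  circular <- (a - b) / a < circular_tol
  structure(list(centre_row_px = mu[1], centre_col_px = mu[2],
                 a_um = a, b_um = b,
                 beta_deg = if (circular) NA_real_ else beta,
                 eccentricity = sqrt(1 - (b / a)^2),
                 circular = circular),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit> a = %.3g, b = %.3g um, beta = %s deg%s\n",
              x$a_um, x$b_um,
              if (is.na(x$beta_deg)) "undefined" else sprintf("%.1f", x$beta_deg),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

# Radial extent of a mask from point M along a unit direction (px).
radial_extent <- function(mask, M, dir, step = 0.25) {
  tmax <- sqrt(sum(dim(mask)^2))
  tt <- seq(0, tmax, by = step)
  rr <- round(M[1] + tt * dir[1])
  cc <- round(M[2] + tt * dir[2])
  ok <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
  inside <- rep(FALSE, length(tt))
  inside[ok] <- mask[cbind(rr[ok], cc[ok])]
  if (!any(inside)) return(0)
  # last inside point of the contiguous run from the centre
  out1 <- which(!inside)
  end <- if (length(out1) && out1[1] > 1) out1[1] - 1 else
    if (inside[1]) max(which(inside)) else return(0)
  tt[end]
}

#' Membrane retraction speeds on both sides of the rupture axis
#'
#' Tracks the boundary intersection of the axis through the rupture point
#' A and the cell's centre of mass M on both sides of the cell over the
#' pre-rupture window, and reports the mean inward displacement rate of
#' each side (vA on the rupture side, vB opposite), clamped at zero.
#'
#' @param masks list of logical cell masks covering the pre-rupture
#'   window, in temporal order.
#' @param rupture_point numeric `c(row, col)` of the rupture point, px; it
#'   must lie within 2 px of the final mask's boundary.
#' @param frame_interval frame interval in minutes.
#' @param pixel_size pixel size in um/px.
#' @param M optional centre `c(row, col)`; defaults to the first mask's
#'   centre of mass.
#' @return A list of class `retraction_speeds`: `vA_um_min`, `vB_um_min`,
#'   and the per-frame radial extents.
#' @export
retraction_speeds <- function(masks, rupture_point, frame_interval = 1,
                              pixel_size = 1, M = NULL) {
  stopifnot(length(masks) >= 2)
  final_b <- which(mask_boundary(masks[[length(masks)]]), arr.ind = TRUE)
  if (!nrow(final_b)) stop("empty final mask")
  dmin <- min(sqrt((final_b[, 1] - rupture_point[1])^2 +
                     (final_b[, 2] - rupture_point[2])^2))
  if (dmin > 2)
    stop("rupture point is ", round(dmin, 1),
         " px off the final cell boundary (> 2 px)")
  if (is.null(M)) M <- mask_centroid(masks[[1]])
  dir <- c(rupture_point[1] - M[1], rupture_point[2] - M[2])
  nd <- sqrt(sum(dir^2))
  if (nd == 0) stop("rupture point coincides with the centre of mass")
  dir <- dir / nd
  rA <- vapply(masks, radial_extent, numeric(1), M = M, dir = dir)
  rB <- vapply(masks, radial_extent, numeric(1), M = M, dir = -dir)
  tt <- (seq_along(masks) - 1) * frame_interval
  slope <- function(y) unname(coef(lm(y ~ tt))[2])
  structure(list(vA_um_min = max(0, -slope(rA)) * pixel_size,
                 vB_um_min = max(0, -slope(rB)) * pixel_size,
                 rA_px = rA, rB_px = rB, t_min = tt),
            class = "retraction_speeds")
}

#' Rupture angle relative to the cell's former major axis
#'
#' The rupture axis runs from the centre of mass M to the rupture point A;
#' its angle alpha is compared with the major-axis angle beta and the
#' deviation |alpha - beta| is folded into [0, 90] degrees (axes are
#' undirected).
#'
#' @param rupture_point numeric `c(row, col)`, px.
#' @param ellipse an [fit_cell_ellipse()] result (non-circular).
#' @return A list with `alpha_deg` (in [0, 360)), `beta_deg` and
#'   `deviation_deg` (in [0, 90]).
#' @export
rupture_angle <- function(rupture_point, ellipse) {
  if (isTRUE(ellipse$circular) || is.na(ellipse$beta_deg))
    stop("circular cell: major-axis angle undefined")
  dr <- rupture_point[1] - ellipse$centre_row_px
  dc <- rupture_point[2] - ellipse$centre_col_px
  alpha <- (atan2(dr, dc) * 180 / pi) %% 360
  list(alpha_deg = alpha, beta_deg = ellipse$beta_deg,
       deviation_deg = fold_axis_deviation(alpha - ellipse$beta_deg))
}

#' Predict the membrane rupture point from the chromatin velocity field
#'
#' The rupture point tends to lie near areas of slow chromatin movement.
#' Among the grid windows touching the membrane boundary (and visited by
#' chromatin at some point), the one with the minimal mean chromatin speed
#' is selected and projected onto the nearest membrane-boundary pixel.
#' When the boundary speeds are near-uniform (centred nucleus) the
#' prediction is flagged low-confidence: the rupture direction is then
#' essentially random.
#'
#' @param field a [velocity_field()].
#' @param membrane_mask logical matrix: the final pre-rupture cell
#'   outline.
#' @param uniform_tol relative speed spread below which the prediction is
#'   flagged low-confidence.
#' @return A list with `point` (row, col of the predicted boundary pixel),
#'   `window` (grid indices), `low_confidence`, and the boundary-window
#'   speeds.
#' @export
predict_rupture_point <- function(field, membrane_mask, uniform_tol = 0.25) {
  stopifnot(inherits(field, "velocity_field"))
  if (all(field$speed == 0)) stop("no prediction: velocity field is zero")
  if (!identical(dim(membrane_mask), field$dims))
    stop("membrane mask shape does not match the field")
  bnd <- mask_boundary(membrane_mask)
  bwin <- unique(field$win_of[bnd])
  res_win <- tapply(field$residence[TRUE], field$win_of[TRUE], max)
  bwin <- bwin[res_win[bwin] > 0]
  if (!length(bwin)) stop("no prediction: no boundary window with chromatin")
  # normalise per window by the cell area it contains: otherwise the
  # comparison is dominated by how much boundary arc falls in each window
  cellpx <- tabulate(field$win_of[membrane_mask], length(field$speed))
  spd <- field$speed[bwin] / pmax(cellpx[bwin], 1)
  sel <- bwin[which.min(spd)]
  low_conf <- (max(spd) - min(spd)) <= uniform_tol * max(spd)
  wc <- c(field$centre_row[sel], field$centre_col[sel])
  bidx <- which(bnd, arr.ind = TRUE)
  d <- sqrt((bidx[, 1] - wc[1])^2 + (bidx[, 2] - wc[2])^2)
  pt <- bidx[which.min(d), ]
  list(point = c(row = unname(pt[1]), col = unname(pt[2])),
       window = c(row = (sel - 1) %% nrow(field$speed) + 1,
                  col = (sel - 1) %/% nrow(field$speed) + 1),
       low_confidence = low_conf,
       boundary_windows = bwin, boundary_speeds = spd)
}
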