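#' Segmentation parameters
#'
#' Defaults for the chromatin segmentation recipe: areas of high contrast
#' (the edge between stained chromatin and background) are carved out with
#' a Sobel gradient, thresholded (Otsu on the gradient image), smoothed and
#' morphologically closed, hole-filled, and the resulting object boundary
#' is refined at the half-maximum intensity level so that areas are
#' unbiased to sub-pixel accuracy. Small connected components are dropped.
#'
#' @param sigma Gaussian pre-smoothing SD in px.
#' @param close_radius radius (px) of the disc brush used for morphological
#'   closing of the edge mask.
#' @param min_area_px connected components smaller than this are removed.
#' @param refine logical; refine the boundary at the half-maximum level
#'   between the object and background intensities.
#' @param max_displacement_px maximal centroid displacement per frame used
#'   by the nearest-centroid tracker in [extract_traces()].
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(sigma = 1, close_radius = 2, min_area_px = 20,
                       refine = TRUE, max_displacement_px = 10) {
  structure(list(sigma = sigma, close_radius = close_radius,
                 min_area_px = min_area_px, refine = refine,
                 max_displacement_px = max_displacement_px),
            class = "seg_params")
}

# Separable convolution along rows/cols with replicate padding: far
# cheaper than FFT filtering for the tiny kernels used here.
conv_rows <- function(m, k) {
  n <- nrow(m); h <- (length(k) - 1) / 2
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(k)) {
    idx <- clamp(seq_len(n) + (i - 1 - h), 1, n)
    out <- out + k[i] * m[idx, , drop = FALSE]
  }
  out
}

conv_cols <- function(m, k) t(conv_rows(t(m), k))

gauss_kernel <- function(sigma) {
  h <- max(1, ceiling(3 * sigma))
  k <- exp(-(-h:h)^2 / (2 * sigma^2))
  k / sum(k)
}

gauss_smooth <- function(m, sigma) {
  k <- gauss_kernel(sigma)
  conv_cols(conv_rows(m, k), k)
}

sobel_magnitude <- function(m) {
  gx <- conv_rows(conv_cols(m, c(-1, 0, 1) / 4), c(1, 2, 1) / 2)
  gy <- conv_cols(conv_rows(m, c(-1, 0, 1) / 4), c(1, 2, 1) / 2)
  sqrt(gx^2 + gy^2)
}

drop_small <- function(mask, min_area_px) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labd <- EBImage::imageData(lab)
  if (max(labd) == 0) return(mask & FALSE)
  sizes <- tabulate(labd[labd > 0])
  keep <- which(sizes >= min_area_px)
  matrix(labd %in% keep, nrow(mask), ncol(mask))
}

#' Segment chromatin in a single frame
#'
#' @param frame numeric matrix (row/column indexed intensity image).
#' @param params a [seg_params()].
#' @return Logical matrix of the same shape: the binary chromatin mask. A
#'   blank frame (no gradient anywhere) yields an empty mask.
#' @export
segment_chromatin <- function(frame, params = seg_params()) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  sm <- gauss_smooth(frame, params$sigma)
  g <- sobel_magnitude(sm)
  gmax <- max(g)
  if (gmax <= 0) return(frame & FALSE)
  gn <- EBImage::Image(g / gmax)
  th <- EBImage::otsu(gn)
  edge <- gn > th
  brush <- EBImage::makeBrush(2 * params$close_radius + 1, "disc")
  m <- EBImage::closing(edge, brush)
  m <- EBImage::fillHull(m)
  mask <- EBImage::imageData(m) > 0
  if (!any(mask)) return(mask)
  if (params$refine) {
    core <- EBImage::imageData(EBImage::erode(m, EBImage::makeBrush(7, "disc"))) > 0
    halo <- EBImage::imageData(EBImage::dilate(m, EBImage::makeBrush(7, "disc"))) > 0
    fg <- if (any(core)) median(sm[core]) else median(sm[mask])
    bg <- if (any(!halo)) median(sm[!halo]) else min(sm)
    if (fg > bg) {
      near <- EBImage::imageData(
        EBImage::dilate(m, EBImage::makeBrush(2 * params$close_radius + 1,
                                              "disc"))) > 0
      ref <- (frame >= bg + 0.5 * (fg - bg)) & near
      ref <- EBImage::imageData(EBImage::fillHull(EBImage::Image(ref * 1))) > 0
      if (any(ref)) mask <- ref
    }
  }
  drop_small(mask, params$min_area_px)
}

label_components <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  n <- max(lab)
  if (n == 0)
    return(list(n = 0L, label = lab,
                stats = data.frame(label = integer(), area_px = integer(),
                                   row = numeric(), col = numeric())))
  idx <- which(lab > 0)
  l <- lab[idx]
  rowi <- (idx - 1) %% nrow(lab) + 1
  coli <- (idx - 1) %/% nrow(lab) + 1
  stats <- data.frame(
    label = seq_len(n),
    area_px = tabulate(l, n),
    row = tapply(rowi, l, mean),
    col = tapply(coli, l, mean))
  list(n = n, label = lab, stats = stats)
}

#' Extract per-cell area-time traces from a movie
#'
#' Segments every frame, links connected components across time by
#' nearest-centroid matching (components further than
#' `max_displacement_px` from any known cell are not linked), converts
#' pixel counts to um^2 via `pixel_size^2`, and normalises the total
#' intensity inside each cell's mask to its first-frame value so that
#' traces are invariant to staining intensity and global background.
#'
#' @param stack a `frame_stack` (see [render_movie()] / [read_movie()]).
#' @param params a [seg_params()].
#' @param masks logical; also return the per-frame label matrices.
#' @return A list of `cell_trace` data frames (columns `t_min`,
#'   `area_um2`, `norm_intensity`, `centroid_row_um`, `centroid_col_um`),
#'   one per tracked cell. If `masks = TRUE` the label matrices are
#'   attached as attribute `"labels"`.
#' @export
extract_traces <- function(stack, params = seg_params(), masks = FALSE) {
  stopifnot(inherits(stack, "frame_stack"))
  px <- stack$pixel_size
  nfr <- length(stack$frames)
  times <- stack$times %||%
    (seq_len(nfr) - 1) * stack$frame_interval
  cells <- list()   # per cell: last centroid, rows of measurements
  labels <- if (masks) vector("list", nfr) else NULL
  meas <- list()
  for (f in seq_len(nfr)) {
    frame <- stack$frames[[f]]
    mask <- segment_chromatin(frame, params)
    comp <- label_components(mask)
    if (masks) labels[[f]] <- comp$label
    if (comp$n > 0) {
      intens <- tapply(frame[comp$label > 0], comp$label[comp$label > 0], sum)
      comp$stats$intensity <- as.numeric(intens)
    }
    taken <- rep(FALSE, comp$n)
    for (ci in seq_along(cells)) {
      if (comp$n == 0) break
      d <- sqrt((comp$stats$row - cells[[ci]]$row)^2 +
                  (comp$stats$col - cells[[ci]]$col)^2)
      d[taken] <- Inf
      j <- which.min(d)
      if (length(j) && is.finite(d[j]) && d[j] <= params$max_displacement_px) {
        taken[j] <- TRUE
        cells[[ci]]$row <- comp$stats$row[j]
        cells[[ci]]$col <- comp$stats$col[j]
        meas[[ci]] <- rbind(meas[[ci]], data.frame(
          frame = f, t_min = times[f],
          area_px = comp$stats$area_px[j],
          intensity = comp$stats$intensity[j],
          row = comp$stats$row[j], col = comp$stats$col[j]))
      }
    }
    if (comp$n > 0 && any(!taken)) {
      for (j in which(!taken)) {
        cells[[length(cells) + 1]] <- list(row = comp$stats$row[j],
                                           col = comp$stats$col[j])
        meas[[length(cells)]] <- data.frame(
          frame = f, t_min = times[f],
          area_px = comp$stats$area_px[j],
          intensity = comp$stats$intensity[j],
          row = comp$stats$row[j], col = comp$stats$col[j])
      }
    }
  }
  out <- vector("list", length(meas))
  for (ci in seq_along(meas)) {
    m <- meas[[ci]]
    if (m$intensity[1] == 0)
      stop("normalization error: zero total intensity in first frame ",
           m$frame[1], " of cell ", ci)
    tr <- data.frame(
      t_min = m$t_min,
      area_um2 = m$area_px * px^2,
      norm_intensity = m$intensity / m$intensity[1],
      centroid_row_um = m$row * px,
      centroid_col_um = m$col * px)
    attr(tr, "cell_id") <- ci
    attr(tr, "frame_interval") <- stack$frame_interval
    class(tr) <- c("cell_trace", "data.frame")
    out[[ci]] <- tr
  }
  if (masks) attr(out, "labels") <- labels
  out
}
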