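# Shared fixtures, generated in code.

# A compact cohort configuration for fast end-to-end tests: coarser pixels
# and smaller cells keep the rendered field at 64 px.
small_cfg <- function(...) {
  args <- modifyList(list(
    n_cells = 4L, field_size = 64L, pixel_size = 0.4, duration = 200,
    onset_mean_t1 = 40, onset_sd_t1 = 8, cell_area_mean = 80,
    cell_area_sd = 5, plateau_mean = 30, plateau_sd = 8,
    noise_sd = 0.05, seed = 11L), list(...))
  do.call(cohort_config, args)
}

# Antialiased disc image: intensity = pixel coverage * fg.
disc_image <- function(n, centre, radius, fg = 0.85) {
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  d <- sqrt((rr - centre[1])^2 + (cc - centre[2])^2)
  fg * pmin(pmax(radius - d + 0.5, 0), 1)
}

disc_mask <- function(n, centre, radius) {
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  (rr - centre[1])^2 + (cc - centre[2])^2 <= radius^2
}

as_stack <- function(frames, pixel_size = 1, frame_interval = 1) {
  structure(list(frames = frames,
                 times = (seq_along(frames) - 1) * frame_interval,
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 meta = list()),
            class = "frame_stack")
}

# Minimal phase annotation for direct unit tests of the mechanics chain.
fake_ann <- function(t1, tD, t2, t3 = t2 + 20, population = 1L,
                     frame_interval = 1) {
  structure(list(t1 = t1, tD = tD, t2 = t2, t3 = t3,
                 population = population, frame_interval = frame_interval),
            class = "phase_fit")
}
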