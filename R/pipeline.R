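#' Run the end-to-end synthetic NETosis analysis pipeline
#'
#' Simulates a cohort, renders each cell's movie, segments it back into an
#' area-time trace, detects the phase time points, fits the diffusion
#' constants and computes the swelling pressure for population-1 cells,
#' and aggregates a cohort summary (means and SEMs of t1, t2, t3, D1 and
#' the pressure at t2). Every output embeds the config hash and seed.
#'
#' @param config a [pipeline_config()] (or a path accepted by
#'   [read_pipeline_config()]).
#' @param t_pad_min per-cell rendering pad after NET release, minutes.
#' @return A list of class `pipeline_result`: `cells` (per-cell detected
#'   time points, truth and status), `summary` (one-row cohort summary),
#'   `config`, `manifest`. If `config$out` is set, per-stage CSVs and a
#'   JSON manifest are written there.
#' @export
run_pipeline <- function(config = pipeline_config(), t_pad_min = 10) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  cc <- config$cohort
  log_info <- function(...) {
    if (config$log_level != "quiet") message(...)
  }
  log_info("netphases pipeline: ", cc$n_cells, " cells, seed ", cc$seed,
           ", config ", substr(config$hash, 1, 8))
  rows <- vector("list", cc$n_cells)
  traces <- vector("list", cc$n_cells)
  for (i in seq_len(cc$n_cells)) {
    row <- tryCatch({
      sim <- generate_cell_trace(cc, i)
      t_max <- min(cc$duration,
                   sim$truth$t3_min +
                     (cc$spill_ramp_frames + t_pad_min) * cc$frame_interval)
      stack <- render_movie(sim$trace, sim$truth, cc, t_max = t_max)
      trs <- extract_traces(stack, config$segmentation)
      if (!length(trs)) stop("segmentation found no cell")
      tr <- trs[[which.max(vapply(trs, nrow, integer(1)))]]
      attr(tr, "cell_id") <- i
      traces[[i]] <- tr
      ann <- detect_phases(tr, config$phases)
      D <- if (ann$population == 1L)
        tryCatch(fit_diffusion(tr, ann), error = function(e) NULL)
      else NULL
      p2 <- if (ann$population == 1L)
        tryCatch(attr(swelling_pressure(tr, ann, config$swelling),
                      "pressure_at_t2_Pa"),
                 error = function(e) NA_real_)
      else NA_real_
      data.frame(
        cell_id = i, status = "ok",
        t1_min = ann$t1, tD_min = ann$tD, t2_min = ann$t2, t3_min = ann$t3,
        population = ann$population,
        rupture_delay_min = ann$rupture_delay,
        area_t3_um2 = approx(tr$t_min, tr$area_um2, xout = ann$t3,
                             rule = 2)$y,
        D1_um2_per_s = if (is.null(D)) NA_real_ else D$D1_um2_per_s,
        D2_um2_per_s = if (is.null(D)) NA_real_ else D$D2_um2_per_s,
        pressure_t2_Pa = p2,
        true_t1_min = sim$truth$t1_min, true_t2_min = sim$truth$t2_min,
        true_t3_min = sim$truth$t3_min,
        true_population = sim$truth$population,
        truncated = sim$truth$truncated)
    }, error = function(e) {
      data.frame(cell_id = i, status = paste0("error: ", conditionMessage(e)),
                 t1_min = NA_real_, tD_min = NA_real_, t2_min = NA_real_,
                 t3_min = NA_real_, population = NA_integer_,
                 rupture_delay_min = NA_real_, area_t3_um2 = NA_real_,
                 D1_um2_per_s = NA_real_, D2_um2_per_s = NA_real_,
                 pressure_t2_Pa = NA_real_,
                 true_t1_min = NA_real_, true_t2_min = NA_real_,
                 true_t3_min = NA_real_, true_population = NA_integer_,
                 truncated = NA)
    })
    if (!identical(row$status, "ok"))
      log_info("  cell ", i, " failed: ", row$status)
    rows[[i]] <- row
  }
  cells <- do.call(rbind, rows)
  ok <- cells[cells$status == "ok" & !cells$truncated, ]
  sem <- function(v) sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v)))
  summary_df <- data.frame(
    n_cells = cc$n_cells, n_ok = nrow(ok),
    mean_t1_min = mean(ok$t1_min), sem_t1_min = sem(ok$t1_min),
    mean_t2_min = mean(ok$t2_min), sem_t2_min = sem(ok$t2_min),
    mean_t3_min = mean(ok$t3_min), sem_t3_min = sem(ok$t3_min),
    mean_D1_um2_per_s = mean(ok$D1_um2_per_s, na.rm = TRUE),
    mean_pressure_t2_Pa = mean(ok$pressure_t2_Pa, na.rm = TRUE),
    population1_fraction = mean(ok$population == 1L),
    config_hash = config$hash, seed = cc$seed)
  manifest <- list(config_hash = config$hash, seed = cc$seed,
                   n_cells = cc$n_cells, n_ok = nrow(ok),
                   package_version = as.character(
                     utils::packageVersion("netphases")))
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    meta_cols <- function(d) cbind(d, config_hash = config$hash,
                                   seed = cc$seed)
    write.table(meta_cols(cells), file.path(config$out, "phases.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    write_traces_csv(traces[!vapply(traces, is.null, logical(1))],
                     file.path(config$out, "traces.csv"))
    write.table(summary_df, file.path(config$out, "summary.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  log_info(sprintf("  done: %d/%d cells ok; t1 = %.1f, t2 = %.1f, t3 = %.1f min",
                   nrow(ok), cc$n_cells, summary_df$mean_t1_min,
                   summary_df$mean_t2_min, summary_df$mean_t3_min))
  structure(list(cells = cells, summary = summary_df, traces = traces,
                 config = config, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("netphases pipeline result\n")
  cat(sprintf("  %d/%d cells analysed (seed %d, config %s)\n",
              s$n_ok, s$n_cells, s$seed, substr(s$config_hash, 1, 8)))
  cat(sprintf("  t1 = %.1f +/- %.1f, t2 = %.1f +/- %.1f, t3 = %.1f +/- %.1f min (mean +/- SEM)\n",
              s$mean_t1_min, s$sem_t1_min, s$mean_t2_min, s$sem_t2_min,
              s$mean_t3_min, s$sem_t3_min))
  cat(sprintf("  D1 = %.4g um^2/s, pressure at t2 = %.3g Pa, population-1 fraction %.2f\n",
              s$mean_D1_um2_per_s, s$mean_pressure_t2_Pa,
              s$population1_fraction))
  invisible(x)
}
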