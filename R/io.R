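# Movie, table and configuration I/O. Time is minutes-since-stimulation
# at the interface; CSV columns carry unit suffixes.

#' Write and read movies as multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per frame (32-bit float). The sidecar `<path>.json`
#' records `pixel_size`, `frame_interval`, `times`, the seed and the
#' config hash so that movies are self-describing; without it the reader
#' demands explicit calibration.
#'
#' @param stack a `frame_stack`.
#' @param path TIFF path.
#' @param meta optional extra metadata stored in the sidecar.
#' @return `write_movie()` the path, invisibly; `read_movie()` a
#'   `frame_stack`.
#' @export
write_movie <- function(stack, path, meta = list()) {
  stopifnot(inherits(stack, "frame_stack"))
  tiff::writeTIFF(stack$frames, path, bits.per.sample = 32L)
  side <- c(list(pixel_size = stack$pixel_size,
                 frame_interval = stack$frame_interval,
                 times = stack$times,
                 n_frames = length(stack$frames)),
            stack$meta, meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @param pixel_size,frame_interval calibration, required when no sidecar
#'   is present.
#' @export
read_movie <- function(path, pixel_size = NULL, frame_interval = NULL) {
  if (!file.exists(path)) stop("movie not found: ", path)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  sidecar <- paste0(path, ".json")
  meta <- list()
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    pixel_size <- pixel_size %||% side$pixel_size
    frame_interval <- frame_interval %||% side$frame_interval
    times <- side$times
    meta <- side[setdiff(names(side),
                         c("pixel_size", "frame_interval", "times",
                           "n_frames"))]
  } else times <- NULL
  if (is.null(pixel_size) || is.null(frame_interval))
    stop("no sidecar ", sidecar, ": pixel_size and frame_interval must be ",
         "supplied explicitly")
  structure(list(frames = frames,
                 times = times %||%
                   (seq_along(frames) - 1) * frame_interval,
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 meta = meta),
            class = "frame_stack")
}

#' Write and read trace tables as CSV
#'
#' Column names carry unit suffixes (`t_min`, `area_um2`, ...). On
#' reading, rows with non-finite time or area are rejected with a warning
#' giving the count.
#'
#' @param traces a list of `cell_trace` data frames or one combined data
#'   frame with a `cell_id` column.
#' @param path CSV path.
#' @return `write_traces_csv()` the path invisibly; `read_traces_csv()` a
#'   list of `cell_trace`.
#' @export
write_traces_csv <- function(traces, path) {
  if (is.data.frame(traces)) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    cbind(cell_id = attr(tr, "cell_id") %||% NA_integer_,
          as.data.frame(tr))
  })
  write.table(do.call(rbind, rows), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @param frame_interval frame interval (min) attached to each trace.
#' @export
read_traces_csv <- function(path, frame_interval = NULL) {
  if (!file.exists(path)) stop("trace table not found: ", path)
  d <- read.table(path, header = TRUE, sep = ",")
  stopifnot(all(c("cell_id", "t_min", "area_um2") %in% names(d)))
  bad <- !is.finite(d$t_min) | !is.finite(d$area_um2)
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-finite time or area rejected")
    d <- d[!bad, ]
  }
  lapply(split(d, d$cell_id), function(g) {
    tr <- g[order(g$t_min), setdiff(names(g), "cell_id"), drop = FALSE]
    rownames(tr) <- NULL
    attr(tr, "cell_id") <- g$cell_id[1]
    fi <- frame_interval %||% median(diff(tr$t_min))
    attr(tr, "frame_interval") <- fi
    class(tr) <- c("cell_trace", "data.frame")
    tr
  })
}

#' Ground truth and annotation CSV writers
#'
#' @param x a `ground_truth` table or a phase-annotation data frame.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_truth_csv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical JSON serialisation; recorded in every output
#' artifact for provenance.
#'
#' @param config any JSON-serialisable list.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected; values overlay the defaults of
#' [pipeline_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Assemble and validate a pipeline configuration
#'
#' @param cohort named list of [cohort_config()] overrides.
#' @param segmentation named list of [seg_params()] overrides.
#' @param phases named list of [phase_params()] overrides.
#' @param swelling named list of [swelling_params()] overrides.
#' @param out output directory (`NULL`: no files written).
#' @param seed master seed (overrides `cohort$seed`).
#' @param log_level `"quiet"`, `"info"` or `"verbose"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = list(), segmentation = list(),
                            phases = list(), swelling = list(),
                            out = NULL, seed = NULL,
                            log_level = c("info", "quiet", "verbose")) {
  log_level <- match.arg(log_level)
  check_keys <- function(given, fun, what) {
    allowed <- names(formals(fun))
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop("unknown ", what, " config key(s): ", paste(bad, collapse = ", "))
  }
  check_keys(cohort, cohort_config, "cohort")
  check_keys(segmentation, seg_params, "segmentation")
  check_keys(phases, phase_params, "phases")
  check_keys(swelling, swelling_params, "swelling")
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  cfg <- list(cohort = do.call(cohort_config, cohort),
              segmentation = do.call(seg_params, segmentation),
              phases = do.call(phase_params, phases),
              swelling = do.call(swelling_params, swelling),
              out = out, log_level = log_level)
  cfg$hash <- config_hash(cfg[c("cohort", "segmentation", "phases",
                                "swelling")])
  class(cfg) <- "pipeline_config"
  cfg
}
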