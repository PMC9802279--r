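## Readers/writers for the pipeline's on-disk formats, plus the end-to-end
## orchestration (simulate -> render -> extract -> align/correlate ->
## metrics -> spurious) with a rerunnable manifest.

SCHEMA_VERSION <- "1"

#' Write an ethogram to CSV
#'
#' Schema: columns `recording_id`, `event_type`, `onset_s`, `offset_s`
#' (empty for point events); a leading comment line records the schema
#' version and the recording duration.
#'
#' @param e an [ethogram].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ethogram_csv <- function(e, path) {
  stopifnot(inherits(e, "ethogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# matecalcium-ethogram v%s duration_s=%.6f",
                     SCHEMA_VERSION, e$duration_s), con)
  df <- data.frame(recording_id = e$recording_id,
                   event_type = e$events$event_type,
                   onset_s = sprintf("%.6f", e$events$onset_s),
                   offset_s = ifelse(is.na(e$events$offset_s), "",
                                     sprintf("%.6f", e$events$offset_s)))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ethogram from CSV
#'
#' @param path CSV written by [write_ethogram_csv()] (or conforming to its
#'   schema). Unknown event types are a parse error naming the offending
#'   line and the controlled vocabulary.
#' @param duration_s recording duration; taken from the header comment when
#'   present, required otherwise.
#' @return An [ethogram].
#' @export
read_ethogram_csv <- function(path, duration_s = NULL) {
  lines <- readLines(path)
  if (length(lines) && startsWith(lines[1], "#")) {
    m <- regmatches(lines[1], regexec("duration_s=([0-9.eE+-]+)", lines[1]))[[1]]
    if (length(m) == 2) duration_s <- as.numeric(m[2])
  }
  if (is.null(duration_s))
    stop("duration_s not found in header and not supplied")
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c(recording_id = "character",
                                       event_type = "character",
                                       onset_s = "numeric",
                                       offset_s = "numeric"))
  voc <- ethogram_vocabulary()
  known <- c(voc$interval, voc$point)
  bad <- which(!(df$event_type %in% known))
  if (length(bad)) {
    data_line <- bad[1] + sum(startsWith(lines, "#")) + 1L  # header offset
    stop("unknown event_type '", df$event_type[bad[1]], "' at line ",
         data_line, "; valid types: ", paste(known, collapse = ", "))
  }
  rid <- if (nrow(df)) df$recording_id[1] else "rec"
  ethogram(df[, c("event_type", "onset_s", "offset_s")],
           recording_id = rid, duration_s = duration_s)
}

#' Write traces to long-form CSV
#'
#' One row per neuron and time point: `recording_id`, `neuron_id`,
#' `time_s`, `green`, `red`, `activity` (empty when only raw channels are
#' available).
#'
#' @param x a `raw_traces` or `activity_trace` object (or both via `raw`
#'   and `activity` arguments).
#' @param path output path.
#' @param activity optional `activity_trace` matching a `raw_traces` `x`.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(x, path, activity = NULL) {
  if (inherits(x, "activity_trace")) {
    df <- do.call(rbind, lapply(x$neurons, function(nm)
      data.frame(recording_id = x$recording_id, neuron_id = nm,
                 time_s = x$time, green = NA_real_, red = NA_real_,
                 activity = x$activity[nm, ])))
  } else {
    stopifnot(inherits(x, "raw_traces"))
    act <- function(nm, n) {
      if (is.null(activity)) return(rep(NA_real_, n))
      stats::approx(activity$time, activity$activity[nm, ], xout = x$time,
                    rule = 2)$y
    }
    df <- do.call(rbind, lapply(x$neurons, function(nm)
      data.frame(recording_id = x$recording_id, neuron_id = nm,
                 time_s = x$time, green = x$green[nm, ], red = x$red[nm, ],
                 activity = act(nm, length(x$time)))))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read long-form trace CSV back into a `raw_traces` object
#'
#' @param path CSV written by [write_traces_csv()] from a `raw_traces`.
#' @param rate sampling rate of the stored series (samples/s); inferred
#'   from the time column when `NULL`.
#' @return `raw_traces` object.
#' @export
read_traces_csv <- function(path, rate = NULL) {
  df <- utils::read.csv(path, colClasses = c(recording_id = "character",
                                             neuron_id = "character"))
  neurons <- sort(unique(df$neuron_id))
  times <- sort(unique(df$time_s))
  if (is.null(rate)) {
    dt <- stats::median(diff(times))
    rate <- 1 / dt
  }
  g <- matrix(NA_real_, length(neurons), length(times),
              dimnames = list(neurons, NULL))
  r <- g
  for (nm in neurons) {
    sub <- df[df$neuron_id == nm, ]
    sub <- sub[order(sub$time_s), ]
    g[nm, ] <- sub$green
    r[nm, ] <- sub$red
  }
  structure(list(time = times, rate = rate, neurons = neurons,
                 green = g, red = r, camera_offset = 0,
                 recording_id = df$recording_id[1]),
            class = "raw_traces")
}

#' Write a volume series to disk
#'
#' HDF5 when the `rhdf5` package is available: datasets `/green` and
#' `/red` with dimensions (t, z, y, x) and root attributes
#' `pixel_size_um`, `slice_spacing_um`, `volume_rate_hz`. Falls back to an
#' RDS container (same in-memory object) otherwise.
#'
#' @param vol a `volume_series`.
#' @param path output path (`.h5` or `.rds`).
#' @return `path`, invisibly.
#' @export
write_volumes <- function(vol, path) {
  stopifnot(inherits(vol, "volume_series"))
  if (grepl("\\.h5$", path) && requireNamespace("rhdf5", quietly = TRUE)) {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    ## stored as (t, z, y, x): reverse of the in-memory (x, y, z, t)
    perm <- c(4, 3, 2, 1)
    rhdf5::h5write(aperm(vol$green, perm), path, "green")
    rhdf5::h5write(aperm(vol$red, perm), path, "red")
    fid <- rhdf5::H5Fopen(path)
    rhdf5::h5writeAttribute(vol$pixel_size_um, fid, "pixel_size_um")
    rhdf5::h5writeAttribute(vol$slice_spacing_um, fid, "slice_spacing_um")
    rhdf5::h5writeAttribute(vol$volume_rate_hz, fid, "volume_rate_hz")
    rhdf5::h5writeAttribute(vol$recording_id %||% "rec", fid, "recording_id")
    rhdf5::H5Fclose(fid)
  } else {
    saveRDS(vol, path)
  }
  invisible(path)
}

#' Read a volume series written by [write_volumes()]
#'
#' @param path `.h5` (requires `rhdf5`) or `.rds` path.
#' @return `volume_series` object.
#' @export
read_volumes <- function(path) {
  if (grepl("\\.h5$", path)) {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("reading HDF5 volumes requires the rhdf5 package")
    perm <- c(4, 3, 2, 1)
    g <- aperm(rhdf5::h5read(path, "green"), perm)
    r <- aperm(rhdf5::h5read(path, "red"), perm)
    at <- rhdf5::h5readAttributes(path, "/")
    structure(list(green = g, red = r,
                   pixel_size_um = as.numeric(at$pixel_size_um),
                   slice_spacing_um = as.numeric(at$slice_spacing_um),
                   volume_rate_hz = as.numeric(at$volume_rate_hz),
                   recording_id = as.character(at$recording_id %||% "rec")),
              class = "volume_series")
  } else {
    readRDS(path)
  }
}

#' Write an analysis result list as JSON
#'
#' Adds `schema_version` and, when given, the manifest hash tying the
#' output to its run.
#'
#' @param x named list of results.
#' @param path output path.
#' @param manifest_hash optional manifest digest string.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(x, path, manifest_hash = NULL) {
  x <- c(list(schema_version = SCHEMA_VERSION), x)
  if (!is.null(manifest_hash)) x$manifest_hash <- manifest_hash
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

## small deterministic digest: 32-bit polynomial rolling hash over the
## serialized manifest text (exact in doubles, < 2^53)
manifest_hash <- function(manifest) {
  txt <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(txt))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%08x", h)
}

#' Run the full synthetic pipeline
#'
#' Simulates an ethogram and coupled traces, renders two-channel volumes,
#' extracts ROI signals and ratiometric activity, runs the event-triggered
#' and lag-correlation analyses for every coupled neuron, scores mating
#' performance, screens for spurious activation, and writes
#' `metrics.csv`, `correlations.json`, `spurious.json`, and
#' `manifest.json` into `out_dir`. All randomness derives from
#' `config$seed`; rerunning with the same config reproduces the outputs
#' byte-identically.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @param geometry a [volume_geometry()].
#' @param render logical: render and re-extract volumes (default) or
#'   analyze the simulated traces directly.
#' @param analysis_rate analysis sampling rate (samples/s); must divide the
#'   acquisition rate.
#' @param window,max_lag_samples analysis constants.
#' @return Invisible list with the in-memory results bundle.
#' @export
run_pipeline <- function(config, out_dir, geometry = volume_geometry(),
                         render = TRUE, analysis_rate = 5,
                         window = c(-7, 13), max_lag_samples = 5L) {
  stopifnot(inherits(config, "sim_config"))
  if (analysis_rate <= 0 || config$acquisition_rate %% analysis_rate != 0)
    stop("config error: analysis_rate (", analysis_rate,
         ") must divide the acquisition rate (", config$acquisition_rate, ")")
  ds_factor <- as.integer(config$acquisition_rate / analysis_rate)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  etho <- simulate_ethogram(config, seed = config$seed)
  sim <- simulate_traces(etho, config, seed = config$seed + 1L)

  if (render) {
    tracks <- simulate_tracks(sim$traces$neurons, length(sim$traces$time),
                              geometry, seed = config$seed + 2L)
    vols <- render_volumes(sim$traces, tracks, geometry)
    raw <- extract_roi_signals(vols, tracks)
    raw$camera_offset <- config$camera_offset
  } else {
    raw <- sim$traces
  }
  act <- compute_activity_trace(raw, camera_offset = config$camera_offset,
                                factor = ds_factor)

  ## event-triggered analysis per coupled neuron
  correlations <- list()
  for (nm in names(config$neuron_couplings)) {
    motif <- config$neuron_couplings[[nm]]$motif
    voc <- ethogram_vocabulary()
    onsets <- if (motif %in% voc$interval)
      event_intervals(etho, motif)[, 1] else event_onsets(etho, motif)
    res <- tryCatch({
      mat <- align_to_events(act, nm, onsets, window)
      lc <- lag_correlation(mat, etho, motif, max_lag_samples)
      lat <- peak_latency(mat)
      list(neuron = nm, motif = motif, n_instances = lc$n_instances,
           n_animals = 1L, lag_samples = lc$lag_samples,
           mean_r = lc$mean_r, t = lc$t, p_value = lc$p_value,
           median_latency_s = lat$median_s)
    }, error = function(e) list(neuron = nm, motif = motif,
                                error = conditionMessage(e)))
    correlations[[nm]] <- res
  }

  metrics <- mating_metrics(etho)
  calls <- lapply(act$neurons, function(nm)
    detect_pulses(act, nm, etho))
  positive <- classify_male(calls)

  manifest <- list(package = "matecalcium",
                   version = as.character(utils::packageVersion("matecalcium")),
                   schema_version = SCHEMA_VERSION,
                   seed = config$seed,
                   config = config[setdiff(names(config), "neuron_couplings")],
                   neuron_couplings = config$neuron_couplings,
                   render = render, window = window,
                   max_lag_samples = max_lag_samples)
  mh <- manifest_hash(manifest)

  write_ethogram_csv(etho, file.path(out_dir, "ethogram.csv"))
  mdf <- data.frame(recording_id = etho$recording_id,
                    measure = performance_measures(),
                    value = vapply(performance_measures(),
                                   function(m) as.numeric(metrics[[m]]),
                                   numeric(1)))
  utils::write.csv(cbind(mdf, manifest_hash = mh),
                   file.path(out_dir, "metrics.csv"), row.names = FALSE)
  write_results_json(list(correlations = correlations),
                     file.path(out_dir, "correlations.json"),
                     manifest_hash = mh)
  pulse_rows <- do.call(rbind, lapply(calls, function(cl)
    if (nrow(cl$pulses)) cbind(recording_id = cl$recording_id,
                               neuron_id = cl$neuron, cl$pulses) else NULL))
  write_results_json(list(n_positive = as.integer(positive),
                          n_total = 1L,
                          spurious_positive = positive,
                          n_pulses = if (is.null(pulse_rows)) 0L
                                     else nrow(pulse_rows)),
                     file.path(out_dir, "spurious.json"),
                     manifest_hash = mh)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(ethogram = etho, traces = raw, activity = act,
                 truth = sim$truth, correlations = correlations,
                 metrics = metrics, spurious_calls = calls,
                 spurious_positive = positive, manifest_hash = mh))
}
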