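## Signal extraction: tracked two-channel volumes -> smoothed ratiometric
## activity traces at the analysis rate.

#' Extract mean ROI intensities around tracked nuclei
#'
#' For each neuron and volume, averages each channel over the axis-aligned
#' box of voxels whose centers fall within `roi_um` of the nucleus center
#' (2.25 x 2.25 x 3.5 um by default: 5 x 5 lateral pixels x 3 optical slices
#' at the native 0.45 um / 1.75 um geometry; voxel centers lying exactly on
#' the ROI face are included). Boxes are clipped at image borders with a
#' warning.
#'
#' @param volumes a `volume_series` (see [render_volumes()] or
#'   [read_volumes()]).
#' @param tracks nucleus track table (`volume_index`, `neuron_id`, `x_um`,
#'   `y_um`, `z_um`); every neuron must be present at every volume.
#' @param roi_um ROI extent (x, y, z) in micrometers.
#' @return `raw_traces` object at the acquisition rate.
#' @export
extract_roi_signals <- function(volumes, tracks, roi_um = c(2.25, 2.25, 3.5)) {
  stopifnot(inherits(volumes, "volume_series"), length(roi_um) == 3,
            all(roi_um > 0))
  d <- dim(volumes$green)
  n_t <- d[4]
  xs <- (seq_len(d[1]) - 0.5) * volumes$pixel_size_um
  ys <- (seq_len(d[2]) - 0.5) * volumes$pixel_size_um
  zs <- (seq_len(d[3]) - 0.5) * volumes$slice_spacing_um
  half <- roi_um / 2
  tol <- 1e-9

  neurons <- sort(unique(tracks$neuron_id))
  g <- matrix(NA_real_, length(neurons), n_t, dimnames = list(neurons, NULL))
  r <- g
  clipped <- FALSE
  tr <- split(tracks, tracks$neuron_id)
  for (nm in neurons) {
    tn <- tr[[nm]]
    idx <- match(seq_len(n_t), tn$volume_index)
    if (anyNA(idx))
      stop("neuron ", nm, " missing from volume ", which(is.na(idx))[1])
    for (tt in seq_len(n_t)) {
      i <- idx[tt]
      ix <- which(abs(xs - tn$x_um[i]) <= half[1] + tol)
      iy <- which(abs(ys - tn$y_um[i]) <= half[2] + tol)
      iz <- which(abs(zs - tn$z_um[i]) <= half[3] + tol)
      if (!length(ix) || !length(iy) || !length(iz))
        stop("ROI for neuron ", nm, " at volume ", tt,
             " contains no voxels inside the image")
      full <- c(ceiling(roi_um[1] / volumes$pixel_size_um - tol),
                ceiling(roi_um[2] / volumes$pixel_size_um - tol))
      if (length(ix) < full[1] || length(iy) < full[2]) clipped <- TRUE
      g[nm, tt] <- mean(volumes$green[ix, iy, iz, tt])
      r[nm, tt] <- mean(volumes$red[ix, iy, iz, tt])
    }
  }
  if (clipped)
    warning("one or more ROIs clipped at the image border")
  structure(list(time = (0:(n_t - 1)) / volumes$volume_rate_hz,
                 rate = volumes$volume_rate_hz, neurons = neurons,
                 green = g, red = r, camera_offset = 0,
                 recording_id = volumes$recording_id %||% "rec"),
            class = "raw_traces")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## block means over consecutive samples; trailing partial block dropped
block_mean <- function(x, factor) {
  n_out <- length(x) %/% factor
  if (n_out == 0L) stop("series shorter than one block")
  colMeans(matrix(x[seq_len(n_out * factor)], nrow = factor))
}

#' Downsample raw traces by block averaging
#'
#' Non-overlapping block means of `factor` consecutive samples per channel;
#' the trailing partial block is dropped. Block means (not decimation)
#' preserve the photon statistics of the ROI means. Default factor 2 takes
#' the 10 volumes/s acquisition to the 5 samples/s analysis rate.
#'
#' @param raw a `raw_traces` object.
#' @param factor integer >= 1.
#' @return `raw_traces` at rate `raw$rate / factor`.
#' @export
downsample_traces <- function(raw, factor = 2L) {
  stopifnot(inherits(raw, "raw_traces"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be an integer >= 1")
  if (factor == 1L) return(raw)
  g <- t(apply(raw$green, 1, block_mean, factor = factor))
  r <- t(apply(raw$red, 1, block_mean, factor = factor))
  if (nrow(raw$green) == 1L) { g <- matrix(g, 1); r <- matrix(r, 1) }
  dimnames(g) <- dimnames(r) <- list(raw$neurons, NULL)
  structure(list(time = (0:(ncol(g) - 1)) / (raw$rate / factor),
                 rate = raw$rate / factor, neurons = raw$neurons,
                 green = g, red = r, camera_offset = raw$camera_offset,
                 recording_id = raw$recording_id),
            class = "raw_traces")
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing with a centered window. With
#' polynomial order 1 the centered filter reduces to the moving average
#' (uniform weights `1/window`). Boundaries are handled by reflect-padding
#' `(window - 1) / 2` samples at each end, keeping the output the same
#' length as the input.
#'
#' @param x numeric series, length >= `window`.
#' @param window odd window length (frames); default 13.
#' @param order polynomial order, `< window`; default 1.
#' @return Smoothed numeric series, same length as `x`.
#' @export
savitzky_golay <- function(x, window = 13L, order = 1L) {
  window <- as.integer(window); order <- as.integer(order)
  if (window %% 2L == 0L || window < 1L) stop("window must be odd and positive")
  if (order < 0L || order >= window) stop("order must satisfy 0 <= order < window")
  if (length(x) < window)
    stop("series length (", length(x), ") shorter than window (", window, ")")
  h <- (window - 1L) %/% 2L
  ## filter weights: first row of the least-squares hat matrix at the center
  A <- outer(-h:h, 0:order, `^`)
  w <- A %*% solve(crossprod(A), c(1, rep(0, order)))
  xp <- c(x[(h + 1L):2L], x, x[(length(x) - 1L):(length(x) - h)])  # reflect
  out <- stats::filter(xp, rev(w), method = "convolution", sides = 2)
  as.numeric(out[(h + 1L):(h + length(x))])
}

#' Ratiometric activity traces
#'
#' The activity signal is the smoothed, offset-corrected green/red ratio at
#' the analysis rate: the ratio `(G - offset) / (R - offset)` is computed
#' per sample at the acquisition rate, downsampled by block means to the
#' analysis rate, and smoothed with a Savitzky-Golay filter (order 1, frame
#' length 13 by default). Taking the ratio before any averaging makes the
#' cancellation of the multiplicative motion artifact shared by both
#' channels algebraically exact; averaging the channels first would leave a
#' residual wherever the artifact varies within a block.
#'
#' @param raw a `raw_traces` object at the acquisition rate.
#' @param camera_offset scalar camera offset subtracted from both channels
#'   (defaults to the offset recorded in `raw`).
#' @param window,order Savitzky-Golay parameters.
#' @param factor downsampling factor (acquisition rate -> analysis rate).
#' @return `activity_trace` object: matrix `activity` (neurons x time) at
#'   `raw$rate / factor` samples/s with a `provenance` record of the
#'   parameters used.
#' @export
compute_activity_trace <- function(raw, camera_offset = raw$camera_offset,
                                   window = 13L, order = 1L, factor = 2L) {
  stopifnot(inherits(raw, "raw_traces"))
  g <- raw$green - camera_offset
  r <- raw$red - camera_offset
  bad <- which(r <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive red signal after offset subtraction for neuron ",
         raw$neurons[bad[1, 1]], " at t = ",
         format(raw$time[bad[1, 2]], digits = 4),
         " s (tracking or offset failure)")
  ratio <- g / r
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be an integer >= 1")
  ds <- if (factor > 1L) {
    out <- t(apply(ratio, 1, block_mean, factor = factor))
    if (nrow(ratio) == 1L) out <- matrix(out, 1)
    out
  } else ratio
  act <- t(apply(ds, 1, savitzky_golay, window = window, order = order))
  if (nrow(ds) == 1L) act <- matrix(act, 1)
  dimnames(act) <- list(raw$neurons, NULL)
  rate <- raw$rate / factor
  structure(list(time = (0:(ncol(act) - 1)) / rate, rate = rate,
                 neurons = raw$neurons, activity = act,
                 provenance = list(camera_offset = camera_offset,
                                   sg_window = as.integer(window),
                                   sg_order = as.integer(order),
                                   downsample_factor = factor,
                                   order_of_operations = "ratio,downsample,smooth"),
                 recording_id = raw$recording_id),
            class = "activity_trace")
}
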