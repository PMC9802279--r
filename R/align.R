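## Event-triggered response analysis: aligned windows, averaged normalized
## curves, lagged cross-correlation against binarized behavior, and peak
## latencies.

window_grid <- function(window, rate) {
  off <- seq.int(round(window[1] * rate), round(window[2] * rate))
  off / rate
}

#' Align a neuron's activity to behavioral event onsets
#'
#' Cuts one window per onset, spanning `window[1]` to `window[2]` seconds
#' around it (default -7 s to +13 s; 101 samples at 5 samples/s), with the
#' onset snapped to the nearest trace sample (window time 0). Onsets whose
#' full window does not fit inside the recording are excluded and counted.
#'
#' @param trace an `activity_trace` (see [compute_activity_trace()]).
#' @param neuron neuron id (a row of the trace).
#' @param onsets event onset times, seconds.
#' @param window two-element window in seconds relative to onset.
#' @return `aligned_matrix`: instance-by-time matrix `rows`, window `times`,
#'   per-row onset metadata, and the exclusion count. Errors when no usable
#'   instance remains.
#' @export
align_to_events <- function(trace, neuron, onsets, window = c(-7, 13)) {
  stopifnot(inherits(trace, "activity_trace"), length(window) == 2,
            window[1] < window[2])
  if (!(neuron %in% trace$neurons)) stop("unknown neuron: ", neuron)
  x <- trace$activity[neuron, ]
  rate <- trace$rate
  offs <- seq.int(round(window[1] * rate), round(window[2] * rate))
  idx0 <- as.integer(round(onsets * rate)) + 1L  # nearest-sample snapping
  ok <- idx0 + offs[1] >= 1L & idx0 + offs[length(offs)] <= length(x)
  n_excl <- sum(!ok)
  if (!any(ok))
    stop("no event instance has a complete [", window[1], ", ", window[2],
         "] s window inside the recording")
  idx0 <- idx0[ok]
  rows <- t(vapply(idx0, function(i) x[i + offs], numeric(length(offs))))
  structure(list(neuron = neuron, rows = rows, times = offs / rate,
                 rate = rate, window = window,
                 onsets = onsets[ok], n_excluded = n_excl,
                 recording_id = trace$recording_id),
            class = "aligned_matrix")
}

#' Thin event onsets to a minimum spacing
#'
#' Greedy left-to-right selection keeping only onsets at least
#' `min_spacing_s` after the previously kept one. Peri-event windows built
#' from thinned onsets do not overlap in time, so their noise is
#' independent across instances -- a prerequisite for the nominal level of
#' the across-instance t-test (overlapping windows share noise and inflate
#' it).
#'
#' @param onsets event times, seconds (sorted internally).
#' @param min_spacing_s minimum spacing; use the window length (default
#'   20 s) for fully non-overlapping windows.
#' @return Subset of `onsets`.
#' @export
thin_onsets <- function(onsets, min_spacing_s = 20) {
  onsets <- sort(onsets)
  keep <- logical(length(onsets))
  last <- -Inf
  for (i in seq_along(onsets)) {
    if (onsets[i] - last >= min_spacing_s) { keep[i] <- TRUE; last <- onsets[i] }
  }
  onsets[keep]
}

#' Dataset-averaged, min-max-normalized response curve
#'
#' Pools the aligned instances of one neuron/motif across animals, averages
#' them sample-by-sample, and normalizes the average to minimum 0 and
#' maximum 1. The per-sample standard deviation (the gray band) is computed
#' before normalization and rescaled by the same affine map. A constant
#' average cannot be normalized: the curve is returned as all zeros with
#' `constant = TRUE` and a warning.
#'
#' @param matrices list of `aligned_matrix` objects (typically one per
#'   animal) on identical window grids.
#' @return `response_curve`: `times`, normalized `curve`, rescaled `sd`,
#'   `n_instances`, `n_animals`, flag `constant`.
#' @export
average_response <- function(matrices) {
  if (inherits(matrices, "aligned_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, inherits, logical(1), "aligned_matrix")))
  times <- matrices[[1]]$times
  for (m in matrices)
    if (!isTRUE(all.equal(m$times, times)))
      stop("aligned matrices are on different window grids")
  rows <- do.call(rbind, lapply(matrices, `[[`, "rows"))
  avg <- colMeans(rows)
  sdev <- apply(rows, 2, stats::sd)
  rng <- range(avg)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[1]))) {
    warning("dataset average is constant; returning an all-zero curve")
    curve <- numeric(length(avg)); sds <- numeric(length(avg)); const <- TRUE
  } else {
    curve <- (avg - rng[1]) / diff(rng)
    sds <- sdev / diff(rng)
    const <- FALSE
  }
  structure(list(times = times, curve = curve, sd = sds,
                 n_instances = nrow(rows), n_animals = length(matrices),
                 constant = const),
            class = "response_curve")
}

## binarized behavior row on an instance's window grid: indicator over the
## motif's intervals for interval motifs, unit impulse at each onset sample
## for point motifs
behavior_row <- function(etho, motif, onset, times, rate) {
  voc <- ethogram_vocabulary()
  abs_t <- onset + times
  b <- numeric(length(times))
  if (motif %in% voc$interval) {
    iv <- event_intervals(etho, motif)
    if (nrow(iv))
      for (i in seq_len(nrow(iv)))
        b[abs_t >= iv[i, 1] - 1e-9 & abs_t < iv[i, 2] - 1e-9] <- 1
  } else if (motif %in% voc$point) {
    ons <- event_onsets(etho, motif)
    snap <- round((ons - onset) * rate) / rate
    b[vapply(times, function(tc) any(abs(snap - tc) < 1e-9), logical(1))] <- 1
  } else stop("unknown motif: ", motif)
  b
}

shifted_cor <- function(a, b, lag) {
  n <- length(a)
  if (lag >= 0) { ai <- (1 + lag):n; bi <- 1:(n - lag) }
  else { ai <- 1:(n + lag); bi <- (1 - lag):n }
  if (length(ai) < 3) return(NA_real_)
  av <- a[ai]; bv <- b[bi]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(NA_real_)
  stats::cor(av, bv)
}

#' Lagged cross-correlation between activity and binarized behavior
#'
#' For every lag in `-max_lag_samples` to `+max_lag_samples` (default 5
#' samples = 1 s at 5 samples/s), computes the per-instance Pearson
#' correlation between each aligned activity row and the instance's
#' binarized behavior row shifted by that lag (overlapping support only).
#' The selected lag maximizes the absolute mean correlation across
#' instances; a one-sample t-test then asks whether the mean correlation at
#' that lag is greater than zero (one-sided). Positive lag means neural
#' activity follows behavior.
#'
#' Instances whose behavior row is constant within the window carry no
#' correlation and are dropped (counted in `n_dropped`); if all instances
#' drop, this is an error.
#'
#' @param mat `aligned_matrix` for one neuron and motif.
#' @param etho the [ethogram] the onsets came from.
#' @param motif motif name (vocabulary of [ethogram_vocabulary()]).
#' @param max_lag_samples maximum absolute lag in samples.
#' @return `lag_correlation`: selected `lag_samples` and `lag_s`,
#'   per-instance correlations at that lag, their `mean_r`, `t`, `df`,
#'   one-sided `p_value`, `n_instances`, `n_dropped`, and the full
#'   lag-by-mean-correlation table.
#' @export
lag_correlation <- function(mat, etho, motif, max_lag_samples = 5L) {
  stopifnot(inherits(mat, "aligned_matrix"), inherits(etho, "ethogram"))
  lags <- seq.int(-max_lag_samples, max_lag_samples)
  n_inst <- nrow(mat$rows)
  brows <- t(vapply(mat$onsets, behavior_row, numeric(length(mat$times)),
                    etho = etho, motif = motif, times = mat$times,
                    rate = mat$rate))
  if (n_inst == 1L) brows <- matrix(brows, 1)
  keep <- apply(brows, 1, function(b) stats::sd(b) > 0)
  n_dropped <- sum(!keep)
  if (!any(keep))
    stop("behavior row constant in every instance window; no correlation defined")
  arows <- mat$rows[keep, , drop = FALSE]
  brows <- brows[keep, , drop = FALSE]

  cors <- matrix(NA_real_, nrow(arows), length(lags))
  for (j in seq_along(lags))
    cors[, j] <- vapply(seq_len(nrow(arows)), function(i)
      shifted_cor(arows[i, ], brows[i, ], lags[j]), numeric(1))
  mean_r <- colMeans(cors, na.rm = TRUE)
  ## exhaustive selection over the 11 lags; ties resolved toward lag 0
  ord <- order(-abs(mean_r), abs(lags), lags)
  best <- ord[1]
  r_best <- cors[, best]
  r_best <- r_best[!is.na(r_best)]
  n <- length(r_best)
  if (n >= 2 && stats::sd(r_best) > 0) {
    tstat <- mean(r_best) / (stats::sd(r_best) / sqrt(n))
    p <- stats::pt(tstat, df = n - 1, lower.tail = FALSE)
  } else {
    tstat <- NA_real_
    p <- NA_real_
  }
  structure(list(neuron = mat$neuron, motif = motif,
                 lag_samples = lags[best], lag_s = lags[best] / mat$rate,
                 lag_convention = "positive = activity follows behavior",
                 correlations = r_best, mean_r = mean(r_best),
                 t = tstat, df = n - 1, p_value = p,
                 n_instances = n, n_dropped = n_dropped,
                 lag_table = data.frame(lag_samples = lags, mean_r = mean_r)),
            class = "lag_correlation")
}

#' Per-instance peak latencies of event-aligned activity
#'
#' For each aligned instance, the time (relative to the event onset) of the
#' maximum activity sample within the search range; ties break toward the
#' earliest sample. Summarized by the median across instances.
#'
#' @param mat an `aligned_matrix`.
#' @param search two-element search range in window seconds.
#' @param group optional group label carried into comparisons.
#' @return `latency_summary`: `peak_times_s`, `median_s`, `n`, `group`,
#'   and a `constant_rows` count (constant rows peak at the search start by
#'   the tie rule).
#' @export
peak_latency <- function(mat, search = c(-7, 13), group = NA_character_) {
  stopifnot(inherits(mat, "aligned_matrix"))
  sel <- mat$times >= search[1] - 1e-9 & mat$times <= search[2] + 1e-9
  if (!any(sel)) stop("search range contains no window samples")
  ts <- mat$times[sel]
  rows <- mat$rows[, sel, drop = FALSE]
  peaks <- apply(rows, 1, function(r) ts[which.max(r)])
  n_const <- sum(apply(rows, 1, function(r) diff(range(r)) == 0))
  structure(list(peak_times_s = unname(peaks),
                 median_s = stats::median(peaks),
                 n = length(peaks), group = group,
                 constant_rows = n_const),
            class = "latency_summary")
}

#' Compare peak latencies between two groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test on per-instance peak
#' times, e.g. successful vs failed turns. Exact p for small untied
#' samples, normal approximation with tie correction otherwise.
#'
#' @param a,b `latency_summary` objects.
#' @return List with `statistic` (W), `p_value`, per-group medians and
#'   sizes.
#' @export
compare_latencies <- function(a, b) {
  stopifnot(inherits(a, "latency_summary"), inherits(b, "latency_summary"))
  if (!a$n || !b$n) stop("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(a$peak_times_s, b$peak_times_s,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = unname(wt$p.value),
       median_a = a$median_s, median_b = b$median_s,
       n_a = a$n, n_b = b$n,
       group_a = a$group, group_b = b$group)
}
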