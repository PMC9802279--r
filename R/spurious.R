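## Screening for spurious activation of the vulva-detecting circuit:
## threshold pulses on per-recording min-max-normalized activity, away from
## (dilated) vulva-contact intervals.

## merge overlapping/adjacent intervals (two-column matrix, sorted output)
merge_intervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    } else out <- rbind(out, iv[i, , drop = FALSE])
  }
  out
}

## set difference a \ b on interval matrices
subtract_intervals <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(a)
  b <- merge_intervals(b)
  pieces <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(a))) {
    segs <- matrix(a[i, ], ncol = 2)
    for (j in seq_len(nrow(b))) {
      nxt <- matrix(numeric(0), ncol = 2)
      for (k in seq_len(nrow(segs))) {
        s <- segs[k, 1]; e <- segs[k, 2]
        bs <- b[j, 1]; be <- b[j, 2]
        if (be <= s || bs >= e) { nxt <- rbind(nxt, c(s, e)); next }
        if (bs > s) nxt <- rbind(nxt, c(s, bs))
        if (be < e) nxt <- rbind(nxt, c(be, e))
      }
      segs <- nxt
      if (!nrow(segs)) break
    }
    if (nrow(segs)) pieces <- rbind(pieces, segs)
  }
  pieces
}

#' Detect spurious activation pulses in one neuron's trace
#'
#' Operationalizes the visual screen for vulva-circuit activation away from
#' the vulva. The trace is min-max normalized per recording; pulses are
#' maximal runs with normalized activity above `threshold` lasting at least
#' `min_duration_s`, intersected with the complement of the vulva-contact
#' intervals dilated by `guard_s` on each side. Runs partially overlapping
#' the dilated intervals are truncated and kept only if the remainder still
#' meets `min_duration_s`.
#'
#' @param trace an `activity_trace`.
#' @param neuron neuron id.
#' @param vulva_intervals two-column matrix (onset, offset) of vulva-contact
#'   intervals in seconds, or an [ethogram] to take them from.
#' @param threshold detection threshold on the normalized \[0, 1\] scale.
#' @param min_duration_s minimum pulse duration, seconds.
#' @param guard_s dilation of vulva-contact intervals, seconds.
#' @return `spurious_call`: data.frame `pulses` (`onset_s`, `offset_s`,
#'   `peak`), the detector parameters, neuron and recording ids. A constant
#'   trace yields zero pulses with a warning (degenerate normalization).
#' @export
detect_pulses <- function(trace, neuron, vulva_intervals,
                          threshold = 0.5, min_duration_s = 1.0,
                          guard_s = 2.0) {
  stopifnot(inherits(trace, "activity_trace"))
  if (!(neuron %in% trace$neurons)) stop("unknown neuron: ", neuron)
  if (inherits(vulva_intervals, "ethogram"))
    vulva_intervals <- event_intervals(vulva_intervals, "vulva_contact")
  x <- trace$activity[neuron, ]
  rate <- trace$rate
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      peak = numeric(0))
  params <- list(threshold = threshold, min_duration_s = min_duration_s,
                 guard_s = guard_s)
  mk <- function(p) structure(list(recording_id = trace$recording_id,
                                   neuron = neuron, pulses = p,
                                   params = params),
                              class = "spurious_call")
  rng <- range(x)
  if (diff(rng) == 0) {
    warning("constant trace for neuron ", neuron,
            ": normalization degenerate, no pulses called")
    return(mk(empty))
  }
  z <- (x - rng[1]) / diff(rng)
  above <- z > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind((starts[r$values] - 1) / rate, ends[r$values] / rate)
  if (!nrow(runs)) return(mk(empty))
  runs <- runs[runs[, 2] - runs[, 1] >= min_duration_s - 1e-9, , drop = FALSE]
  if (!nrow(runs)) return(mk(empty))

  guard <- if (nrow(vulva_intervals))
    cbind(vulva_intervals[, 1] - guard_s, vulva_intervals[, 2] + guard_s)
  else matrix(numeric(0), ncol = 2)
  pieces <- subtract_intervals(runs, guard)
  if (nrow(pieces))
    pieces <- pieces[pieces[, 2] - pieces[, 1] >= min_duration_s - 1e-9, ,
                     drop = FALSE]
  if (!nrow(pieces)) return(mk(empty))
  pieces <- pieces[order(pieces[, 1]), , drop = FALSE]
  peak <- vapply(seq_len(nrow(pieces)), function(i) {
    sel <- trace$time >= pieces[i, 1] - 1e-9 & trace$time < pieces[i, 2] - 1e-9
    if (!any(sel)) NA_real_ else max(z[sel])
  }, numeric(1))
  mk(data.frame(onset_s = pieces[, 1], offset_s = pieces[, 2], peak = peak))
}

#' Classify a male as spurious-positive
#'
#' A male is positive iff at least one pulse was detected in any neuron of
#' the designated vulva-detecting circuit.
#'
#' @param calls list of `spurious_call` objects for one recording.
#' @param circuit_neurons neurons counted toward the classification.
#' @return Logical scalar.
#' @export
classify_male <- function(calls,
                          circuit_neurons = c("PCB", "PCC", "HOA", "HOB", "R2B")) {
  if (inherits(calls, "spurious_call")) calls <- list(calls)
  any(vapply(calls, function(cl)
    cl$neuron %in% circuit_neurons && nrow(cl$pulses) >= 1L, logical(1)))
}

#' Fraction of spurious-positive males in a cohort
#'
#' @param labels logical vector, one per male (from [classify_male()]).
#' @return List `n_positive`, `n_total`, `percent` (integer,
#'   `floor(100 * n_positive / n_total)`).
#' @export
cohort_spurious_fraction <- function(labels) {
  if (!length(labels)) stop("empty cohort")
  stopifnot(is.logical(labels))
  n <- length(labels)
  list(n_positive = sum(labels), n_total = n,
       percent = as.integer(floor(100 * sum(labels) / n)))
}
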