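## Controlled vocabulary for behavioral events.  Interval events carry both
## onset and offset; point events carry onset only (offset is NA).

#' Behavioral event vocabulary
#'
#' Interval events span `[onset_s, offset_s)`; point events are instantaneous
#' (`offset_s` is `NA`). All timestamps are seconds from recording start.
#'
#' @return Named list with character vectors `interval` and `point`.
#' @export
ethogram_vocabulary <- function() {
  list(
    interval = c("ventral_contact", "vulva_contact", "pause_away_from_vulva",
                 "backward_slide", "forward_slide"),
    point = c("turn_success", "turn_fail", "slide_over", "loss_of_contact",
              "vulva_pass", "spicule_insertion", "ejaculation")
  )
}

#' Construct an ethogram
#'
#' An ethogram is the timestamped inventory of one male's behavioral events
#' during a single mating recording: interval events (ventral contact, vulva
#' contact, backward/forward sliding, pauses away from the vulva) and point
#' events (turn outcomes, vulva passes, slide-overs, contact losses, spicule
#' insertion, ejaculation).
#'
#' @param events data.frame with columns `event_type`, `onset_s`, `offset_s`
#'   (`NA` for point events).
#' @param recording_id character scalar identifying the recording.
#' @param duration_s recording duration in seconds.
#' @return Object of class `ethogram`: a list with `recording_id`,
#'   `duration_s`, and the `events` data.frame sorted by onset.
#' @export
ethogram <- function(events, recording_id = "rec", duration_s) {
  stopifnot(is.data.frame(events),
            all(c("event_type", "onset_s", "offset_s") %in% names(events)))
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("duration_s must be a positive scalar")
  voc <- ethogram_vocabulary()
  known <- c(voc$interval, voc$point)
  bad <- setdiff(unique(as.character(events$event_type)), known)
  if (length(bad))
    stop("unknown event_type(s): ", paste(bad, collapse = ", "),
         "; valid types are: ", paste(known, collapse = ", "))
  events$event_type <- as.character(events$event_type)
  events$onset_s <- as.numeric(events$onset_s)
  events$offset_s <- as.numeric(events$offset_s)
  events <- events[order(events$onset_s, events$event_type), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(recording_id = as.character(recording_id),
                 duration_s = as.numeric(duration_s),
                 events = events),
            class = "ethogram")
}

#' @export
print.ethogram <- function(x, ...) {
  cat(sprintf("<ethogram> %s: %.1f s, %d events (%d interval, %d point)\n",
              x$recording_id, x$duration_s, nrow(x$events),
              sum(!is.na(x$events$offset_s)), sum(is.na(x$events$offset_s))))
  invisible(x)
}

## intervals of one type, as a two-column matrix (onset, offset)
event_intervals <- function(e, type) {
  ev <- e$events[e$events$event_type == type & !is.na(e$events$offset_s), ,
                 drop = FALSE]
  cbind(onset = ev$onset_s, offset = ev$offset_s)
}

## onsets of one point-event type
event_onsets <- function(e, type) {
  e$events$onset_s[e$events$event_type == type]
}

total_duration <- function(iv) if (nrow(iv)) sum(iv[, 2] - iv[, 1]) else 0

## is every [a1,a2) interval contained in some [b1,b2) interval?
intervals_nested <- function(inner, outer) {
  if (!nrow(inner)) return(rep(TRUE, 0L))
  vapply(seq_len(nrow(inner)), function(i) {
    any(outer[, 1] <= inner[i, 1] + 1e-9 & inner[i, 2] <= outer[, 2] + 1e-9)
  }, logical(1))
}

#' Validate an ethogram against its structural invariants
#'
#' Checks: interval bounds inside `[0, duration]` with onset < offset;
#' same-type intervals non-overlapping; vulva-contact intervals nested in
#' ventral-contact intervals; at most one ejaculation; point events inside
#' the recording.
#'
#' @param e an [ethogram].
#' @return List with logical `valid` and character vector `violations`
#'   (empty when valid).
#' @export
validate_ethogram <- function(e) {
  stopifnot(inherits(e, "ethogram"))
  v <- character(0)
  voc <- ethogram_vocabulary()
  ev <- e$events
  iv <- ev[ev$event_type %in% voc$interval, , drop = FALSE]
  pt <- ev[ev$event_type %in% voc$point, , drop = FALSE]

  if (nrow(iv)) {
    bad <- is.na(iv$offset_s) | !(iv$onset_s >= 0 & iv$onset_s < iv$offset_s &
                                    iv$offset_s <= e$duration_s + 1e-9)
    if (any(bad))
      v <- c(v, sprintf("interval event '%s' at %.3f s violates 0 <= onset < offset <= duration",
                        iv$event_type[bad], iv$onset_s[bad]))
  }
  if (nrow(pt)) {
    bad <- pt$onset_s < 0 | pt$onset_s > e$duration_s + 1e-9
    if (any(bad))
      v <- c(v, sprintf("point event '%s' at %.3f s outside [0, duration]",
                        pt$event_type[bad], pt$onset_s[bad]))
    if (any(!is.na(pt$offset_s)))
      v <- c(v, sprintf("point event '%s' carries an offset",
                        pt$event_type[!is.na(pt$offset_s)]))
  }
  for (ty in voc$interval) {
    m <- event_intervals(e, ty)
    if (nrow(m) > 1L) {
      m <- m[order(m[, 1]), , drop = FALSE]
      if (any(m[-1, 1] < m[-nrow(m), 2] - 1e-9))
        v <- c(v, sprintf("overlapping '%s' intervals", ty))
    }
  }
  vul <- event_intervals(e, "vulva_contact")
  ven <- event_intervals(e, "ventral_contact")
  if (nrow(vul)) {
    nested <- intervals_nested(vul, ven)
    if (any(!nested))
      v <- c(v, sprintf("vulva_contact [%.3f, %.3f] outside ventral contact",
                        vul[!nested, 1], vul[!nested, 2]))
  }
  n_ej <- length(event_onsets(e, "ejaculation"))
  if (n_ej > 1L) v <- c(v, sprintf("%d ejaculation events (at most 1 allowed)", n_ej))

  list(valid = length(v) == 0L, violations = v)
}

#' Mating-performance measures for one male
#'
#' Computes the eight per-male performance measures scored from a mating
#' ethogram, plus the mating success index:
#' \describe{
#'   \item{turning_success_rate}{successful turns / total turn attempts}
#'   \item{ejaculations_per_ventral_min}{ejaculation events per minute of
#'     ventral contact}
#'   \item{ejaculations_per_vulva_min}{ejaculation events per minute of vulva
#'     contact}
#'   \item{spurious_pause_ratio}{total pause-away-from-vulva duration /
#'     total vulva-contact duration}
#'   \item{vulva_passes_per_ventral_min}{vulva-pass events per minute of
#'     ventral contact}
#'   \item{mean_vulva_contact_s}{mean vulva-contact interval length (s)}
#'   \item{slide_over_per_ventral_min}{slide-over events per minute of
#'     ventral contact}
#'   \item{contact_loss_per_ventral_min}{contact-loss events per minute of
#'     ventral contact}
#'   \item{mating_success_index}{ejaculation events per minute of courtship;
#'     courtship runs from the first ventral-contact onset to the
#'     ejaculation, or to the recording end when no ejaculation occurred}
#' }
#' Measures whose denominator is zero are reported as `NA` (undefined), which
#' is distinct from 0.
#'
#' @param e a valid [ethogram]; validated internally and refused when invalid.
#' @return Named list of class `mating_performance` (numeric scalars, `NA`
#'   when undefined).
#' @export
mating_metrics <- function(e) {
  chk <- validate_ethogram(e)
  if (!chk$valid)
    stop("invalid ethogram: ", paste(chk$violations, collapse = "; "))

  ven_min <- total_duration(event_intervals(e, "ventral_contact")) / 60
  vul <- event_intervals(e, "vulva_contact")
  vul_min <- total_duration(vul) / 60
  pause_s <- total_duration(event_intervals(e, "pause_away_from_vulva"))
  n_succ <- length(event_onsets(e, "turn_success"))
  n_fail <- length(event_onsets(e, "turn_fail"))
  n_ej <- length(event_onsets(e, "ejaculation"))

  rate <- function(num, den_min) if (den_min > 0) num / den_min else NA_real_

  ven <- event_intervals(e, "ventral_contact")
  courtship_min <- if (nrow(ven)) {
    t0 <- min(ven[, 1])
    t1 <- if (n_ej) event_onsets(e, "ejaculation")[1] else e$duration_s
    (t1 - t0) / 60
  } else NA_real_

  structure(list(
    turning_success_rate = if (n_succ + n_fail > 0) n_succ / (n_succ + n_fail) else NA_real_,
    ejaculations_per_ventral_min = rate(n_ej, ven_min),
    ejaculations_per_vulva_min = rate(n_ej, vul_min),
    spurious_pause_ratio = if (vul_min > 0) pause_s / (vul_min * 60) else NA_real_,
    vulva_passes_per_ventral_min = rate(length(event_onsets(e, "vulva_pass")), ven_min),
    mean_vulva_contact_s = if (nrow(vul)) mean(vul[, 2] - vul[, 1]) else NA_real_,
    slide_over_per_ventral_min = rate(length(event_onsets(e, "slide_over")), ven_min),
    contact_loss_per_ventral_min = rate(length(event_onsets(e, "loss_of_contact")), ven_min),
    mating_success_index = if (!is.na(courtship_min) && courtship_min > 0)
      n_ej / courtship_min else NA_real_,
    n_turn_attempts = n_succ + n_fail,
    n_ejaculations = n_ej
  ), class = "mating_performance")
}

#' Measure names accepted by [compare_cohorts()]
#' @return Character vector of valid measure names.
#' @export
performance_measures <- function() {
  c("turning_success_rate", "ejaculations_per_ventral_min",
    "ejaculations_per_vulva_min", "spurious_pause_ratio",
    "vulva_passes_per_ventral_min", "mean_vulva_contact_s",
    "slide_over_per_ventral_min", "contact_loss_per_ventral_min",
    "mating_success_index")
}

#' Fraction of males in a cohort that mated successfully
#'
#' A male is scored successful iff his ethogram contains at least one
#' ejaculation event. The percentage is the floor of `100 * n_success /
#' n_total`, matching the integer percentages reported for cohort counts.
#'
#' @param cohort list of [ethogram] objects.
#' @return List `n_success`, `n_total`, `percent` (integer).
#' @export
cohort_success_percent <- function(cohort) {
  if (!length(cohort)) stop("empty cohort")
  ok <- vapply(cohort, function(e) length(event_onsets(e, "ejaculation")) >= 1L,
               logical(1))
  n <- length(ok)
  list(n_success = sum(ok), n_total = n,
       percent = as.integer(floor(100 * sum(ok) / n)))
}

#' Compare one performance measure between two cohorts
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test on a per-male measure.
#' Undefined (`NA`) values are dropped per cohort and their counts reported;
#' they are never imputed as 0. Exact p-values for small samples without
#' ties, normal approximation with continuity and tie correction otherwise
#' (the `stats::wilcox.test` policy).
#'
#' @param a,b lists of `mating_performance` objects (from [mating_metrics()]).
#' @param measure one of [performance_measures()].
#' @return List with `measure`, `p_value`, `statistic` (W), medians, group
#'   sizes after NA removal, and NA counts.
#' @export
compare_cohorts <- function(a, b, measure) {
  valid <- performance_measures()
  if (!is.character(measure) || length(measure) != 1L || !(measure %in% valid))
    stop("unknown measure '", measure, "'; valid measures: ",
         paste(valid, collapse = ", "))
  if (!length(a) || !length(b)) stop("both cohorts must be non-empty")
  xa <- vapply(a, function(m) as.numeric(m[[measure]]), numeric(1))
  xb <- vapply(b, function(m) as.numeric(m[[measure]]), numeric(1))
  na_a <- sum(is.na(xa)); na_b <- sum(is.na(xb))
  xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
  if (!length(xa) || !length(xb))
    stop("all values undefined in one cohort for measure '", measure, "'")
  wt <- suppressWarnings(stats::wilcox.test(xa, xb, alternative = "two.sided"))
  list(measure = measure,
       p_value = unname(wt$p.value),
       statistic = unname(wt$statistic),
       median_a = stats::median(xa), median_b = stats::median(xb),
       n_a = length(xa), n_b = length(xb),
       n_undefined_a = na_a, n_undefined_b = na_b)
}
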