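## Shared fixtures: tiny hand-built ethograms and simulator configs used
## across the module tests. Everything is generated in code.

## minimal hand-written ethogram: one contact episode with a nested vulva
## contact, 2 successful + 1 failed turn, one ejaculation at 49 s
fixture_ethogram <- function(duration = 120) {
  ev <- data.frame(
    event_type = c("ventral_contact", "vulva_contact", "turn_success",
                   "turn_success", "turn_fail", "ejaculation"),
    onset_s = c(0, 40, 10, 20, 30, 49),
    offset_s = c(120, 50, NA, NA, NA, NA))
  ethogram(ev, recording_id = "fix", duration_s = duration)
}

## single-neuron config for trace-level tests
fixture_config <- function(..., duration = 300, seed = 1L) {
  sim_config(recording_duration = duration,
             neuron_couplings = list(N1 = list(motif = "backward_slide",
                                               gain = 0.5, latency = 0.4)),
             spurious_neurons = character(0),
             ejaculation_prob_per_vulva_contact = 0,
             seed = seed, ...)
}

## wrap a plain matrix (instances x samples) as an aligned_matrix on the
## standard -7..+13 s grid, for unit tests of the downstream operations
as_aligned <- function(rows, rate = 5, window = c(-7, 13),
                       onsets = NULL, neuron = "N1") {
  times <- seq(window[1] * rate, window[2] * rate) / rate
  stopifnot(ncol(rows) == length(times))
  if (is.null(onsets)) onsets <- seq_len(nrow(rows)) * 30
  structure(list(neuron = neuron, rows = rows, times = times, rate = rate,
                 window = window, onsets = onsets, n_excluded = 0L,
                 recording_id = "fix"),
            class = "aligned_matrix")
}

## wrap an activity matrix as an activity_trace
as_activity <- function(mat, rate = 5, neurons = rownames(mat)) {
  if (is.null(neurons)) neurons <- paste0("N", seq_len(nrow(mat)))
  dimnames(mat) <- list(neurons, NULL)
  structure(list(time = (0:(ncol(mat) - 1)) / rate, rate = rate,
                 neurons = neurons, activity = mat,
                 provenance = list(), recording_id = "fix"),
            class = "activity_trace")
}

## exact two-sided rank-sum p-value by enumeration of all assignments
## (independent oracle for the Wilcoxon comparisons)
ranksum_exact_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)])
  combs <- utils::combn(n + m, n)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n * (n + m + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
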