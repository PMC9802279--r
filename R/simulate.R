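## Synthetic mating recordings: semi-Markov ethograms, kernel-coupled neural
## activity, two-channel emissions with a shared multiplicative motion
## artifact, and rendered two-channel volumes -- all with full ground truth.

#' Simulation configuration
#'
#' Parameters of the synthetic-recording generator. Defaults describe a
#' control-like male recorded for a 15-minute mating assay; none of them are
#' estimates of real data.
#'
#' @param recording_duration recording length, seconds.
#' @param state_dwell_means named list of mean dwell times (s) for the
#'   semi-Markov behavioral states: `off_contact`, `ventral_contact`,
#'   `backward_slide`, `forward_slide`, `vulva_contact`,
#'   `pause_away_from_vulva`.
#' @param turn_success_prob probability that a turn attempt succeeds.
#' @param vulva_encounter_rate vulva encounters per minute of scanning.
#' @param vulva_pass_prob probability an encounter is passed over (point
#'   `vulva_pass`) instead of becoming a vulva-contact interval.
#' @param ejaculation_prob_per_vulva_contact probability a vulva contact ends
#'   in spicule insertion and ejaculation (terminates the recording).
#' @param pause_prob probability of a pause-away-from-vulva interval after a
#'   forward slide.
#' @param slide_over_rate slide-over point events per minute of ventral
#'   contact.
#' @param neuron_couplings named list (one entry per neuron) of
#'   `list(motif =, gain =, latency =)`: the neuron responds to that motif
#'   through the calcium kernel, peaking `latency` seconds after each onset
#'   (point motifs) or following the boxcar-convolved kernel delayed by
#'   `latency` (interval motifs).
#' @param calcium_decay_tau decay time constant of the calcium kernel, s.
#' @param calcium_rise_tau rise time constant of the calcium kernel, s.
#' @param spurious_pulse_rate spurious activation pulses per minute, injected
#'   into each neuron listed in `spurious_neurons`, always outside vulva
#'   contact.
#' @param spurious_neurons neurons receiving spurious pulses.
#' @param spurious_pulse_amplitude,spurious_pulse_duration pulse plateau
#'   amplitude (activity units) and boxcar duration (s).
#' @param motion_artifact list `ar` (AR(1) coefficient of the log-scale
#'   motion process) and `sd` (stationary log-scale standard deviation);
#'   the resulting multiplicative factor is shared by both channels of a
#'   neuron.
#' @param channel_noise_sd additive Gaussian noise per channel, fluorescence
#'   units.
#' @param camera_offset additive camera offset per channel, fluorescence
#'   units.
#' @param channel_gains list `green`, `red`: baseline fluorescence per
#'   channel (units).
#' @param acquisition_rate volumes per second.
#' @param seed default integer seed used when an operation is not given one.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(recording_duration = 900,
                       state_dwell_means = list(off_contact = 20,
                                                ventral_contact = 60,
                                                backward_slide = 6,
                                                forward_slide = 3,
                                                vulva_contact = 8,
                                                pause_away_from_vulva = 3),
                       turn_success_prob = 0.9,
                       vulva_encounter_rate = 2,
                       vulva_pass_prob = 0.3,
                       ejaculation_prob_per_vulva_contact = 0.3,
                       pause_prob = 0.2,
                       slide_over_rate = 0.3,
                       neuron_couplings = list(
                         PCA = list(motif = "backward_slide", gain = 1, latency = 0.5),
                         PVV = list(motif = "turn_success", gain = 1, latency = 1.2),
                         PCB = list(motif = "vulva_contact", gain = 1, latency = 0.5),
                         HOA = list(motif = "vulva_contact", gain = 1, latency = 0.5)),
                       calcium_decay_tau = 1.5,
                       calcium_rise_tau = 0.2,
                       spurious_pulse_rate = 0,
                       spurious_neurons = c("PCB", "PCC", "HOA", "HOB", "R2B"),
                       spurious_pulse_amplitude = 1,
                       spurious_pulse_duration = 2,
                       motion_artifact = list(ar = 0.95, sd = 0.05),
                       channel_noise_sd = 0,
                       camera_offset = 0,
                       channel_gains = list(green = 100, red = 100),
                       acquisition_rate = 10,
                       seed = 1L) {
  cfg <- list(recording_duration = recording_duration,
              state_dwell_means = state_dwell_means,
              turn_success_prob = turn_success_prob,
              vulva_encounter_rate = vulva_encounter_rate,
              vulva_pass_prob = vulva_pass_prob,
              ejaculation_prob_per_vulva_contact = ejaculation_prob_per_vulva_contact,
              pause_prob = pause_prob,
              slide_over_rate = slide_over_rate,
              neuron_couplings = neuron_couplings,
              calcium_decay_tau = calcium_decay_tau,
              calcium_rise_tau = calcium_rise_tau,
              spurious_pulse_rate = spurious_pulse_rate,
              spurious_neurons = spurious_neurons,
              spurious_pulse_amplitude = spurious_pulse_amplitude,
              spurious_pulse_duration = spurious_pulse_duration,
              motion_artifact = motion_artifact,
              channel_noise_sd = channel_noise_sd,
              camera_offset = camera_offset,
              channel_gains = channel_gains,
              acquisition_rate = acquisition_rate,
              seed = as.integer(seed))
  probs <- c(turn_success_prob, vulva_pass_prob,
             ejaculation_prob_per_vulva_contact, pause_prob)
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  dw <- unlist(state_dwell_means)
  need <- c("off_contact", "ventral_contact", "backward_slide",
            "forward_slide", "vulva_contact", "pause_away_from_vulva")
  if (!all(need %in% names(state_dwell_means)))
    stop("state_dwell_means must name: ", paste(need, collapse = ", "))
  if (any(dw <= 0) || recording_duration <= 0 || acquisition_rate <= 0)
    stop("all durations and rates must be strictly positive")
  if (calcium_decay_tau <= 0 || calcium_rise_tau <= 0 ||
      calcium_rise_tau >= calcium_decay_tau)
    stop("calcium kernel requires 0 < rise tau < decay tau")
  if (vulva_encounter_rate < 0 || spurious_pulse_rate < 0 || slide_over_rate < 0)
    stop("rates must be non-negative")
  if (motion_artifact$ar < 0 || motion_artifact$ar >= 1 || motion_artifact$sd < 0)
    stop("motion_artifact: need 0 <= ar < 1 and sd >= 0")
  if (channel_noise_sd < 0) stop("channel_noise_sd must be >= 0")
  structure(cfg, class = "sim_config")
}

## Run expr with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a mating ethogram
#'
#' Semi-Markov behavioral generator. The male alternates off-contact and
#' ventral-contact episodes with exponential dwell times. Within a contact
#' episode he scans by backward sliding; each completed backward slide ends
#' in a turn attempt (Bernoulli success). A successful turn is followed by a
#' forward slide (and possibly a pause away from the vulva); a failed turn
#' ends ventral contact with a loss-of-contact event. Vulva encounters occur
#' as a Poisson process during backward sliding and become either a
#' vulva-pass point event or a nested vulva-contact interval, which may end
#' in spicule insertion and ejaculation, terminating the recording (at most
#' one ejaculation per recording).
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param recording_id identifier for the emitted ethogram.
#' @return An [ethogram].
#' @export
simulate_ethogram <- function(config, seed = config$seed, recording_id = "sim") {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, simulate_ethogram_impl(config, recording_id))
}

simulate_ethogram_impl <- function(cfg, recording_id) {
  dur <- cfg$recording_duration
  dw <- cfg$state_dwell_means
  ev <- list()  # accumulated rows
  add <- function(type, onset, offset = NA_real_) {
    ev[[length(ev) + 1L]] <<- data.frame(event_type = type, onset_s = onset,
                                         offset_s = offset)
  }
  t <- stats::rexp(1, 1 / dw$off_contact)  # approach before first contact
  terminated <- FALSE

  while (t < dur && !terminated) {
    ## one ventral-contact episode
    c0 <- t
    t_nat <- c0 + stats::rexp(1, 1 / dw$ventral_contact)
    ended <- FALSE
    while (!ended) {
      ## backward slide (scanning), possibly interrupted by vulva encounters
      slide_end <- t + stats::rexp(1, 1 / dw$backward_slide)
      repeat {
        lim <- min(slide_end, t_nat, dur)
        enc <- t + stats::rexp(1, max(cfg$vulva_encounter_rate, 1e-12) / 60)
        if (cfg$vulva_encounter_rate > 0 && enc < lim) {
          if (enc > t) add("backward_slide", t, enc)
          t <- enc
          if (stats::runif(1) < cfg$vulva_pass_prob) {
            add("vulva_pass", t)     # slid over the vulva, keeps scanning
          } else {
            vc_end <- t + stats::rexp(1, 1 / dw$vulva_contact)
            vc_end <- min(vc_end, dur)
            if (vc_end > t) {
              add("vulva_contact", t, vc_end)
              t_nat <- max(t_nat, vc_end + 1e-6)  # contact encloses vulva contact
              if (stats::runif(1) < cfg$ejaculation_prob_per_vulva_contact) {
                add("spicule_insertion", max(t, vc_end - 1))
                add("ejaculation", vc_end)
                t <- vc_end
                terminated <- TRUE; ended <- TRUE
                break
              }
            }
            t <- vc_end
            slide_end <- t + stats::rexp(1, 1 / dw$backward_slide)
          }
        } else {
          ## slide runs to its end, or the episode/recording boundary
          if (lim > t) add("backward_slide", t, lim)
          t <- lim
          break
        }
      }
      if (ended) break
      if (t >= dur) { ended <- TRUE; break }
      if (t >= t_nat) {           # natural loss of contact mid-scan
        add("loss_of_contact", t)
        ended <- TRUE; break
      }
      ## turn attempt at the end of the completed backward slide
      if (stats::runif(1) < cfg$turn_success_prob) {
        add("turn_success", t)
        fw_end <- min(t + stats::rexp(1, 1 / dw$forward_slide), t_nat, dur)
        if (fw_end > t) add("forward_slide", t, fw_end)
        t <- fw_end
        if (t >= dur) { ended <- TRUE; break }
        if (t >= t_nat) { add("loss_of_contact", t); ended <- TRUE; break }
        if (stats::runif(1) < cfg$pause_prob) {
          p_end <- min(t + stats::rexp(1, 1 / dw$pause_away_from_vulva), t_nat, dur)
          if (p_end > t) add("pause_away_from_vulva", t, p_end)
          t <- p_end
          if (t >= dur) { ended <- TRUE; break }
          if (t >= t_nat) { add("loss_of_contact", t); ended <- TRUE; break }
        }
      } else {
        add("turn_fail", t)       # failed turn: tail loses the partner
        add("loss_of_contact", t)
        ended <- TRUE; break
      }
    }
    c1 <- min(t, dur)
    if (c1 > c0) {
      add("ventral_contact", c0, c1)
      ## slide-over events sprinkled over the episode
      if (cfg$slide_over_rate > 0) {
        n_so <- stats::rpois(1, cfg$slide_over_rate / 60 * (c1 - c0))
        if (n_so > 0)
          for (ts in sort(stats::runif(n_so, c0, c1))) add("slide_over", ts)
      }
    }
    if (!terminated)
      t <- t + stats::rexp(1, 1 / dw$off_contact)
  }

  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(event_type = character(0), onset_s = numeric(0),
               offset_s = numeric(0))
  recording_end <- if (terminated) min(t, dur) else dur
  ethogram(events, recording_id = recording_id, duration_s = recording_end)
}

## --- calcium kernel -------------------------------------------------------

## Difference-of-exponentials kernel, unit peak, argmax at u_star.
kernel_peak_time <- function(tau_r, tau_d) {
  tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
}

calcium_kernel <- function(u, tau_r, tau_d) {
  k <- ifelse(u >= 0, exp(-u / tau_d) - exp(-u / tau_r), 0)
  us <- kernel_peak_time(tau_r, tau_d)
  k / (exp(-us / tau_d) - exp(-us / tau_r))
}

## Peak-time shift induced by the standard analysis chain (block-mean
## downsampling + order-1 SG smoothing) on the calcium kernel: the uniform
## smoothing of a fast-rise/slow-decay kernel moves its argmax toward the
## heavy (decay) side. Deterministic in the kernel and filter parameters.
pipeline_peak_shift <- function(tau_r, tau_d, acq_rate, factor = 2L,
                                window = 13L, order = 1L) {
  pad <- 5L * window
  len <- ceiling(12 * tau_d * acq_rate)
  u <- (0:(len - 1)) / acq_rate
  k <- c(rep(0, pad * factor), calcium_kernel(u, tau_r, tau_d))
  n_out <- length(k) %/% factor
  d <- colMeans(matrix(k[seq_len(n_out * factor)], nrow = factor))
  sm <- savitzky_golay(d, window, order)
  (which.max(sm) - 1L - pad) / (acq_rate / factor) -
    kernel_peak_time(tau_r, tau_d)
}

## Discrete kernels on the acquisition grid.
## point kernel: unit peak; `shift` (the filter-induced peak displacement)
## is subtracted so that the *analysis-pipeline* response peaks `latency`
## seconds after the onset. The kernel may be mildly anticipatory.
## interval kernel: unit DC gain, so a long unit boxcar plateaus at 1.
point_kernel <- function(latency, tau_r, tau_d, rate, len, shift = 0) {
  us <- kernel_peak_time(tau_r, tau_d)
  off <- latency - shift - us             # time origin of the kernel support
  pre <- max(0L, ceiling(max(0, -off) * rate) + 1L)
  u <- ((-pre):(len - 1)) / rate
  list(weights = calcium_kernel(u - off, tau_r, tau_d), pre = pre)
}

## half-rise time of the kernel's step response: the T with
## int_0^T k = (1/2) int_0^inf k; closed CDF tau_d(1-e^{-T/tau_d}) -
## tau_r(1-e^{-T/tau_r})
kernel_half_rise <- function(tau_r, tau_d) {
  total <- tau_d - tau_r
  f <- function(T) tau_d * (1 - exp(-T / tau_d)) -
    tau_r * (1 - exp(-T / tau_r)) - total / 2
  stats::uniroot(f, c(1e-6, 50 * tau_d))$root
}

## Interval (boxcar-driven) kernel, unit DC gain. When `compensate`, the
## kernel is advanced by its half-rise time so that the response's
## half-rise follows each motif onset by exactly `latency` seconds -- the
## injected latency is then the lag that cross-correlation against the
## motif indicator estimates. The advanced kernel is mildly anticipatory
## (activity may start rising shortly before the onset), as real
## pre-motor activity does.
interval_kernel <- function(latency, tau_r, tau_d, rate, len,
                            compensate = TRUE) {
  shift <- if (compensate) latency - kernel_half_rise(tau_r, tau_d) else latency
  pre <- max(0L, ceiling(max(0, -shift) * rate) + 1L)
  u <- ((-pre):(len - 1)) / rate
  k <- calcium_kernel(u - shift, tau_r, tau_d)
  s <- sum(k) / rate
  if (s <= 0) stop("degenerate interval kernel")
  list(weights = k / (s * rate), pre = pre)
}

## convolution of a driver with kernel weights whose first `pre` samples
## precede time zero (anticipatory part); pre = 0 gives causal convolution
convolve_kernel <- function(driver, weights, pre = 0L) {
  n <- length(driver)
  out <- stats::convolve(c(driver, rep(0, length(weights))),
                         rev(weights), type = "open")
  out[(1L + pre):(n + pre)]
}

motif_driver <- function(e, motif, times, rate) {
  voc <- ethogram_vocabulary()
  n <- length(times)
  d <- numeric(n)
  if (motif %in% voc$interval) {
    iv <- event_intervals(e, motif)
    if (nrow(iv))
      for (i in seq_len(nrow(iv)))
        d[times >= iv[i, 1] & times < iv[i, 2]] <- 1
  } else if (motif %in% voc$point) {
    on <- event_onsets(e, motif)
    idx <- round(on * rate) + 1L
    idx <- idx[idx >= 1L & idx <= n]
    d[idx] <- 1
  } else stop("unknown motif: ", motif)
  d
}

#' Simulate neural traces and two-channel emissions from an ethogram
#'
#' Builds each neuron's noiseless activity \eqn{a_i(t)} as baseline 0 plus
#' kernel responses to its coupled motif (boxcar-convolved for interval
#' motifs, impulse responses for point motifs, peaking `latency` seconds
#' after each onset), plus any injected spurious pulses outside vulva
#' contact. Emissions per neuron share one multiplicative log-AR(1) motion
#' process \eqn{m(t)}:
#' \deqn{G(t) = c_g (1 + a(t)) m(t) + \mathrm{offset} + \epsilon_G, \quad
#'       R(t) = c_r m(t) + \mathrm{offset} + \epsilon_R.}
#'
#' @param etho an [ethogram] (events must lie within its duration).
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return List with `traces` (a `raw_traces` object: matrices `green`,
#'   `red` of neurons x time at the acquisition rate) and `truth` (a
#'   `ground_truth` object: noiseless activity, motif intervals, spurious
#'   pulse intervals, coupling latencies).
#' @export
simulate_traces <- function(etho, config, seed = config$seed) {
  stopifnot(inherits(etho, "ethogram"), inherits(config, "sim_config"))
  chk <- validate_ethogram(etho)
  if (!chk$valid)
    stop("inconsistent ethogram: ", paste(chk$violations, collapse = "; "))
  with_seed(seed, simulate_traces_impl(etho, config))
}

simulate_traces_impl <- function(etho, cfg) {
  rate <- cfg$acquisition_rate
  n <- max(1L, floor(etho$duration_s * rate))
  times <- (0:(n - 1)) / rate
  neurons <- union(names(cfg$neuron_couplings), cfg$spurious_neurons)
  if (!length(neurons)) stop("no neurons configured")
  voc <- ethogram_vocabulary()

  klen <- min(n, ceiling((cfg$calcium_decay_tau * 8 +
                            max(0, vapply(cfg$neuron_couplings,
                                          function(cp) cp$latency, numeric(1),
                                          USE.NAMES = FALSE))) * rate) + 1L)

  act <- matrix(0, nrow = length(neurons), ncol = n,
                dimnames = list(neurons, NULL))
  spurious_truth <- stats::setNames(vector("list", length(neurons)), neurons)
  ## filter-induced peak displacement of the standard analysis chain;
  ## point-coupling latencies are defined on the processed trace
  sg_shift <- pipeline_peak_shift(cfg$calcium_rise_tau, cfg$calcium_decay_tau,
                                  rate)
  ## peak of the unit-boxcar kernel response of the injected pulse duration
  ## (normalized step response), used so the injected pulse's ground-truth
  ## peak equals the configured amplitude
  pulse_peak0 <- {
    d <- cfg$spurious_pulse_duration
    (cfg$calcium_decay_tau * (1 - exp(-d / cfg$calcium_decay_tau)) -
       cfg$calcium_rise_tau * (1 - exp(-d / cfg$calcium_rise_tau))) /
      (cfg$calcium_decay_tau - cfg$calcium_rise_tau)
  }

  vul <- event_intervals(etho, "vulva_contact")
  for (nm in neurons) {
    a <- numeric(n)
    cp <- cfg$neuron_couplings[[nm]]
    if (!is.null(cp) && cp$gain != 0) {
      drv <- motif_driver(etho, cp$motif, times, rate)
      if (cp$motif %in% voc$interval) {
        kw <- interval_kernel(cp$latency, cfg$calcium_rise_tau,
                              cfg$calcium_decay_tau, rate, klen)
        a <- a + cp$gain * convolve_kernel(drv, kw$weights, kw$pre)
      } else {
        kw <- point_kernel(cp$latency, cfg$calcium_rise_tau,
                           cfg$calcium_decay_tau, rate, klen,
                           shift = sg_shift)
        a <- a + cp$gain * convolve_kernel(drv, kw$weights, kw$pre)
      }
    }
    ## spurious pulses: boxcar-driven kernel events wholly outside vulva contact
    sp <- matrix(numeric(0), ncol = 2)
    if (cfg$spurious_pulse_rate > 0 && nm %in% cfg$spurious_neurons) {
      n_p <- stats::rpois(1, cfg$spurious_pulse_rate / 60 * etho$duration_s)
      onsets <- sort(stats::runif(n_p, 0,
                                  max(0, etho$duration_s - cfg$spurious_pulse_duration)))
      keep <- vapply(onsets, function(t0) {
        t1 <- t0 + cfg$spurious_pulse_duration
        !nrow(vul) || all(t1 <= vul[, 1] | t0 >= vul[, 2])
      }, logical(1))
      onsets <- onsets[keep]
      ## enforce disjoint pulses
      if (length(onsets) > 1L) {
        sel <- c(TRUE, diff(onsets) > cfg$spurious_pulse_duration)
        onsets <- onsets[sel]
      }
      if (length(onsets)) {
        drv <- numeric(n)
        for (t0 in onsets)
          drv[times >= t0 & times < t0 + cfg$spurious_pulse_duration] <- 1
        kw <- interval_kernel(0, cfg$calcium_rise_tau, cfg$calcium_decay_tau,
                              rate, klen, compensate = FALSE)
        a <- a + (cfg$spurious_pulse_amplitude / pulse_peak0) *
          convolve_kernel(drv, kw$weights, kw$pre)
        sp <- cbind(onset = onsets,
                    offset = onsets + cfg$spurious_pulse_duration)
      }
    }
    act[nm, ] <- a
    spurious_truth[[nm]] <- sp
  }

  ## emissions
  g <- matrix(NA_real_, length(neurons), n, dimnames = list(neurons, NULL))
  r <- g
  ma <- cfg$motion_artifact
  for (nm in neurons) {
    m <- if (ma$sd > 0) {
      x <- numeric(n)
      x[1] <- stats::rnorm(1, 0, ma$sd)
      innov_sd <- ma$sd * sqrt(1 - ma$ar^2)
      eps <- stats::rnorm(n - 1, 0, innov_sd)
      for (i in seq_len(n - 1)) x[i + 1] <- ma$ar * x[i] + eps[i]
      exp(x)
    } else rep(1, n)
    g[nm, ] <- cfg$channel_gains$green * (1 + act[nm, ]) * m +
      cfg$camera_offset + stats::rnorm(n, 0, cfg$channel_noise_sd)
    r[nm, ] <- cfg$channel_gains$red * m +
      cfg$camera_offset + stats::rnorm(n, 0, cfg$channel_noise_sd)
  }

  traces <- structure(list(time = times, rate = rate, neurons = neurons,
                           green = g, red = r,
                           camera_offset = cfg$camera_offset,
                           recording_id = etho$recording_id),
                      class = "raw_traces")
  truth <- structure(list(time = times, rate = rate, activity = act,
                          couplings = cfg$neuron_couplings,
                          spurious = spurious_truth,
                          motifs = etho),
                     class = "ground_truth")
  list(traces = traces, truth = truth)
}

## --- volume rendering ------------------------------------------------------

#' Imaging geometry for rendered volumes
#'
#' Acquisition constants match the recording setup (0.45 um lateral pixels,
#' 1.75 um slice spacing, 10 volumes/s); the default lateral extent is
#' reduced (64 x 32 px, 10 slices) to keep rendered fixtures desk-scale.
#'
#' @param n_x,n_y,n_z grid size (pixels laterally, optical slices axially).
#' @param pixel_size_um lateral pixel size, micrometers.
#' @param slice_spacing_um axial slice spacing, micrometers.
#' @param volume_rate_hz volumes per second.
#' @param blob_sigma_um Gaussian nucleus blob sigmas (x, y, z), micrometers.
#' @return List of class `volume_geometry`.
#' @export
volume_geometry <- function(n_x = 64, n_y = 32, n_z = 10,
                            pixel_size_um = 0.45, slice_spacing_um = 1.75,
                            volume_rate_hz = 10,
                            blob_sigma_um = c(0.9, 0.9, 1.2)) {
  stopifnot(n_x > 0, n_y > 0, n_z > 0, pixel_size_um > 0,
            slice_spacing_um > 0, volume_rate_hz > 0, all(blob_sigma_um > 0))
  structure(list(n_x = as.integer(n_x), n_y = as.integer(n_y),
                 n_z = as.integer(n_z), pixel_size_um = pixel_size_um,
                 slice_spacing_um = slice_spacing_um,
                 volume_rate_hz = volume_rate_hz,
                 blob_sigma_um = blob_sigma_um),
            class = "volume_geometry")
}

#' Simulate nucleus tracks
#'
#' Places neurons on a grid in the volume interior and lets each drift as a
#' reflected Gaussian random walk, emulating residual motion after
#' registration and stage tracking.
#'
#' @param neurons character vector of neuron ids.
#' @param n_volumes number of volumes.
#' @param geometry a [volume_geometry()].
#' @param seed integer seed.
#' @param drift_sd per-volume positional jitter, micrometers.
#' @return data.frame `volume_index` (1-based), `neuron_id`, `x_um`, `y_um`,
#'   `z_um`.
#' @export
simulate_tracks <- function(neurons, n_volumes, geometry = volume_geometry(),
                            seed = 1L, drift_sd = 0.05) {
  stopifnot(length(neurons) >= 1, n_volumes >= 1)
  g <- geometry
  ext <- c(g$n_x * g$pixel_size_um, g$n_y * g$pixel_size_um,
           g$n_z * g$slice_spacing_um)
  margin <- pmin(c(3, 3, 2 * g$slice_spacing_um), ext / 2)
  with_seed(seed, {
    k <- length(neurons)
    x0 <- margin[1] + (ext[1] - 2 * margin[1]) * (seq_len(k) - 0.5) / k
    y0 <- rep(ext[2] / 2, k)
    z0 <- rep(ext[3] / 2, k)
    out <- vector("list", k)
    for (i in seq_len(k)) {
      pos <- matrix(NA_real_, n_volumes, 3)
      pos[1, ] <- c(x0[i], y0[i], z0[i])
      if (n_volumes > 1) {
        steps <- matrix(stats::rnorm(3 * (n_volumes - 1), 0, drift_sd),
                        ncol = 3)
        for (tt in 2:n_volumes) {
          p <- pos[tt - 1, ] + steps[tt - 1, ]
          p <- pmin(pmax(p, margin), ext - margin)  # reflecting clamp
          pos[tt, ] <- p
        }
      }
      out[[i]] <- data.frame(volume_index = seq_len(n_volumes),
                             neuron_id = neurons[i],
                             x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3])
    }
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    df
  })
}

#' Render two-channel volumes from raw traces
#'
#' Each nucleus is rendered into both channels as an anisotropic 3D Gaussian
#' blob centered on its tracked position, with amplitude equal to the
#' channel signal minus the camera offset; the offset is then added to every
#' voxel. Because the blob profile is identical in both channels of a
#' neuron, ROI means preserve the (offset-subtracted) green/red ratio
#' exactly.
#'
#' @param raw a `raw_traces` object from [simulate_traces()].
#' @param tracks nucleus tracks (see [simulate_tracks()]); must cover every
#'   neuron at every volume.
#' @param geometry a [volume_geometry()].
#' @param seed integer seed (reserved for future stochastic rendering; the
#'   renderer itself is deterministic).
#' @return `volume_series` object: arrays `green`, `red` with dimensions
#'   (x, y, z, volume) plus the geometry constants.
#' @export
render_volumes <- function(raw, tracks, geometry = volume_geometry(),
                           seed = 1L) {
  stopifnot(inherits(raw, "raw_traces"))
  g <- geometry
  n_t <- length(raw$time)
  neurons <- raw$neurons
  need <- expand.grid(volume_index = seq_len(n_t), neuron_id = neurons,
                      stringsAsFactors = FALSE)
  key <- paste(tracks$volume_index, tracks$neuron_id)
  miss <- !(paste(need$volume_index, need$neuron_id) %in% key)
  if (any(miss))
    stop("tracks missing for neuron ", need$neuron_id[which(miss)[1]],
         " at volume ", need$volume_index[which(miss)[1]])

  ext <- c(g$n_x * g$pixel_size_um, g$n_y * g$pixel_size_um,
           g$n_z * g$slice_spacing_um)
  xs <- (seq_len(g$n_x) - 0.5) * g$pixel_size_um
  ys <- (seq_len(g$n_y) - 0.5) * g$pixel_size_um
  zs <- (seq_len(g$n_z) - 0.5) * g$slice_spacing_um
  sig <- g$blob_sigma_um

  green <- array(raw$camera_offset, dim = c(g$n_x, g$n_y, g$n_z, n_t))
  red <- array(raw$camera_offset, dim = c(g$n_x, g$n_y, g$n_z, n_t))

  tr <- split(tracks, tracks$neuron_id)
  for (nm in neurons) {
    tn <- tr[[nm]]
    tn <- tn[order(tn$volume_index), , drop = FALSE]
    for (tt in seq_len(n_t)) {
      p <- c(tn$x_um[tt], tn$y_um[tt], tn$z_um[tt])
      if (any(p < 0) || any(p > ext))
        stop("blob center outside grid for neuron ", nm, " at volume ", tt)
      ix <- which(abs(xs - p[1]) <= 3 * sig[1])
      iy <- which(abs(ys - p[2]) <= 3 * sig[2])
      iz <- which(abs(zs - p[3]) <= 3 * sig[3])
      if (!length(ix) || !length(iy) || !length(iz)) next
      bx <- exp(-(xs[ix] - p[1])^2 / (2 * sig[1]^2))
      by <- exp(-(ys[iy] - p[2])^2 / (2 * sig[2]^2))
      bz <- exp(-(zs[iz] - p[3])^2 / (2 * sig[3]^2))
      blob <- outer(outer(bx, by), bz)       # ix x iy x iz
      amp_g <- raw$green[nm, tt] - raw$camera_offset
      amp_r <- raw$red[nm, tt] - raw$camera_offset
      green[ix, iy, iz, tt] <- green[ix, iy, iz, tt] + amp_g * blob
      red[ix, iy, iz, tt] <- red[ix, iy, iz, tt] + amp_r * blob
    }
  }
  structure(list(green = green, red = red,
                 pixel_size_um = g$pixel_size_um,
                 slice_spacing_um = g$slice_spacing_um,
                 volume_rate_hz = g$volume_rate_hz,
                 recording_id = raw$recording_id),
            class = "volume_series")
}
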