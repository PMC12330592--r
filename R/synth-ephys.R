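#' Multichannel recording session container
#'
#' @param signals Numeric matrix, samples x channels, volts.
#' @param sample_rate Sampling rate, Hz.
#' @param events data.frame with columns `time` (s) and `type`.
#' @param channel_ids Optional channel identifiers (default `ch1..chN`).
#' @param layout Optional data.frame with `channel`, `x`, `y` positions (mm).
#' @param impedances Optional per-channel impedance magnitudes, ohms.
#' @return An object of class `recording_session`.
#' @export
recording_session <- function(signals, sample_rate,
                              events = data.frame(time = numeric(0),
                                                  type = character(0)),
                              channel_ids = NULL, layout = NULL,
                              impedances = NULL) {
  signals <- as.matrix(signals)
  stopifnot(is.numeric(signals), all(is.finite(signals)), sample_rate > 0)
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(ncol(signals)))
  dur <- nrow(signals) / sample_rate
  if (nrow(events) > 0 && any(events$time < 0 | events$time > dur))
    stop("events outside the recording duration")
  structure(list(signals = signals, sample_rate = sample_rate,
                 events = events, channel_ids = channel_ids,
                 layout = layout, impedances = impedances),
            class = "recording_session")
}

#' Session configuration for the synthetic generators
#'
#' @param n_channels Number of channels.
#' @param sample_rate Sampling rate, Hz (30 kHz for broadband/spiking
#'   material, 1 kHz is convenient for LFP-only sessions).
#' @param duration Total duration, seconds (inferred from the schedule if
#'   omitted).
#' @param events data.frame with `time` (strictly increasing) and `type`.
#' @param seed Mandatory RNG seed; the session is fully reproducible.
#' @return An object of class `session_config`.
#' @export
session_config <- function(n_channels, sample_rate = 30000, duration = NULL,
                           events = NULL, seed) {
  stopifnot(n_channels >= 1, sample_rate > 0, !missing(seed))
  if (is.null(events))
    events <- data.frame(time = numeric(0), type = character(0))
  if (nrow(events) > 1 && any(diff(events$time) <= 0))
    stop("events must be strictly increasing in time")
  if (is.null(duration)) {
    duration <- if (nrow(events)) max(events$time) + 1 else 10
  }
  structure(list(n_channels = as.integer(n_channels),
                 sample_rate = sample_rate, duration = duration,
                 events = events, seed = as.integer(seed)),
            class = "session_config")
}

#' Regular trial schedule
#'
#' @param n_trials Number of trials.
#' @param period Trial-to-trial period, seconds.
#' @param t0 Time of the first event, seconds.
#' @param type Event type label.
#' @return data.frame with `time`, `type`.
#' @export
trial_schedule <- function(n_trials, period = 1, t0 = 1, type = "trial_start") {
  data.frame(time = t0 + (seq_len(n_trials) - 1) * period,
             type = rep(type, n_trials))
}

#' Planted evoked band-power effect
#'
#' Describes an event-locked multiplicative band-power gain on a set of
#' target channels: within the response window the expected power in
#' `band` is `power_multiplier` times the channel's baseline band power.
#'
#' @param channels Target channel indices.
#' @param band Frequency band `c(low, high)`, Hz.
#' @param power_multiplier Expected task/baseline band-power ratio (>= 1).
#' @param latency Response latency after the event, seconds.
#' @param duration Response duration, seconds.
#' @param event_type Event type the response is locked to.
#' @return An object of class `evoked_spec`.
#' @export
evoked_spec <- function(channels, band, power_multiplier, latency = 0,
                        duration = 0.5, event_type = "trial_start") {
  stopifnot(power_multiplier >= 1, band[1] > 0, band[2] > band[1])
  structure(list(channels = as.integer(channels), band = band,
                 power_multiplier = power_multiplier, latency = latency,
                 duration = duration, event_type = event_type),
            class = "evoked_spec")
}

# 1/f^slope - shaped Gaussian background, unit variance, length n
pink_noise <- function(n, sample_rate, slope = 1) {
  x <- stats::rnorm(n)
  if (slope == 0) return(x)
  xf <- stats::fft(x)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f) * sample_rate / n
  w <- c(0, 1 / f[-1]^(slope / 2))
  y <- Re(stats::fft(xf * w, inverse = TRUE)) / n
  (y - mean(y)) / stats::sd(y)
}

#' Generate a trial-structured synthetic LFP session
#'
#' Per channel: `1/f`-shaped Gaussian background, power-line components at
#' 60/120/180 Hz, optional transient artifacts, and event-locked
#' band-limited evoked components on the target channels of each
#' [evoked_spec()]. Evoked effects are additive band-limited noise scaled
#' to the channel's measured baseline band power so that the expected
#' task/baseline power ratio equals the spec's multiplier exactly.
#'
#' @param config A [session_config()] (the seed makes the session
#'   bit-reproducible).
#' @param evoked List of [evoked_spec()] objects.
#' @param background_sd Background SD per channel, volts.
#' @param slope Spectral slope of the background (power ~ 1/f^slope).
#' @param line_amplitude Amplitude of each power-line component, volts.
#' @param line_freqs Power-line frequencies, Hz.
#' @param artifacts Optional data.frame with `time`, `channel`,
#'   `amplitude` (volts), `tau` (s): decaying-exponential artifacts.
#' @param layout,impedances Passed through to the session container.
#' @return List with `session` (a [recording_session()]) and `truth`
#'   (everything planted).
#' @export
generate_lfp_session <- function(config, evoked = list(),
                                 background_sd = 20e-6, slope = 1,
                                 line_amplitude = 2e-6,
                                 line_freqs = c(60, 120, 180),
                                 artifacts = NULL,
                                 layout = NULL, impedances = NULL) {
  stopifnot(inherits(config, "session_config"))
  for (ev in evoked) {
    if (ev$band[2] >= config$sample_rate / 2)
      stop("evoked band above Nyquist")
    if (any(ev$channels > config$n_channels))
      stop("evoked channel index out of range")
  }
  set.seed(config$seed)
  fs <- config$sample_rate
  n <- round(config$duration * fs)
  tt <- (seq_len(n) - 1) / fs
  sig <- matrix(0, n, config$n_channels)
  for (c in seq_len(config$n_channels)) {
    x <- pink_noise(n, fs, slope) * background_sd
    for (f in line_freqs) {
      if (f < fs / 2)
        x <- x + line_amplitude * sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
    }
    sig[, c] <- x
  }
  for (ev in evoked) {
    onsets <- config$events$time[config$events$type == ev$event_type]
    gate <- rep(0, n)
    for (t0 in onsets) {
      a <- floor((t0 + ev$latency) * fs) + 1
      b <- min(n, a + round(ev$duration * fs) - 1)
      if (a <= n) gate[a:b] <- 1
    }
    for (c in ev$channels) {
      base_band <- bandpass_filter(sig[, c], fs, ev$band)
      target_var <- (ev$power_multiplier - 1) * stats::var(base_band)
      if (target_var <= 0) next
      # calibrate the gated component through the analysis band-pass, so
      # that the measured in-window band power gain equals the multiplier
      # (rectangular gating and filter skirts included in the calibration)
      gated <- bandpass_filter(stats::rnorm(n), fs, ev$band) * gate
      through <- bandpass_filter(gated, fs, ev$band)
      mean_in <- mean(through[gate == 1]^2)
      if (mean_in <= 0) next
      sig[, c] <- sig[, c] + gated * sqrt(target_var / mean_in)
    }
  }
  if (!is.null(artifacts)) {
    for (k in seq_len(nrow(artifacts))) {
      a <- floor(artifacts$time[k] * fs) + 1
      if (a > n) next
      idx <- a:min(n, a + round(5 * artifacts$tau[k] * fs))
      sig[idx, artifacts$channel[k]] <- sig[idx, artifacts$channel[k]] +
        artifacts$amplitude[k] * exp(-(idx - a) / (artifacts$tau[k] * fs))
    }
  }
  session <- recording_session(sig, fs, events = config$events,
                               layout = layout, impedances = impedances)
  truth <- list(evoked = evoked, background_sd = background_sd,
                slope = slope, line_amplitude = line_amplitude,
                line_freqs = line_freqs, artifacts = artifacts,
                seed = config$seed)
  list(session = session, truth = truth)
}

# default extracellular spike template: trough-dominant biphasic wave,
# peak-to-trough normalized to 1
default_spike_template <- function(sample_rate, duration = 1.2e-3) {
  t <- seq(0, duration, by = 1 / sample_rate)
  w <- -0.9 * exp(-(t - 0.3e-3)^2 / (2 * (0.08e-3)^2)) +
        0.25 * exp(-(t - 0.62e-3)^2 / (2 * (0.16e-3)^2))
  w / (max(w) - min(w))
}

#' Generate a synthetic spiking trace with known ground truth
#'
#' Poisson spike times (with an enforced refractory period) carrying a
#' trough-dominant template over Gaussian background noise. The template
#' is scaled so that the peak-to-trough amplitude over the background SD
#' matches the requested SNR (`SNR_dB = 20 log10(A_spike / sigma_b)`).
#'
#' @param config A [session_config()] (single- or multi-channel; each
#'   channel gets an independent realization of the same parameters).
#' @param rate Mean firing rate, Hz (>= 0).
#' @param target_snr_db Target spike SNR in dB.
#' @param template Spike waveform (peak-to-trough-normalized); default a
#'   1.2 ms biphasic shape.
#' @param background_sd Background noise SD, volts.
#' @param refractory Minimum inter-spike interval, seconds.
#' @param clip_limit Absolute voltage ceiling of the virtual front end; an
#'   SNR requiring amplitudes above it raises an error.
#' @return List with `session` ([recording_session()]) and `truth`
#'   (`spike_times` per channel, `amplitude`, `template`, `background_sd`).
#' @export
generate_spiking <- function(config, rate, target_snr_db, template = NULL,
                             background_sd = 10e-6, refractory = 1e-3,
                             clip_limit = Inf) {
  stopifnot(inherits(config, "session_config"), rate >= 0)
  set.seed(config$seed)
  fs <- config$sample_rate
  n <- round(config$duration * fs)
  if (is.null(template)) template <- default_spike_template(fs)
  amp <- background_sd * 10^(target_snr_db / 20)
  if (amp > clip_limit)
    stop("target SNR requires amplitudes beyond the clipping limit")
  w <- template * amp
  lw <- length(w)
  sig <- matrix(0, n, config$n_channels)
  spike_times <- vector("list", config$n_channels)
  for (c in seq_len(config$n_channels)) {
    x <- stats::rnorm(n, 0, background_sd)
    times <- numeric(0)
    if (rate > 0) {
      t <- 0
      repeat {
        t <- t + refractory + stats::rexp(1, rate)
        if (t > config$duration - lw / fs) break
        times <- c(times, t)
      }
      for (ts in times) {
        a <- round(ts * fs) + 1
        x[a:(a + lw - 1)] <- x[a:(a + lw - 1)] + w
      }
    }
    sig[, c] <- x
    spike_times[[c]] <- times
  }
  session <- recording_session(sig, fs, events = config$events)
  truth <- list(spike_times = spike_times, amplitude = amp,
                template = template, background_sd = background_sd,
                target_snr_db = target_snr_db, seed = config$seed)
  list(session = session, truth = truth)
}
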