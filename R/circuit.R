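#' Equivalent-circuit parameters for an electrode-electrolyte interface
#'
#' Describes a Randles-type cell: the solution (access) resistance `Rs` in
#' series with the interface, modelled as the charge-transfer resistance
#' `Rct` in parallel with a constant-phase element (CPE). With
#' `cpe_exponent = 1` the CPE is an ideal double-layer capacitor.
#'
#' @param solution_resistance Solution (access) resistance, ohms.
#' @param charge_transfer_resistance Charge-transfer resistance, ohms. May be
#'   `Inf` for a blocking (purely capacitive) interface.
#' @param interface_capacitance Double-layer / pseudo-capacitance, farads
#'   (CPE coefficient `Q` in F s^(alpha-1) when `cpe_exponent < 1`).
#' @param cpe_exponent CPE exponent in (0, 1]; 1 is an ideal capacitor.
#' @return An object of class `circuit_params`.
#' @export
circuit_params <- function(solution_resistance,
                           charge_transfer_resistance,
                           interface_capacitance,
                           cpe_exponent = 1) {
  stopifnot(is.numeric(solution_resistance), solution_resistance > 0,
            is.numeric(charge_transfer_resistance), charge_transfer_resistance > 0,
            is.numeric(interface_capacitance), interface_capacitance > 0,
            is.numeric(cpe_exponent), cpe_exponent > 0, cpe_exponent <= 1)
  structure(list(rs = solution_resistance,
                 rct = charge_transfer_resistance,
                 cap = interface_capacitance,
                 alpha = cpe_exponent),
            class = "circuit_params")
}

#' Charge-balanced biphasic stimulation pulse train
#'
#' The default burst mirrors a typical surface-stimulation protocol for
#' primate cortex: 5 biphasic charge-balanced pulses, 0.6 ms per phase with
#' a 200 us interphase gap, cathodic phase first. Equal phase widths and
#' amplitudes make each pulse charge balanced by construction.
#'
#' @param amplitude Current amplitude of each phase, amperes (0 is a
#'   valid null stimulus).
#' @param cathodic_pulse_width Width of each phase, seconds.
#' @param interphase_gap Gap between the two phases of a pulse, seconds.
#' @param pulses_per_burst Number of biphasic pulses per burst.
#' @param pulse_frequency Pulse repetition rate within a burst, Hz.
#' @param burst_frequency Burst repetition rate, Hz.
#' @param cathodic_first Logical; cathodic (negative) phase leads.
#' @param sample_rate Sampling rate used when the train is synthesized, Hz.
#' @return An object of class `pulse_train`.
#' @export
pulse_train <- function(amplitude,
                        cathodic_pulse_width = 0.6e-3,
                        interphase_gap = 200e-6,
                        pulses_per_burst = 5,
                        pulse_frequency = 500,
                        burst_frequency = 1,
                        cathodic_first = TRUE,
                        sample_rate = 1e6) {
  stopifnot(amplitude >= 0, cathodic_pulse_width > 0, interphase_gap > 0,
            pulses_per_burst >= 1, pulse_frequency > 0, burst_frequency > 0,
            sample_rate > 0)
  if (1 / pulse_frequency < 2 * cathodic_pulse_width + interphase_gap)
    stop("pulse period shorter than the biphasic pulse itself")
  structure(list(amplitude = amplitude,
                 cathodic_pulse_width = cathodic_pulse_width,
                 interphase_gap = interphase_gap,
                 pulses_per_burst = as.integer(pulses_per_burst),
                 pulse_frequency = pulse_frequency,
                 burst_frequency = burst_frequency,
                 cathodic_first = isTRUE(cathodic_first),
                 sample_rate = sample_rate),
            class = "pulse_train")
}

#' Complex impedance of the equivalent circuit
#'
#' @param params A [circuit_params()] object.
#' @param frequencies Frequencies, Hz (> 0).
#' @return Complex impedance vector, ohms.
#' @keywords internal
circuit_impedance <- function(params, frequencies) {
  w <- 2 * pi * frequencies
  # Y_int = 1/Rct + Q (i w)^alpha
  y <- (1i * w)^params$alpha * params$cap
  if (is.finite(params$rct)) y <- y + 1 / params$rct
  params$rs + 1 / y
}

#' Simulate an electrochemical impedance spectrum
#'
#' Evaluates `Z(f) = Rs + 1 / (1/Rct + Q (i 2 pi f)^alpha)` and returns
#' magnitude and phase as an [impedance_spectrum()].
#'
#' @param params A [circuit_params()] object.
#' @param frequencies Frequencies, Hz, all > 0.
#' @param electrode_id Identifier stored in the spectrum.
#' @return An [impedance_spectrum()].
#' @examples
#' p <- circuit_params(1e3, 1e5, 100e-9)
#' simulate_eis(p, c(10, 100, 1000))
#' @export
simulate_eis <- function(params, frequencies, electrode_id = "sim") {
  stopifnot(inherits(params, "circuit_params"))
  if (!is.numeric(frequencies) || any(frequencies <= 0))
    stop("frequencies must be positive")
  z <- circuit_impedance(params, frequencies)
  impedance_spectrum(electrode_id = electrode_id,
                     frequency = frequencies,
                     magnitude = Mod(z),
                     phase = Arg(z) * 180 / pi)
}

# Voigt-chain (series of parallel RC) approximation of the interface
# impedance Z_int = 1/(1/Rct + Q (iw)^alpha) over a frequency band.
# Time constants are log-spaced over the band extended by a decade on each
# side (a saturating RC branch cannot mimic a CPE right at the band edge);
# branch resistances are fitted by magnitude-weighted least squares with
# backward elimination of negative branches. alpha = 1 is exact: a single
# RC branch (or a pure integrator for a blocking interface, rct = Inf).
fit_rc_ladder <- function(params, f_lo, f_hi, n_branches = 7) {
  if (params$alpha == 1) {
    if (!is.finite(params$rct)) {
      return(list(r = numeric(0), tau = numeric(0), pure_cap = TRUE))
    }
    return(list(r = params$rct, tau = params$rct * params$cap,
                pure_cap = FALSE))
  }
  tau <- 10^seq(log10(1 / (2 * pi * f_hi * 10)),
                log10(10 / (2 * pi * f_lo)), length.out = n_branches)
  f <- 10^seq(log10(f_lo), log10(f_hi), length.out = 80)
  w <- 2 * pi * f
  zint <- 1 / (1 / params$rct + params$cap * (1i * w)^params$alpha)
  # design matrix: column k = 1/(1 + i w tau_k), stacked Re over Im,
  # weighted by 1/|Z| so relative error is equalized across the band
  h <- outer(w, tau, function(wi, tk) 1 / (1 + 1i * wi * tk))
  wt <- 1 / Mod(zint)
  a <- rbind(Re(h) * wt, Im(h) * wt)
  b <- c(Re(zint) * wt, Im(zint) * wt)
  active <- rep(TRUE, n_branches)
  r <- numeric(n_branches)
  repeat {
    r[] <- 0
    r[active] <- qr.solve(a[, active, drop = FALSE], b)
    if (all(r >= 0)) break
    active[which.min(r)] <- FALSE
    if (!any(active)) stop("RC-ladder fit failed")
  }
  keep <- r > 0
  list(r = r[keep], tau = tau[keep], pure_cap = FALSE)
}

#' Simulate a stimulation voltage transient
#'
#' Synthesizes the reference-electrode voltage during a charge-balanced
#' biphasic burst: `v(t) = offset + i(t) Rs + v_int(t)`, where the interface
#' polarization `v_int` follows exact exponential RC charging for
#' `cpe_exponent = 1`, and a 7-branch series-RC (Voigt) approximation of the
#' CPE spectrum otherwise. The per-sample update is exact for the
#' piecewise-constant current, so pulse edges are single-sample steps of
#' `-I Rs` / `+I Rs` (cathodic-first convention: cathodic current is
#' negative).
#'
#' @param params A [circuit_params()] object.
#' @param train A [pulse_train()] object. `sample_rate` must resolve the
#'   pulse width (`sample_rate >= 20 / cathodic_pulse_width`).
#' @param polarization_offset Initial polarization bias, volts.
#' @param baseline Pre-burst baseline duration, seconds.
#' @param tail Post-burst duration, seconds; default five interface time
#'   constants (capped at 50 ms).
#' @param noise_sd Optional additive Gaussian measurement noise SD, volts.
#' @param seed Optional seed for the measurement noise.
#' @param n_ladder Number of RC branches used to approximate a CPE.
#' @return A `voltage_transient`: list with `time`, `voltage`, `current`,
#'   `train`, `circuit_truth`, `first_onset`.
#' @examples
#' p <- circuit_params(1e4, 1e6, 100e-9)
#' tr <- simulate_transient(p, pulse_train(50e-6), polarization_offset = 0.2)
#' @export
simulate_transient <- function(params, train, polarization_offset = 0,
                               baseline = 2e-3, tail = NULL,
                               noise_sd = 0, seed = NULL, n_ladder = 7) {
  stopifnot(inherits(params, "circuit_params"), inherits(train, "pulse_train"))
  fs <- train$sample_rate
  if (fs < 20 / train$cathodic_pulse_width)
    stop("sample_rate too low to resolve the pulse width (configuration error)")
  dt <- 1 / fs
  period <- 1 / train$pulse_frequency
  burst_dur <- (train$pulses_per_burst - 1) * period +
    2 * train$cathodic_pulse_width + train$interphase_gap
  tau0 <- min(params$rct * params$cap, 50e-3)
  if (is.null(tail)) tail <- min(max(5 * tau0, 2e-3), 50e-3)
  n <- ceiling((baseline + burst_dur + tail) * fs) + 1L
  tt <- (seq_len(n) - 1L) * dt

  # piecewise-constant current waveform
  i_t <- numeric(n)
  sgn1 <- if (train$cathodic_first) -1 else 1
  pw <- train$cathodic_pulse_width
  gap <- train$interphase_gap
  for (p in seq_len(train$pulses_per_burst)) {
    t0 <- baseline + (p - 1) * period
    ph1 <- tt >= t0 & tt < t0 + pw
    ph2 <- tt >= t0 + pw + gap & tt < t0 + 2 * pw + gap
    i_t[ph1] <- sgn1 * train$amplitude
    i_t[ph2] <- -sgn1 * train$amplitude
  }

  lad <- fit_rc_ladder(params, f_lo = max(1, 1 / (10 * burst_dur)),
                       f_hi = 10 / pw, n_branches = n_ladder)
  if (isTRUE(lad$pure_cap)) {
    # blocking interface: ideal integrator dv = i dt / C
    v_int <- cumsum(c(0, i_t[-n])) * dt / params$cap
  } else {
    v_int <- numeric(n)
    for (k in seq_along(lad$r)) {
      e <- exp(-dt / lad$tau[k])
      drive <- c(0, i_t[-n]) * lad$r[k] * (1 - e)
      v_int <- v_int + as.numeric(stats::filter(drive, e, method = "recursive"))
    }
  }

  v <- polarization_offset + i_t * params$rs + v_int
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + stats::rnorm(n, 0, noise_sd)
  }
  structure(list(time = tt, voltage = v, current = i_t,
                 train = train, circuit_truth = params,
                 first_onset = baseline),
            class = "voltage_transient")
}
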