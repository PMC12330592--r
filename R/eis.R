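#' Electrochemical impedance spectrum of one electrode
#'
#' @param electrode_id Identifier.
#' @param frequency Frequencies, Hz.
#' @param magnitude Impedance magnitude `|Z|`, ohms.
#' @param phase Impedance phase, degrees (capacitive phase negative).
#' @return An object of class `impedance_spectrum` with the derived real
#'   part `R = |Z| cos(theta)`.
#' @export
impedance_spectrum <- function(electrode_id, frequency, magnitude, phase) {
  stopifnot(length(frequency) == length(magnitude),
            length(frequency) == length(phase),
            all(magnitude >= 0))
  structure(list(electrode_id = electrode_id,
                 frequency = as.numeric(frequency),
                 magnitude = as.numeric(magnitude),
                 phase = as.numeric(phase),
                 real_part = as.numeric(magnitude) * cos(phase * pi / 180)),
            class = "impedance_spectrum")
}

#' Johnson-Nyquist noise model
#'
#' @param temperature Absolute temperature, kelvin (default 300).
#' @param bandwidth Recording bandwidth, Hz (default 30 kHz, i.e. the
#'   sampling rate of a typical broadband electrophysiology front end).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(temperature = 300, bandwidth = 30000) {
  stopifnot(temperature > 0, bandwidth > 0)
  structure(list(temperature = temperature, bandwidth = bandwidth,
                 boltzmann = 1.380649e-23),
            class = "noise_model")
}

#' Disc electrode geometry
#'
#' @param diameter Electrode diameter, micrometers.
#' @return An object of class `electrode_geometry` with the geometric
#'   surface area (GSA) in cm^2 and um^2.
#' @export
electrode_geometry <- function(diameter) {
  stopifnot(diameter > 0)
  gsa_um2 <- pi * (diameter / 2)^2
  structure(list(diameter = diameter,
                 gsa_um2 = gsa_um2,
                 gsa_cm2 = gsa_um2 * 1e-8),
            class = "electrode_geometry")
}

#' Impedance from the reference voltage and counter current
#'
#' Two-point impedance of the electrode-electrolyte interface,
#' `Z = V_ref / I_c`. Accepts complex or real inputs; with magnitudes in,
#' the magnitude comes out.
#'
#' @param reference_voltage Reference-electrode voltage, volts.
#' @param counter_current Counter-electrode current, amperes (non-zero).
#' @return Impedance, ohms (complex if the inputs are complex).
#' @examples
#' impedance_from_vi(1e-3, 1e-6)   # 1 kOhm
#' @export
impedance_from_vi <- function(reference_voltage, counter_current) {
  if (any(counter_current == 0))
    stop("counter_current must be non-zero (division by zero)")
  reference_voltage / counter_current
}

#' Thermal (Johnson) noise of a resistive electrode
#'
#' `V_rms = sqrt(4 kB T R df)` with `R` the real part of the electrode
#' impedance.
#'
#' @param real_part Real part of the impedance, ohms (>= 0).
#' @param model A [noise_model()].
#' @return RMS noise voltage, volts.
#' @examples
#' thermal_noise_rms(1e4, noise_model())   # ~2.23 uVrms
#' @export
thermal_noise_rms <- function(real_part, model = noise_model()) {
  stopifnot(inherits(model, "noise_model"))
  if (any(real_part < 0)) stop("real_part must be non-negative")
  sqrt(4 * model$boltzmann * model$temperature * real_part * model$bandwidth)
}

#' Theoretical signal-to-noise ratio in decibels
#'
#' `SNR_dB = 20 log10(V_signal / V_noise_rms)`.
#'
#' @param signal_amplitude Signal amplitude, volts.
#' @param noise_rms RMS noise, volts (> 0).
#' @return SNR in dB.
#' @export
snr_db <- function(signal_amplitude, noise_rms) {
  if (any(noise_rms <= 0)) stop("noise_rms must be positive")
  20 * log10(signal_amplitude / noise_rms)
}

# |Z| of one spectrum at (or nearest, within rel. tolerance) a frequency
magnitude_at <- function(spectrum, frequency, tol = 0.01) {
  i <- which.min(abs(spectrum$frequency - frequency))
  if (abs(spectrum$frequency[i] - frequency) > tol * frequency)
    stop(sprintf("frequency %g Hz not present in spectrum '%s' (nearest: %g)",
                 frequency, spectrum$electrode_id, spectrum$frequency[i]))
  spectrum$magnitude[i]
}

#' Population summary of electrode impedances at one frequency
#'
#' Mean, sample (n-1) standard deviation and coefficient of variation of
#' `|Z|` across electrodes, looked up at the nearest grid frequency within
#' a 1% relative tolerance.
#'
#' @param spectra A list of [impedance_spectrum()] objects.
#' @param frequency Query frequency, Hz.
#' @return A list with `mean`, `sd`, `cv`, `n` (ohms; `cv` is unit-free).
#' @export
impedance_summary <- function(spectra, frequency) {
  if (inherits(spectra, "impedance_spectrum")) spectra <- list(spectra)
  if (length(spectra) == 0) stop("empty spectrum set")
  z <- vapply(spectra, magnitude_at, numeric(1), frequency = frequency)
  m <- mean(z)
  s <- if (length(z) > 1) stats::sd(z) else 0
  list(mean = m, sd = s, cv = s / m, n = length(z))
}

#' Electroplating deposition charge cutoff
#'
#' Charge limit used to terminate electrodeposition of a conductive polymer
#' coating, `density x GSA`, with a default density of 1 uC/um^2.
#'
#' @param geometry An [electrode_geometry()].
#' @param density Areal charge density, uC/um^2 (> 0).
#' @return A list with `charge_uc` (exact) and `charge_uc_truncated`
#'   (integer report, truncated toward zero).
#' @examples
#' deposition_charge_cutoff(electrode_geometry(40))   # 1256.64 -> 1256 uC
#' @export
deposition_charge_cutoff <- function(geometry, density = 1) {
  stopifnot(inherits(geometry, "electrode_geometry"))
  if (density <= 0) stop("density must be positive")
  q <- density * geometry$gsa_um2
  list(charge_uc = q, charge_uc_truncated = trunc(q))
}

#' Fraction of working channels in an array
#'
#' A channel counts as working when its 1 kHz impedance magnitude lies
#' inside configurable bounds (default 1 kOhm to 1 MOhm; open or shorted
#' channels fall outside). The bounds are a toolkit convention, not a
#' universal standard.
#'
#' @param spectra A list of [impedance_spectrum()] objects.
#' @param frequency Frequency used for the criterion, Hz.
#' @param bounds Closed `[low, high]` magnitude bounds, ohms.
#' @param criterion Optional function(spectrum) -> logical overriding the
#'   bounds-based rule.
#' @return Fraction of working channels in [0, 1].
#' @export
channel_yield <- function(spectra, frequency = 1000,
                          bounds = c(1e3, 1e6), criterion = NULL) {
  if (inherits(spectra, "impedance_spectrum")) spectra <- list(spectra)
  if (length(spectra) == 0) stop("empty spectrum set")
  ok <- if (is.null(criterion)) {
    vapply(spectra, function(s) {
      z <- magnitude_at(s, frequency)
      z >= bounds[1] && z <= bounds[2]
    }, logical(1))
  } else {
    vapply(spectra, criterion, logical(1))
  }
  mean(ok)
}
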