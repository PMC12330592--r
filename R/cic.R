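#' Electrochemical water window
#'
#' Potential bounds within which water is not electrolyzed at the electrode
#' surface. The defaults are the bounds commonly used for PEDOT:PSS-coated
#' electrodes (-0.9 V to 0.6 V); compliance uses the closed interval.
#'
#' @param lower Lower (cathodic) bound, volts.
#' @param upper Upper (anodic) bound, volts.
#' @return An object of class `water_window`.
#' @export
water_window <- function(lower = -0.9, upper = 0.6) {
  stopifnot(lower < upper)
  structure(list(lower = lower, upper = upper), class = "water_window")
}

#' Central finite difference derivative
#'
#' Interior points use `(f[i+1] - f[i-1]) / (2 dx)` (exact for quadratics);
#' the endpoints use one-sided differences.
#'
#' @param series Sampled values (length >= 3).
#' @param step Uniform sampling step.
#' @return Derivative estimate, same length as `series`.
#' @export
central_difference <- function(series, step) {
  n <- length(series)
  if (n < 3) stop("need at least 3 samples")
  stopifnot(step > 0)
  d <- numeric(n)
  d[2:(n - 1)] <- (series[3:n] - series[1:(n - 2)]) / (2 * step)
  d[1] <- (series[2] - series[1]) / step
  d[n] <- (series[n] - series[n - 1]) / step
  d
}

#' Detect current-pulse edges in a voltage transient
#'
#' Edges are located where the magnitude of the central-difference
#' derivative exceeds an adaptive threshold (by default 10x the median
#' absolute derivative of the pre-pulse baseline; for noise-free synthetic
#' traces whose baseline derivative is exactly zero, 10% of the peak
#' derivative is used instead). Contiguous supra-threshold runs are merged
#' into single edges; the reported index `i` is the last pre-step sample,
#' i.e. the step lies between samples `i` and `i + 1`.
#'
#' @param trace A `voltage_transient` (from [simulate_transient()] or
#'   [read_transient()]).
#' @param threshold_factor Multiple of the baseline median absolute
#'   derivative used as the adaptive threshold component.
#' @param steep_fraction Fraction of the peak absolute derivative a sample
#'   must additionally reach; this separates the near-instantaneous access
#'   steps from the slower intra-pulse interface charging (the detection
#'   precondition is that edges are steeper than the intra-pulse
#'   dynamics).
#' @return A data.frame with `index`, `time` (time of the first post-step
#'   sample) and `step` (signed voltage step across the edge).
#' @export
detect_pulse_edges <- function(trace, threshold_factor = 10,
                               steep_fraction = 0.3) {
  v <- trace$voltage
  dt <- trace$time[2] - trace$time[1]
  d <- central_difference(v, dt)
  peak <- max(abs(d))
  if (peak == 0) stop("no pulses found")
  thr <- steep_fraction * peak
  hot <- abs(d) > thr
  # raise the threshold if the pre-pulse baseline derivative calls for it
  first_hot <- which(hot)[1]
  if (first_hot > 20) {
    med_b <- stats::median(abs(d[1:(first_hot - 2)]))
    thr <- max(thr, threshold_factor * med_b)
    if (thr >= peak) thr <- steep_fraction * peak
    hot <- abs(d) > thr
  }
  if (!any(hot)) stop("no pulses found")
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  idx <- integer(0)
  dv <- diff(v)
  for (r in which(runs$values)) {
    a <- max(1, starts[r] - 1)
    b <- min(length(dv), ends[r])
    m <- a + which.max(abs(dv[a:b])) - 1L
    idx <- c(idx, m)
  }
  idx <- unique(idx)
  data.frame(index = idx, time = trace$time[idx + 1], step = dv[idx])
}

#' Estimate the initial polarization bias (pre-pulse baseline)
#'
#' Mean of the samples in `[window_start, first_onset)`; subtracting this
#' value re-references the transient to zero bias.
#'
#' @param trace A `voltage_transient`.
#' @param first_onset Time of the first pulse onset, seconds; defaults to
#'   the trace's recorded onset or the first detected edge.
#' @param window_start Start of the baseline window, seconds.
#' @return Baseline mean, volts.
#' @export
estimate_eipp <- function(trace, first_onset = NULL, window_start = 0) {
  if (is.null(first_onset)) {
    first_onset <- if (!is.null(trace$first_onset)) trace$first_onset
                   else detect_pulse_edges(trace)$time[1]
  }
  sel <- trace$time >= window_start & trace$time < first_onset
  if (sum(sel) < 10) stop("baseline window contains fewer than 10 samples")
  mean(trace$voltage[sel])
}

#' Isolate the electrode-electrolyte interface voltage
#'
#' Removes the bias and the near-instantaneous access-voltage steps from a
#' raw transient. Each detected edge contributes a step measured between
#' the samples flanking it (a guard of `guard` samples on each side);
#' subtracting the running sum of steps leaves the continuous interface
#' polarization, whose extrema are the minimum cathodic (`emc`) and maximum
#' anodic (`ema`) interface potentials.
#'
#' @param trace A `voltage_transient`.
#' @param edges Edge table from [detect_pulse_edges()]; detected if `NULL`.
#' @param eipp Polarization bias, volts; estimated if `NULL`.
#' @param guard Samples skipped on each side of an edge when measuring the
#'   step (default 1: the immediately flanking samples).
#' @param cathodic_first Logical; whether the first phase is cathodic
#'   (taken from the trace's pulse train when available).
#' @return A `transient_analysis`: list with `eipp`,
#'   `access_voltage_cathodic`, `access_voltage_anodic`,
#'   `interface_voltage`, `time`, `emc`, `ema`, `edges`.
#' @export
isolate_interface_voltage <- function(trace, edges = NULL, eipp = NULL,
                                      guard = 1, cathodic_first = NULL) {
  if (is.null(edges)) edges <- detect_pulse_edges(trace)
  if (is.null(eipp)) eipp <- estimate_eipp(trace)
  if (is.null(cathodic_first))
    cathodic_first <- if (!is.null(trace$train)) trace$train$cathodic_first else TRUE
  n <- length(trace$voltage)
  v0 <- trace$voltage - eipp
  idx <- edges$index
  if (!is.null(trace$train) &&
      length(idx) != 4L * trace$train$pulses_per_burst)
    stop("detected edges inconsistent with the pulse train")
  a <- pmax(idx - (guard - 1L), 1L)
  b <- pmin(idx + 1L + (guard - 1L), n)
  steps <- v0[b] - v0[a]
  corr <- numeric(n)
  for (k in seq_along(idx)) corr[(idx[k] + 1L):n] <- corr[(idx[k] + 1L):n] + steps[k]
  vue <- v0 - corr
  # onset edges: 1st (leading phase) and 3rd (trailing phase) of each pulse
  n_edges <- length(idx)
  onset1 <- seq(1L, n_edges, by = 4L)
  onset2 <- seq(3L, n_edges, by = 4L)
  onset2 <- onset2[onset2 <= n_edges]
  va1 <- mean(abs(steps[onset1]))
  va2 <- if (length(onset2)) mean(abs(steps[onset2])) else NA_real_
  structure(list(eipp = eipp,
                 access_voltage_cathodic = if (cathodic_first) va1 else va2,
                 access_voltage_anodic = if (cathodic_first) va2 else va1,
                 interface_voltage = vue,
                 time = trace$time,
                 emc = min(vue),
                 ema = max(vue),
                 edges = edges),
            class = "transient_analysis")
}

#' Water-window compliance of a transient analysis
#'
#' Compliant iff `lower <= Emc` and `Ema <= upper` (closed interval).
#' Margins are signed distances to the bounds (negative = violation).
#'
#' @param analysis A `transient_analysis`.
#' @param window A [water_window()].
#' @return List with `compliant`, `margin_low`, `margin_high` (volts).
#' @export
check_water_window <- function(analysis, window = water_window()) {
  stopifnot(inherits(analysis, "transient_analysis"),
            inherits(window, "water_window"))
  list(compliant = analysis$emc >= window$lower && analysis$ema <= window$upper,
       margin_low = analysis$emc - window$lower,
       margin_high = window$upper - analysis$ema)
}

#' Charge-injection capacity
#'
#' `Q_inj = I * pw_c / GSA`, reported in mC/cm^2.
#'
#' @param current Current amplitude, amperes (> 0).
#' @param cathodic_width Cathodic phase width, seconds (> 0).
#' @param geometry An [electrode_geometry()].
#' @return Charge-injection capacity, mC/cm^2.
#' @examples
#' charge_injection_capacity(50e-6, 0.6e-3, electrode_geometry(40)) # 2.387
#' @export
charge_injection_capacity <- function(current, cathodic_width, geometry) {
  stopifnot(inherits(geometry, "electrode_geometry"))
  if (current <= 0 || cathodic_width <= 0) stop("inputs must be positive")
  if (geometry$gsa_cm2 <= 0) stop("zero GSA")
  (current * cathodic_width / geometry$gsa_cm2) * 1e3
}

#' Current ramp to the maximum water-window-compliant amplitude
#'
#' Runs the full transient-analysis pipeline at each amplitude (either by
#' simulating through `simulator` or on supplied traces), checks
#' water-window compliance, and reports the charge-injection capacity at
#' the largest compliant amplitude.
#'
#' @param simulator_or_traces Either a function `(train) -> voltage_transient`
#'   or a list of `voltage_transient` objects of the same length as
#'   `amplitudes`.
#' @param train_template A [pulse_train()] whose amplitude is swept.
#' @param amplitudes Strictly increasing current amplitudes, amperes.
#' @param window A [water_window()].
#' @param geometry An [electrode_geometry()].
#' @return A `cic_result`: list with `max_safe_current`,
#'   `charge_injection_capacity` (mC/cm^2), `analysis_at_max`,
#'   `none_compliant` and a per-amplitude data.frame `sweep`.
#' @export
cic_ramp <- function(simulator_or_traces, train_template, amplitudes,
                     window = water_window(), geometry) {
  if (length(amplitudes) == 0) stop("empty amplitude list")
  if (any(diff(amplitudes) <= 0)) stop("amplitudes must be strictly increasing")
  get_trace <- if (is.function(simulator_or_traces)) {
    function(k) {
      tr <- train_template
      tr$amplitude <- amplitudes[k]
      simulator_or_traces(tr)
    }
  } else {
    stopifnot(length(simulator_or_traces) == length(amplitudes))
    function(k) simulator_or_traces[[k]]
  }
  analyses <- vector("list", length(amplitudes))
  rows <- lapply(seq_along(amplitudes), function(k) {
    an <- isolate_interface_voltage(get_trace(k))
    analyses[[k]] <<- an
    cw <- check_water_window(an, window)
    data.frame(amplitude = amplitudes[k], emc = an$emc, ema = an$ema,
               compliant = cw$compliant)
  })
  sweep <- do.call(rbind, rows)
  ok <- which(sweep$compliant)
  if (length(ok) == 0) {
    return(structure(list(max_safe_current = NA_real_,
                          charge_injection_capacity = NA_real_,
                          analysis_at_max = NULL,
                          none_compliant = TRUE, sweep = sweep),
                     class = "cic_result"))
  }
  k <- max(ok)
  structure(list(max_safe_current = amplitudes[k],
                 charge_injection_capacity = charge_injection_capacity(
                   amplitudes[k], train_template$cathodic_pulse_width, geometry),
                 analysis_at_max = analyses[[k]],
                 none_compliant = FALSE, sweep = sweep),
            class = "cic_result")
}
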