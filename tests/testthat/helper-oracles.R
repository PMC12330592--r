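# Independent oracles used across the suite.

# Closed-form phase-by-phase recursion for the interface voltage of a
# series-RC interface (alpha = 1) driven by a piecewise-constant current:
# v(t + d) = v e^(-d/tau) + i R (1 - e^(-d/tau)). Returns the interface
# voltage extrema over a charge-balanced cathodic-first burst.
rc_burst_extrema <- function(amplitude, rs, rct, cap, pw, gap,
                             n_pulses, pulse_freq) {
  tau <- rct * cap
  stepv <- function(v, i, d) v * exp(-d / tau) + i * rct * (1 - exp(-d / tau))
  period <- 1 / pulse_freq
  v <- 0
  vmin <- 0; vmax <- 0
  for (p in seq_len(n_pulses)) {
    v <- stepv(v, -amplitude, pw)          # cathodic phase (monotone down)
    vmin <- min(vmin, v)
    v <- stepv(v, 0, gap)
    v <- stepv(v, amplitude, pw)           # anodic phase (monotone up)
    vmax <- max(vmax, v)
    if (p < n_pulses) v <- stepv(v, 0, period - 2 * pw - gap)
  }
  list(emc = vmin, ema = vmax)
}

# Monte-Carlo rasterization of the blocked fraction of a layout: uniform
# random points over the window disc, point-in-feature tests done with
# plain distance checks and pracma::inpolygon (independent of the
# scanline-union implementation).
mc_blocked_fraction <- function(layout, n_points, ignore_below = 0) {
  rw <- layout$window_diameter / 2
  r <- rw * sqrt(stats::runif(n_points))
  th <- stats::runif(n_points, 0, 2 * pi)
  px <- r * cos(th); py <- r * sin(th)
  blocked <- rep(FALSE, n_points)
  el <- layout$electrodes
  if (!is.null(el)) {
    for (k in seq_len(nrow(el))) {
      blocked <- blocked |
        ((px - el$x[k])^2 + (py - el$y[k])^2 < (el$diameter[k] / 2000)^2)
    }
  }
  seg_d2 <- function(x1, y1, x2, y2) {
    ux <- x2 - x1; uy <- y2 - y1
    l2 <- ux^2 + uy^2
    tt <- pmin(pmax(((px - x1) * ux + (py - y1) * uy) / l2, 0), 1)
    (px - x1 - tt * ux)^2 + (py - y1 - tt * uy)^2
  }
  for (tr in layout$traces) {
    if (tr$width <= ignore_below) next
    for (s in seq_len(length(tr$x) - 1)) {
      blocked <- blocked |
        (seg_d2(tr$x[s], tr$y[s], tr$x[s + 1], tr$y[s + 1]) <
           (tr$width / 2000)^2)
    }
  }
  for (tp in layout$tapers) {
    blocked <- blocked | pracma::inpolygon(px, py, tp[, 1], tp[, 2])
  }
  mean(blocked)
}

# random layout generator for the optics property tests: electrodes spread
# over the window with radial traces routed to the rim
random_layout <- function(n_electrodes = 24, window_diameter = 20,
                          electrode_um = 40, trace_um = 30) {
  rw <- window_diameter / 2
  ang <- stats::runif(n_electrodes, 0, 2 * pi)
  rad <- sqrt(stats::runif(n_electrodes)) * rw * 0.8
  el <- data.frame(x = rad * cos(ang), y = rad * sin(ang),
                   diameter = electrode_um)
  traces <- lapply(seq_len(n_electrodes), function(k) {
    d <- sqrt(el$x[k]^2 + el$y[k]^2)
    if (d < 1e-6) {
      list(x = c(0, rw * 0.95), y = c(0, 0), width = trace_um)
    } else {
      list(x = c(el$x[k], el$x[k] / d * rw * 0.95),
           y = c(el$y[k], el$y[k] / d * rw * 0.95),
           width = trace_um)
    }
  })
  layout_spec(window_diameter, electrodes = el, traces = traces)
}

# match detected event times to planted times within a tolerance; returns
# the number of true positives (one-to-one greedy matching)
count_matches <- function(detected, planted, tol = 1e-3) {
  used <- rep(FALSE, length(planted))
  tp <- 0
  for (d in detected) {
    j <- which(!used & abs(planted - d) < tol)
    if (length(j)) {
      used[j[1]] <- TRUE
      tp <- tp + 1
    }
  }
  tp
}
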