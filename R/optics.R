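#' Optical layer
#'
#' @param name Layer name.
#' @param refractive_index Refractive index `n` (>= 1).
#' @param thickness Thickness, micrometers (optional; semi-infinite media
#'   such as air or tissue may omit it).
#' @param absorption Optional Beer-Lambert absorption coefficient, 1/um.
#' @return An object of class `optical_layer`.
#' @export
optical_layer <- function(name, refractive_index, thickness = NA_real_,
                          absorption = 0) {
  stopifnot(refractive_index >= 1)
  structure(list(name = name, n = refractive_index,
                 thickness = thickness, absorption = absorption),
            class = "optical_layer")
}

#' Spectrometer reading
#'
#' @param wavelength Wavelengths, nm, strictly increasing.
#' @param counts Detector counts (arbitrary units).
#' @param kind One of `"dark"`, `"reference"`, `"sample"`.
#' @return An object of class `spectrum_reading`.
#' @export
spectrum_reading <- function(wavelength, counts,
                             kind = c("sample", "reference", "dark")) {
  kind <- match.arg(kind)
  stopifnot(length(wavelength) == length(counts), all(diff(wavelength) > 0))
  structure(list(wavelength = as.numeric(wavelength),
                 counts = as.numeric(counts), kind = kind),
            class = "spectrum_reading")
}

#' Normal-incidence Fresnel reflectance at a refractive-index step
#'
#' `R = ((n1 - n2) / (n1 + n2))^2`. For a polymer window (n = 1.64)
#' against air this is 5.88%; against water/CSF (n = 1.33) only 1.09% --
#' the reason a device reads as more transparent once implanted.
#'
#' @param n1,n2 Refractive indices of the two media (>= 1).
#' @return Reflected power fraction in [0, 1).
#' @examples
#' fresnel_reflectance(1.64, 1.00) * 100   # 5.88
#' fresnel_reflectance(1.64, 1.33) * 100   # 1.09
#' @export
fresnel_reflectance <- function(n1, n2) {
  stopifnot(all(n1 >= 1), all(n2 >= 1))
  ((n1 - n2) / (n1 + n2))^2
}

#' Incoherent transmission through a layered stack
#'
#' Product of `(1 - R)` over the successive interfaces of the stack,
#' deliberately neglecting multiple partial reflections (no Fabry-Perot
#' etalon terms), plus optional Beer-Lambert attenuation for layers that
#' carry an absorption coefficient and a thickness.
#'
#' @param layers List of [optical_layer()] objects, ordered entry to exit.
#' @return Transmitted power fraction in (0, 1].
#' @examples
#' air <- optical_layer("air", 1.0)
#' par <- optical_layer("parylene", 1.64, thickness = 10)
#' wat <- optical_layer("water", 1.33)
#' stack_transmission(list(air, par, wat))   # 0.9309
#' @export
stack_transmission <- function(layers) {
  stopifnot(all(vapply(layers, inherits, logical(1), "optical_layer")))
  if (length(layers) < 2) return(1.0)
  tr <- 1.0
  for (k in seq_len(length(layers) - 1)) {
    tr <- tr * (1 - fresnel_reflectance(layers[[k]]$n, layers[[k + 1]]$n))
  }
  for (l in layers) {
    if (l$absorption > 0 && is.finite(l$thickness))
      tr <- tr * exp(-l$absorption * l$thickness)
  }
  tr
}

#' Dark/reference/sample spectrometer processing
#'
#' `T(lambda) = (sample - dark) / (reference - dark)`, after linear
#' interpolation of the dark and reference readings onto the sample grid.
#' Wavelengths where the dark-corrected reference is not positive are
#' masked (`NA`) with a warning.
#'
#' @param dark,reference,sample [spectrum_reading()] objects.
#' @param range Optional reporting range `c(min, max)` in nm.
#' @return data.frame with `wavelength` (nm) and `transmission`.
#' @export
process_spectra <- function(dark, reference, sample, range = NULL) {
  stopifnot(inherits(dark, "spectrum_reading"),
            inherits(reference, "spectrum_reading"),
            inherits(sample, "spectrum_reading"))
  wl <- sample$wavelength
  d <- stats::approx(dark$wavelength, dark$counts, xout = wl, rule = 2)$y
  r <- stats::approx(reference$wavelength, reference$counts, xout = wl, rule = 2)$y
  denom <- r - d
  tr <- (sample$counts - d) / denom
  bad <- denom <= 0
  if (any(bad)) {
    warning(sprintf("%d wavelengths masked (reference does not exceed dark)",
                    sum(bad)))
    tr[bad] <- NA_real_
  }
  out <- data.frame(wavelength = wl, transmission = tr)
  if (!is.null(range)) out <- out[wl >= range[1] & wl <= range[2], ]
  out
}

#' Array layout on a circular optical window
#'
#' Geometry is in millimeters with the origin at the window center;
#' electrode diameters and trace widths are in micrometers. Traces are
#' polylines rendered as capsules (rectangles with round caps/joins), so
#' that a point is opaque iff it lies within half a width of the polyline.
#'
#' @param window_diameter Window diameter, mm.
#' @param electrodes data.frame with columns `x`, `y` (mm) and
#'   `diameter` (um); may be `NULL`.
#' @param traces List of polylines, each a list with numeric `x`, `y` (mm)
#'   and scalar `width` (um); may be `NULL`.
#' @param tapers List of polygons (trapezoids), each a two-column matrix of
#'   vertices in mm; may be `NULL`.
#' @return An object of class `layout_spec`.
#' @export
layout_spec <- function(window_diameter, electrodes = NULL, traces = NULL,
                        tapers = NULL) {
  stopifnot(window_diameter > 0)
  if (!is.null(electrodes)) {
    stopifnot(all(c("x", "y", "diameter") %in% names(electrodes)),
              all(electrodes$diameter > 0))
  }
  if (!is.null(traces)) {
    for (tr in traces) {
      stopifnot(length(tr$x) == length(tr$y), length(tr$x) >= 2, tr$width > 0)
    }
  }
  if (!is.null(tapers)) {
    for (tp in tapers) stopifnot(ncol(tp) == 2, nrow(tp) >= 3)
  }
  structure(list(window_diameter = window_diameter,
                 electrodes = electrodes, traces = traces, tapers = tapers),
            class = "layout_spec")
}

# Decompose a layout into primitive opaque features (units: mm).
# Returns list(circles = data.frame(cx, cy, r), polys = list of matrices).
layout_features <- function(layout, ignore_traces_narrower_than = 0) {
  circles <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0))
  polys <- list()
  el <- layout$electrodes
  if (!is.null(el) && nrow(el) > 0) {
    circles <- rbind(circles,
                     data.frame(cx = el$x, cy = el$y, r = el$diameter / 2000))
  }
  for (tr in layout$traces %||% list()) {
    if (tr$width <= ignore_traces_narrower_than) next
    hw <- tr$width / 2000
    for (s in seq_len(length(tr$x) - 1)) {
      p <- c(tr$x[s], tr$y[s]); q <- c(tr$x[s + 1], tr$y[s + 1])
      u <- q - p
      len <- sqrt(sum(u^2))
      if (len == 0) next
      nrm <- c(-u[2], u[1]) / len * hw
      polys[[length(polys) + 1]] <-
        rbind(p + nrm, q + nrm, q - nrm, p - nrm)
    }
    circles <- rbind(circles,
                     data.frame(cx = tr$x, cy = tr$y, r = hw))
  }
  for (tp in layout$tapers %||% list()) {
    polys[[length(polys) + 1]] <- tp
  }
  list(circles = circles, polys = polys)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# x-crossings of a polygon's boundary with horizontal lines at heights ys.
# Even-odd rule with a half-open [ymin, ymax) edge convention; returns a
# data.frame(yi, x) of crossings.
poly_crossings <- function(poly, ys) {
  nv <- nrow(poly)
  out_yi <- integer(0); out_x <- numeric(0)
  for (e in seq_len(nv)) {
    p1 <- poly[e, ]; p2 <- poly[if (e == nv) 1 else e + 1, ]
    if (p1[2] == p2[2]) next
    ylo <- min(p1[2], p2[2]); yhi <- max(p1[2], p2[2])
    sel <- which(ys >= ylo & ys < yhi)
    if (!length(sel)) next
    x <- p1[1] + (ys[sel] - p1[2]) * (p2[1] - p1[1]) / (p2[2] - p1[2])
    out_yi <- c(out_yi, sel); out_x <- c(out_x, x)
  }
  data.frame(yi = out_yi, x = out_x)
}

#' Optical access of an array layout
#'
#' Fraction of the circular window not blocked by opaque features
#' (electrodes, metal traces, trace-to-electrode tapers). The blocked area
#' is the area of the *union* of all features intersected with the window
#' disc (overlaps counted once), computed by exact per-scanline interval
#' union and trapezoidal integration across scanlines. Features extending
#' beyond the window are clipped with a warning. Traces whose width is at
#' or below `ignore_traces_narrower_than` are excluded, which models thin
#' traces that are effectively transparent to an imaging system focused
#' below the device.
#'
#' @param layout A [layout_spec()].
#' @param ignore_traces_narrower_than Width threshold, um; traces with
#'   `width <= threshold` are treated as transparent (default 0: none).
#' @param n_scanlines Number of scanlines used for the area integration.
#' @return List with `blocked_fraction`, `access_percent`,
#'   `blocked_area_mm2` and `window_area_mm2`.
#' @export
optical_access <- function(layout, ignore_traces_narrower_than = 0,
                           n_scanlines = 4001) {
  stopifnot(inherits(layout, "layout_spec"))
  rw <- layout$window_diameter / 2
  feats <- layout_features(layout, ignore_traces_narrower_than)
  window_area <- pi * rw^2
  # warn once if any feature leaves the window disc
  outside <- FALSE
  if (nrow(feats$circles) > 0) {
    d <- sqrt(feats$circles$cx^2 + feats$circles$cy^2) + feats$circles$r
    outside <- outside || any(d > rw + 1e-12)
  }
  for (p in feats$polys) {
    if (any(sqrt(p[, 1]^2 + p[, 2]^2) > rw + 1e-12)) outside <- TRUE
  }
  if (outside) warning("features extend beyond the window disc; clipped")

  if (nrow(feats$circles) == 0 && length(feats$polys) == 0) {
    return(list(blocked_fraction = 0, access_percent = 100,
                blocked_area_mm2 = 0, window_area_mm2 = window_area))
  }

  ys <- seq(-rw, rw, length.out = n_scanlines)
  dy <- ys[2] - ys[1]
  # gather candidate intervals (yi, x1, x2) from every feature
  yi_all <- integer(0); x1_all <- numeric(0); x2_all <- numeric(0)
  cc <- feats$circles
  for (k in seq_len(nrow(cc))) {
    h2 <- cc$r[k]^2 - (ys - cc$cy[k])^2
    sel <- which(h2 > 0)
    if (!length(sel)) next
    h <- sqrt(h2[sel])
    yi_all <- c(yi_all, sel)
    x1_all <- c(x1_all, cc$cx[k] - h)
    x2_all <- c(x2_all, cc$cx[k] + h)
  }
  for (p in feats$polys) {
    cr <- poly_crossings(p, ys)
    if (!nrow(cr)) next
    o <- order(cr$yi, cr$x)
    cr <- cr[o, ]
    # pair successive crossings per scanline (even-odd rule)
    runs <- rle(cr$yi)
    pos <- cumsum(runs$lengths) - runs$lengths
    for (r in seq_along(runs$values)) {
      m <- runs$lengths[r]
      if (m < 2) next
      xs <- cr$x[pos[r] + seq_len(m)]
      np <- m %/% 2
      yi_all <- c(yi_all, rep(runs$values[r], np))
      x1_all <- c(x1_all, xs[2 * seq_len(np) - 1])
      x2_all <- c(x2_all, xs[2 * seq_len(np)])
    }
  }

  blocked <- numeric(n_scanlines)
  if (length(yi_all)) {
    chord <- sqrt(pmax(rw^2 - ys^2, 0))
    o <- order(yi_all, x1_all)
    yi_all <- yi_all[o]; x1_all <- x1_all[o]; x2_all <- x2_all[o]
    bounds <- c(0, which(diff(yi_all) > 0), length(yi_all))
    for (g in seq_len(length(bounds) - 1)) {
      sel <- (bounds[g] + 1):bounds[g + 1]
      yi <- yi_all[sel[1]]
      lo <- pmax(x1_all[sel], -chord[yi])
      hi <- pmin(x2_all[sel], chord[yi])
      keep <- hi > lo
      if (!any(keep)) next
      lo <- lo[keep]; hi <- hi[keep]
      # union of sorted intervals
      tot <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
      if (length(lo) > 1) {
        for (j in 2:length(lo)) {
          if (lo[j] > cur_hi) {
            tot <- tot + (cur_hi - cur_lo)
            cur_lo <- lo[j]; cur_hi <- hi[j]
          } else if (hi[j] > cur_hi) cur_hi <- hi[j]
        }
      }
      blocked[yi] <- tot + (cur_hi - cur_lo)
    }
  }
  area <- sum((blocked[-1] + blocked[-n_scanlines]) / 2) * dy
  frac <- area / window_area
  list(blocked_fraction = frac,
       access_percent = 100 * (1 - frac),
       blocked_area_mm2 = area,
       window_area_mm2 = window_area)
}
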