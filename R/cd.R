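# Circular dichroism: unit conversion, point-by-point difference spectra
# (mixture minus components), and a transparent single-wavelength helix
# estimator. Units are explicit tags: "mdeg" (raw rotatory power in
# millidegrees) and "mre" (mean residue ellipticity, deg cm^2 dmol^-1).

#' Construct a CD spectrum
#'
#' @param wavelength nm grid, strictly ascending.
#' @param signal per-wavelength values.
#' @param unit `"mdeg"` (rotatory power, millidegrees) or `"mre"` (mean
#'   residue ellipticity).
#' @param conc molar protein concentration (metadata, needed for unit
#'   conversion).
#' @param path_cm cuvette path length in cm.
#' @param n_residues number of residues (for the per-residue normalization
#'   and the helix estimator).
#' @return a `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelength, signal, unit = c("mdeg", "mre"),
                        conc = NULL, path_cm = NULL, n_residues = NULL) {
  unit <- match.arg(unit)
  stopifnot(length(wavelength) == length(signal),
            all(diff(wavelength) > 0), all(is.finite(signal)))
  structure(list(wavelength = wavelength, signal = signal, unit = unit,
                 conc = conc, path_cm = path_cm, n_residues = n_residues),
            class = "cd_spectrum")
}

#' Convert millidegrees to mean residue ellipticity (and back)
#'
#' `[theta]_MRW = theta_mdeg / (10 c l N)` with molar concentration `c`,
#' path length `l` in cm and `N` residues; [to_millidegrees()] is the exact
#' inverse.
#'
#' @param s a `cd_spectrum` with complete metadata.
#' @return a `cd_spectrum` in the other unit.
#' @export
to_mean_residue_ellipticity <- function(s) {
  stopifnot(inherits(s, "cd_spectrum"))
  if (s$unit != "mdeg") stop("spectrum is not in millidegrees")
  if (is.null(s$conc) || is.null(s$path_cm) || is.null(s$n_residues))
    stop("conversion requires concentration, path length and residue count")
  cd_spectrum(s$wavelength,
              s$signal / (10 * s$conc * s$path_cm * s$n_residues),
              "mre", s$conc, s$path_cm, s$n_residues)
}

#' @rdname to_mean_residue_ellipticity
#' @export
to_millidegrees <- function(s) {
  stopifnot(inherits(s, "cd_spectrum"))
  if (s$unit != "mre") stop("spectrum is not in mean residue ellipticity")
  if (is.null(s$conc) || is.null(s$path_cm) || is.null(s$n_residues))
    stop("conversion requires concentration, path length and residue count")
  cd_spectrum(s$wavelength,
              s$signal * (10 * s$conc * s$path_cm * s$n_residues),
              "mdeg", s$conc, s$path_cm, s$n_residues)
}

# Pointwise combination on the overlap of two grids; the second spectrum is
# linearly interpolated onto the first one's grid.
.cd_combine <- function(a, b, op, meta_from = a) {
  stopifnot(inherits(a, "cd_spectrum"), inherits(b, "cd_spectrum"))
  if (a$unit != b$unit)
    stop("unit mismatch: '", a$unit, "' vs '", b$unit, "'")
  lo <- max(min(a$wavelength), min(b$wavelength))
  hi <- min(max(a$wavelength), max(b$wavelength))
  if (lo > hi) stop("wavelength ranges do not overlap")
  keep <- a$wavelength >= lo & a$wavelength <= hi
  wl <- a$wavelength[keep]
  bi <- stats::approx(b$wavelength, b$signal, xout = wl)$y
  cd_spectrum(wl, op(a$signal[keep], bi), a$unit,
              meta_from$conc, meta_from$path_cm, meta_from$n_residues)
}

#' Point-by-point difference of CD spectra
#'
#' Subtracts `subtrahend` from `minuend` over their overlapping wavelength
#' range, linearly interpolating the subtrahend onto the minuend's grid.
#' Both spectra must carry the same unit tag.
#'
#' @param minuend,subtrahend `cd_spectrum`s.
#' @return a `cd_spectrum` on the overlap.
#' @export
cd_difference <- function(minuend, subtrahend)
  .cd_combine(minuend, subtrahend, `-`)

#' Point-by-point sum of CD spectra
#'
#' @param a,b `cd_spectrum`s with common unit; `b` is interpolated onto
#'   `a`'s grid over the overlap.
#' @return a `cd_spectrum`.
#' @export
cd_sum <- function(a, b) .cd_combine(a, b, `+`)

#' Scale a CD spectrum
#'
#' Pure vertical amplification (preserves zero crossings), as used to
#' display small difference traces.
#'
#' @param s a `cd_spectrum`.
#' @param k scalar factor.
#' @return a `cd_spectrum`.
#' @export
cd_scale <- function(s, k) {
  stopifnot(inherits(s, "cd_spectrum"), length(k) == 1L, is.finite(k))
  cd_spectrum(s$wavelength, k * s$signal, s$unit, s$conc, s$path_cm,
              s$n_residues)
}

#' Binding-induced conformational changes from mixture and component spectra
#'
#' The difference-spectrum procedure: from the spectrum of an equimolar
#' mixture and the spectra of the two components alone,
#' `delta_a = (mixture - b_alone) - a_alone` isolates the change induced on
#' component A by complex formation, and symmetrically for B. By
#' construction the two traces are pointwise identical (both equal
#' `mixture - a_alone - b_alone`); a non-interacting pair gives a zero
#' trace.
#'
#' @param mixture,a_alone,b_alone `cd_spectrum`s with a common unit.
#' @return list with `cd_spectrum`s `delta_a` and `delta_b`.
#' @export
complex_induced_changes <- function(mixture, a_alone, b_alone) {
  list(delta_a = cd_difference(cd_difference(mixture, b_alone), a_alone),
       delta_b = cd_difference(cd_difference(mixture, a_alone), b_alone))
}

# Limiting mean residue ellipticities at 222 nm used by the helix
# estimator: a fully helical chain of N residues and a coil at temperature
# T (deg C). Standard single-wavelength parameterization.
.theta_helix_222 <- function(n_residues) -39500 * (1 - 2.57 / n_residues)
.theta_coil_222 <- function(temperature) 2220 - 53 * temperature

#' Helix fraction from the 222 nm ellipticity
#'
#' Transparent single-wavelength estimator: the mean residue ellipticity at
#' 222 nm is interpolated from the spectrum and placed on the scale between
#' the coil limit `theta_C = 2220 - 53 T` and the length-corrected helix
#' limit `theta_H = -39500 (1 - 2.57/N)`; the fraction
#' `([theta]_222 - theta_C) / (theta_H - theta_C)` is clipped to `[0, 1]`.
#' This deliberately simple estimator replaces basis-set deconvolution
#' servers and is documented as such.
#'
#' @param s a `cd_spectrum` in mean residue ellipticity whose range covers
#'   222 nm, with `n_residues >= 2` in its metadata.
#' @param temperature degrees Celsius (default 25).
#' @return helix fraction in `[0, 1]`.
#' @export
helix_fraction_theta222 <- function(s, temperature = 25) {
  stopifnot(inherits(s, "cd_spectrum"))
  if (s$unit != "mre") stop("helix estimator needs mean residue ellipticity")
  if (is.null(s$n_residues) || s$n_residues < 2)
    stop("metadata must give a residue count >= 2")
  if (222 < min(s$wavelength) || 222 > max(s$wavelength))
    stop("222 nm is outside the spectral range")
  th222 <- stats::approx(s$wavelength, s$signal, xout = 222)$y
  thH <- .theta_helix_222(s$n_residues)
  thC <- .theta_coil_222(temperature)
  min(max((th222 - thC) / (thH - thC), 0), 1)
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat("CD spectrum [", x$unit, "]: ", min(x$wavelength), "-",
      max(x$wavelength), " nm, ", length(x$wavelength), " points\n",
      sep = "")
  invisible(x)
}
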