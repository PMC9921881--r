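#' EEG frequency band definition
#'
#' @param name band name.
#' @param lo,hi passband edges in Hz, \code{0 < lo < hi}; \code{hi} must
#'   stay below the Nyquist frequency of any signal the band is applied to.
#' @return An object of class \code{"band_def"}.
#' @export
band_def <- function(name, lo, hi) {
  if (!is.character(name) || length(name) != 1L) stop("name must be a string")
  if (!(is.finite(lo) && is.finite(hi) && lo > 0 && lo < hi)) {
    stop("band edges must satisfy 0 < lo < hi (got ", lo, ", ", hi, ")")
  }
  structure(list(name = name, lo = lo, hi = hi), class = "band_def")
}

#' @export
print.band_def <- function(x, ...) {
  cat("<band> ", x$name, ": ", x$lo, "-", x$hi, " Hz\n", sep = "")
  invisible(x)
}

#' Canonical EEG rhythm bands
#'
#' The five classical rhythms -- delta (2-4 Hz), theta (4-8), alpha (8-12),
#' beta (12-30), gamma (30-60) -- plus the three gamma subbands: slow
#' (30-40), mid (40-50) and fast (50-60 Hz). The delta low edge is 2 Hz,
#' matching the band table this pipeline standardizes on.
#'
#' @return Named list of \code{\link{band_def}} objects.
#' @examples
#' names(eeg_bands())
#' eeg_bands()$alpha
#' @export
eeg_bands <- function() {
  defs <- list(delta = c(2, 4), theta = c(4, 8), alpha = c(8, 12),
               beta = c(12, 30), gamma = c(30, 60),
               slow_gamma = c(30, 40), mid_gamma = c(40, 50),
               fast_gamma = c(50, 60))
  mapply(function(nm, e) band_def(nm, e[1], e[2]), names(defs), defs,
         SIMPLIFY = FALSE)
}

#' Design a Butterworth band-pass filter
#'
#' Digital Butterworth band-pass with -3 dB points exactly at \code{lo} and
#' \code{hi} (bilinear transform with prewarping) and monotone magnitude in
#' both stopbands.
#'
#' @param band a \code{\link{band_def}}.
#' @param fs sampling rate in Hz; \code{band$hi} must be below \code{fs/2}.
#' @param order analog prototype order (default 3; the band-pass transfer
#'   function has twice that order).
#' @return A \code{signal::Arma} coefficient object (elements \code{b},
#'   \code{a}).
#' @export
design_bandpass <- function(band, fs, order = 3L) {
  stopifnot(inherits(band, "band_def"))
  if (order < 1L) stop("filter order must be >= 1")
  nyq <- fs / 2
  if (band$hi >= nyq) {
    stop("band '", band$name, "' upper edge ", band$hi,
         " Hz is at or above the Nyquist frequency ", nyq, " Hz")
  }
  if (band$lo <= 0) stop("band lower edge must be positive")
  signal::butter(order, c(band$lo, band$hi) / nyq, type = "pass")
}

#' Magnitude response of a digital filter
#'
#' @param flt coefficients from \code{\link{design_bandpass}}.
#' @param f frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @return \code{|H(f)|} at each frequency.
#' @export
filter_gain <- function(flt, f, fs) {
  z <- exp(1i * 2 * pi * f / fs)
  horner <- function(p, x) {
    s <- rep(0 + 0i, length(x))
    for (c in p) s <- s * x + c
    s
  }
  abs(horner(rev(flt$b), z) / horner(rev(flt$a), z))
}

# Zero-phase forward-backward filtering with odd-reflection padding of
# 3 * n_coef samples at both ends to suppress edge transients.
filtfilt_reflect <- function(flt, x) {
  p <- 3L * max(length(flt$b), length(flt$a))
  n <- length(x)
  if (n <= p) {
    stop("series of ", n, " samples is too short to band-pass filter ",
         "(needs > ", p, ")")
  }
  xs <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- as.numeric(signal::filter(flt, xs))
  y <- rev(as.numeric(signal::filter(flt, rev(y))))
  y[(p + 1):(p + n)]
}

#' Band-pass filter a sample series
#'
#' Applies the Butterworth design forward and backward (zero phase, squared
#' magnitude response, effective 6th-order roll-off at the default order)
#' and returns a band-limited signal of the same length.
#'
#' @param x numeric sample vector.
#' @param fs sampling rate in Hz.
#' @param band a \code{\link{band_def}} (or a name from
#'   \code{\link{eeg_bands}}).
#' @param order analog prototype order (default 3).
#' @param provenance optional free-form metadata (channel, timeslot, ...).
#' @return An object of class \code{"band_signal"}: list with
#'   \code{samples}, \code{fs}, \code{band}, \code{provenance}.
#' @examples
#' x <- sin(2 * pi * 10 * (0:1279) / 128)
#' bs <- apply_bandpass(x, 128, eeg_bands()$alpha)
#' var(bs$samples) / var(x) # close to 1: 10 Hz is mid-alpha
#' @export
apply_bandpass <- function(x, fs, band, order = 3L, provenance = list()) {
  if (is.character(band)) {
    bands <- eeg_bands()
    if (!band %in% names(bands)) {
      stop("unknown band '", band, "'; known: ",
           paste(names(bands), collapse = ", "))
    }
    band <- bands[[band]]
  }
  flt <- design_bandpass(band, fs, order)
  y <- filtfilt_reflect(flt, as.numeric(x))
  structure(list(samples = y, fs = fs, band = band, provenance = provenance),
            class = "band_signal")
}

#' @export
print.band_signal <- function(x, ...) {
  cat("<band_signal> ", x$band$name, " (", x$band$lo, "-", x$band$hi,
      " Hz), ", length(x$samples), " samples @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}
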