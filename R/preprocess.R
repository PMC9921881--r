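#' Remove the leading pre-trial baseline
#'
#' Drops the first \code{round(baseline_s * fs)} samples. The baseline is
#' discarded outright, not used for baseline correction.
#'
#' @param x numeric sample vector.
#' @param fs sampling rate in Hz.
#' @param baseline_s baseline duration in seconds; \code{baseline_s * fs}
#'   should be a whole number of samples.
#' @return The trimmed sample vector (e.g. 8064 samples at 128 Hz with a
#'   3 s baseline become 7680).
#' @export
drop_baseline <- function(x, fs, baseline_s) {
  nb <- round(baseline_s * fs)
  if (abs(nb - baseline_s * fs) > 1e-8) {
    warning("baseline_s * fs is not an integer; rounding to ", nb, " samples")
  }
  if (nb > length(x)) {
    stop("baseline of ", nb, " samples exceeds series length ", length(x))
  }
  if (nb < 0) stop("baseline_s must be non-negative")
  if (nb == 0) x else x[-seq_len(nb)]
}

#' Prefrontal difference signal
#'
#' Element-wise \code{a - b}; with the canonical pair this is Fp1 minus Fp2
#' (left minus right), the asymmetry signal on which all features are
#' computed. Every implemented feature is invariant to the sign of the
#' signal, so the order convention only affects stored intermediates.
#'
#' @param a,b numeric sample vectors of equal length.
#' @return Numeric vector \code{a - b}.
#' @export
channel_difference <- function(a, b) {
  if (length(a) != length(b)) {
    stop("channel length mismatch: ", length(a), " vs ", length(b))
  }
  a - b
}

#' Timeslot specification
#'
#' A half-open time window \code{[t0, t1)} in seconds, measured after
#' baseline removal. Presets follow the three 20 s thirds of a one-minute
#' trial plus the full minute.
#'
#' @param name one of \code{"first20"} (0-20 s), \code{"middle20"}
#'   (20-40 s), \code{"last20"} (40-60 s), \code{"full60"} (0-60 s) or
#'   \code{"custom"}.
#' @param t0,t1 window bounds in seconds, required for \code{"custom"}.
#' @return An object of class \code{"timeslot_spec"}.
#' @export
timeslot_spec <- function(name = c("full60", "first20", "middle20", "last20",
                                   "custom"),
                          t0 = NULL, t1 = NULL) {
  name <- match.arg(name)
  bounds <- switch(name,
                   first20 = c(0, 20), middle20 = c(20, 40),
                   last20 = c(40, 60), full60 = c(0, 60),
                   custom = c(t0, t1))
  if (name == "custom" && (is.null(t0) || is.null(t1))) {
    stop("custom timeslot needs t0 and t1")
  }
  if (length(bounds) != 2L || !(bounds[1] >= 0 && bounds[1] < bounds[2])) {
    stop("timeslot must satisfy 0 <= t0 < t1")
  }
  structure(list(name = name, t0 = bounds[1], t1 = bounds[2]),
            class = "timeslot_spec")
}

#' Extract a timeslot from a sample series
#'
#' Returns samples with 0-based indices in \code{[round(t0 * fs),
#' round(t1 * fs))}; the half-open convention makes the three 20 s presets
#' an exact partition of the 60 s trial.
#'
#' @param x numeric sample vector (post-baseline).
#' @param fs sampling rate in Hz.
#' @param slot a \code{\link{timeslot_spec}} (or preset name).
#' @return The windowed sample vector.
#' @export
extract_timeslot <- function(x, fs, slot = timeslot_spec("full60")) {
  if (is.character(slot)) slot <- timeslot_spec(slot)
  stopifnot(inherits(slot, "timeslot_spec"))
  i0 <- round(slot$t0 * fs)
  i1 <- round(slot$t1 * fs)
  if (i1 > length(x)) {
    stop("timeslot [", slot$t0, ", ", slot$t1, ") s exceeds series of ",
         length(x) / fs, " s")
  }
  x[(i0 + 1L):i1]
}
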