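as_samples <- function(x) {
  if (inherits(x, "band_signal")) x$samples else as.numeric(x)
}

pop_var <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}

#' Hjorth parameters
#'
#' Time-domain descriptors of a signal \code{y}: activity is the
#' (population) variance; mobility is \code{sqrt(var(dy) / var(y))}, a
#' dominant-frequency proxy; complexity is \code{mobility(dy) /
#' mobility(y)}, equal to 1 for a pure sinusoid and larger for less
#' sinusoid-like signals. The derivative is approximated by the unscaled
#' first-difference sequence \code{d[n] = y[n+1] - y[n]}; the omitted
#' \code{fs} factor cancels in complexity and rescales mobility by a
#' dataset-wide constant that downstream standardization removes. For a
#' sampled sinusoid of frequency \code{f} the mobility is exactly
#' \code{2 * sin(pi * f / fs)}.
#'
#' @param x numeric sample vector or \code{band_signal}.
#' @return Named numeric vector \code{c(activity, mobility, complexity)};
#'   for a constant signal, activity is 0 and mobility/complexity are
#'   \code{NA} (undefined, not an error).
#' @examples
#' y <- 2 * sin(2 * pi * 10 * (0:7679) / 128)
#' hjorth_params(y) # activity ~ 2, mobility ~ 2 sin(pi 10/128), complexity ~ 1
#' @export
hjorth_params <- function(x) {
  y <- as_samples(x)
  if (length(y) < 3L) stop("Hjorth parameters need at least 3 samples")
  a0 <- pop_var(y)
  if (a0 == 0) {
    return(c(activity = 0, mobility = NA_real_, complexity = NA_real_))
  }
  d1 <- diff(y)
  d2 <- diff(d1)
  a1 <- pop_var(d1)
  a2 <- pop_var(d2)
  mob <- sqrt(a1 / a0)
  cmp <- if (a1 == 0) NA_real_ else sqrt(a2 / a1) / mob
  c(activity = a0, mobility = mob, complexity = cmp)
}

#' Zero-crossing count
#'
#' Number of strict sign reversals of the sample sequence. A zero sample
#' inherits the most recent nonzero sign (leading zeros are ignored), so
#' sinusoids that hit exact grid zeros are counted deterministically.
#'
#' @param x numeric sample vector or \code{band_signal}.
#' @return Integer count (0 for an all-zero signal).
#' @examples
#' zero_crossings(c(1, -1, 1, -1)) # 3
#' zero_crossings(c(1, 0, -1))     # 1
#' @export
zero_crossings <- function(x) {
  y <- as_samples(x)
  if (length(y) < 2L) stop("zero_crossings needs at least 2 samples")
  s <- sign(y)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0L)
}

#' Total spectral power (PSD feature)
#'
#' Mean signal power from the DFT: \code{sum(|X(k)|^2) / N^2} over all
#' bins of the un-windowed signal, which by Parseval's theorem equals the
#' mean square \code{mean(y^2)}. The mean is not subtracted: band-passed
#' signals are zero-mean by construction, so the DC bin contributes
#' nothing, and for such signals this feature coincides with Hjorth
#' activity.
#'
#' @param x numeric sample vector or \code{band_signal}.
#' @return Mean power in uV^2.
#' @export
psd_total_power <- function(x) {
  y <- as_samples(x)
  if (length(y) < 2L) stop("psd_total_power needs at least 2 samples")
  sum(Mod(stats::fft(y))^2) / length(y)^2
}

#' Names of the per-band features
#'
#' @return Character vector: \code{activity}, \code{mobility},
#'   \code{complexity}, \code{zero_crossings}, \code{psd}.
#' @export
feature_names <- function() {
  c("activity", "mobility", "complexity", "zero_crossings", "psd")
}

band_feature_row <- function(y, fs, bands, order = 3L) {
  out <- numeric(0)
  for (b in bands) {
    bs <- apply_bandpass(y, fs, b, order = order)
    h <- hjorth_params(bs)
    v <- c(h, zero_crossings = as.numeric(zero_crossings(bs)),
           psd = psd_total_power(bs))
    names(v) <- paste(b$name, feature_names(), sep = "_")
    out <- c(out, v)
  }
  out
}

#' Extract the per-trial feature table
#'
#' The canonical pipeline, per trial: drop the baseline from both channels,
#' form the prefrontal difference signal, window it to the requested
#' timeslot, band-pass it into each requested band, and compute the five
#' features. Differencing precedes filtering; the two commute for linear
#' filters.
#'
#' @param archive a \code{\link{trial_archive}}.
#' @param pair two channel labels, difference taken first minus second
#'   (default \code{c("Fp1", "Fp2")}).
#' @param bands list of \code{\link{band_def}} (default: all eight
#'   \code{\link{eeg_bands}}).
#' @param slot a \code{\link{timeslot_spec}} or preset name (default
#'   \code{"full60"}).
#' @param order Butterworth prototype order.
#' @return A data.frame with columns \code{subject_id}, \code{trial},
#'   \code{rating_valence} (if ratings are present) and one
#'   \code{{band}_{feature}} column per band and feature
#'   (\code{n_trials x (5 * n_bands)} feature columns).
#' @export
extract_features <- function(archive, pair = c("Fp1", "Fp2"),
                             bands = eeg_bands(),
                             slot = timeslot_spec("full60"),
                             order = 3L) {
  stopifnot(inherits(archive, "trial_archive"))
  if (is.character(slot)) slot <- timeslot_spec(slot)
  if (inherits(bands, "band_def")) bands <- list(bands)
  ch <- channel_pair(archive, pair[1], pair[2])
  has_val <- "valence" %in% archive$dimension_names
  rows <- vector("list", archive$n_trials)
  for (t in seq_len(archive$n_trials)) {
    res <- tryCatch({
      a <- drop_baseline(ch$a[t, ], archive$fs, archive$baseline_s)
      b <- drop_baseline(ch$b[t, ], archive$fs, archive$baseline_s)
      y <- extract_timeslot(channel_difference(a, b), archive$fs, slot)
      band_feature_row(y, archive$fs, bands, order)
    }, error = function(e) {
      stop("trial ", t, ": ", conditionMessage(e), call. = FALSE)
    })
    rows[[t]] <- res
  }
  feat <- do.call(rbind, rows)
  out <- data.frame(subject_id = archive$subject_id,
                    trial = seq_len(archive$n_trials),
                    stringsAsFactors = FALSE)
  if (has_val) out$rating_valence <- valence_ratings(archive)
  cbind(out, as.data.frame(feat))
}

#' Select feature columns of a feature table
#'
#' @param features a table from \code{\link{extract_features}}.
#' @param bands band names (character).
#' @param feats feature names (subset of \code{\link{feature_names}}).
#' @return Numeric matrix of the requested \code{{band}_{feature}} columns.
#' @export
feature_matrix <- function(features, bands, feats) {
  cols <- as.vector(outer(bands, feats, paste, sep = "_"))
  missing <- setdiff(cols, names(features))
  if (length(missing)) {
    stop("feature table lacks columns: ", paste(missing, collapse = ", "))
  }
  as.matrix(features[, cols, drop = FALSE])
}
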