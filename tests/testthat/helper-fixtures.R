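# Shared fixture builders: everything is generated in code at test time.

# sampled sinusoid, amplitude A, frequency f Hz, duration in seconds
sinusoid <- function(f, fs = 128, dur = 60, A = 1, phase = 0) {
  A * sin(2 * pi * f * (0:(round(fs * dur) - 1)) / fs + phase)
}

# minimal two-channel archive from explicit per-channel trial matrices
two_channel_archive <- function(fp1, fp2, fs = 128, baseline_s = 0,
                                ratings = NULL, subject_id = "T01") {
  fp1 <- rbind(fp1); fp2 <- rbind(fp2)
  n_trials <- nrow(fp1)
  data <- array(NA_real_, c(n_trials, 2L, ncol(fp1)))
  data[, 1L, ] <- fp1
  data[, 2L, ] <- fp2
  if (is.null(ratings)) ratings <- rep(5, n_trials)
  trial_archive(data, matrix(ratings, ncol = 1),
                montage(c("Fp1", "Fp2")), fs = fs, baseline_s = baseline_s,
                subject_id = subject_id, dimension_names = "valence")
}

# small fast synthetic spec for cohort-level tests: short trials, fewer
# subjects; band structure and rating model kept at the package defaults
small_spec <- function(n_subjects = 4, n_trials = 12, effect_ratio = 3,
                       seed = 11, duration_s = 11, baseline_s = 1, ...) {
  sim_spec(n_subjects = n_subjects, n_trials = n_trials,
           duration_s = duration_s, baseline_s = baseline_s,
           effect_ratio = effect_ratio, seed = seed, ...)
}

short_slot <- function(dur = 10) timeslot_spec("custom", 0, dur)

# exhaustive-distance kNN oracle, independent of the implementation:
# recomputes all distances, sorts with explicit tie rules, counts votes
knn_oracle <- function(train_x, train_y, query, k) {
  train_x <- as.matrix(train_x)
  d <- apply(train_x, 1, function(r) sqrt(sum((r - query)^2)))
  ord <- order(d, seq_along(d))
  nb <- as.character(train_y)[ord[1:k]]
  counts <- sapply(unique(nb), function(l) sum(nb == l))
  tied <- names(counts)[counts == max(counts)]
  if (length(tied) == 1) return(tied)
  for (l in nb) if (l %in% tied) return(l)
}

# mean band power of a signal via an independent FFT (periodogram) oracle
fft_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * fs / n
  sum(p[(f >= lo & f <= hi) | (f >= fs - hi & f <= fs - lo)])
}
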