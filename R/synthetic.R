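#' Synthetic affective-EEG cohort specification
#'
#' Conditions for generating cohorts with the statistical structure the
#' valence pipeline assumes: two prefrontal channels built as sums of
#' band-limited Gaussian noise sharing a common (symmetric) component plus
#' an antisymmetric component, with a class-dependent variance boost of
#' the antisymmetric component in one target band. The difference signal
#' Fp1 - Fp2 cancels the common component and retains twice the
#' antisymmetric one, so the planted high/low variance ratio appears
#' exactly where the pipeline measures it.
#'
#' @param n_subjects subjects in the cohort.
#' @param n_trials trials per subject (default 40).
#' @param fs sampling rate in Hz (default 128).
#' @param duration_s trial duration in seconds including the baseline
#'   (default 63).
#' @param baseline_s leading baseline in seconds (default 3).
#' @param band_amplitudes per-band RMS of the common component in uV
#'   (defaults delta 20, theta 15, alpha 10, beta 8, gamma 5 -- a typical
#'   low-frequency-dominant scalp spectrum).
#' @param asym_fraction RMS of the antisymmetric component as a fraction
#'   of the band amplitude (default 0.3).
#' @param effect_band band carrying the class effect (default
#'   \code{"alpha"}).
#' @param effect_ratio high/low class variance ratio of the effect band in
#'   the difference signal; must be >= 1 (1 = null cohort).
#' @param rating_model \code{c(low_mean, high_mean, sd)} of the truncated
#'   normal generating ratings on the 1-9 scale (default 3, 7, 1, so
#'   strongest-trial selection and a threshold-5 split agree).
#' @param subject_variability lognormal sdlog of per-subject multiplicative
#'   band-amplitude factors, drawn once per subject (default 0.1).
#' @param noise_rms per-channel white sensor noise RMS in uV (default 2).
#' @param seed cohort master seed.
#' @return An object of class \code{"sim_spec"}.
#' @export
sim_spec <- function(n_subjects = 32L, n_trials = 40L, fs = 128,
                     duration_s = 63, baseline_s = 3,
                     band_amplitudes = c(delta = 20, theta = 15, alpha = 10,
                                         beta = 8, gamma = 5),
                     asym_fraction = 0.3,
                     effect_band = "alpha", effect_ratio = 2,
                     rating_model = c(low_mean = 3, high_mean = 7, sd = 1),
                     subject_variability = 0.1, noise_rms = 2,
                     seed = 1L) {
  if (effect_ratio < 1) stop("effect_ratio must be >= 1")
  if (fs <= 0 || duration_s <= 0 || baseline_s < 0) {
    stop("fs and durations must be positive")
  }
  if (n_trials < 2L) stop("need at least 2 trials")
  if (!effect_band %in% names(band_amplitudes)) {
    stop("effect_band '", effect_band, "' is not among band_amplitudes: ",
         paste(names(band_amplitudes), collapse = ", "))
  }
  known <- names(eeg_bands())
  unknown <- setdiff(names(band_amplitudes), known)
  if (length(unknown)) {
    stop("unknown bands in band_amplitudes: ",
         paste(unknown, collapse = ", "))
  }
  rating_model <- as.numeric(rating_model)
  if (length(rating_model) != 3L || rating_model[3] <= 0) {
    stop("rating_model must be c(low_mean, high_mean, sd) with sd > 0")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials),
                 fs = fs, duration_s = duration_s, baseline_s = baseline_s,
                 band_amplitudes = band_amplitudes,
                 asym_fraction = asym_fraction,
                 effect_band = effect_band, effect_ratio = effect_ratio,
                 rating_model = rating_model,
                 subject_variability = subject_variability,
                 noise_rms = noise_rms, seed = as.integer(seed)),
            class = "sim_spec")
}

# unit-RMS band-limited Gaussian noise
band_noise <- function(n, fs, band) {
  y <- apply_bandpass(stats::rnorm(n), fs, band)$samples
  y / sqrt(mean(y^2))
}

rtruncnorm_19 <- function(n, mean, sd) {
  pmin(pmax(stats::rnorm(n, mean, sd), 1), 9)
}

#' Generate one synthetic subject
#'
#' Trials are balanced between the low and high class (extra trial to the
#' low class when odd), in seeded random order. Ratings come from the
#' class's truncated normal. Channels: \code{Fp1 = sum_b(common_b +
#' antisym_b) + noise}, \code{Fp2 = sum_b(common_b - antisym_b) + noise};
#' the antisymmetric effect-band amplitude is scaled by
#' \code{sqrt(effect_ratio)} on high-class trials.
#'
#' @param spec a \code{\link{sim_spec}}.
#' @param subject_seed integer seed for this subject's generator.
#' @param subject_id identifier for the returned archive.
#' @return A two-channel \code{\link{trial_archive}} (montage Fp1, Fp2)
#'   with an extra element \code{sim_classes}, the ground-truth class
#'   factor.
#' @export
generate_subject <- function(spec, subject_seed = spec$seed,
                             subject_id = "S01") {
  stopifnot(inherits(spec, "sim_spec"))
  n <- round(spec$duration_s * spec$fs)
  bands <- eeg_bands()[names(spec$band_amplitudes)]
  withr::with_seed(subject_seed, {
    mult <- stats::rlnorm(length(bands), 0, spec$subject_variability)
    names(mult) <- names(bands)
    n_low <- ceiling(spec$n_trials / 2)
    classes <- sample(rep(c("low", "high"),
                          c(n_low, spec$n_trials - n_low)))
    ratings <- ifelse(classes == "low",
                      rtruncnorm_19(spec$n_trials, spec$rating_model[1],
                                    spec$rating_model[3]),
                      rtruncnorm_19(spec$n_trials, spec$rating_model[2],
                                    spec$rating_model[3]))
    data <- array(NA_real_, c(spec$n_trials, 2L, n))
    for (t in seq_len(spec$n_trials)) {
      fp1 <- numeric(n)
      fp2 <- numeric(n)
      for (bn in names(bands)) {
        amp <- spec$band_amplitudes[[bn]] * mult[[bn]]
        common <- amp * band_noise(n, spec$fs, bands[[bn]])
        s_amp <- spec$asym_fraction * amp
        if (bn == spec$effect_band && classes[t] == "high") {
          s_amp <- s_amp * sqrt(spec$effect_ratio)
        }
        antisym <- s_amp * band_noise(n, spec$fs, bands[[bn]])
        fp1 <- fp1 + common + antisym
        fp2 <- fp2 + common - antisym
      }
      data[t, 1L, ] <- fp1 + spec$noise_rms * stats::rnorm(n)
      data[t, 2L, ] <- fp2 + spec$noise_rms * stats::rnorm(n)
    }
  })
  out <- trial_archive(data, matrix(ratings, ncol = 1), montage(c("Fp1", "Fp2")),
                       fs = spec$fs, baseline_s = spec$baseline_s,
                       subject_id = subject_id,
                       dimension_names = "valence")
  out$sim_classes <- factor(classes, levels = c("low", "high"))
  out
}

#' Derive a subject seed from the cohort seed
#'
#' Splitting rule: \code{(seed * 48271 + index * 1299721) mod (2^31 - 1)},
#' keeping every derived seed a valid 32-bit integer.
#'
#' @param seed cohort master seed.
#' @param index 1-based subject index.
#' @return Integer seed.
#' @export
derive_subject_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 1299721) %%
               2147483647)
}

#' Generate a synthetic cohort
#'
#' One archive per subject, each generated from its own derived seed (see
#' \code{\link{derive_subject_seed}}); no global RNG state is consumed, so
#' cohorts are bit-identical across runs and safe to generate in parallel.
#'
#' @param spec a \code{\link{sim_spec}}.
#' @return List of \code{\link{trial_archive}} objects named
#'   \code{S01 ... Snn}.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(sim_spec(n_subjects = 2, n_trials = 4,
#'                                    duration_s = 7, baseline_s = 1))
#' length(cohort)
#' }
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  ids <- sprintf("S%02d", seq_len(spec$n_subjects))
  out <- lapply(seq_len(spec$n_subjects), function(i) {
    generate_subject(spec, derive_subject_seed(spec$seed, i), ids[i])
  })
  names(out) <- ids
  out
}
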