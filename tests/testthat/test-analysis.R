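# cohorts here are deliberately small/short; the full-scale study
# conditions are exercised in test-acceptance.R

test_that("band/feature analysis localizes a planted alpha effect", {
  cohort <- generate_cohort(small_spec(n_subjects = 4, n_trials = 20,
                                       effect_ratio = 4, seed = 101))
  cache <- cohort_features(cohort, eeg_bands()[1:5], slot = short_slot(10))
  acc <- band_feature_analysis(cohort, bands = eeg_bands()[1:5],
                               slot = short_slot(10), cache = cache)
  expect_equal(dim(acc), c(5, 5))
  expect_equal(which.max(acc["activity", ]), c(alpha = 3))
  expect_equal(which.max(acc["psd", ]), c(alpha = 3))
  expect_gte(acc["activity", "alpha"], acc["mobility", "alpha"])
})

test_that("a zero-effect cohort stays inside the null chance band", {
  cohort <- generate_cohort(small_spec(n_subjects = 4, n_trials = 20,
                                       effect_ratio = 1, seed = 102))
  acc <- band_feature_analysis(cohort, bands = eeg_bands()[1:5],
                               features = c("activity", "psd"),
                               slot = short_slot(10))
  # simultaneous band over 10 cells: per-cell level 1 - 0.01/10
  band <- loocv_chance_band(c(8, 8), k = 5, n_subjects = 4,
                            level = 1 - 0.01 / 10)
  expect_true(all(acc >= band["lower"] & acc <= band["upper"]))
})

test_that("gamma subband analysis isolates a fast-gamma effect", {
  spec <- small_spec(n_subjects = 4, n_trials = 20, effect_ratio = 6,
                     seed = 103,
                     band_amplitudes = c(delta = 20, theta = 15, alpha = 10,
                                         beta = 8, fast_gamma = 5),
                     effect_band = "fast_gamma")
  cohort <- generate_cohort(spec)
  acc <- gamma_subband_analysis(cohort, slot = short_slot(10))
  expect_equal(dim(acc), c(2, 3))
  expect_equal(colnames(acc), c("slow_gamma", "mid_gamma", "fast_gamma"))
  # maximal cell (the 50 Hz crossover lets mid-gamma tie when saturated)
  expect_equal(acc["activity", "fast_gamma"], max(acc["activity", ]))
  expect_equal(acc["psd", "fast_gamma"], max(acc["psd", ]))
  expect_gt(acc["activity", "fast_gamma"], acc["activity", "slow_gamma"])
})

test_that("a uniform-in-time effect is best read from the full minute", {
  cohort <- generate_cohort(sim_spec(n_subjects = 3, n_trials = 16,
                                     effect_ratio = 1.5, seed = 104))
  acc <- timeslot_analysis(cohort, bands = eeg_bands()["alpha"])
  expect_equal(dim(acc), c(4, 2))
  for (sl in c("first20", "middle20", "last20")) {
    expect_gte(mean(acc["full60", ]), mean(acc[sl, ]))
  }
})

test_that("a middle-slot-only effect is best read from the middle slot", {
  set.seed(105)
  fs <- 128
  n <- 63 * fs
  mid <- 3 * fs + (20 * fs):(40 * fs - 1) + 1 # middle 20 s, post-baseline
  make_subject <- function(id) {
    n_tr <- 16
    classes <- sample(rep(c("low", "high"), each = 8))
    fp1 <- matrix(0, n_tr, n)
    fp2 <- matrix(0, n_tr, n)
    for (t in seq_len(n_tr)) {
      common <- 10 * apply_bandpass(rnorm(n), fs, eeg_bands()$alpha)$samples
      antis <- 3 * apply_bandpass(rnorm(n), fs, eeg_bands()$alpha)$samples
      if (classes[t] == "high") antis[mid] <- antis[mid] * sqrt(6)
      fp1[t, ] <- common + antis + rnorm(n)
      fp2[t, ] <- common - antis + rnorm(n)
    }
    ratings <- ifelse(classes == "high", pmin(9, rnorm(n_tr, 7, 0.5)),
                      pmax(1, rnorm(n_tr, 3, 0.5)))
    two_channel_archive(fp1, fp2, fs = fs, baseline_s = 3,
                        ratings = ratings, subject_id = id)
  }
  cohort <- list(make_subject("A"), make_subject("B"))
  acc <- timeslot_analysis(cohort, slots = c("first20", "middle20", "last20"),
                           bands = eeg_bands()["alpha"],
                           features = "activity")
  expect_gt(acc["middle20", 1], acc["first20", 1])
  expect_gt(acc["middle20", 1], acc["last20", 1])
})

test_that("evaluate_valence returns cohort means, per-subject table and methods", {
  cohort <- generate_cohort(small_spec(n_subjects = 3, n_trials = 12,
                                       effect_ratio = 4, seed = 106))
  cache <- cohort_features(cohort, list(eeg_bands()$alpha),
                           slot = short_slot(10))
  ev <- evaluate_valence(cohort, "binary", "knn",
                         bands = list(eeg_bands()$alpha),
                         slot = short_slot(10), cache = cache)
  expect_s3_class(ev, "valence_eval")
  expect_equal(dim(ev$mean_accuracy), c(3, 1))
  expect_equal(dim(ev$per_subject), c(3, 3, 1))
  expect_gte(ev$mean_accuracy["variance+psd", "alpha"], 75)
  tab <- summary(ev, feature_set = "variance+psd")
  expect_equal(nrow(tab), 4)
  expect_equal(tab$subject[4], "Average")
  expect_equal(tab$alpha[4],
               aggregate_cohort(ev$per_subject[, "variance+psd", "alpha"]))
  expect_output(print(ev), "Mean accuracy")

  # recomputation from the cached features equals recomputation from raw
  ev_raw <- evaluate_valence(cohort, "binary", "knn",
                             bands = list(eeg_bands()$alpha),
                             slot = short_slot(10))
  expect_identical(ev$mean_accuracy, ev_raw$mean_accuracy)
  expect_identical(ev$per_subject, ev_raw$per_subject)
})

test_that("three-class evaluation handles the neutral band", {
  spec <- small_spec(n_subjects = 2, n_trials = 18, effect_ratio = 4,
                     seed = 107,
                     rating_model = c(low_mean = 2.5, high_mean = 7.5,
                                      sd = 1.6))
  cohort <- generate_cohort(spec)
  ev <- evaluate_valence(cohort, "three_class", "knn",
                         bands = list(eeg_bands()$alpha),
                         feature_sets = list(variance = "activity"),
                         slot = short_slot(10))
  preds <- unlist(ev$predictions)
  expect_true(all(preds %in% c("low", "neutral", "high")))
  expect_equal(dim(ev$mean_accuracy), c(1, 1))
})

test_that("threshold sensitivity reports rating statistics and accuracies", {
  spec <- small_spec(n_subjects = 3, n_trials = 16, effect_ratio = 4,
                     seed = 108,
                     rating_model = c(low_mean = 4.5, high_mean = 6.9,
                                      sd = 1))
  cohort <- generate_cohort(spec)
  out <- threshold_sensitivity(cohort, thresholds = c(5, 6),
                               slot = short_slot(10))
  expect_equal(out$rating_stats$subject, c("S01", "S02", "S03", "all"))
  pooled <- unlist(lapply(cohort, valence_ratings))
  all_row <- out$rating_stats[out$rating_stats$subject == "all", ]
  expect_equal(all_row$median, median(pooled))
  expect_equal(all_row$mean, mean(pooled))
  expect_equal(all_row$sd, sqrt(mean((pooled - mean(pooled))^2)))
  # ratings centred near 6: the threshold-6 split aligns with the planted
  # classes, the threshold-5 split does not
  acc <- out$accuracy
  expect_gte(acc$cohort_mean[acc$threshold == 6],
             acc$cohort_mean[acc$threshold == 5])
})

test_that("boxplot summaries separate the classes on the effect band", {
  cohort <- generate_cohort(small_spec(n_subjects = 3, n_trials = 16,
                                       effect_ratio = 4, seed = 109))
  bx <- boxplot_summary(cohort, bands = list(eeg_bands()$alpha),
                        n_per_side = 8, slot = short_slot(10))
  expect_equal(names(bx), c("feature", "band", "class", "n", "min", "q1",
                            "median", "q3", "max"))
  act <- bx[bx$feature == "activity", ]
  expect_equal(sum(act$n), 16 * 3) # strongest mode bookkeeping
  hi <- act[act$class == "high", ]
  lo <- act[act$class == "low", ]
  pooled_iqr <- mean(c(hi$q3 - hi$q1, lo$q3 - lo$q1))
  expect_gt(abs(hi$median - lo$median), pooled_iqr / 2)
  expect_true(all(bx$min <= bx$q1 & bx$q1 <= bx$median &
                    bx$median <= bx$q3 & bx$q3 <= bx$max))
})
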