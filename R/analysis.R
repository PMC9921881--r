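#' Extract features for every subject of a cohort
#'
#' One shared feature-extraction pass; the returned list serves as a cache
#' for the analysis functions so band, timeslot and classifier comparisons
#' reuse identical features.
#'
#' @param cohort list of \code{\link{trial_archive}} objects.
#' @param bands list of \code{\link{band_def}}.
#' @param slot a \code{\link{timeslot_spec}} or preset name.
#' @param pair channel pair, difference first minus second.
#' @return Named list of per-subject feature tables
#'   (\code{\link{extract_features}} output).
#' @export
cohort_features <- function(cohort, bands = eeg_bands(),
                            slot = timeslot_spec("full60"),
                            pair = c("Fp1", "Fp2")) {
  stopifnot(length(cohort) >= 1L)
  out <- lapply(cohort, extract_features, pair = pair, bands = bands,
                slot = slot)
  names(out) <- vapply(cohort, function(a) a$subject_id, "")
  out
}

strongest_labels <- function(ft, n_per_side) {
  sel <- select_strongest(ft$rating_valence, n_per_side)
  list(rows = sel$index, labels = as.character(sel$labels))
}

#' Band/feature analysis on the strongest emotions
#'
#' For each subject, the \code{n_per_side} lowest- and highest-rated
#' trials are selected and labelled by selection side; each single
#' (feature, band) column is then evaluated with LOOCV kNN and the cohort
#' mean accuracy reported per cell.
#'
#' @param cohort list of \code{\link{trial_archive}} objects.
#' @param bands list of \code{\link{band_def}} (default: the five
#'   canonical rhythms).
#' @param features feature names to compare (default: all five).
#' @param k kNN neighbour count.
#' @param n_per_side strongest trials per side (default 8).
#' @param slot a \code{\link{timeslot_spec}} or preset name for feature
#'   extraction (default full minute).
#' @param cache optional \code{\link{cohort_features}} result computed
#'   with a band set covering \code{bands} at \code{slot}.
#' @return Accuracy matrix (percent), rows = features, columns = bands.
#' @export
band_feature_analysis <- function(cohort, bands = eeg_bands()[1:5],
                                  features = feature_names(), k = 5L,
                                  n_per_side = 8L,
                                  slot = timeslot_spec("full60"),
                                  cache = NULL) {
  if (is.null(cache)) cache <- cohort_features(cohort, bands, slot = slot)
  band_names <- unname(vapply(bands, function(b) b$name, ""))
  acc <- array(0, c(length(features), length(band_names), length(cache)),
               dimnames = list(features, band_names, NULL))
  cfg <- classifier_config("knn", k = k)
  for (s in seq_along(cache)) {
    ft <- cache[[s]]
    sel <- strongest_labels(ft, n_per_side)
    for (b in band_names) {
      for (f in features) {
        x <- feature_matrix(ft[sel$rows, , drop = FALSE], b, f)
        acc[f, b, s] <- loocv_evaluate(x, sel$labels, cfg)$accuracy
      }
    }
  }
  apply(acc, c(1, 2), mean)
}

#' Gamma subband analysis
#'
#' The band/feature analysis restricted to the three gamma subbands
#' (30-40, 40-50, 50-60 Hz), variance (activity) and PSD only.
#'
#' @inheritParams band_feature_analysis
#' @param subbands list of gamma subband \code{\link{band_def}}s.
#' @return Accuracy matrix, 2 features x 3 subbands.
#' @export
gamma_subband_analysis <- function(cohort,
                                   subbands = eeg_bands()[
                                     c("slow_gamma", "mid_gamma",
                                       "fast_gamma")],
                                   features = c("activity", "psd"),
                                   k = 5L, n_per_side = 8L,
                                   slot = timeslot_spec("full60"),
                                   cache = NULL) {
  band_feature_analysis(cohort, bands = subbands, features = features,
                        k = k, n_per_side = n_per_side, slot = slot,
                        cache = cache)
}

#' Timeslot analysis
#'
#' Variance and PSD accuracies on the strongest emotions when features
#' are computed from the first, middle or last 20 s of the trial versus
#' the full minute, for the retained bands.
#'
#' @inheritParams band_feature_analysis
#' @param slots timeslot preset names.
#' @param bands list of \code{\link{band_def}} (default delta, alpha,
#'   fast gamma).
#' @param features feature names (default variance and PSD).
#' @return Accuracy matrix, rows = slots, columns = \code{{band}_{feature}}.
#' @export
timeslot_analysis <- function(cohort,
                              slots = c("first20", "middle20", "last20",
                                        "full60"),
                              bands = eeg_bands()[c("delta", "alpha",
                                                    "fast_gamma")],
                              features = c("activity", "psd"),
                              k = 5L, n_per_side = 8L) {
  band_names <- unname(vapply(bands, function(b) b$name, ""))
  cols <- as.vector(outer(band_names, features, paste, sep = "_"))
  out <- matrix(NA_real_, length(slots), length(cols),
                dimnames = list(slots, cols))
  cfg <- classifier_config("knn", k = k)
  for (sl in slots) {
    cache <- cohort_features(cohort, bands, slot = sl)
    acc <- matrix(0, length(cache), length(cols),
                  dimnames = list(NULL, cols))
    for (s in seq_along(cache)) {
      ft <- cache[[s]]
      sel <- strongest_labels(ft, n_per_side)
      for (b in band_names) {
        for (f in features) {
          x <- feature_matrix(ft[sel$rows, , drop = FALSE], b, f)
          acc[s, paste(b, f, sep = "_")] <-
            loocv_evaluate(x, sel$labels, cfg)$accuracy
        }
      }
    }
    out[sl, ] <- colMeans(acc)
  }
  out
}

default_feature_sets <- function() {
  list(variance = "activity", psd = "psd",
       `variance+psd` = c("activity", "psd"))
}

#' Subject-dependent valence evaluation over a cohort
#'
#' The package's main evaluation: all trials of every subject are
#' labelled by the rating scheme, and each (feature set, band) cell is
#' scored per subject with leave-one-out cross-validation, then averaged
#' over subjects (unweighted). Subjects whose ratings fall entirely on
#' one side of the threshold are skipped with a warning (a
#' cross-validated accuracy is undefined for a one-class task).
#'
#' @param cohort list of \code{\link{trial_archive}} objects.
#' @param mode \code{"binary"} or \code{"three_class"} labelling.
#' @param classifier \code{"knn"} or \code{"svm_rbf"}.
#' @param bands list of \code{\link{band_def}} (default delta, alpha,
#'   fast gamma).
#' @param feature_sets named list of feature-name vectors (default:
#'   variance, psd, variance+psd).
#' @param scheme a \code{\link{label_scheme}} (default: built from
#'   \code{mode}).
#' @param config a \code{\link{classifier_config}} (default: built from
#'   \code{classifier}).
#' @param slot a \code{\link{timeslot_spec}} or preset name for feature
#'   extraction.
#' @param cache optional \code{\link{cohort_features}} result for these
#'   bands at \code{slot}.
#' @return An object of class \code{"valence_eval"} with components
#'   \code{mean_accuracy} (matrix feature sets x bands, percent, 2
#'   decimals), \code{per_subject} (3-d array subjects x sets x bands),
#'   \code{predictions}, \code{scheme}, \code{config}.
#' @export
evaluate_valence <- function(cohort,
                             mode = c("binary", "three_class"),
                             classifier = c("knn", "svm_rbf"),
                             bands = eeg_bands()[c("delta", "alpha",
                                                   "fast_gamma")],
                             feature_sets = default_feature_sets(),
                             scheme = NULL, config = NULL,
                             slot = timeslot_spec("full60"), cache = NULL) {
  mode <- match.arg(mode)
  classifier <- match.arg(classifier)
  if (is.null(scheme)) scheme <- label_scheme(mode)
  if (is.null(config)) config <- classifier_config(classifier)
  if (inherits(bands, "band_def")) bands <- list(bands)
  if (is.null(cache)) cache <- cohort_features(cohort, bands, slot = slot)
  band_names <- unname(vapply(bands, function(b) b$name, ""))
  set_names <- names(feature_sets)
  ids <- names(cache)
  acc <- array(NA_real_, c(length(ids), length(set_names),
                           length(band_names)),
               dimnames = list(ids, set_names, band_names))
  preds <- list()
  for (s in seq_along(cache)) {
    ft <- cache[[s]]
    labels <- apply_labels(ft$rating_valence, scheme)
    if (length(unique(as.character(labels))) < 2L) {
      warning("subject ", ids[s], " has a single class under this scheme; ",
              "skipped")
      next
    }
    for (b in band_names) {
      for (fs_name in set_names) {
        x <- feature_matrix(ft, b, feature_sets[[fs_name]])
        ev <- loocv_evaluate(x, labels, config)
        acc[s, fs_name, b] <- ev$accuracy
        preds[[paste(ids[s], fs_name, b, sep = ".")]] <- ev$predictions
      }
    }
  }
  mean_acc <- apply(acc, c(2, 3), function(v) {
    aggregate_cohort(v[!is.na(v)])
  })
  structure(list(mean_accuracy = mean_acc, per_subject = acc,
                 predictions = preds, scheme = scheme, config = config,
                 bands = band_names, feature_sets = feature_sets,
                 n_subjects = length(ids)),
            class = "valence_eval")
}

#' @export
print.valence_eval <- function(x, ...) {
  cat("<valence_eval> ", x$scheme$mode, " valence, ", x$config$kind,
      ", ", x$n_subjects, " subjects\n", sep = "")
  cat("Mean accuracy (%) by feature set and band:\n")
  print(round(x$mean_accuracy, 2))
  invisible(x)
}

#' Per-subject accuracy table of a valence evaluation
#'
#' @param object a \code{\link{evaluate_valence}} result.
#' @param feature_set which feature set to tabulate (default
#'   \code{"variance+psd"}).
#' @param ... unused.
#' @return A data.frame with one row per subject and one column per band,
#'   plus a final \code{Average} row of cohort aggregates.
#' @export
summary.valence_eval <- function(object, feature_set = "variance+psd",
                                 ...) {
  if (!feature_set %in% dimnames(object$per_subject)[[2]]) {
    stop("unknown feature set '", feature_set, "'")
  }
  tab <- object$per_subject[, feature_set, , drop = FALSE]
  tab <- matrix(tab, nrow = dim(object$per_subject)[1],
                dimnames = list(dimnames(object$per_subject)[[1]],
                                dimnames(object$per_subject)[[3]]))
  avg <- apply(tab, 2, function(v) aggregate_cohort(v[!is.na(v)]))
  out <- as.data.frame(rbind(tab, Average = avg))
  cbind(subject = rownames(out), out, row.names = NULL)
}

#' Boxplot of per-subject accuracies by band
#'
#' @param x a \code{\link{evaluate_valence}} result.
#' @param feature_set feature set to plot.
#' @param ... passed to \code{\link[graphics]{boxplot}}.
#' @method plot valence_eval
#' @export
plot.valence_eval <- function(x, feature_set = "variance+psd", ...) {
  tab <- x$per_subject[, feature_set, , drop = TRUE]
  if (is.null(dim(tab))) tab <- matrix(tab, ncol = length(x$bands),
                                       dimnames = list(NULL, x$bands))
  graphics::boxplot(as.data.frame(tab),
                    ylab = "per-subject LOOCV accuracy (%)",
                    xlab = "band", main = paste0("valence (", feature_set,
                                                 ", ", x$config$kind, ")"),
                    ...)
  invisible(x)
}

#' Rating-threshold sensitivity
#'
#' Rating statistics (median, mean, population SD) per listed subject and
#' pooled over the cohort, together with the binary evaluation re-run at
#' each threshold.
#'
#' @param cohort list of \code{\link{trial_archive}} objects.
#' @param subject_ids subjects to tabulate individually (default: all).
#' @param thresholds binary thresholds to compare (default 5 and 6).
#' @param band a single \code{\link{band_def}} (default alpha).
#' @param features feature set (default variance + psd).
#' @param config a \code{\link{classifier_config}} (default kNN).
#' @param slot a \code{\link{timeslot_spec}} or preset name.
#' @param cache optional \code{\link{cohort_features}} for \code{band}.
#' @return List with \code{rating_stats} (data.frame, one row per listed
#'   subject plus \code{"all"}) and \code{accuracy} (data.frame threshold
#'   x (cohort mean + listed subjects)).
#' @export
threshold_sensitivity <- function(cohort, subject_ids = NULL,
                                  thresholds = c(5, 6),
                                  band = eeg_bands()$alpha,
                                  features = c("activity", "psd"),
                                  config = classifier_config("knn"),
                                  slot = timeslot_spec("full60"),
                                  cache = NULL) {
  if (is.null(cache)) cache <- cohort_features(cohort, list(band), slot = slot)
  ids <- names(cache)
  if (is.null(subject_ids)) subject_ids <- ids
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  stat_row <- function(v) {
    data.frame(median = stats::median(v), mean = mean(v), sd = pop_sd(v))
  }
  all_ratings <- unlist(lapply(cache, function(ft) ft$rating_valence))
  rating_stats <- do.call(rbind, c(
    lapply(subject_ids, function(id) {
      cbind(subject = id, stat_row(cache[[id]]$rating_valence))
    }),
    list(cbind(subject = "all", stat_row(all_ratings)))))
  acc_rows <- lapply(thresholds, function(th) {
    per <- vapply(ids, function(id) {
      ft <- cache[[id]]
      labels <- binarize_valence(ft$rating_valence, th)
      if (length(unique(as.character(labels))) < 2L) return(NA_real_)
      x <- feature_matrix(ft, band$name, features)
      loocv_evaluate(x, labels, config)$accuracy
    }, numeric(1))
    c(threshold = th, cohort_mean = aggregate_cohort(per[!is.na(per)]),
      per[subject_ids])
  })
  list(rating_stats = rating_stats,
       accuracy = as.data.frame(do.call(rbind, acc_rows)))
}

#' Five-number summaries of features by class
#'
#' Boxplot-ready summaries -- minimum, first quartile, median, third
#' quartile, maximum (quartiles by linear interpolation, whiskers at the
#' data extremes) -- of each (feature, band) over the pooled cohort
#' trials, split by class.
#'
#' @param cohort list of \code{\link{trial_archive}} objects.
#' @param bands list of \code{\link{band_def}}.
#' @param features feature names (default variance and PSD).
#' @param strongest use only the strongest 8 + 8 trials per subject,
#'   labelled by selection side (default \code{TRUE}); otherwise all
#'   trials, labelled by \code{scheme}.
#' @param scheme \code{\link{label_scheme}} for the all-trials mode.
#' @param n_per_side strongest trials per side.
#' @param slot a \code{\link{timeslot_spec}} or preset name.
#' @param cache optional \code{\link{cohort_features}} result.
#' @return A data.frame with columns \code{feature}, \code{band},
#'   \code{class}, \code{n}, \code{min}, \code{q1}, \code{median},
#'   \code{q3}, \code{max}.
#' @export
boxplot_summary <- function(cohort,
                            bands = eeg_bands()[c("delta", "alpha",
                                                  "fast_gamma")],
                            features = c("activity", "psd"),
                            strongest = TRUE,
                            scheme = label_scheme("binary"),
                            n_per_side = 8L,
                            slot = timeslot_spec("full60"), cache = NULL) {
  if (is.null(cache)) cache <- cohort_features(cohort, bands, slot = slot)
  band_names <- unname(vapply(bands, function(b) b$name, ""))
  pooled <- list()
  for (ft in cache) {
    if (strongest) {
      sel <- strongest_labels(ft, n_per_side)
      rows <- sel$rows; labels <- sel$labels
    } else {
      rows <- seq_len(nrow(ft))
      labels <- as.character(apply_labels(ft$rating_valence, scheme))
    }
    pooled[[length(pooled) + 1L]] <-
      cbind(ft[rows, , drop = FALSE], .class = labels)
  }
  pooled <- do.call(rbind, pooled)
  out <- list()
  for (b in band_names) {
    for (f in features) {
      col <- paste(b, f, sep = "_")
      for (cl in unique(pooled$.class)) {
        v <- pooled[pooled$.class == cl, col]
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          feature = f, band = b, class = cl, n = length(v),
          min = min(v), q1 = q[1], median = q[2], q3 = q[3], max = max(v))
      }
    }
  }
  do.call(rbind, out)
}
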