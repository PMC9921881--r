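#' Classifier configuration
#'
#' Settings for the subject-dependent classifiers. kNN uses k = 5
#' Euclidean-distance neighbours by default. The RBF-SVM's cost and gamma
#' are tuned per subject by an inner cross-validated search over log2
#' ranges, either Bayesian (Gaussian-process surrogate with expected
#' improvement) or an exhaustive grid; both are deterministic given
#' \code{tuner_seed}.
#'
#' @param kind \code{"knn"} or \code{"svm_rbf"}.
#' @param k neighbour count (odd for binary tasks; default 5).
#' @param distance only \code{"euclidean"} is supported.
#' @param cost_log2_range,gamma_log2_range search intervals on the log2
#'   scale (defaults \code{[-5, 15]} and \code{[-15, 3]}).
#' @param tuner \code{"bayesian"} or \code{"grid"}.
#' @param tuner_iters evaluation budget of the Bayesian tuner (default 30).
#' @param tuner_seed integer seed making tuning and fold assignment
#'   reproducible.
#' @param inner_folds folds of the inner tuning cross-validation
#'   (default 5).
#' @param grid_points grid resolution per axis for the grid tuner
#'   (default 6).
#' @param standardize z-score features inside every training fold
#'   (default \code{TRUE}; variance and power features span orders of
#'   magnitude and both classifiers are scale-sensitive).
#' @param log_transform_power_features optionally log-transform
#'   activity/psd columns before standardization (default \code{FALSE}).
#' @return An object of class \code{"classifier_config"}.
#' @export
classifier_config <- function(kind = c("knn", "svm_rbf"), k = 5L,
                              distance = "euclidean",
                              cost_log2_range = c(-5, 15),
                              gamma_log2_range = c(-15, 3),
                              tuner = c("bayesian", "grid"),
                              tuner_iters = 30L, tuner_seed = 1L,
                              inner_folds = 5L, grid_points = 6L,
                              standardize = TRUE,
                              log_transform_power_features = FALSE) {
  kind <- match.arg(kind)
  tuner <- match.arg(tuner)
  distance <- match.arg(distance, "euclidean")
  if (k < 1L) stop("k must be positive")
  if (kind == "knn" && k %% 2L == 0L) {
    warning("even k can produce balanced votes on binary tasks; ",
            "odd k is recommended")
  }
  if (diff(cost_log2_range) < 0 || diff(gamma_log2_range) < 0) {
    stop("search ranges must be nonempty")
  }
  if (tuner_iters < 1L) stop("tuner_iters must be >= 1")
  structure(list(kind = kind, k = as.integer(k), distance = distance,
                 cost_log2_range = cost_log2_range,
                 gamma_log2_range = gamma_log2_range,
                 tuner = tuner, tuner_iters = as.integer(tuner_iters),
                 tuner_seed = as.integer(tuner_seed),
                 inner_folds = as.integer(inner_folds),
                 grid_points = as.integer(grid_points),
                 standardize = isTRUE(standardize),
                 log_transform_power_features =
                   isTRUE(log_transform_power_features)),
            class = "classifier_config")
}

# training-fold scaler: z-score statistics; zero-variance columns are left
# unscaled (divisor 1) so constant features stay constant
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(center = mu, scale = sdv)
}

apply_scaler <- function(x, scaler) {
  scale(x, center = scaler$center, scale = scaler$scale)
}

#' k-nearest-neighbour prediction
#'
#' Majority vote among the k Euclidean-nearest training rows. Distance
#' ties are broken by the lower training-row index; vote ties are broken
#' by the label of the single nearest neighbour belonging to one of the
#' tied classes.
#'
#' @param train_x numeric matrix of training rows (standardized upstream).
#' @param train_y training labels.
#' @param query a query row, or a matrix of query rows.
#' @param k neighbour count, \code{k <= nrow(train_x)}.
#' @return Predicted label(s), a character vector.
#' @examples
#' x <- matrix(c(0, 1, 2, 10, 11, 12))
#' knn_predict(x, rep(c("A", "B"), each = 3), 1.5, k = 5) # "A", 3-2
#' @export
knn_predict <- function(train_x, train_y, query, k = 5L) {
  train_x <- as.matrix(train_x)
  n <- nrow(train_x)
  if (k > n) stop("k = ", k, " exceeds ", n, " training rows")
  train_y <- as.character(train_y)
  if (!is.matrix(query)) {
    query <- matrix(query, ncol = ncol(train_x))
  }
  apply(query, 1L, function(q) {
    d <- sqrt(rowSums(sweep(train_x, 2L, q)^2))
    ord <- order(d, seq_len(n))
    nb <- train_y[ord[seq_len(k)]]
    votes <- table(nb)
    tied <- names(votes)[votes == max(votes)]
    if (length(tied) == 1L) tied else nb[nb %in% tied][1L]
  })
}

# deterministic seeded inner-fold assignment, stratified by class so every
# fold sees every class where counts permit
inner_fold_ids <- function(y, n_folds, seed) {
  y <- as.character(y)
  ids <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      pos <- which(y == cl)
      ids[pos] <- sample(rep_len(seq_len(n_folds), length(pos)))
    }
  })
  ids
}

svm_cv_accuracy <- function(x, y, log2c, log2g, fold_ids) {
  correct <- 0L
  for (f in unique(fold_ids)) {
    tr <- fold_ids != f
    if (length(unique(y[tr])) < 2L) {
      # degenerate inner split: majority-class prediction
      maj <- names(which.max(table(y[tr])))
      correct <- correct + sum(y[!tr] == maj)
      next
    }
    fit <- e1071::svm(x[tr, , drop = FALSE], factor(y[tr]),
                      kernel = "radial", cost = 2^log2c, gamma = 2^log2g,
                      scale = FALSE)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    correct <- correct + sum(as.character(pred) == y[!tr])
  }
  correct / length(y)
}

tune_svm_grid <- function(x, y, config, seed) {
  fold_ids <- inner_fold_ids(y, config$inner_folds, seed)
  cs <- seq(config$cost_log2_range[1], config$cost_log2_range[2],
            length.out = config$grid_points)
  gs <- seq(config$gamma_log2_range[1], config$gamma_log2_range[2],
            length.out = config$grid_points)
  best <- list(acc = -Inf, log2c = cs[1], log2g = gs[1])
  for (lc in cs) {       # ascending C then gamma: ties keep the smaller,
    for (lg in gs) {     # smoother model
      acc <- svm_cv_accuracy(x, y, lc, lg, fold_ids)
      if (acc > best$acc) best <- list(acc = acc, log2c = lc, log2g = lg)
    }
  }
  best
}

tune_svm_bayes <- function(x, y, config, seed) {
  fold_ids <- inner_fold_ids(y, config$inner_folds, seed)
  lo <- c(config$cost_log2_range[1], config$gamma_log2_range[1])
  hi <- c(config$cost_log2_range[2], config$gamma_log2_range[2])
  span <- pmax(hi - lo, .Machine$double.eps)
  n_init <- min(max(4L, ceiling(config$tuner_iters / 3)), config$tuner_iters)
  # the whole search (LHS start, candidate pool, GP surrogate -- whose
  # kernel-width heuristic itself draws random pairs) runs under one
  # derived seed so tuning is bit-reproducible
  withr::with_seed(seed + 1L, {
    pts <- lhs::maximinLHS(n_init, 2L)
    cand_pool <- matrix(stats::runif(256L * 2L), ncol = 2L)
    pts <- sweep(sweep(pts, 2L, span, "*"), 2L, lo, "+")
    cand <- sweep(sweep(cand_pool, 2L, span, "*"), 2L, lo, "+")
    acc <- apply(pts, 1L, function(p) {
      svm_cv_accuracy(x, y, p[1], p[2], fold_ids)
    })
    farthest <- function() {
      # exploration fallback: pool point farthest from those already tried
      dmin <- apply(cand, 1L, function(p) {
        min(sqrt(rowSums(sweep(pts, 2L, p)^2)))
      })
      cand[which.max(dmin), ]
    }
    while (nrow(pts) < config$tuner_iters) {
      nxt <- tryCatch({
        utils::capture.output(
          gp <- kernlab::gausspr(pts, acc, variance.model = TRUE,
                                 tol = 1e-6))
        mu <- as.numeric(kernlab::predict(gp, cand))
        sdv <- pmax(as.numeric(kernlab::predict(gp, cand,
                                                type = "sdeviation")), 1e-9)
        z <- (mu - max(acc)) / sdv
        ei <- (mu - max(acc)) * stats::pnorm(z) + sdv * stats::dnorm(z)
        if (!any(is.finite(ei))) farthest() else cand[which.max(ei), ]
      }, error = function(e) farthest())
      if (!all(is.finite(nxt))) nxt <- farthest()
      pts <- rbind(pts, unname(nxt))
      acc <- c(acc, svm_cv_accuracy(x, y, nxt[1], nxt[2], fold_ids))
    }
  })
  # ties: best accuracy, then smaller cost, then smaller gamma
  ord <- order(-acc, pts[, 1], pts[, 2])
  list(acc = acc[ord[1]], log2c = pts[ord[1], 1], log2g = pts[ord[1], 2])
}

tune_svm <- function(x, y, config, seed) {
  if (config$tuner == "grid") {
    tune_svm_grid(x, y, config, seed)
  } else {
    tune_svm_bayes(x, y, config, seed)
  }
}

maybe_log_power <- function(x, config) {
  if (!config$log_transform_power_features) return(x)
  pw <- grepl("_(activity|psd)$", colnames(x))
  x[, pw] <- log1p(pmax(x[, pw, drop = FALSE], 0))
  x
}

#' Leave-one-out cross-validated evaluation
#'
#' For every trial i, a model is fit on the remaining n - 1 trials and
#' used to predict trial i. The feature scaler -- and, for the SVM, the
#' hyperparameter search -- see only the n - 1 training trials, so the
#' held-out trial can never leak into fold statistics. Accuracy is the
#' percentage of correctly predicted folds.
#'
#' @param x numeric feature matrix (rows = trials) or a data.frame of
#'   feature columns.
#' @param labels per-trial class labels (at least two classes present).
#' @param config a \code{\link{classifier_config}}.
#' @return An object of class \code{"loocv_eval"}: list with
#'   \code{predictions}, \code{labels}, \code{accuracy} (percent),
#'   \code{config} and per-fold details (\code{fold_scalers},
#'   \code{fold_hyper} for the SVM).
#' @export
loocv_evaluate <- function(x, labels, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  n <- nrow(x)
  if (n < 2L) stop("LOOCV needs at least 2 trials")
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels must match rows of x")
  if (length(unique(labels)) < 2L) {
    stop("degenerate task: only one class present")
  }
  x <- maybe_log_power(x, config)
  preds <- character(n)
  scalers <- vector("list", n)
  hyper <- vector("list", n)
  for (i in seq_len(n)) {
    tr_x <- x[-i, , drop = FALSE]
    tr_y <- labels[-i]
    scaler <- if (config$standardize) fit_scaler(tr_x) else
      list(center = rep(0, ncol(x)), scale = rep(1, ncol(x)))
    xs <- apply_scaler(tr_x, scaler)
    q <- apply_scaler(x[i, , drop = FALSE], scaler)
    if (config$kind == "knn") {
      preds[i] <- knn_predict(xs, tr_y, q, k = config$k)
    } else {
      tuned <- tune_svm(xs, tr_y, config, seed = config$tuner_seed + i)
      fit <- e1071::svm(xs, factor(tr_y), kernel = "radial",
                        cost = 2^tuned$log2c, gamma = 2^tuned$log2g,
                        scale = FALSE)
      preds[i] <- as.character(predict(fit, q))
      hyper[[i]] <- tuned
    }
    scalers[[i]] <- scaler
  }
  structure(list(predictions = preds, labels = labels,
                 accuracy = 100 * mean(preds == labels),
                 config = config, fold_scalers = scalers,
                 fold_hyper = hyper),
            class = "loocv_eval")
}

#' @export
print.loocv_eval <- function(x, ...) {
  cat("<loocv_eval> ", x$config$kind, ", ", length(x$labels),
      " folds, accuracy ", sprintf("%.2f", x$accuracy), "%\n", sep = "")
  invisible(x)
}

# round half away from zero, the convention of reported accuracy tables
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cohort-level accuracy aggregate
#'
#' Unweighted arithmetic mean of per-subject accuracies, reported to two
#' decimals (half away from zero).
#'
#' @param per_subject_accuracies numeric vector of per-subject accuracies
#'   in percent.
#' @return Mean accuracy in percent, rounded to 2 decimals.
#' @examples
#' aggregate_cohort(c(100, 90)) # 95
#' @export
aggregate_cohort <- function(per_subject_accuracies) {
  if (length(per_subject_accuracies) == 0L) {
    stop("need at least one per-subject accuracy")
  }
  round_half_up(mean(per_subject_accuracies), 2L)
}

#' Chance band for a null LOOCV-kNN evaluation
#'
#' Under the null (features carry no class information) the k nearest
#' neighbours of a held-out trial are an exchangeable random k-subset of
#' the remaining trials, so the per-fold success probability is the
#' hypergeometric probability that the held-out trial's own class holds
#' the majority -- slightly below 1/2 for balanced classes, because the
#' held-out trial is missing from its own class. The band is the central
#' binomial interval at that probability over the total fold count.
#'
#' @param class_counts per-class trial counts for one subject (e.g.
#'   \code{c(20, 20)}).
#' @param k neighbour count.
#' @param n_subjects number of independent subjects pooled into the mean.
#' @param level coverage level (default 0.99).
#' @return Named vector \code{c(lower, upper, p0)}: band bounds in percent
#'   and the per-fold null success probability.
#' @export
loocv_chance_band <- function(class_counts, k = 5L, n_subjects = 1L,
                              level = 0.99) {
  stopifnot(length(class_counts) == 2L, all(class_counts >= 1L))
  n <- sum(class_counts)
  p_correct <- function(m) {
    # held out from the class with m members: m - 1 same-class among n - 1
    same <- m - 1L
    other <- n - m
    kk <- min(k, n - 1L)
    need <- floor(kk / 2) + 1L
    sum(stats::dhyper(need:kk, same, other, kk))
  }
  p0 <- sum(vapply(class_counts, function(m) {
    (m / n) * p_correct(m)
  }, numeric(1)))
  total <- n * n_subjects
  a <- (1 - level) / 2
  qs <- stats::qbinom(c(a, 1 - a), total, p0)
  c(lower = 100 * qs[1] / total, upper = 100 * qs[2] / total, p0 = p0)
}
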