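#' Electrode montage
#'
#' An ordered set of 10/20-system channel labels. Label lookup is
#' case-insensitive on the letter part and exact on the digits, so
#' \code{"fp1"} resolves to \code{"Fp1"} but \code{"Fp2"} never matches
#' \code{"Fp1"}.
#'
#' @param channel_names character vector of unique 10/20 labels, in the
#'   channel order of the recording (e.g. \code{c("Fp1", "Fp2")}).
#' @param reference_note free-text note on the reference scheme.
#' @return An object of class \code{"montage"}.
#' @examples
#' m <- montage(c("Fp1", "Fp2"))
#' match_channel(m, "fp1")
#' @export
montage <- function(channel_names, reference_note = "") {
  channel_names <- as.character(channel_names)
  if (length(channel_names) < 1L) {
    stop("montage needs at least one channel label")
  }
  key <- toupper(channel_names)
  if (anyDuplicated(key)) {
    stop("montage labels must be unique (case-insensitive): ",
         paste(unique(channel_names[duplicated(key)]), collapse = ", "))
  }
  structure(list(channel_names = channel_names,
                 reference_note = reference_note),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$channel_names), " channels: ",
      paste(x$channel_names, collapse = ", "), "\n", sep = "")
  if (nzchar(x$reference_note)) cat("  reference:", x$reference_note, "\n")
  invisible(x)
}

#' Resolve a channel label within a montage
#'
#' @param montage a \code{\link{montage}}.
#' @param label a single channel label; letters are matched
#'   case-insensitively, digits exactly.
#' @return The integer channel index.
#' @export
match_channel <- function(montage, label) {
  stopifnot(inherits(montage, "montage"), length(label) == 1L)
  idx <- match(toupper(label), toupper(montage$channel_names))
  if (is.na(idx)) {
    stop("channel '", label, "' not in montage; available: ",
         paste(montage$channel_names, collapse = ", "))
  }
  idx
}

#' Per-subject trial archive
#'
#' The common in-memory container for one subject's EEG trials: a numeric
#' tensor \code{[n_trials x n_channels x n_samples]} in microvolts, the
#' per-trial self-assessment ratings on the 1-9 scale, the montage, the
#' sampling rate, and the duration of the leading pre-trial baseline.
#' Amplitudes are taken as given and never rescaled.
#'
#' @param data numeric array \code{[n_trials x n_channels x n_samples]} (uV).
#' @param ratings numeric matrix \code{[n_trials x n_dimensions]}, each value
#'   in \code{[1, 9]}. May have zero columns (feature-extraction-only mode,
#'   e.g. EDF input).
#' @param montage a \code{\link{montage}} whose length equals
#'   \code{n_channels}.
#' @param fs sampling rate in Hz.
#' @param baseline_s leading baseline duration in seconds (default 0).
#' @param subject_id subject identifier string.
#' @param dimension_names names of the rating dimensions; must contain
#'   \code{"valence"} whenever ratings are present.
#' @return An object of class \code{"trial_archive"}.
#' @examples
#' arr <- array(rnorm(2 * 2 * 128), c(2, 2, 128))
#' rat <- matrix(c(3, 7), ncol = 1)
#' a <- trial_archive(arr, rat, montage(c("Fp1", "Fp2")), fs = 128,
#'                    dimension_names = "valence")
#' a$n_trials
#' @export
trial_archive <- function(data, ratings, montage, fs, baseline_s = 0,
                          subject_id = "S01",
                          dimension_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("data must be a 3-d array [n_trials x n_channels x n_samples]; got ",
         paste(dim(data), collapse = "x"))
  }
  d <- dim(data)
  if (d[1] < 1L) stop("archive must contain at least one trial")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive sampling rate in Hz")
  }
  if (!inherits(montage, "montage")) stop("montage must be a montage object")
  if (length(montage$channel_names) != d[2]) {
    stop("montage has ", length(montage$channel_names),
         " labels but data has ", d[2], " channels")
  }
  ratings <- as.matrix(ratings)
  if (nrow(ratings) == 0L && ncol(ratings) == 0L) {
    ratings <- matrix(numeric(0), nrow = d[1], ncol = 0)
  }
  if (nrow(ratings) != d[1]) {
    stop("ratings has ", nrow(ratings), " rows but data has ", d[1], " trials")
  }
  if (ncol(ratings) > 0L) {
    bad <- which(ratings < 1 | ratings > 9 | !is.finite(ratings),
                 arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop("rating outside [1, 9] at trial ", bad[1, 1],
           ", dimension ", bad[1, 2], " (value ",
           ratings[bad[1, 1], bad[1, 2]], ")")
    }
    if (is.null(dimension_names)) dimension_names <- colnames(ratings)
    if (is.null(dimension_names) || length(dimension_names) != ncol(ratings)) {
      stop("dimension_names must name every ratings column")
    }
    if (!("valence" %in% dimension_names)) {
      stop("dimension_names must contain \"valence\"")
    }
    colnames(ratings) <- dimension_names
  } else {
    dimension_names <- character(0)
  }
  if (baseline_s < 0 || baseline_s * fs > d[3]) {
    stop("baseline_s must be in [0, n_samples/fs]")
  }
  structure(list(subject_id = as.character(subject_id),
                 data = data,
                 ratings = ratings,
                 dimension_names = dimension_names,
                 montage = montage,
                 fs = fs,
                 baseline_s = baseline_s,
                 n_trials = d[1],
                 n_channels = d[2],
                 n_samples = d[3]),
            class = "trial_archive")
}

#' @export
print.trial_archive <- function(x, ...) {
  cat("<trial_archive> subject ", x$subject_id, ": ",
      x$n_trials, " trials x ", x$n_channels, " channels x ",
      x$n_samples, " samples @ ", x$fs, " Hz (",
      x$baseline_s, " s baseline)\n", sep = "")
  if (ncol(x$ratings) > 0L) {
    cat("  ratings:", paste(x$dimension_names, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Valence ratings of an archive
#'
#' @param archive a \code{\link{trial_archive}} with a "valence" dimension.
#' @return Numeric vector of per-trial valence ratings.
#' @export
valence_ratings <- function(archive) {
  stopifnot(inherits(archive, "trial_archive"))
  if (!("valence" %in% archive$dimension_names)) {
    stop("archive has no \"valence\" rating dimension")
  }
  archive$ratings[, "valence"]
}

#' Extract a channel pair from an archive
#'
#' Returns the per-trial sample series of two named channels, in the order
#' requested. The canonical prefrontal pair is \code{c("Fp1", "Fp2")}.
#'
#' @param archive a \code{\link{trial_archive}}.
#' @param a,b channel labels (letters case-insensitive, digits exact).
#' @return A list with elements \code{a} and \code{b}, each a numeric matrix
#'   \code{[n_trials x n_samples]}, plus \code{labels}, the resolved names.
#' @export
channel_pair <- function(archive, a = "Fp1", b = "Fp2") {
  stopifnot(inherits(archive, "trial_archive"))
  ia <- match_channel(archive$montage, a)
  ib <- match_channel(archive$montage, b)
  list(a = matrix(archive$data[, ia, ], nrow = archive$n_trials),
       b = matrix(archive$data[, ib, ], nrow = archive$n_trials),
       labels = archive$montage$channel_names[c(ia, ib)])
}

#' Write a trial archive to the native container
#'
#' The native container is a pair of files sharing a path stem: a raw
#' little-endian float64 dump of the data tensor (\code{<stem>.dat}, R array
#' order, i.e. trial index fastest) and a JSON sidecar (\code{<stem>.json})
#' holding dimensions, sampling rate, montage, baseline and the ratings
#' matrix. The layout mirrors a per-subject release of a trials-by-channels
#' recording so real archives drop in.
#'
#' @param archive a \code{\link{trial_archive}}.
#' @param stem file path without extension.
#' @return \code{stem}, invisibly.
#' @export
write_trial_archive <- function(archive, stem) {
  stopifnot(inherits(archive, "trial_archive"))
  sidecar <- list(subject_id = archive$subject_id,
                  dims = dim(archive$data),
                  fs = archive$fs,
                  baseline_s = archive$baseline_s,
                  channel_names = archive$montage$channel_names,
                  reference_note = archive$montage$reference_note,
                  dimension_names = archive$dimension_names,
                  ratings = archive$ratings)
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(archive$data), con, size = 8, endian = "little")
  jsonlite::write_json(sidecar, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read a trial archive from the native container
#'
#' Declared geometry arguments, when given, are validated against the
#' sidecar: a mismatch is a structural error naming the expected and found
#' values. No resampling or rescaling is performed.
#'
#' @param stem file path without extension (expects \code{<stem>.dat} and
#'   \code{<stem>.json}).
#' @param montage optional declared \code{\link{montage}} to validate.
#' @param fs optional declared sampling rate to validate.
#' @param baseline_s optional declared baseline duration to validate.
#' @return A validated \code{\link{trial_archive}}.
#' @export
read_trial_archive <- function(stem, montage = NULL, fs = NULL,
                               baseline_s = NULL) {
  dat_path <- paste0(stem, ".dat")
  json_path <- paste0(stem, ".json")
  if (!file.exists(dat_path) || !file.exists(json_path)) {
    stop("native archive needs both ", dat_path, " and ", json_path)
  }
  sc <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  dims <- as.integer(sc$dims)
  if (length(dims) != 3L) stop("sidecar dims must have length 3")
  n <- prod(dims)
  con <- file(dat_path, "rb")
  on.exit(close(con))
  values <- readBin(con, what = "numeric", n = n + 1L, size = 8,
                    endian = "little")
  if (length(values) != n) {
    stop("data file holds ", length(values), " samples, sidecar declares ",
         paste(dims, collapse = "x"), " = ", n)
  }
  if (!is.null(fs) && fs != sc$fs) {
    stop("declared fs ", fs, " Hz but sidecar records ", sc$fs, " Hz")
  }
  if (!is.null(baseline_s) && baseline_s != sc$baseline_s) {
    stop("declared baseline_s ", baseline_s, " but sidecar records ",
         sc$baseline_s)
  }
  mont <- montage %||% montage_from_sidecar(sc)
  if (!identical(toupper(mont$channel_names),
                 toupper(as.character(sc$channel_names)))) {
    stop("declared montage (", paste(mont$channel_names, collapse = ", "),
         ") does not match sidecar (",
         paste(sc$channel_names, collapse = ", "), ")")
  }
  ratings <- sc$ratings
  if (is.null(ratings) || length(ratings) == 0L) {
    ratings <- matrix(numeric(0), nrow = dims[1], ncol = 0)
  } else {
    ratings <- matrix(as.numeric(as.matrix(ratings)), nrow = dims[1])
  }
  trial_archive(array(values, dims), ratings, mont,
                fs = sc$fs, baseline_s = sc$baseline_s,
                subject_id = sc$subject_id,
                dimension_names = if (length(sc$dimension_names)) {
                  as.character(sc$dimension_names)
                } else NULL)
}

montage_from_sidecar <- function(sc) {
  montage(as.character(sc$channel_names),
          reference_note = if (is.null(sc$reference_note)) "" else
            sc$reference_note)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
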