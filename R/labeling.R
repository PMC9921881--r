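#' Rating-to-label scheme
#'
#' Thresholding rules mapping continuous 1-9 valence ratings to class
#' labels. Binary: \code{high} iff rating > threshold (default 5, the
#' conventional midpoint split). Three-class: \code{low} iff rating <=
#' low_cut (default 3), \code{high} iff rating >= high_cut (default 6),
#' \code{neutral} otherwise.
#'
#' @param mode \code{"binary"} or \code{"three_class"}.
#' @param threshold binary split point in rating units.
#' @param low_cut,high_cut three-class cut points, \code{1 <= low_cut <
#'   high_cut <= 9}.
#' @return An object of class \code{"label_scheme"}.
#' @export
label_scheme <- function(mode = c("binary", "three_class"), threshold = 5,
                         low_cut = 3, high_cut = 6) {
  mode <- match.arg(mode)
  if (!(threshold >= 1 && threshold <= 9)) {
    stop("binary threshold must lie in [1, 9]")
  }
  if (!(low_cut >= 1 && low_cut < high_cut && high_cut <= 9)) {
    stop("cuts must satisfy 1 <= low_cut < high_cut <= 9")
  }
  structure(list(mode = mode, threshold = threshold,
                 low_cut = low_cut, high_cut = high_cut),
            class = "label_scheme")
}

check_ratings <- function(rating) {
  bad <- which(!is.finite(rating) | rating < 1 | rating > 9)
  if (length(bad)) {
    stop("rating outside [1, 9] at position ", bad[1],
         " (value ", rating[bad[1]], ")")
  }
}

#' Binary valence labels
#'
#' @param rating numeric ratings on the 1-9 scale.
#' @param threshold split point; \code{high} iff rating strictly exceeds it.
#' @return Factor with levels \code{low}, \code{high}.
#' @examples
#' binarize_valence(c(7.2, 5.0, 6.08), threshold = 5)
#' @export
binarize_valence <- function(rating, threshold = 5) {
  check_ratings(rating)
  factor(ifelse(rating > threshold, "high", "low"),
         levels = c("low", "high"))
}

#' Three-class valence labels
#'
#' @param rating numeric ratings on the 1-9 scale.
#' @param low_cut \code{low} iff rating <= low_cut.
#' @param high_cut \code{high} iff rating >= high_cut.
#' @return Factor with levels \code{low}, \code{neutral}, \code{high}.
#' @export
three_class_valence <- function(rating, low_cut = 3, high_cut = 6) {
  check_ratings(rating)
  if (!(low_cut < high_cut)) stop("low_cut must be below high_cut")
  lab <- ifelse(rating <= low_cut, "low",
                ifelse(rating >= high_cut, "high", "neutral"))
  factor(lab, levels = c("low", "neutral", "high"))
}

#' Apply a label scheme to ratings
#'
#' @param rating numeric ratings on the 1-9 scale.
#' @param scheme a \code{\link{label_scheme}}.
#' @return Factor of class labels.
#' @export
apply_labels <- function(rating, scheme) {
  stopifnot(inherits(scheme, "label_scheme"))
  if (scheme$mode == "binary") {
    binarize_valence(rating, scheme$threshold)
  } else {
    three_class_valence(rating, scheme$low_cut, scheme$high_cut)
  }
}

#' Select the strongest-emotion trials
#'
#' Picks the \code{n_per_side} lowest- and \code{n_per_side} highest-rated
#' trials (default 8 + 8 = 16, the strongest sad and happy responses).
#' Ties are broken by ascending trial index; the low side claims its
#' trials first and the two sides are always disjoint.
#'
#' @param ratings per-trial valence ratings.
#' @param n_per_side trials per side (default 8).
#' @return List with integer index vectors \code{low} and \code{high}
#'   (1-based, each sorted ascending) and \code{labels}, a factor over the
#'   combined \code{c(low, high)} indices.
#' @export
select_strongest <- function(ratings, n_per_side = 8L) {
  n <- length(ratings)
  if (n < 2L * n_per_side) {
    stop("need at least ", 2L * n_per_side, " trials, got ", n)
  }
  check_ratings(ratings)
  asc <- order(ratings, seq_len(n))
  low <- sort(asc[seq_len(n_per_side)])
  desc <- order(-ratings, seq_len(n))
  desc <- desc[!desc %in% low]
  high <- sort(desc[seq_len(n_per_side)])
  idx <- c(low, high)
  list(low = low, high = high, index = idx,
       labels = factor(rep(c("low", "high"), each = n_per_side),
                       levels = c("low", "high")))
}
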