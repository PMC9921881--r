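# Minimal EDF/EDF+ continuous-recording reader and writer. EDF stores a
# 256-byte ASCII header, 256 ASCII bytes per signal, then data records of
# 16-bit little-endian integers mapped linearly from digital to physical
# range. Only recordings whose channels share one sampling rate are
# supported; annotation channels are not.

edf_ascii <- function(con, n) {
  raw <- readBin(con, "raw", n = n)
  if (length(raw) < n) stop("unreadable or truncated EDF header")
  trimws(rawToChar(raw))
}

pad_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  if (nchar(s) > width) stop("EDF header field too wide: ", x)
  s
}

# shortest decimal rendering of v that fits an EDF numeric field
edf_num_field <- function(v, width = 8L) {
  for (d in 7:1) {
    s <- formatC(v, digits = d, format = "g")
    if (nchar(s) <= width) return(s)
  }
  stop("cannot render ", v, " in ", width, " characters")
}

#' Read an EDF recording as a one-trial archive
#'
#' Channel labels and the sampling rate are taken from the EDF headers; a
#' leading \code{"EEG "} prefix and a reference suffix (anything from the
#' first \code{"-"}) are stripped from labels so \code{"EEG Fp1-A1"} yields
#' montage label \code{"Fp1"}. Ratings are empty: EDF input serves the
#' feature-extraction-only mode.
#'
#' @param path path to an EDF/EDF+ file.
#' @param subject_id subject identifier for the returned archive (default:
#'   the EDF local patient field, or the file name).
#' @return A one-trial \code{\link{trial_archive}}.
#' @export
read_edf <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) < 256) stop("not a valid EDF file (truncated): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  edf_ascii(con, 8)                      # version
  patient <- edf_ascii(con, 80)
  edf_ascii(con, 80)                     # recording id
  edf_ascii(con, 8); edf_ascii(con, 8)   # start date, time
  header_bytes <- as.integer(edf_ascii(con, 8))
  edf_ascii(con, 44)                     # reserved
  n_records <- as.integer(edf_ascii(con, 8))
  record_dur <- as.numeric(edf_ascii(con, 8))
  ns <- as.integer(edf_ascii(con, 4))
  if (is.na(ns) || ns < 1L) stop("not a valid EDF file (no signals): ", path)
  if (is.na(n_records) || is.na(record_dur) || record_dur <= 0) {
    stop("not a valid EDF file (bad record geometry): ", path)
  }
  field <- function(w) vapply(seq_len(ns), function(i) edf_ascii(con, w), "")
  labels <- field(16)
  field(80)                              # transducer
  field(8)                               # physical dimension
  phys_min <- as.numeric(field(8)); phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8));  dig_max <- as.numeric(field(8))
  field(80)                              # prefiltering
  spr <- as.integer(field(8))
  field(32)                              # reserved
  if (length(unique(spr)) != 1L) {
    stop("unsupported EDF: heterogeneous per-channel sampling rates (",
         paste(unique(spr / record_dur), collapse = ", "), " Hz)")
  }
  if (any(dig_max <= dig_min)) stop("not a valid EDF file (digital range)")
  fs <- spr[1] / record_dur
  seek(con, header_bytes)
  need <- n_records * ns * spr[1]
  dig <- readBin(con, "integer", n = need, size = 2, signed = TRUE,
                 endian = "little")
  if (length(dig) < need) stop("unreadable or truncated EDF data: ", path)
  # records x (signal-major blocks of spr samples)
  n_samples <- n_records * spr[1]
  data <- array(NA_real_, c(1L, ns, n_samples))
  dig <- array(dig, c(spr[1], ns, n_records))
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (s in seq_len(ns)) {
    data[1L, s, ] <- as.numeric(dig[, s, ]) * gain[s] +
      (phys_min[s] - dig_min[s] * gain[s])
  }
  clean <- sub("-.*$", "", sub("^EEG[ _]?", "", labels))
  clean[!nzchar(clean)] <- labels[!nzchar(clean)]
  if (is.null(subject_id)) {
    subject_id <- if (nzchar(patient)) patient else basename(path)
  }
  trial_archive(data, matrix(numeric(0), 1, 0), montage(clean),
                fs = fs, baseline_s = 0, subject_id = subject_id)
}

#' Write a one-trial archive (or channel matrix) as EDF
#'
#' Samples are quantized to the full 16-bit digital range over each
#' channel's own physical range, the standard EDF convention; the
#' quantization step is the channel's peak-to-peak range / 65535. All
#' samples are written as one data record.
#'
#' @param x a one-trial \code{\link{trial_archive}}, or a numeric matrix
#'   \code{[n_channels x n_samples]}.
#' @param path output file path.
#' @param fs sampling rate in Hz (taken from the archive when \code{x} is
#'   one).
#' @param labels channel labels when \code{x} is a matrix.
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(x, path, fs = NULL, labels = NULL) {
  if (inherits(x, "trial_archive")) {
    if (x$n_trials != 1L) stop("write_edf expects a one-trial archive")
    fs <- x$fs
    labels <- x$montage$channel_names
    mat <- matrix(x$data[1L, , ], nrow = x$n_channels)
  } else {
    mat <- as.matrix(x)
    if (is.null(fs)) stop("fs required when writing a raw matrix")
    if (is.null(labels)) labels <- paste0("Ch", seq_len(nrow(mat)))
  }
  ns <- nrow(mat); n_samples <- ncol(mat)
  phys_min <- apply(mat, 1, min); phys_max <- apply(mat, 1, max)
  flat <- phys_max - phys_min < .Machine$double.eps
  phys_min[flat] <- phys_min[flat] - 1; phys_max[flat] <- phys_max[flat] + 1
  # digitize against the header-rounded ranges so reader and writer agree
  min_str <- vapply(phys_min, edf_num_field, "")
  max_str <- vapply(phys_max, edf_num_field, "")
  phys_min <- as.numeric(min_str); phys_max <- as.numeric(max_str)
  wide <- phys_min > apply(mat, 1, min) | phys_max < apply(mat, 1, max)
  phys_min[wide] <- phys_min[wide] - abs(phys_min[wide]) * 1e-5 - 1e-5
  phys_max[wide] <- phys_max[wide] + abs(phys_max[wide]) * 1e-5 + 1e-5
  min_str <- vapply(phys_min, edf_num_field, "")
  max_str <- vapply(phys_max, edf_num_field, "")
  phys_min <- as.numeric(min_str); phys_max <- as.numeric(max_str)
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, w) writeBin(charToRaw(pad_field(x, w)), con)
  header_bytes <- 256L + 256L * ns
  put("0", 8); put("X", 80); put("valeeg", 80)
  put("01.01.26", 8); put("00.00.00", 8)
  put(header_bytes, 8); put("", 44)
  put(1L, 8)                                   # one data record
  put(format(n_samples / fs, digits = 10), 8)  # of the full duration
  put(ns, 4)
  for (l in labels) put(l, 16)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put("uV", 8)
  for (v in min_str) put(v, 8)
  for (v in max_str) put(v, 8)
  for (i in seq_len(ns)) put(dig_min, 8)
  for (i in seq_len(ns)) put(dig_max, 8)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put(n_samples, 8)
  for (i in seq_len(ns)) put("", 32)
  for (s in seq_len(ns)) {
    gain <- (phys_max[s] - phys_min[s]) / (dig_max - dig_min)
    dig <- round((mat[s, ] - phys_min[s]) / gain) + dig_min
    writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}
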