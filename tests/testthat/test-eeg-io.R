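test_that("trial_archive validates geometry and ratings", {
  arr <- array(rnorm(40 * 32 * 8064 / 1000), c(2, 2, 128))
  dim(arr) <- c(2, 2, 128)
  ok <- trial_archive(arr, matrix(c(5, 6), ncol = 1),
                      montage(c("Fp1", "Fp2")), fs = 128,
                      dimension_names = "valence")
  expect_s3_class(ok, "trial_archive")
  expect_equal(ok$n_trials, 2)

  # DEAP-shaped declaration: 40 x 32 x 8064 at 128 Hz, 3 s baseline
  big <- array(0, c(40, 32, 8064))
  ratings <- matrix(runif(40 * 4, 1, 9), 40, 4)
  labels <- paste0("C", 1:32)
  labels[1:2] <- c("Fp1", "Fp2")
  deap <- trial_archive(big, ratings, montage(labels), fs = 128,
                        baseline_s = 3,
                        dimension_names = c("valence", "arousal",
                                            "dominance", "liking"))
  expect_equal(deap$n_trials, 40)
  expect_equal(deap$n_samples, 63 * 128)

  bad <- matrix(c(5, 9.5), ncol = 1)
  expect_error(trial_archive(arr, bad, montage(c("Fp1", "Fp2")), fs = 128,
                             dimension_names = "valence"),
               "trial 2")
  expect_error(trial_archive(arr, matrix(c(5, 6, 7), ncol = 1),
                             montage(c("Fp1", "Fp2")), fs = 128,
                             dimension_names = "valence"),
               "3 rows")
  expect_error(trial_archive(arr, matrix(c(5, 6), ncol = 1),
                             montage(c("Fp1", "Fp2", "F3")), fs = 128,
                             dimension_names = "valence"),
               "channels")
})

test_that("native container round-trips bit-exactly", {
  arr <- array(rnorm(3 * 2 * 200), c(3, 2, 200))
  a <- trial_archive(arr, matrix(runif(3, 1, 9), ncol = 1),
                     montage(c("Fp1", "Fp2"), "average reference"),
                     fs = 128, baseline_s = 0.5, subject_id = "S09",
                     dimension_names = "valence")
  stem <- file.path(withr::local_tempdir(), "S09")
  write_trial_archive(a, stem)
  b <- read_trial_archive(stem)
  expect_identical(b$data, a$data)
  expect_equal(b$ratings, a$ratings)
  expect_equal(b$fs, a$fs)
  expect_equal(b$baseline_s, a$baseline_s)
  expect_equal(b$montage$channel_names, a$montage$channel_names)
  expect_equal(b$subject_id, "S09")
  # declared-geometry validation
  expect_error(read_trial_archive(stem, fs = 256), "256")
  expect_error(read_trial_archive(stem, montage = montage(c("Oz", "Cz"))),
               "montage")
})

test_that("channel pair lookup is case-insensitive on letters, exact on digits", {
  a <- two_channel_archive(matrix(1:8, 2), matrix(8:1, 2))
  p1 <- channel_pair(a, "Fp1", "Fp2")
  p2 <- channel_pair(a, "fp1", "FP2")
  expect_identical(p1$a, p2$a)
  expect_identical(p1$b, p2$b)
  expect_equal(p1$labels, c("Fp1", "Fp2"))
  # order preserved
  rev <- channel_pair(a, "Fp2", "Fp1")
  expect_identical(rev$a, p1$b)
  expect_error(channel_pair(a, "Oz", "Fp2"), "available")
  expect_error(channel_pair(a, "Fp3", "Fp2"), "Fp3")
})

test_that("EDF round-trip preserves header geometry and samples to read precision", {
  set.seed(41)
  n <- 2560
  mat <- rbind(50 * sin(2 * pi * 10 * (0:(n - 1)) / 256) + rnorm(n),
               30 * sin(2 * pi * 6 * (0:(n - 1)) / 256) + rnorm(n))
  path <- file.path(withr::local_tempdir(), "probe.edf")
  write_edf(mat, path, fs = 256, labels = c("Fp1", "Fp2"))
  e <- read_edf(path)
  expect_equal(e$n_trials, 1)
  expect_equal(e$n_samples, 2560)
  expect_equal(e$fs, 256)
  expect_equal(e$montage$channel_names, c("Fp1", "Fp2"))
  expect_equal(ncol(e$ratings), 0)
  # 16-bit quantization: error bounded by one digital step
  step <- (max(mat) - min(mat)) / 65535
  expect_lt(max(abs(e$data[1, , ] - mat)), 2 * step)
})

test_that("EDF feature extraction matches extraction on the source array", {
  set.seed(42)
  fs <- 128
  n <- fs * 10
  fp1 <- 20 * apply_bandpass(rnorm(n), fs, eeg_bands()$alpha)$samples +
    rnorm(n)
  fp2 <- rnorm(n)
  path <- file.path(withr::local_tempdir(), "sig.edf")
  write_edf(rbind(fp1, fp2), path, fs = fs, labels = c("Fp1", "Fp2"))
  e <- read_edf(path)
  slot <- timeslot_spec("custom", 0, 10)
  direct <- band_signal_features <- function(arch) {
    extract_features(arch, bands = list(eeg_bands()$alpha), slot = slot)
  }
  from_edf <- direct(e)
  from_raw <- direct(two_channel_archive(fp1, fp2, fs = fs))
  for (col in grep("alpha_", names(from_raw), value = TRUE)) {
    expect_equal(from_edf[[col]], from_raw[[col]], tolerance = 1e-3)
  }
})

test_that("EDF reader rejects malformed input", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.edf")
  file.create(empty)
  expect_error(read_edf(empty), "truncated")
  expect_error(read_edf(file.path(dir, "absent.edf")), "no such file")

  # mixed per-channel sampling rates: patch signal 2's samples-per-record
  mixed <- file.path(dir, "mixed.edf")
  write_edf(matrix(rnorm(512), 2), mixed, fs = 128,
            labels = c("Fp1", "Fp2"))
  raw <- readBin(mixed, "raw", file.size(mixed))
  spr2_off <- 256 + 2 * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80) + 8
  raw[(spr2_off + 1):(spr2_off + 8)] <- charToRaw(sprintf("%-8d", 128L))
  writeBin(raw, mixed)
  expect_error(read_edf(mixed), "heterogeneous")
})
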