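test_that("EDF round trip preserves the signal within 16-bit quantization", {
  set.seed(1)
  rec <- eeg_recording(matrix(rnorm(18 * 10 * 256, sd = 40), nrow = 18),
                       fs = 256, channel_labels = default_montage(),
                       subject_id = "chb99")
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_recording(path, default_montage())
  expect_equal(dim(back$data), c(18, 2560))
  expect_equal(back$fs, 256)
  qstep <- apply(rec$data, 1, function(r) 2 * max(abs(r)) * 1.0001 / 65535)
  expect_true(all(abs(back$data - rec$data) <= qstep + 1e-9))
  unlink(path)
})

test_that("montage selection normalizes labels and reports missing channels", {
  set.seed(2)
  rec <- eeg_recording(matrix(rnorm(3 * 256), nrow = 3), fs = 256,
                       channel_labels = c("FP1-F7", "F7-T7", "FZ-CZ"))
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  got <- read_recording(path, c("fp1 f7", "FZ-CZ"))
  expect_equal(got$channel_labels, c("fp1 f7", "FZ-CZ"))
  expect_equal(unname(got$data[2, 1:5]), unname(rec$data[3, 1:5]),
               tolerance = 1e-3)
  expect_error(read_recording(path, c("FP1-F7", "P7-O1")), "P7-O1")
  expect_error(read_recording(path, character(0)), "at least one")
  unlink(path)
})

test_that("mixed sampling rates across requested channels are rejected", {
  set.seed(3)
  rec <- eeg_recording(matrix(rnorm(2 * 512), nrow = 2), fs = 256,
                       channel_labels = c("FP1-F7", "F7-T7"))
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  # patch channel 2's samples-per-record header field (offset 256 + 2*216 + 8)
  con <- file(path, "r+b")
  seek(con, 256 + 2 * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80) + 8, rw = "write")
  writeBin(charToRaw(formatC("128", width = 8, flag = "-")), con)
  close(con)
  expect_error(read_recording(path, c("FP1-F7", "F7-T7")), "mixed sampling")
  unlink(path)
})

test_that("seizure summaries parse starts, ends and counts", {
  txt <- paste(
    "File Name: chb01_03.edf",
    "Number of Seizures in File: 1",
    "Seizure Start Time: 2996 seconds",
    "Seizure End Time: 3036 seconds",
    "",
    "File Name: chb01_04.edf",
    "Number of Seizures in File: 0",
    "",
    "File Name: chb01_05.edf",
    "Number of Seizures in File: 2",
    "Seizure 1 Start Time: 417 seconds",
    "Seizure 1 End Time: 532 seconds",
    "Seizure 2 Start Time: 130 seconds",
    "Seizure 2 End Time: 212 seconds",
    sep = "\n")
  ev <- parse_seizure_summary(txt)
  expect_equal(ev[["chb01_03.edf"]]$onset_s, 2996)
  expect_equal(ev[["chb01_03.edf"]]$offset_s, 3036)
  expect_equal(nrow(ev[["chb01_04.edf"]]), 0)
  expect_equal(ev[["chb01_05.edf"]]$onset_s, c(130, 417))  # onset order

  bad_order <- "File Name: x.edf\nNumber of Seizures in File: 1\nSeizure Start Time: 100 seconds\nSeizure End Time: 50 seconds"
  expect_error(parse_seizure_summary(bad_order), "before start")
  bad_count <- "File Name: x.edf\nNumber of Seizures in File: 2\nSeizure Start Time: 10 seconds\nSeizure End Time: 20 seconds"
  expect_error(parse_seizure_summary(bad_count), "declares 2")
})

test_that("pre-ictal windows cover [onset - 30, onset) and skip short leads", {
  fs <- 32
  data <- matrix(0, 2, 200 * fs)
  data[, (120 * fs + 1):(200 * fs)] <- 999   # sentinel at/after onset
  rec <- eeg_recording(data, fs = fs, channel_labels = c("C1", "C2"),
                       subject_id = "S1")
  w <- extract_preictal_window(rec, onset_s = 120)
  expect_equal(w$start_s, 90)
  expect_equal(w$end_s, 120)
  expect_equal(ncol(w$data), 30 * fs)
  expect_true(all(w$data == 0))              # never reads samples at/after onset
  expect_warning(w2 <- extract_preictal_window(rec, onset_s = 20), "skipped")
  expect_null(w2)

  events <- data.frame(onset_s = c(20, 120), offset_s = c(30, 130),
                       source_file = "x.edf")
  res <- suppressWarnings(extract_preictal_windows(rec, events))
  expect_equal(length(res$windows), 1)
  expect_equal(res$manifest$skipped, c(TRUE, FALSE))
})

test_that("a 30-s window at 256 Hz holds 7680 samples per channel", {
  gw <- fixture_window()
  expect_equal(ncol(gw$window$data), 7680)
  manifest <- write_window_manifest(list(gw$window), tempfile(fileext = ".tsv"))
  expect_equal(manifest$n_samples, 7680)
})
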