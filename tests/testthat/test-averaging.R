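test_that("R detector finds all beats on synthetic ECG", {
  ses <- small_session(seed = 9, duration_s = 30)
  rec <- ses$recording
  pk <- detect_r_peaks(rec)
  truth <- ses$truth$r_peaks
  tol <- round(0.010 * rec$sample_rate)           # +-10 ms
  hits <- vapply(pk$peaks, function(p) any(abs(truth - p) <= tol), logical(1))
  found <- vapply(truth, function(t) any(abs(pk$peaks - t) <= tol), logical(1))
  expect_true(all(hits))    # precision 100%
  expect_true(all(found))   # recall 100%

  # polarity-robust: inverted ECG yields the identical peak set
  inv <- rec
  i_ecg <- channels_by_role(rec, "ecg")
  inv$samples[i_ecg, ] <- -inv$samples[i_ecg, ]
  expect_identical(detect_r_peaks(inv)$peaks, pk$peaks)

  # refractory respected
  expect_true(all(diff(pk$peaks) >= 0.2 * rec$sample_rate))
})

test_that("flat signals yield empty peak lists, bad input errors", {
  expect_length(detect_r_peaks(rep(0, 2000), 500)$peaks, 0L)
  expect_length(detect_r_peaks(rep(3.3, 2000), 500)$peaks, 0L)
  expect_error(detect_r_peaks(rnorm(2000), -1), "parameter error")
  expect_error(detect_r_peaks(rnorm(100), 500), "shorter than 2 s")
})

test_that("epoch extraction window arithmetic and boundary drops", {
  fs <- 500
  rec <- make_rec(matrix(rnorm(10 * fs), 1), fs)
  peaks <- seq(fs, 9 * fs, by = fs)   # 1..9 s
  es <- extract_epochs(rec, peaks, pre_ms = 300, post_ms = 600)
  expect_equal(dim(es$epochs)[1] + es$n_dropped, length(peaks))
  # all nine 1..9 s peaks fit a (-300, +600) ms window inside 10 s
  expect_equal(dim(es$epochs)[1], 9L)
  expect_equal(es$n_dropped, 0L)
  expect_equal(dim(es$epochs)[3], round(0.9 * fs) + 1)

  # single centered peak
  es1 <- extract_epochs(rec, 5 * fs, pre_ms = 300, post_ms = 600)
  expect_equal(dim(es1$epochs)[1], 1L)
  expect_equal(dim(es1$epochs)[3], round(0.9 * fs) + 1)

  # peak at the first sample cannot fit its pre-window
  es2 <- extract_epochs(rec, c(1L, 5L * fs), pre_ms = 300, post_ms = 600)
  expect_equal(es2$n_dropped, 1L)
  expect_error(extract_epochs(rec, 1L, pre_ms = 300, post_ms = 600),
               "empty-epoch")
  expect_error(extract_epochs(rec, 5 * fs, pre_ms = -1, post_ms = 600),
               "parameter error")
})

test_that("averaging is the mean, with baseline correction and rejection", {
  fs <- 500
  nsamp <- round(0.9 * fs) + 1
  tmpl <- c(rep(0, 60), sin(seq(0, pi, length.out = nsamp - 60)))  # flat start
  ep <- array(rep(tmpl, each = 5 * 2), c(5, 2, nsamp))
  es <- structure(list(epochs = ep, pre_ms = 300, post_ms = 600,
                       sample_rate = fs, r_indices = 1:5, n_dropped = 0L,
                       rejected = rep(FALSE, 5),
                       channel_roles = c("mcg", "mcg"),
                       channel_ids = c("MCG01", "MCG02"),
                       channel_units = c("pT", "pT")),
                  class = "epoch_set")
  avg <- average_epochs(es)
  expect_equal(avg$samples[1, ], tmpl, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(avg$n_epochs_averaged, 5L)
  expect_equal(range(avg$time_ms), c(-300, 600))

  # permissive threshold retains everything
  avg2 <- average_epochs(es, reject_ptp_pT = 10)
  expect_false(any(avg2$rejected))
  # threshold below every epoch's swing rejects them all
  expect_error(average_epochs(es, reject_ptp_pT = 1e-6), "empty-average")
})

test_that("averaged R apex stays at time zero", {
  ses <- small_session(seed = 10, duration_s = 30)
  rec <- ses$recording
  # average the clean cardiac field at the true beat times
  clean_rec <- mcg_recording(ses$truth$clean, rec$sample_rate,
                             rep("mcg", 42))
  es <- extract_epochs(clean_rec, ses$truth$r_peaks)
  avg <- average_epochs(es)
  ch <- which.max(rowSums(avg$samples^2))
  apex <- avg$time_ms[which.max(abs(avg$samples[ch, ]))]
  expect_lte(abs(apex), 2)
})
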