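two_ch_rec <- function(mcg, ref, fs = 500) {
  mcg_recording(rbind(mcg, ref), fs,
                channel_roles = c("mcg", "reference"))
}

test_that("offline fit recovers an exact scaled-copy contamination", {
  set.seed(1)
  n <- 5000
  s <- sin(2 * pi * 3 * (1:n) / 500)          # the signal of interest
  ref <- rnorm(n)
  ref <- ref - s * sum(ref * s) / sum(s^2)    # exactly uncorrelated noise
  rec <- two_ch_rec(s + 2 * ref, ref)
  filt <- fit_anc(rec, taps = 1, lambda = 0)
  expect_equal(unname(filt$weights[1, 1]), 2, tolerance = 1e-6)
  out <- apply_anc(rec, filt)
  expect_equal(out$samples[1, ], s, tolerance = 1e-6, ignore_attr = TRUE)
  # reference channel passes through untouched
  expect_identical(out$samples[2, ], rec$samples[2, ])
})

test_that("independent references attract near-zero weights", {
  set.seed(2)
  n <- 10000
  rec <- mcg_recording(rbind(rnorm(n), rnorm(n), rnorm(n)), 500,
                       c("mcg", "reference", "reference"))
  filt <- fit_anc(rec, taps = 3)
  expect_lt(max(abs(filt$weights)), 0.05)
})

test_that("parameter and degeneracy errors are raised", {
  set.seed(3)
  rec <- two_ch_rec(rnorm(6000), rnorm(6000))
  expect_error(fit_anc(rec, taps = 0), "taps")
  expect_error(fit_anc(two_ch_rec(rnorm(6000), rep(0, 6000))),
               "degenerate-design")
  filt <- fit_anc(rec)
  rec3 <- mcg_recording(matrix(rnorm(3 * 6000), 3), 500,
                        c("mcg", "reference", "reference"))
  expect_error(apply_anc(rec3, filt), "consistency error")
})

test_that("zero weights give the identity; residuals are orthogonal", {
  set.seed(4)
  n <- 6000
  rec <- two_ch_rec(rnorm(n), rnorm(n))
  filt <- fit_anc(rec, taps = 3)
  filt$weights[] <- 0
  expect_identical(apply_anc(rec, filt)$samples, rec$samples)

  # unregularized LS residual is orthogonal to the lagged regressors
  scn <- default_interference_scenario()
  ses <- small_session(seed = 5, duration_s = 10)
  f0 <- fit_anc(ses$recording, taps = 3, lambda = 0, exclude_transient = FALSE)
  out <- apply_anc(ses$recording, f0)
  X <- stormmcg:::lagged_design(
    ses$recording$samples[channels_by_role(ses$recording, "reference"), ],
    f0$offsets)
  r <- out$samples[1, ]
  ip <- abs(crossprod(X, r)) / (sqrt(colSums(X^2)) * sqrt(sum(r^2)))
  expect_lt(max(ip), 1e-6)
})

test_that("repeated fit-and-apply is idempotent up to noise", {
  ses <- small_session(seed = 6, duration_s = 15)
  f1 <- fit_anc(ses$recording)
  out1 <- apply_anc(ses$recording, f1)
  f2 <- fit_anc(out1)
  out2 <- apply_anc(out1, f2)
  p1 <- mean(out1$samples[1:42, ]^2)
  p2 <- mean(out2$samples[1:42, ]^2)
  expect_lt(abs(10 * log10(p2 / p1)), 1)
})

test_that("NLMS converges near the offline least-squares solution", {
  set.seed(7)
  n <- 100000
  u <- as.numeric(stats::filter(rnorm(n), 0.5, method = "recursive"))
  v <- as.numeric(stats::filter(rnorm(n), 0.3, method = "recursive"))
  s <- 5 * sin(2 * pi * 2 * (1:n) / 500) + rnorm(n, sd = 0.5)
  rec <- mcg_recording(rbind(s + 1.5 * u - 0.8 * v, u, v), 500,
                       c("mcg", "reference", "reference"))
  f_ls <- fit_anc(rec, taps = 1, lambda = 0)
  f_nl <- fit_anc(rec, taps = 1, mode = "nlms", step = 0.01)
  tail_idx <- (n - 20000):n
  resid_power <- function(f) {
    out <- apply_anc(rec, f)
    mean(out$samples[1, tail_idx]^2)
  }
  expect_lt(resid_power(f_nl), resid_power(f_ls) * 1.10)
})

test_that("suppression report behaves at its fixed points", {
  ses <- small_session(seed = 8, duration_s = 16)
  rep0 <- anc_report(ses$recording, ses$recording, "MCG18", window_s = 4)
  expect_equal(rep0$broadband_db, 0)
  expect_equal(rep0$suppression_1hz_db, 0)
  expect_false(rep0$degenerate)

  zero <- ses$recording
  zero$samples[] <- 0
  repz <- anc_report(ses$recording, zero, "MCG18", window_s = 4)
  expect_true(repz$degenerate)
})
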