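make_ern_rec <- function(Y, fs = 500) {
  mcg_recording(Y, fs, rep("mcg", nrow(Y)))
}

random_loadings <- function(d, k, scale = 1) {
  matrix(rnorm(d * k), d, k) * scale
}

test_that("interference subspace is recovered from empty-room noise", {
  set.seed(21)
  d <- 42; q <- 3; n <- 6000
  B0 <- random_loadings(d, q, scale = 5)
  Y <- B0 %*% matrix(rnorm(q * n), q, n) + matrix(rnorm(d * n), d, n)
  im <- fit_interference_model(make_ern_rec(Y), q = q)
  expect_lt(principal_angle(im$B, B0), 5)
  expect_true(all(im$psi_ern > 0))
})

test_that("isotropic noise yields negligible loadings and correct variances", {
  set.seed(22)
  d <- 20; n <- 8000
  Y <- matrix(rnorm(d * n, sd = 2), d, n)
  im <- fit_interference_model(make_ern_rec(Y), q = 1)
  ch_sd <- apply(Y, 1, sd)
  expect_lt(max(abs(im$B)), 0.1 * max(ch_sd) * sqrt(d))
  expect_lt(sqrt(mean(im$B^2)) / mean(ch_sd), 0.10)
  expect_equal(im$psi_ern, apply(Y, 1, var) * (n - 1) / n - rowSums(im$B^2),
               tolerance = 0.1, ignore_attr = TRUE)
})

test_that("q = 0 reduces to the diagonal model exactly", {
  set.seed(23)
  Y <- matrix(rnorm(10 * 6000), 10)
  im <- fit_interference_model(make_ern_rec(Y), q = 0)
  expect_equal(ncol(im$B), 0L)
  Yc <- Y - rowMeans(Y)
  expect_equal(im$psi_ern, rowSums(Yc^2) / ncol(Y), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("parameter errors and factor-count selection", {
  set.seed(24)
  Y <- matrix(rnorm(10 * 6000), 10)
  expect_error(fit_interference_model(make_ern_rec(Y), q = 10),
               "parameter error")
  expect_error(fit_interference_model(make_ern_rec(Y[, 1:100])), "shorter")

  # scree picks the planted rank on strongly structured covariance
  B0 <- random_loadings(10, 2, scale = 10)
  Y2 <- B0 %*% matrix(rnorm(2 * 6000), 2) + matrix(rnorm(10 * 6000), 10)
  S <- stormmcg:::channel_covariance(Y2)
  expect_equal(scree_factor_count(S), 2L)
})

test_that("constrained fit recovers the signal subspace with B frozen", {
  set.seed(25)
  d <- 30; q <- 3; p <- 2; n <- 4000
  B0 <- random_loadings(d, q, scale = 4)
  A0 <- random_loadings(d, p, scale = 6)
  X <- matrix(rnorm(p * n), p, n)
  U <- matrix(rnorm(q * n), q, n)
  Y <- A0 %*% X + B0 %*% U + matrix(rnorm(d * n, sd = 0.5), d, n)
  im <- structure(list(B = B0, psi_ern = rep(0.25, d), q = q,
                       loglik_trace = 0, iterations = 0L, converged = TRUE),
                  class = "interference_model")
  sm <- fit_signal_model(make_avg(Y), im, p = p)
  expect_lt(principal_angle(sm$A, A0), 5)

  # EM monotonicity on the constrained fit
  expect_true(all(diff(sm$loglik_trace) >=
                    -1e-8 * abs(sm$loglik_trace[-1])))

  expect_error(fit_signal_model(make_avg(Y), im, p = d - q),
               "parameter error")
})

test_that("with q = 0 the fit agrees with the principal subspace", {
  set.seed(26)
  d <- 25; p <- 3; n <- 4000
  A0 <- random_loadings(d, p, scale = 5)
  Y <- A0 %*% matrix(rnorm(p * n), p, n) + matrix(rnorm(d * n, sd = 0.1), d, n)
  im0 <- structure(list(B = matrix(0, d, 0), psi_ern = rep(0.01, d), q = 0L,
                        loglik_trace = 0, iterations = 0L, converged = TRUE),
                   class = "interference_model")
  sm <- fit_signal_model(make_avg(Y), im0, p = p)
  pc <- eigen(stormmcg:::channel_covariance(Y))$vectors[, 1:p]
  expect_lt(principal_angle(sm$A, pc), 5)
})

test_that("EM log-likelihood is non-decreasing", {
  set.seed(27)
  for (rep in 1:5) {
    d <- 15; q <- 2; n <- 6000
    B0 <- random_loadings(d, q, scale = 3)
    Y <- B0 %*% matrix(rnorm(q * n), q, n) + matrix(rnorm(d * n), d, n)
    im <- fit_interference_model(make_ern_rec(Y), q = q)
    tr <- im$loglik_trace
    expect_true(all(diff(tr) >= -1e-8 * abs(tr[-1])))
  }
})

test_that("posterior projection: linearity, span identity, idempotence", {
  set.seed(28)
  d <- 20; p <- 2
  A0 <- random_loadings(d, p, scale = 3)
  im0 <- structure(list(B = matrix(0, d, 0), psi_ern = rep(1e-6, d), q = 0L,
                        loglik_trace = 0, iterations = 0L, converged = TRUE),
                   class = "interference_model")
  sm0 <- structure(list(A = A0, psi = rep(1e-6, d), p = p,
                        loglik_trace = 0, iterations = 0L, converged = TRUE,
                        channel_ids = sprintf("MCG%02d", 1:d)),
                   class = "signal_model")

  # zero in, zero out
  z <- denoise(make_avg(matrix(0, d, 50)), sm0, im0)
  expect_equal(max(abs(z$waveform$samples)), 0)

  # y exactly in span(A), noiseless: y_S reproduces y
  Yin <- A0 %*% matrix(rnorm(p * 100), p, 100)
  dn <- denoise(make_avg(Yin), sm0, im0)
  expect_lt(max(abs(dn$waveform$samples - Yin)) / max(abs(Yin)), 1e-6)

  # idempotence in the noiseless limit
  dn2 <- denoise(dn$waveform, sm0, im0)
  expect_equal(dn2$waveform$samples, dn$waveform$samples, tolerance = 1e-6)
})

test_that("signal factors are separated from planted interference", {
  set.seed(29)
  d <- 42; q <- 2; n_epoch <- 400
  B0 <- random_loadings(d, q, scale = 2)
  # smooth cardiac-like template on a rank-1 spatial pattern
  tt <- seq(-300, 600, length.out = n_epoch)
  tmpl <- pqrst_waveform(tt)
  a0 <- rnorm(d)
  Y <- outer(a0, tmpl) * 30 +
    B0 %*% matrix(rnorm(q * n_epoch), q, n_epoch) +
    matrix(rnorm(d * n_epoch, sd = 0.3), d, n_epoch)
  im <- structure(list(B = B0, psi_ern = rep(0.09, d), q = q,
                       loglik_trace = 0, iterations = 0L, converged = TRUE),
                  class = "interference_model")
  sm <- fit_signal_model(make_avg(Y), im, p = 1)
  dn <- denoise(make_avg(Y), sm, im)
  best <- which.max(abs(a0))
  expect_gt(abs(cor(dn$waveform$samples[best, ], tmpl)), 0.98)
  # baseline flattening: early-window RMS drops after projection
  base_idx <- tt < -250
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(dn$waveform$samples[best, base_idx]),
            0.5 * rms(Y[best, base_idx]) + 1e-9)
})
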