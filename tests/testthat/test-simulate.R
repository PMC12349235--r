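test_that("beat timing follows the configured rate and jitter", {
  src0 <- cardiac_source_model(rr_jitter_ms = 0)
  cm <- cardiac_moment_series(src0, 10, 5000, seed = 1)
  expect_length(cm$r_peaks, 10L)                     # 60 bpm, 10 s
  expect_equal(unique(diff(cm$r_peaks)), 5000L)      # exact periodicity

  # seeded determinism
  src <- cardiac_source_model(rr_jitter_ms = 30)
  a <- cardiac_moment_series(src, 30, 500, seed = 42)
  b <- cardiac_moment_series(src, 30, 500, seed = 42)
  expect_identical(a$r_peaks, b$r_peaks)
  expect_identical(a$moment, b$moment)

  # mean RR at 60 bpm with 30 ms jitter stays near 1000 ms
  cm2 <- cardiac_moment_series(src, 120, 500, seed = 7)
  expect_lt(abs(mean(diff(cm2$r_peaks)) / 500 * 1000 - 1000), 10)

  expect_error(cardiac_moment_series(
    cardiac_source_model(rr_jitter_ms = 400), 10, 500), "parameter error")
})

test_that("forward field obeys the dipole law", {
  g <- default_geometry()
  expect_equal(forward_field(c(0, 0, 0), c(0, 0, -0.1), g),
               rep(0, 63))
  q <- c(2, -1, 0.5)
  f <- forward_field(q, c(0, 0, -0.1), g)
  expect_equal(forward_field(-q, c(0, 0, -0.1), g), -f)   # linearity

  # 1/r^2 falloff at fixed geometry factor: single sensor on the
  # moment's perpendicular, axis along the cross-product direction
  one <- sensor_array_geometry(
    matrix(rep(c(0, 0, 0.1), 42), 42, byrow = TRUE),
    matrix(rep(c(0, 1, 0), 42), 42, byrow = TRUE),
    matrix(rep(c(1, 0, 0), 21), 21, byrow = TRUE),
    matrix(rep(c(0, 0, 1), 21), 21, byrow = TRUE))
  f1 <- forward_field(c(1, 0, 0), c(0, 0, 0), one, sensors = "recording")[1]
  one2 <- one
  one2$recording_positions <- matrix(rep(c(0, 0, 0.2), 42), 42, byrow = TRUE)
  f2 <- forward_field(c(1, 0, 0), c(0, 0, 0), one2, sensors = "recording")[1]
  expect_equal(f1 / f2, 4, tolerance = 1e-12)

  expect_error(forward_field(c(1, 0, 0), c(0, 0, 0.1004), one),
               "proximity error")
})

test_that("interference is low-rank and visible to the references", {
  scn <- default_interference_scenario()
  x <- generate_interference(scn, 10, 500, seed = 5)
  sv <- svd(x)$d
  expect_equal(sum(sv > 1e-9 * sv[1]), 4L)           # rank = n_patterns

  # every pattern excites references with >= 10% of its recording energy
  P <- scn$spatial_patterns
  for (j in seq_len(ncol(P)))
    expect_gt(mean(P[43:63, j]^2) / mean(P[1:42, j]^2), 0.10)

  # single pure-tone pattern: each channel a scaled copy of the course
  scn1 <- interference_scenario(
    matrix(c(1, 2, -0.5), 3, 1),
    list(list(type = "powerline", amplitude_pT = 10, f0_hz = 50,
              harmonic_ratio = 0)))
  y <- generate_interference(scn1, 2, 500, seed = 1)
  expect_equal(y[2, ] / y[1, ], rep(2, ncol(y)), tolerance = 1e-9)
  expect_equal(y[3, ] / y[1, ], rep(-0.5, ncol(y)), tolerance = 1e-9)
})

test_that("sessions decompose exactly and respect field scales", {
  ses <- small_session(seed = 11, duration_s = 10)
  rec <- ses$recording
  i_mcg <- channels_by_role(rec, "mcg")
  i_ref <- channels_by_role(rec, "reference")

  # construction identity on MCG rows: residual is the white noise
  resid <- rec$samples[i_mcg, ] - ses$truth$clean - ses$truth$interference
  sigma <- ses$config$sensor_noise_asd * sqrt(ses$config$sample_rate / 2)
  expect_lt(abs(sd(resid) / sigma - 1), 0.02)

  # peak clean field hits the configured target exactly
  expect_equal(max(abs(ses$truth$clean)), 100, tolerance = 1e-9)

  # reference cardiac energy attenuation contract
  ratio <- mean(ses$truth$clean_reference^2) / mean(ses$truth$clean^2)
  expect_lte(ratio, 1e-4)

  # sample count and determinism
  expect_equal(ncol(rec$samples), 10 * 500)
  ses2 <- small_session(seed = 11, duration_s = 10)
  expect_identical(ses2$recording$samples, rec$samples)
  expect_identical(ses2$empty_room$samples, ses$empty_room$samples)

  # empty room shares the spatial patterns but not the realization
  expect_identical(ses$truth$spatial_patterns,
                   ses$config$scenario$spatial_patterns)
  expect_false(identical(ses$empty_room$samples[1, ],
                         rec$samples[1, seq_len(ncol(ses$empty_room$samples))]))

  expect_error(generate_session(session_config(duration_s = -1)),
               "parameter error")
})

test_that("default-scale session matches the unshielded noise regime", {
  # full-rate short session: amplitude density at 1 Hz on a central
  # channel sits in the hundreds of pT/sqrt(Hz) before cancellation
  ses <- generate_session(session_config(duration_s = 30, ern_duration_s = 10),
                          seed = 2)
  nsd <- noise_spectral_density(ses$recording, "MCG18", window_s = 10)
  asd1 <- density_at(nsd, 1)
  expect_gt(asd1, 100)
  expect_lt(asd1, 500)
})
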