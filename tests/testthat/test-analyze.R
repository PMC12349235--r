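test_that("SNR formula closed forms", {
  defn <- snr_definition()
  expect_equal(snr_db(snr_fixture(10), defn, 1), 20, tolerance = 1e-9)
  expect_equal(snr_db(snr_fixture(1), defn, 1), 0, tolerance = 1e-9)
  expect_equal(snr_db(snr_fixture(20), defn, 1) - snr_db(snr_fixture(10), defn, 1),
               20 * log10(2), tolerance = 1e-9)

  # scale invariance
  a <- snr_fixture(10)
  a$samples <- a$samples * 3.7
  expect_equal(snr_db(a, defn, 1), 20, tolerance = 1e-9)

  zero <- snr_fixture(0); zero$samples[] <- 0
  expect_error(snr_db(zero, defn, 1), "undefined-SNR")
  expect_error(snr_definition(qrs_window_ms = c(-400, 50)), "disjoint")
})

test_that("channel selection maximizes QRS amplitude with stable ties", {
  defn <- snr_definition()
  one <- snr_fixture(10, d = 1)
  expect_equal(select_channel(one, defn), "MCG01")

  two <- snr_fixture(10, d = 2)          # identical rows
  expect_equal(select_channel(two, defn), "MCG01")   # lowest index wins

  two$samples[2, ] <- two$samples[2, ] * 2
  expect_equal(select_channel(two, defn), "MCG02")

  rep <- snr_report(two, defn)
  expect_equal(rep$selected_channel, "MCG02")
  expect_equal(nrow(rep$table), 2L)
})

test_that("selected channel sits near the dipole field extrema", {
  ses <- small_session(seed = 13, duration_s = 20)
  clean_rec <- mcg_recording(ses$truth$clean, ses$recording$sample_rate,
                             rep("mcg", 42))
  avg <- average_epochs(extract_epochs(clean_rec, ses$truth$r_peaks))
  sel <- select_channel(avg)
  pattern <- forward_field(ses$config$source$dipole_orientation,
                           ses$config$source$dipole_position,
                           ses$config$geometry, sensors = "recording")
  top <- order(abs(pattern), decreasing = TRUE)[1:4]
  expect_true(match(sel, avg$channel_ids) %in% top)
})

test_that("cohort summary computes mean and n-1 SD", {
  s <- summarize_cohort(c(0, 0, 0))
  expect_equal(s$mean, 0); expect_equal(s$sd, 0)
  s2 <- summarize_cohort(c(1, 2, 3, 4))
  expect_equal(s2$mean, 2.5)
  expect_equal(s2$sd, sd(c(1, 2, 3, 4)))
  expect_error(summarize_cohort(5), "parameter error")
})

test_that("isofield maps interpolate exactly and preserve structure", {
  g <- default_geometry()
  # uniform field: flat map
  flat <- make_avg(matrix(3.3, 42, 11), 500, pre_ms = 0)
  m <- build_isofield_map(flat, g, latency_ms = 10)
  expect_lt(max(abs(m$field - 3.3)), 1e-9)

  # interpolation exactness at sensor nodes
  ses <- small_session(seed = 14, duration_s = 10)
  clean_rec <- mcg_recording(ses$truth$clean, 500, rep("mcg", 42))
  avg <- average_epochs(extract_epochs(clean_rec, ses$truth$r_peaks))
  mp <- build_isofield_map(avg, g, latency_ms = 0)
  expect_lt(max(abs(isofield_at_sensors(mp) - mp$sensor_values)),
            1e-9 * max(abs(mp$sensor_values)))

  # in-plane dipole at R: two opposite-sign poles separated orthogonally
  # to the (x-oriented) moment, i.e. along y
  expect_lt(min(mp$field), -0.2 * max(mp$field))
  imax <- which(mp$field == max(mp$field), arr.ind = TRUE)[1, ]
  imin <- which(mp$field == min(mp$field), arr.ind = TRUE)[1, ]
  sep <- c(mp$x[imax["col"]] - mp$x[imin["col"]],
           mp$y[imax["row"]] - mp$y[imin["row"]])
  expect_gt(abs(sep[2]), abs(sep[1]))

  expect_error(build_isofield_map(avg, g, latency_ms = 10000),
               "parameter error")
})
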