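#' SNR definition
#'
#' The signal-to-noise ratio of an averaged beat is
#' `20 * log10(QRS amplitude / baseline amplitude)`, with the baseline
#' taken as the 100 ms window ending at the P-wave onset. P onset is a
#' configured latency (default -250 ms relative to R, giving a baseline
#' window of \[-350, -250\] ms); automatic onset detection in noisy
#' unshielded data is unreliable, so a fixed latency is the default.
#'
#' Amplitude conventions (both selectable):
#' * QRS: `"peak_abs"` (default) — maximum absolute deviation from the
#'   baseline-window mean inside the QRS window — or `"peak_to_peak"`.
#' * baseline: `"rms"` (default) — RMS about the baseline mean — or
#'   `"peak_to_peak"`.
#'
#' @param qrs_window_ms QRS window relative to R (default `c(-50, 50)`).
#' @param p_onset_ms configured P-onset latency (default -250).
#' @param qrs_amplitude,baseline_amplitude convention selectors.
#' @return an object of class `snr_definition`.
#' @export
snr_definition <- function(qrs_window_ms = c(-50, 50), p_onset_ms = -250,
                           qrs_amplitude = c("peak_abs", "peak_to_peak"),
                           baseline_amplitude = c("rms", "peak_to_peak")) {
  baseline_window_ms <- c(p_onset_ms - 100, p_onset_ms)
  if (baseline_window_ms[2] > qrs_window_ms[1])
    stopf("baseline and QRS windows must be disjoint")
  structure(list(qrs_window_ms = qrs_window_ms,
                 baseline_window_ms = baseline_window_ms,
                 p_onset_ms = p_onset_ms,
                 qrs_amplitude = match.arg(qrs_amplitude),
                 baseline_amplitude = match.arg(baseline_amplitude)),
            class = "snr_definition")
}

amplitudes_for_channel <- function(avg, defn, i) {
  w_qrs <- avg$time_ms >= defn$qrs_window_ms[1] &
    avg$time_ms <= defn$qrs_window_ms[2]
  w_base <- avg$time_ms >= defn$baseline_window_ms[1] &
    avg$time_ms <= defn$baseline_window_ms[2]
  if (!any(w_qrs) || !any(w_base))
    stopf("parameter error: SNR windows outside the epoch span")
  x <- avg$samples[i, ]
  b_mean <- mean(x[w_base])
  qrs <- switch(defn$qrs_amplitude,
                peak_abs = max(abs(x[w_qrs] - b_mean)),
                peak_to_peak = diff(range(x[w_qrs])))
  base <- switch(defn$baseline_amplitude,
                 rms = sqrt(mean((x[w_base] - b_mean)^2)),
                 peak_to_peak = diff(range(x[w_base])))
  c(qrs = qrs, baseline = base)
}

#' Signal-to-noise ratio of an averaged waveform
#'
#' @param avg an `averaged_waveform` (or the `waveform` element of a
#'   [denoise()] result).
#' @param defn an [snr_definition()].
#' @param channel channel id or index; NULL selects by
#'   [select_channel()].
#' @return SNR in dB.
#' @export
snr_db <- function(avg, defn = snr_definition(), channel = NULL) {
  avg <- as_waveform(avg)
  i <- resolve_channel(avg, channel %||% select_channel(avg, defn))
  a <- amplitudes_for_channel(avg, defn, i)
  if (a["baseline"] <= 0) stopf("undefined-SNR error: zero baseline amplitude")
  unname(20 * log10(a["qrs"] / a["baseline"]))
}

as_waveform <- function(avg) {
  if (inherits(avg, "denoised_waveform")) avg$waveform else avg
}

resolve_channel <- function(avg, channel) {
  if (is.character(channel)) {
    i <- match(channel, avg$channel_ids)
    if (is.na(i)) stopf("channel '%s' not found", channel)
    i
  } else as.integer(channel)
}

#' Select the reporting channel by maximum QRS amplitude
#'
#' Deterministic tie-break: the lowest channel index wins. Only mcg
#' channels are considered when roles are present.
#'
#' @inheritParams snr_db
#' @return the selected channel id (or index when ids are absent).
#' @export
select_channel <- function(avg, defn = snr_definition()) {
  avg <- as_waveform(avg)
  cand <- which(avg$channel_roles == "mcg")
  if (!length(cand)) cand <- seq_len(nrow(avg$samples))
  amps <- vapply(cand, function(i)
    amplitudes_for_channel(avg, defn, i)["qrs"], numeric(1))
  best <- cand[which.max(amps)]   # which.max breaks ties by first index
  if (!is.null(avg$channel_ids)) avg$channel_ids[best] else best
}

#' Per-channel SNR report
#'
#' @inheritParams snr_db
#' @return an object of class `snr_report`: data frame of per-channel
#'   QRS/baseline amplitudes and SNR, plus the selected channel.
#' @export
snr_report <- function(avg, defn = snr_definition()) {
  avg <- as_waveform(avg)
  cand <- which(avg$channel_roles == "mcg")
  if (!length(cand)) cand <- seq_len(nrow(avg$samples))
  rows <- t(vapply(cand, function(i) amplitudes_for_channel(avg, defn, i),
                   numeric(2)))
  df <- data.frame(channel_id = avg$channel_ids[cand],
                   qrs_pT = rows[, "qrs"], baseline_pT = rows[, "baseline"],
                   snr_db = ifelse(rows[, "baseline"] > 0,
                                   20 * log10(rows[, "qrs"] / rows[, "baseline"]),
                                   NA_real_))
  structure(list(table = df,
                 selected_channel = df$channel_id[which.max(df$qrs_pT)]),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("<snr_report> %d channels, selected %s (%.1f dB)\n",
              nrow(x$table), x$selected_channel,
              x$table$snr_db[x$table$channel_id == x$selected_channel]))
  invisible(x)
}

#' Cohort summary: mean and SD
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' per-participant values, with one-decimal rounding for report output.
#'
#' @param values numeric vector (length >= 2).
#' @return list with `mean`, `sd`, `n`, and a formatted `label`
#'   `"mean +- sd"` rounded to one decimal.
#' @export
summarize_cohort <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stopf("parameter error: need >= 2 values for an SD")
  m <- mean(values); s <- stats::sd(values)
  list(mean = m, sd = s, n = length(values),
       label = sprintf("%.1f ± %.1f", round(m, 1), round(s, 1)))
}

#' Bundled 40-participant SNR benchmark table
#'
#' Published per-participant SNRs (dB) from a 40-subject healthy cohort
#' recorded with an unshielded magnetoresistive MCG array, at three
#' processing stages (digital filters only, + adaptive noise
#' cancellation, + Bayesian signal-space projection) plus the
#' simultaneously recorded ECG. Used as the reference for cohort-level
#' summaries.
#'
#' @return data frame with columns `participant`, `digital_filters_db`,
#'   `anc_db`, `bayesian_ssp_db`, `ecg_db`.
#' @export
cohort_snr_reference <- function() {
  utils::read.csv(system.file("extdata", "cohort_snr_40.csv",
                              package = "stormmcg", mustWork = TRUE))
}

#' Isomagnetic field map at one latency
#'
#' Arranges the averaged field values at the requested latency on the
#' 6 x 7 recording grid and interpolates between sensors with separable
#' piecewise-cubic splines (an interpolant, not a smoother: it
#' reproduces the sensor values exactly at the sensor nodes). No
#' extrapolation beyond the grid hull.
#'
#' @param avg an `averaged_waveform` (mcg channels in row-major grid
#'   order) or a [denoise()] result.
#' @param geometry the [sensor_array_geometry()] of the recording grid.
#' @param latency_ms latency relative to R.
#' @param resolution upsampling factor per grid interval (default 10).
#' @return an object of class `isofield_map`: `x`, `y` grid coordinate
#'   vectors (metres), `field` matrix (length(y) x length(x), pT),
#'   `sensor_values`, `sensor_x`, `sensor_y`, `latency_ms`.
#' @export
build_isofield_map <- function(avg, geometry, latency_ms, resolution = 10L) {
  avg <- as_waveform(avg)
  i_mcg <- which(avg$channel_roles == "mcg")
  if (!length(i_mcg)) i_mcg <- seq_len(nrow(avg$samples))
  rows <- geometry$grid_shape[1]; cols <- geometry$grid_shape[2]
  if (length(i_mcg) != rows * cols)
    stopf("waveform has %d mcg channels; geometry grid needs %d",
          length(i_mcg), rows * cols)
  it <- latency_index(avg, latency_ms)
  v <- avg$samples[i_mcg, it]
  # channel order is row-major over the grid
  F0 <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  xs <- sort(unique(round(geometry$recording_positions[, 1], 12)))
  ys <- sort(unique(round(geometry$recording_positions[, 2], 12)))
  # grid rows run from +y (row 1) downward
  ys_desc <- rev(ys)
  resolution <- max(1L, as.integer(resolution))
  fine_x <- seq(min(xs), max(xs), length.out = (cols - 1L) * resolution + 1L)
  fine_y <- seq(max(ys), min(ys), length.out = (rows - 1L) * resolution + 1L)
  # separable interpolation: cubic spline along x per grid row, then
  # along y per fine column
  tmp <- t(apply(F0, 1, function(rv)
    stats::spline(xs, rv, xout = fine_x, method = "fmm")$y))
  field <- apply(tmp, 2, function(cv)
    stats::spline(ys_desc, cv, xout = fine_y, method = "fmm")$y)
  structure(list(x = fine_x, y = fine_y, field = field,
                 sensor_values = v,
                 sensor_x = geometry$recording_positions[, 1],
                 sensor_y = geometry$recording_positions[, 2],
                 latency_ms = latency_ms, resolution = resolution),
            class = "isofield_map")
}

#' @export
print.isofield_map <- function(x, ...) {
  cat(sprintf("<isofield_map> %d x %d grid at %+g ms, range [%.1f, %.1f] pT\n",
              nrow(x$field), ncol(x$field), x$latency_ms,
              min(x$field), max(x$field)))
  invisible(x)
}

#' @export
plot.isofield_map <- function(x, ...) {
  zlim <- max(abs(x$field))
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(255)
  graphics::image(x$x, rev(x$y), t(x$field[nrow(x$field):1, ]),
                  col = pal, zlim = c(-zlim, zlim),
                  xlab = "x (m)", ylab = "y (m)",
                  main = sprintf("Isofield map, %+g ms", x$latency_ms), ...)
  graphics::contour(x$x, rev(x$y), t(x$field[nrow(x$field):1, ]),
                    levels = 0, add = TRUE, lwd = 2, drawlabels = FALSE)
  graphics::points(x$sensor_x, x$sensor_y, pch = 3, cex = 0.5)
  invisible(x)
}

#' Evaluate an isofield map at the sensor coordinates
#'
#' Looks up the interpolated grid at the sensor node coordinates (the
#' fine grid contains the sensor nodes by construction); used to verify
#' interpolation exactness.
#'
#' @param map an `isofield_map`.
#' @return numeric vector in the sensor (channel) order.
#' @export
isofield_at_sensors <- function(map) {
  vapply(seq_along(map$sensor_values), function(k) {
    ix <- which.min(abs(map$x - map$sensor_x[k]))
    iy <- which.min(abs(map$y - map$sensor_y[k]))
    map$field[iy, ix]
  }, numeric(1))
}
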