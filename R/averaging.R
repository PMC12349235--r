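#' Detect R peaks on the ECG channel
#'
#' Classic filtered-derivative-energy detector: 5-25 Hz zero-phase
#' bandpass, squaring, 150 ms moving-window integration, adaptive
#' threshold at 0.4 x a rolling 95th percentile of the integrated
#' signal, and a 200 ms refractory period. Squaring makes the detector
#' polarity-robust. Within each supra-threshold region the apex is the
#' maximum of the absolute bandpassed signal.
#'
#' @param ecg single-channel numeric series (or an [mcg_recording()], in
#'   which case its ecg channel is used).
#' @param sample_rate Hz.
#' @param threshold_frac fraction of the rolling 95th percentile used as
#'   detection threshold (default 0.4).
#' @param refractory_ms minimum inter-peak interval (default 200).
#' @param integration_ms moving-integration window (default 150).
#' @return an object of class `r_peak_list`: strictly increasing 1-based
#'   sample indices plus a snapshot of the detection parameters. A flat
#'   signal yields an empty list.
#' @export
detect_r_peaks <- function(ecg, sample_rate = NULL, threshold_frac = 0.4,
                           refractory_ms = 200, integration_ms = 150) {
  if (inherits(ecg, "mcg_recording")) {
    i <- channels_by_role(ecg, "ecg")
    if (!length(i)) stopf("recording has no ecg channel")
    sample_rate <- ecg$sample_rate
    ecg <- ecg$samples[i[1], ]
  }
  if (is.null(sample_rate) || sample_rate <= 0)
    stopf("parameter error: sample_rate must be positive")
  n <- length(ecg)
  if (n < 2 * sample_rate) stopf("ecg shorter than 2 s")

  sos <- rbind(butter_sos(2L, 5, sample_rate, "high"),
               butter_sos(2L, 25, sample_rate, "low"))
  bp <- sos_filter_vec(sos, ecg, zero_phase = TRUE,
                       pad = ceiling(sample_rate))
  energy <- bp^2
  w <- max(1L, round(integration_ms / 1000 * sample_rate))
  integ <- as.numeric(stats::filter(energy, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0

  if (max(integ) <= .Machine$double.eps * max(1, mean(ecg^2)))
    return(new_r_peak_list(integer(0), sample_rate, threshold_frac,
                           refractory_ms, integration_ms))

  # rolling 95th percentile on ~10 s blocks, interpolated across blocks
  blk <- max(1L, round(10 * sample_rate))
  starts <- seq(1L, n, by = blk)
  q95 <- vapply(starts, function(s)
    stats::quantile(integ[s:min(n, s + blk - 1L)], 0.95, names = FALSE),
    numeric(1))
  centers <- pmin(starts + blk / 2, n)
  thr_series <- if (length(q95) > 1)
    stats::approx(centers, q95, xout = seq_len(n), rule = 2)$y
  else rep(q95, n)
  thr <- threshold_frac * thr_series

  above <- integ > thr
  d <- diff(c(FALSE, above, FALSE))
  reg_start <- which(d == 1L)
  reg_end <- which(d == -1L) - 1L
  peaks <- integer(0)
  for (k in seq_along(reg_start)) {
    span <- reg_start[k]:reg_end[k]
    peaks <- c(peaks, span[which.max(abs(bp[span]))])
  }
  # refractory: greedy merge keeping the larger-energy peak
  refr <- round(refractory_ms / 1000 * sample_rate)
  if (length(peaks) > 1) {
    keep <- peaks[1]
    for (p in peaks[-1]) {
      last <- keep[length(keep)]
      if (p - last >= refr) keep <- c(keep, p)
      else if (integ[p] > integ[last]) keep[length(keep)] <- p
    }
    peaks <- keep
  }
  new_r_peak_list(peaks, sample_rate, threshold_frac, refractory_ms,
                  integration_ms)
}

new_r_peak_list <- function(peaks, sample_rate, threshold_frac,
                            refractory_ms, integration_ms) {
  structure(list(peaks = as.integer(peaks), sample_rate = sample_rate,
                 params = list(threshold_frac = threshold_frac,
                               refractory_ms = refractory_ms,
                               integration_ms = integration_ms)),
            class = "r_peak_list")
}

#' @export
print.r_peak_list <- function(x, ...) {
  cat(sprintf("<r_peak_list> %d peaks", length(x$peaks)))
  if (length(x$peaks) > 1)
    cat(sprintf(", mean RR %.0f ms",
                mean(diff(x$peaks)) / x$sample_rate * 1000))
  cat("\n"); invisible(x)
}

#' @export
length.r_peak_list <- function(x) length(x$peaks)

#' Extract R-aligned epochs
#'
#' Cuts one fixed-length window around each detected R peak across all
#' channels. Peaks whose window falls outside the recording are dropped
#' and counted.
#'
#' @param rec an [mcg_recording()].
#' @param peaks an `r_peak_list` (or integer sample indices).
#' @param pre_ms window before R, ms (default 300).
#' @param post_ms window after R, ms (default 600).
#' @return an object of class `epoch_set`: array `epochs x channels x
#'   samples`, window metadata, source peak indices, the count of
#'   boundary-dropped peaks, and an all-FALSE rejection mask.
#' @export
extract_epochs <- function(rec, peaks, pre_ms = 300, post_ms = 600) {
  if (pre_ms <= 0 || post_ms <= 0)
    stopf("parameter error: window must be positive on both sides")
  idx <- if (inherits(peaks, "r_peak_list")) peaks$peaks else as.integer(peaks)
  fs <- rec$sample_rate
  npre <- round(pre_ms / 1000 * fs)
  npost <- round(post_ms / 1000 * fs)
  ok <- idx - npre >= 1L & idx + npost <= ncol(rec$samples)
  dropped <- sum(!ok)
  idx <- idx[ok]
  if (!length(idx)) stopf("empty-epoch error: no peak window fits the recording")
  nsamp <- npre + npost + 1L
  ep <- array(NA_real_, c(length(idx), nrow(rec$samples), nsamp))
  for (k in seq_along(idx))
    ep[k, , ] <- rec$samples[, (idx[k] - npre):(idx[k] + npost)]
  structure(list(epochs = ep,
                 pre_ms = pre_ms, post_ms = post_ms,
                 sample_rate = fs,
                 r_indices = idx, n_dropped = dropped,
                 rejected = rep(FALSE, length(idx)),
                 channel_roles = rec$channel_roles,
                 channel_ids = rec$channel_ids,
                 channel_units = rec$channel_units),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d ch x %d samples ([-%g, +%g] ms), %d dropped at bounds\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
              x$pre_ms, x$post_ms, x$n_dropped))
  invisible(x)
}

#' Average R-aligned epochs
#'
#' Per-channel arithmetic mean over retained epochs, with optional
#' peak-to-peak amplitude rejection (off by default) applied first, and
#' per-channel baseline correction: the mean over the earliest 100 ms of
#' the window is subtracted. Phase-locked cardiac activity survives the
#' mean; non-phase-locked noise shrinks by about sqrt(N).
#'
#' @param es an `epoch_set`.
#' @param reject_ptp_pT reject an epoch when the peak-to-peak amplitude
#'   of any mcg channel exceeds this value (NULL = no rejection).
#' @param baseline_ms span at the start of the window used for the
#'   offset estimate (default 100).
#' @return an object of class `averaged_waveform`: `samples` (channels x
#'   samples), `time_ms` axis relative to R, and `n_epochs_averaged`.
#' @export
average_epochs <- function(es, reject_ptp_pT = NULL, baseline_ms = 100) {
  rejected <- es$rejected
  if (!is.null(reject_ptp_pT)) {
    i_mcg <- which(es$channel_roles == "mcg")
    if (!length(i_mcg)) i_mcg <- seq_len(dim(es$epochs)[2])
    ptp <- apply(es$epochs[, i_mcg, , drop = FALSE], 1,
                 function(m) max(apply(m, 1, function(v) diff(range(v)))))
    rejected <- rejected | ptp > reject_ptp_pT
  }
  keep <- which(!rejected)
  if (!length(keep)) stopf("empty-average error: all epochs rejected")
  avg <- apply(es$epochs[keep, , , drop = FALSE], c(2, 3), mean)
  nsamp <- dim(es$epochs)[3]
  time_ms <- (seq_len(nsamp) - 1) / es$sample_rate * 1000 - es$pre_ms
  nb <- max(1L, sum(time_ms <= time_ms[1] + baseline_ms))
  avg <- avg - rowMeans(avg[, seq_len(nb), drop = FALSE])
  structure(list(samples = avg, time_ms = time_ms,
                 sample_rate = es$sample_rate,
                 n_epochs_averaged = length(keep),
                 rejected = rejected,
                 channel_roles = es$channel_roles,
                 channel_ids = es$channel_ids,
                 channel_units = es$channel_units),
            class = "averaged_waveform")
}

#' @export
print.averaged_waveform <- function(x, ...) {
  cat(sprintf("<averaged_waveform> %d ch x %d samples, [%g, %g] ms, %d epochs\n",
              nrow(x$samples), ncol(x$samples), min(x$time_ms),
              max(x$time_ms), x$n_epochs_averaged))
  invisible(x)
}

# nearest sample index for a latency in ms
latency_index <- function(avg, latency_ms) {
  if (latency_ms < min(avg$time_ms) || latency_ms > max(avg$time_ms))
    stopf("parameter error: latency %g ms outside epoch span [%g, %g]",
          latency_ms, min(avg$time_ms), max(avg$time_ms))
  which.min(abs(avg$time_ms - latency_ms))
}
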