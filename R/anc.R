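#' Adaptive noise cancellation from reference sensors
#'
#' Environmental interference seen by the recording sensors is estimated
#' from the reference channels (which observe the interference but
#' essentially no cardiac field) and subtracted. Two adaptation modes:
#'
#' * `"ls"` (default): offline regularized least squares over the whole
#'   fit span — the normal-equations solution per recording channel on
#'   the lagged reference design. Interference in a seated session is
#'   quasi-stationary, so a single projection is appropriate, and the
#'   residual is exactly orthogonal to the regressors when `lambda = 0`.
#' * `"nlms"`: per-sample normalized LMS for streaming use; the final
#'   weight vector is returned.
#'
#' A few taps per reference (default 3, centered) absorb small phase
#' mismatch between reference and recording paths; magnetic coupling
#' itself is effectively instantaneous.
#'
#' @param rec an [mcg_recording()] with mcg and reference channels.
#' @param taps taps per reference channel (default 3).
#' @param lambda ridge regularization relative to the mean regressor
#'   power (default 1e-3); `"ls"` mode only.
#' @param mode `"ls"` or `"nlms"`.
#' @param step NLMS step size (default 0.01).
#' @param exclude_transient drop flagged filter-transient edges from the
#'   fit span (default TRUE).
#' @return an object of class `anc_filter` with the weight array
#'   (`n_mcg x n_ref x taps`), lag offsets, and fit metadata.
#' @export
fit_anc <- function(rec, taps = 3L, lambda = 1e-3,
                    mode = c("ls", "nlms"), step = 0.01,
                    exclude_transient = TRUE) {
  mode <- match.arg(mode)
  validate_recording(rec)
  taps <- as.integer(taps)
  if (taps < 1L) stopf("parameter error: taps must be >= 1")
  i_mcg <- channels_by_role(rec, "mcg")
  i_ref <- channels_by_role(rec, "reference")
  if (!length(i_mcg) || !length(i_ref))
    stopf("need at least one mcg and one reference channel")
  refs <- rec$samples[i_ref, , drop = FALSE]
  if (all(refs == 0)) stopf("degenerate-design error: reference channels are all zero")
  if (!all(is.finite(rec$samples))) stopf("validation error: non-finite samples")

  n <- ncol(rec$samples)
  offsets <- seq_len(taps) - 1L - (taps - 1L) %/% 2L   # centered lags
  fit_idx <- seq_len(n)
  tr <- rec$transient_s %||% 0
  if (exclude_transient && tr > 0 && n > 4 * tr * rec$sample_rate) {
    ntr <- round(tr * rec$sample_rate)
    fit_idx <- (ntr + 1L):(n - ntr)
  }
  X <- lagged_design(refs, offsets)
  Xf <- X[fit_idx, , drop = FALSE]
  Y <- t(rec$samples[i_mcg, fit_idx, drop = FALSE])

  if (mode == "ls") {
    XtX <- crossprod(Xf)
    ridge <- lambda * mean(diag(XtX))
    W <- solve(XtX + diag(ridge, ncol(Xf)), crossprod(Xf, Y))
  } else {
    W <- vapply(seq_len(ncol(Y)), function(j)
      .nlms(Xf, Y[, j], step, eps = 1e-3 * mean(Xf^2) * ncol(Xf))$weights,
      numeric(ncol(Xf)))
  }
  structure(list(weights = W,   # (n_ref*taps) x n_mcg
                 taps = taps, offsets = offsets,
                 n_mcg = length(i_mcg), n_ref = length(i_ref),
                 mode = mode, lambda = lambda, step = step,
                 fitted_on = list(n_samples = length(fit_idx),
                                  sample_rate = rec$sample_rate,
                                  channel_ids = rec$channel_ids)),
            class = "anc_filter")
}

# lagged reference design matrix: one column per (reference, lag),
# edges padded by replication so the design spans the full recording
lagged_design <- function(refs, offsets) {
  n <- ncol(refs)
  cols <- vector("list", nrow(refs) * length(offsets))
  k <- 1L
  for (i in seq_len(nrow(refs))) {
    for (off in offsets) {
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      cols[[k]] <- refs[i, idx]
      k <- k + 1L
    }
  }
  do.call(cbind, cols)
}

#' @export
print.anc_filter <- function(x, ...) {
  cat(sprintf("<anc_filter> %s: %d mcg x %d ref x %d taps (lags %s)\n",
              x$mode, x$n_mcg, x$n_ref, x$taps,
              paste(x$offsets, collapse = ",")))
  invisible(x)
}

#' Subtract the estimated interference
#'
#' Replaces the mcg channels by the residual `mcg - weights (*) refs`;
#' reference and ecg channels pass through unchanged.
#'
#' @param rec an [mcg_recording()] whose layout matches the filter.
#' @param filt an `anc_filter` from [fit_anc()].
#' @return the cleaned recording.
#' @export
apply_anc <- function(rec, filt) {
  validate_recording(rec)
  i_mcg <- channels_by_role(rec, "mcg")
  i_ref <- channels_by_role(rec, "reference")
  if (length(i_mcg) != filt$n_mcg || length(i_ref) != filt$n_ref)
    stopf("consistency error: recording layout (%d mcg, %d ref) does not match filter (%d, %d)",
          length(i_mcg), length(i_ref), filt$n_mcg, filt$n_ref)
  X <- lagged_design(rec$samples[i_ref, , drop = FALSE], filt$offsets)
  rec$samples[i_mcg, ] <- rec$samples[i_mcg, , drop = FALSE] -
    t(X %*% filt$weights)
  rec
}

#' Noise-suppression report
#'
#' Compares a channel before and after cancellation: amplitude spectral
#' density at 1 Hz, and broadband suppression in dB over the
#' non-transient span.
#'
#' @param before,after recordings with identical layout and length.
#' @param channel_id channel to report on.
#' @param ... passed to [noise_spectral_density()].
#' @return list with `asd_1hz_before`, `asd_1hz_after`,
#'   `suppression_1hz_db`, `broadband_db`, and a `degenerate` flag (set
#'   when the cleaned channel is identically zero).
#' @export
anc_report <- function(before, after, channel_id, ...) {
  if (nrow(before$samples) != nrow(after$samples) ||
      ncol(before$samples) != ncol(after$samples))
    stopf("consistency error: before/after layout mismatch")
  sd_b <- noise_spectral_density(before, channel_id, ...)
  sd_a <- noise_spectral_density(after, channel_id, ...)
  i <- channel_index(before, channel_id)
  span <- seq_len(ncol(before$samples))
  tr <- max(before$transient_s %||% 0, after$transient_s %||% 0)
  if (tr > 0 && length(span) > 4 * tr * before$sample_rate) {
    ntr <- round(tr * before$sample_rate)
    span <- (ntr + 1L):(length(span) - ntr)
  }
  pb <- mean(before$samples[i, span]^2)
  pa <- mean(after$samples[i, span]^2)
  degenerate <- pa == 0
  list(channel_id = channel_id,
       asd_1hz_before = density_at(sd_b, 1),
       asd_1hz_after = density_at(sd_a, 1),
       suppression_1hz_db = 20 * log10(density_at(sd_b, 1) /
                                         max(density_at(sd_a, 1), .Machine$double.xmin)),
       broadband_db = 10 * log10(pb / max(pa, .Machine$double.xmin)),
       degenerate = degenerate)
}
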