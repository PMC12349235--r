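# shared fixtures: small, fast synthetic objects built in code

# compact session for unit tests: low rate / short duration keeps the
# suite quick; study-scale defaults are exercised in test-acceptance.R
small_session <- function(seed = 1L, duration_s = 20, sample_rate = 500) {
  generate_session(session_config(duration_s = duration_s,
                                  sample_rate = sample_rate,
                                  ern_duration_s = duration_s),
                   seed = seed)
}

# single-role recording wrapper around a channels x time matrix
make_rec <- function(samples, sample_rate = 500, roles = NULL) {
  samples <- rbind(samples)
  mcg_recording(samples, sample_rate = sample_rate,
                channel_roles = roles %||% rep("mcg", nrow(samples)))
}

# minimal averaged_waveform for model-level tests
make_avg <- function(samples, sample_rate = 500, pre_ms = 300) {
  samples <- rbind(samples)
  nsamp <- ncol(samples)
  structure(list(samples = samples,
                 time_ms = (seq_len(nsamp) - 1) / sample_rate * 1000 - pre_ms,
                 sample_rate = sample_rate,
                 n_epochs_averaged = 1L,
                 rejected = logical(0),
                 channel_roles = rep("mcg", nrow(samples)),
                 channel_ids = sprintf("MCG%02d", seq_len(nrow(samples))),
                 channel_units = rep("pT", nrow(samples))),
            class = "averaged_waveform")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# waveform with unit-RMS baseline (in [-350, -250] ms) and a
# controllable QRS peak at time zero; 1 kHz epoch from -400 to +600 ms
snr_fixture <- function(qrs_peak, d = 1) {
  nsamp <- 1001L
  tms <- (0:(nsamp - 1)) - 400
  x <- numeric(nsamp)
  base_idx <- tms >= -350 & tms <= -250
  v <- rep(c(1, -1), length.out = sum(base_idx))
  v <- v - mean(v)
  x[base_idx] <- v / sqrt(mean(v^2))   # zero mean, RMS exactly 1
  x[tms == 0] <- qrs_peak
  make_avg(matrix(rep(x, d), d, byrow = TRUE), 1000, pre_ms = 400)
}

# memoized full-scale default session shared by acceptance blocks
.acceptance_cache <- new.env(parent = emptyenv())
default_session_cached <- function(seed = 101L) {
  key <- paste0("s", seed)
  if (is.null(.acceptance_cache[[key]]))
    .acceptance_cache[[key]] <- generate_session(seed = seed)
  .acceptance_cache[[key]]
}
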