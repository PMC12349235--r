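#' Multichannel recording container
#'
#' Time-aligned multichannel samples with per-channel roles. Magnetic
#' channels (`mcg`, `reference`) are in picotesla; the `ecg` channel in
#' millivolt. The canonical session layout is 42 `mcg` + 21 `reference` +
#' 1 `ecg` channel at 5000 Hz.
#'
#' Magnetic samples must be finite and inside the sensor dynamic range of
#' +-4.5e7 pT (+-45 uT).
#'
#' @param samples numeric matrix, channels x time.
#' @param sample_rate sampling rate in Hz (default 5000).
#' @param channel_roles character vector, one of `"mcg"`, `"reference"`,
#'   `"ecg"` per channel.
#' @param channel_units per-channel units; defaults to `"pT"` for magnetic
#'   roles and `"mV"` for ecg.
#' @param start_time recording start in seconds (default 0).
#' @param channel_ids stable channel labels; defaults to `MCG01..`,
#'   `REF01..`, `ECG1` by role order of appearance.
#' @param acquisition_date optional date tag (used for empty-room
#'   calibration recordings).
#' @return an object of class `mcg_recording`.
#' @export
mcg_recording <- function(samples, sample_rate = 5000, channel_roles,
                          channel_units = NULL, start_time = 0,
                          channel_ids = NULL, acquisition_date = NULL) {
  samples <- as.matrix(samples)
  channel_roles <- as.character(channel_roles)
  bad <- setdiff(unique(channel_roles), c("mcg", "reference", "ecg"))
  if (length(bad))
    stopf("unknown channel role(s): %s", paste(bad, collapse = ", "))
  if (is.null(channel_units))
    channel_units <- ifelse(channel_roles == "ecg", "mV", "pT")
  if (is.null(channel_ids)) {
    channel_ids <- character(length(channel_roles))
    for (role in unique(channel_roles)) {
      idx <- which(channel_roles == role)
      pre <- c(mcg = "MCG", reference = "REF", ecg = "ECG")[[role]]
      wid <- if (role == "ecg") 1L else 2L
      channel_ids[idx] <- sprintf(paste0(pre, "%0", wid, "d"), seq_along(idx))
    }
  }
  rec <- structure(
    list(samples = samples, sample_rate = sample_rate,
         channel_roles = channel_roles, channel_units = channel_units,
         start_time = start_time, channel_ids = channel_ids,
         acquisition_date = acquisition_date),
    class = "mcg_recording")
  validate_recording(rec)
  rec
}

DYNAMIC_RANGE_PT <- 4.5e7

#' @rdname mcg_recording
#' @param rec an `mcg_recording`.
#' @export
validate_recording <- function(rec) {
  req <- c("samples", "sample_rate", "channel_roles", "channel_units",
           "channel_ids")
  miss <- setdiff(req, names(rec))
  if (length(miss))
    stopf("recording format error: missing field(s) %s",
          paste(miss, collapse = ", "))
  assert_scalar_num(rec$sample_rate, "sample_rate", positive = TRUE)
  n_ch <- nrow(rec$samples)
  if (length(rec$channel_roles) != n_ch ||
      length(rec$channel_units) != n_ch ||
      length(rec$channel_ids) != n_ch)
    stopf("recording consistency error: %d sample rows but %d roles / %d units / %d ids",
          n_ch, length(rec$channel_roles), length(rec$channel_units),
          length(rec$channel_ids))
  bad <- setdiff(unique(rec$channel_roles), c("mcg", "reference", "ecg"))
  if (length(bad)) stopf("unknown channel role(s): %s", paste(bad, collapse = ", "))
  mag <- rec$channel_roles != "ecg"
  if (any(mag)) {
    ms <- rec$samples[mag, , drop = FALSE]
    if (anyNA(ms) || !all(is.finite(ms)))
      stopf("validation error: non-finite magnetic samples")
    if (max(abs(ms)) > DYNAMIC_RANGE_PT)
      stopf("validation error: magnetic samples exceed dynamic range of +-%g pT",
            DYNAMIC_RANGE_PT)
  }
  if (any(!mag) && anyNA(rec$samples[!mag, , drop = FALSE]))
    stopf("validation error: NA ecg samples")
  invisible(rec)
}

#' @export
print.mcg_recording <- function(x, ...) {
  tab <- table(factor(x$channel_roles, c("mcg", "reference", "ecg")))
  cat(sprintf("<mcg_recording> %d ch (%s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples),
              paste(sprintf("%s:%d", names(tab), tab), collapse = " "),
              ncol(x$samples), x$sample_rate,
              ncol(x$samples) / x$sample_rate))
  invisible(x)
}

#' Channel helpers
#'
#' `channels_by_role` returns the row indices of a role; `channel_index`
#' resolves a channel id; `n_samples` the recording length.
#'
#' @param rec an [mcg_recording()].
#' @param role one of `"mcg"`, `"reference"`, `"ecg"`.
#' @export
channels_by_role <- function(rec, role) which(rec$channel_roles == role)

#' @rdname channels_by_role
#' @param channel_id a channel label such as `"MCG05"`.
#' @export
channel_index <- function(rec, channel_id) {
  i <- match(channel_id, rec$channel_ids)
  if (is.na(i)) stopf("channel '%s' not found", channel_id)
  i
}

#' @rdname channels_by_role
#' @export
n_samples <- function(rec) ncol(rec$samples)

#' Write / load a recording container
#'
#' Recordings are persisted through R's native serialization, which
#' round-trips samples and metadata bit-identically. The writer validates
#' the recording (non-finite magnetic samples are rejected before
#' anything touches disk).
#'
#' @param rec an [mcg_recording()].
#' @param path file path.
#' @return `load_recording` returns the recording; `write_recording`
#'   returns `path` invisibly.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "mcg_recording")) stopf("not an mcg_recording")
  validate_recording(rec)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stopf("I/O error: cannot open '%s' for writing", path))
  on.exit(close(con))
  saveRDS(rec, con)
  invisible(path)
}

#' @rdname write_recording
#' @export
load_recording <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  rec <- readRDS(path)
  if (!inherits(rec, "mcg_recording"))
    stopf("recording format error: '%s' does not contain an mcg_recording", path)
  validate_recording(rec)
  rec
}

#' Tag a recording as an empty-room calibration recording
#'
#' Empty-room noise (ERN) recordings share the magnetic channel layout of
#' the sessions they calibrate but contain no ECG channel and carry an
#' acquisition-date tag. Used to learn the interference spatial model for
#' signal-space projection.
#'
#' @param rec an [mcg_recording()] without ecg channels.
#' @param acquisition_date date tag (default today).
#' @return the recording with class `empty_room_recording` prepended.
#' @export
as_empty_room <- function(rec, acquisition_date = Sys.Date()) {
  if (any(rec$channel_roles == "ecg"))
    stopf("empty-room recording must not contain an ecg channel")
  rec$acquisition_date <- as.character(acquisition_date)
  class(rec) <- unique(c("empty_room_recording", class(rec)))
  rec
}
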