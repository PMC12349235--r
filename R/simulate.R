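#' Cardiac source model for session simulation
#'
#' A single equivalent current dipole with a PQRST time course modeled as
#' a sum of five Gaussians. Defaults place the dipole 12 cm in front of
#' the array center (negative z), oriented in-plane, which produces the
#' classic two-pole isofield pattern at the array. Relative component
#' amplitudes put P and T roughly an order of magnitude below R, so P
#' resolution genuinely depends on the later denoising stages. The dipole
#' moment is scaled at generation time so the peak field over the
#' recording sensors equals `peak_field_pT` (cardiac fields at the torso
#' are of order 50-100 pT).
#'
#' @param dipole_position 3-vector, metres (default `c(0, 0, -0.12)`).
#' @param dipole_orientation 3-vector, normalized internally (default in-plane, +x).
#' @param pqrst data frame with columns `wave`, `amplitude` (relative),
#'   `center_ms` (relative to R), `width_ms` (Gaussian SD).
#' @param heart_rate_bpm mean heart rate (default 60).
#' @param rr_jitter_ms SD of the inter-beat interval, ms (default 30).
#' @param peak_field_pT target peak field at the nearest sensor (default 100).
#' @return an object of class `cardiac_source_model`.
#' @export
cardiac_source_model <- function(dipole_position = c(0, 0, -0.12),
                                 dipole_orientation = c(1, 0, 0),
                                 pqrst = default_pqrst(),
                                 heart_rate_bpm = 60,
                                 rr_jitter_ms = 30,
                                 peak_field_pT = 100) {
  if (any(pqrst$width_ms <= 0)) stopf("pqrst widths must be positive")
  r_amp <- abs(pqrst$amplitude[pqrst$wave == "R"])
  if (!length(r_amp) || any(abs(pqrst$amplitude) > r_amp))
    stopf("R must be the largest-magnitude pqrst component")
  dipole_orientation <- dipole_orientation / sqrt(sum(dipole_orientation^2))
  structure(list(dipole_position = dipole_position,
                 dipole_orientation = dipole_orientation,
                 pqrst = pqrst, heart_rate_bpm = heart_rate_bpm,
                 rr_jitter_ms = rr_jitter_ms, peak_field_pT = peak_field_pT),
            class = "cardiac_source_model")
}

#' @rdname cardiac_source_model
#' @export
default_pqrst <- function() {
  data.frame(wave = c("P", "Q", "R", "S", "T"),
             amplitude = c(0.08, -0.12, 1.0, -0.25, 0.35),
             center_ms = c(-200, -25, 0, 30, 250),
             width_ms = c(25, 8, 12, 12, 50))
}

#' Evaluate a PQRST template
#'
#' Sum-of-Gaussians beat template at times `t_ms` relative to the R apex.
#'
#' @param t_ms times in ms relative to R.
#' @param pqrst template table as in [cardiac_source_model()].
#' @return numeric vector of relative amplitudes.
#' @export
pqrst_waveform <- function(t_ms, pqrst = default_pqrst()) {
  out <- numeric(length(t_ms))
  for (i in seq_len(nrow(pqrst)))
    out <- out + pqrst$amplitude[i] *
      exp(-0.5 * ((t_ms - pqrst$center_ms[i]) / pqrst$width_ms[i])^2)
  out
}

# dipole->sensor gain matrix: field along each sensing axis per unit
# moment. B(r) = (mu0/4pi) Q x (r - r0) / |r - r0|^3 projected on the
# axis, i.e. gain row = K (d x axis)/|d|^3 (scalar triple product
# rearrangement). K converts A.m / m^2 to pT.
geometry_gain <- function(dipole_position, positions, axes) {
  K <- 1e5   # (mu0/4pi) * 1e12
  d <- sweep(positions, 2, dipole_position)
  r3 <- (rowSums(d^2))^(3 / 2)
  if (any(sqrt(rowSums(d^2)) < 1e-3))
    stopf("proximity error: dipole within 1 mm of a sensor")
  cr <- cbind(d[, 2] * axes[, 3] - d[, 3] * axes[, 2],
              d[, 3] * axes[, 1] - d[, 1] * axes[, 3],
              d[, 1] * axes[, 2] - d[, 2] * axes[, 1])
  K * cr / r3
}

#' Current-dipole forward field
#'
#' Free-space magnetostatic field of a current dipole, projected on each
#' sensor's sensing axis. Linear in the moment.
#'
#' @param moment dipole moment: a 3-vector, or a T x 3 matrix for a time
#'   series.
#' @param dipole_position 3-vector, metres.
#' @param geometry a [sensor_array_geometry()].
#' @param sensors `"all"` (recording then reference), `"recording"`, or
#'   `"reference"`.
#' @return a vector (one value per sensor, pT) for a single moment, or a
#'   sensors x time matrix for a series.
#' @export
forward_field <- function(moment, dipole_position, geometry,
                          sensors = c("all", "recording", "reference")) {
  sensors <- match.arg(sensors)
  pos <- switch(sensors,
                all = rbind(geometry$recording_positions, geometry$reference_positions),
                recording = geometry$recording_positions,
                reference = geometry$reference_positions)
  axes <- switch(sensors,
                 all = rbind(geometry$recording_axes, geometry$reference_axes),
                 recording = geometry$recording_axes,
                 reference = geometry$reference_axes)
  G <- geometry_gain(dipole_position, pos, axes)
  if (is.matrix(moment)) G %*% t(moment) else drop(G %*% moment)
}

#' Simulate the dipole-moment time series and beat times
#'
#' Places beats at jittered RR intervals, evaluates the PQRST template
#' around each R time, and scales the moment so the peak forward field
#' over the recording sensors equals the configured target.
#'
#' @param src a [cardiac_source_model()].
#' @param duration_s recording length, s.
#' @param sample_rate Hz.
#' @param seed integer seed (beat-timing jitter).
#' @param geometry geometry used for the peak-field normalization.
#' @return list with `moment` (T x 3 matrix, A.m), `waveform` (relative
#'   template series), `r_peaks` (1-based sample indices of R apices),
#'   and `moment_scale`.
#' @export
cardiac_moment_series <- function(src, duration_s, sample_rate, seed = 1L,
                                  geometry = default_geometry()) {
  if (duration_s <= 0 || sample_rate <= 0)
    stopf("parameter error: duration and sample rate must be positive")
  rr_s <- 60 / src$heart_rate_bpm
  jit_s <- src$rr_jitter_ms / 1000
  if (5 * jit_s >= rr_s)
    stopf("parameter error: rr jitter too large for the mean RR interval")
  set.seed(derive_seed(seed, 11L))
  t_r <- 0.5
  repeat {
    iv <- rr_s + stats::rnorm(1) * jit_s
    if (iv <= 0) stopf("parameter error: non-positive RR interval sampled")
    nxt <- t_r[length(t_r)] + iv
    if (nxt > duration_s) break
    t_r <- c(t_r, nxt)
  }
  n <- round(duration_s * sample_rate)
  wf <- numeric(n)
  half_win <- 0.6  # template support half-width, s
  for (tr in t_r) {
    i0 <- max(1L, floor((tr - half_win) * sample_rate) + 1L)
    i1 <- min(n, ceiling((tr + half_win) * sample_rate) + 1L)
    tt <- ((i0:i1) - 1) / sample_rate - tr
    wf[i0:i1] <- wf[i0:i1] + pqrst_waveform(tt * 1000, src$pqrst)
  }
  G <- geometry_gain(src$dipole_position, geometry$recording_positions,
                     geometry$recording_axes)
  unit_gain <- max(abs(G %*% src$dipole_orientation))
  scale <- src$peak_field_pT / (unit_gain * max(abs(wf)))
  r_peaks <- round(t_r * sample_rate) + 1L
  r_peaks <- r_peaks[r_peaks >= 1L & r_peaks <= n]
  list(moment = outer(wf * scale, src$dipole_orientation),
       waveform = wf, r_peaks = r_peaks, moment_scale = scale)
}

#' Environmental interference scenario
#'
#' Low-rank spatially coherent interference: a small number of fixed
#' spatial patterns (field values at every magnetic sensor, recording
#' then reference) driven by independent time courses. Default patterns
#' are uniform and first-order-gradient far-field structures, which is
#' what distant environmental sources produce at a compact array; each
#' pattern is normalized to unit RMS over the recording sensors so the
#' time-course amplitudes are in pT at the array.
#'
#' Default time courses: 50 Hz powerline with a 150 Hz harmonic, two
#' independent 1/f-amplitude drift processes (calibrated so the central
#' recording channel sees an amplitude density of a few hundred
#' pT/sqrt(Hz) at 1 Hz, the regime that swamps unshielded cardiac
#' fields), and one broadband AR(1) course.
#'
#' @param spatial_patterns (n_recording + n_reference) x n_patterns matrix.
#' @param time_course_spec list (one element per pattern) of lists with a
#'   `type` in `"powerline"`, `"drift"`, `"broadband"` plus amplitude
#'   parameters (`amplitude_pT`, `asd_1hz`, `rms_pT`).
#' @return an object of class `interference_scenario`.
#' @export
interference_scenario <- function(spatial_patterns, time_course_spec) {
  k <- ncol(spatial_patterns)
  if (length(time_course_spec) != k)
    stopf("need one time-course spec per pattern")
  if (qr(spatial_patterns)$rank < k)
    stopf("spatial pattern matrix must have full column rank")
  structure(list(n_patterns = k, spatial_patterns = spatial_patterns,
                 time_course_spec = time_course_spec),
            class = "interference_scenario")
}

#' @rdname interference_scenario
#' @param geometry a [sensor_array_geometry()].
#' @param drift_asd_1hz 1 Hz amplitude density of each drift course,
#'   pT/sqrt(Hz) (default 350, putting the central recording channel
#'   near 345 pT/sqrt(Hz) at 1 Hz before cancellation).
#' @param powerline_pT powerline amplitude at the array (default 1000).
#' @param broadband_rms_pT RMS of the broadband course (default 40).
#' @export
default_interference_scenario <- function(geometry = default_geometry(),
                                          drift_asd_1hz = 350,
                                          powerline_pT = 1000,
                                          broadband_rms_pT = 40) {
  pos <- rbind(geometry$recording_positions, geometry$reference_positions)
  axes <- rbind(geometry$recording_axes, geometry$reference_axes)
  n_rec <- nrow(geometry$recording_positions)
  field_patterns <- list(
    function(r) c(0.25, 0.30, 0.92),
    function(r) c(0.55, -0.25, 0.60) + c(0, 0, 1) * (r[1] / 0.3),
    function(r) c(-0.20, 0.65, 0.45) + c(0, 0, 1) * (r[2] / 0.25),
    function(r) c(0.35, -0.30, 0.30) + c(0, 0, 1) * (r[1] * r[2] / 0.03)
  )
  P <- vapply(field_patterns, function(fp)
    vapply(seq_len(nrow(pos)),
           function(i) sum(fp(pos[i, ]) * axes[i, ]), numeric(1)),
    numeric(nrow(pos)))
  # unit RMS over recording sensors
  P <- sweep(P, 2, sqrt(colMeans(P[seq_len(n_rec), , drop = FALSE]^2)), "/")
  spec <- list(
    list(type = "powerline", amplitude_pT = powerline_pT,
         f0_hz = 50, harmonic_ratio = 0.3),
    list(type = "drift", asd_1hz = drift_asd_1hz),
    list(type = "drift", asd_1hz = drift_asd_1hz),
    list(type = "broadband", rms_pT = broadband_rms_pT, corner_hz = 5)
  )
  interference_scenario(P, spec)
}

# colored-noise synthesis with one-sided amplitude density asd_fun(f),
# by random-phase frequency-domain shaping; draws from the current RNG
synth_colored_noise <- function(n, fs, asd_fun) {
  nf <- n %/% 2
  f <- (1:nf) * fs / n
  mag <- asd_fun(f) * sqrt(fs * n / 2)
  z <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) / sqrt(2)
  X <- numeric(0)
  spec <- mag * z
  if (n %% 2 == 0) spec[nf] <- complex(real = Re(spec[nf]) * sqrt(2), imaginary = 0)
  full <- c(0 + 0i, spec,
            if (n %% 2 == 0) Conj(rev(spec[-nf])) else Conj(rev(spec)))
  Re(stats::fft(full, inverse = TRUE)) / n
}

#' Realize interference time courses and channel series
#'
#' @param scn an [interference_scenario()].
#' @param duration_s length, s.
#' @param sample_rate Hz.
#' @param seed integer seed.
#' @return matrix (n_channels x time): `spatial_patterns %*% t(courses)`.
#' @export
generate_interference <- function(scn, duration_s, sample_rate, seed = 1L) {
  if (duration_s <= 0 || sample_rate <= 0)
    stopf("parameter error: duration and sample rate must be positive")
  n <- round(duration_s * sample_rate)
  tt <- (seq_len(n) - 1) / sample_rate
  set.seed(derive_seed(seed, 23L))
  courses <- matrix(0, n, scn$n_patterns)
  for (j in seq_len(scn$n_patterns)) {
    sp <- scn$time_course_spec[[j]]
    courses[, j] <- switch(sp$type,
      powerline = {
        ph <- stats::runif(2, 0, 2 * pi)
        sp$amplitude_pT * (sin(2 * pi * sp$f0_hz * tt + ph[1]) +
          (sp$harmonic_ratio %||% 0.3) * sin(2 * pi * 3 * sp$f0_hz * tt + ph[2]))
      },
      drift = synth_colored_noise(n, sample_rate,
        function(f) sp$asd_1hz / pmax(f, 0.05)),
      broadband = {
        phi <- exp(-2 * pi * (sp$corner_hz %||% 5) / sample_rate)
        x <- stats::filter(stats::rnorm(n), phi, method = "recursive")
        as.numeric(x) / stats::sd(x) * sp$rms_pT
      },
      stopf("unknown time-course type '%s'", sp$type))
  }
  scn$spatial_patterns %*% t(courses)
}

#' Session simulation configuration
#'
#' Defaults mirror the acquisition protocol the pipeline targets: 120 s
#' at 5000 Hz, sensor noise floor 3.1 pT/sqrt(Hz), 42+21+1 channels, and
#' a matched empty-room recording generated from the same interference
#' scenario with an independent realization.
#'
#' @param source a [cardiac_source_model()].
#' @param scenario an [interference_scenario()] (default scenario if NULL).
#' @param geometry a [sensor_array_geometry()].
#' @param duration_s session length, s (default 120).
#' @param sample_rate Hz (default 5000).
#' @param sensor_noise_asd white sensor-noise amplitude density,
#'   pT/sqrt(Hz) (default 3.1).
#' @param ecg_amplitude_mV R amplitude of the synthetic lead-II-like ECG.
#' @param ecg_noise_mV additive white noise SD on the ECG channel, mV
#'   (default 0.1; after averaging ~120 beats this yields surface-ECG-like
#'   baseline quality).
#' @param ern_duration_s empty-room recording length (default `duration_s`).
#' @return an object of class `session_config`.
#' @export
session_config <- function(source = cardiac_source_model(),
                           scenario = NULL,
                           geometry = default_geometry(),
                           duration_s = 120, sample_rate = 5000,
                           sensor_noise_asd = 3.1,
                           ecg_amplitude_mV = 1.0, ecg_noise_mV = 0.1,
                           ern_duration_s = duration_s) {
  if (duration_s <= 0 || sample_rate <= 0)
    stopf("parameter error: duration and sample rate must be positive")
  if (is.null(scenario)) scenario <- default_interference_scenario(geometry)
  structure(list(source = source, scenario = scenario, geometry = geometry,
                 duration_s = duration_s, sample_rate = sample_rate,
                 sensor_noise_asd = sensor_noise_asd,
                 ecg_amplitude_mV = ecg_amplitude_mV,
                 ecg_noise_mV = ecg_noise_mV,
                 ern_duration_s = ern_duration_s),
            class = "session_config")
}

# lead-II-like surrogate template (mV, R-normalized)
ecg_pqrst <- function() {
  data.frame(wave = c("P", "Q", "R", "S", "T"),
             amplitude = c(0.15, -0.10, 1.0, -0.25, 0.30),
             center_ms = c(-180, -20, 0, 25, 250),
             width_ms = c(22, 7, 10, 10, 55))
}

#' Generate a synthetic recording session with ground truth
#'
#' Builds a full session: cardiac dipole fields at all magnetic sensors,
#' low-rank environmental interference, white sensor noise at the
#' configured floor, a simultaneous R-aligned ECG channel, and a matched
#' empty-room recording (same interference scenario, independent
#' realization, no cardiac source). MCG rows decompose exactly as
#' `clean + interference + noise`.
#'
#' Cardiac leakage into the reference sensors keeps the forward-law
#' spatial pattern but its gain is bounded so the mean reference-channel
#' cardiac energy is 5e-5 of the mean recording-channel cardiac energy
#' (>= 100x amplitude attenuation): reference modules are placed and
#' oriented to reject the near-field source, and adaptive noise
#' cancellation's signal-preservation guarantee rests on that rejection.
#'
#' @param config a [session_config()].
#' @param seed integer seed; every stochastic component derives an
#'   independent stream from it.
#' @return an object of class `synthetic_session`: list with `recording`
#'   ([mcg_recording()]), `empty_room`, and `truth` (per-channel clean
#'   cardiac field, interference, R-peak indices, reference leakage,
#'   spatial patterns, source waveform).
#' @export
generate_session <- function(config = session_config(), seed = 1L) {
  fs <- config$sample_rate
  geom <- config$geometry
  n <- round(config$duration_s * fs)
  n_rec <- nrow(geom$recording_positions)
  n_ref <- nrow(geom$reference_positions)

  cm <- cardiac_moment_series(config$source, config$duration_s, fs,
                              seed = seed, geometry = geom)
  clean_rec <- geometry_gain(config$source$dipole_position,
                             geom$recording_positions, geom$recording_axes) %*%
    t(cm$moment)
  clean_ref <- geometry_gain(config$source$dipole_position,
                             geom$reference_positions, geom$reference_axes) %*%
    t(cm$moment)
  e_rec <- mean(rowMeans(clean_rec^2))
  e_ref <- mean(rowMeans(clean_ref^2))
  leak_gain <- if (e_ref > 0) min(1, sqrt(5e-5 * e_rec / e_ref)) else 0
  clean_ref <- clean_ref * leak_gain

  interf <- generate_interference(config$scenario, config$duration_s, fs,
                                  seed = derive_seed(seed, 2L))
  sigma <- config$sensor_noise_asd * sqrt(fs / 2)
  set.seed(derive_seed(seed, 3L))
  noise <- matrix(stats::rnorm((n_rec + n_ref) * n, sd = sigma),
                  n_rec + n_ref, n)

  set.seed(derive_seed(seed, 4L))
  t_ms_all <- rep(0, n)
  ecg <- numeric(n)
  for (tr in (cm$r_peaks - 1) / fs) {
    i0 <- max(1L, floor((tr - 0.6) * fs) + 1L)
    i1 <- min(n, ceiling((tr + 0.6) * fs) + 1L)
    tt <- ((i0:i1) - 1) / fs - tr
    ecg[i0:i1] <- ecg[i0:i1] + pqrst_waveform(tt * 1000, ecg_pqrst())
  }
  ecg <- ecg * config$ecg_amplitude_mV +
    stats::rnorm(n, sd = config$ecg_noise_mV)

  mag <- rbind(clean_rec, clean_ref) + interf + noise
  samples <- rbind(mag, ecg)
  recording <- mcg_recording(samples, sample_rate = fs,
                             channel_roles = c(rep("mcg", n_rec),
                                               rep("reference", n_ref), "ecg"))

  n_ern <- round(config$ern_duration_s * fs)
  ern_interf <- generate_interference(config$scenario, config$ern_duration_s,
                                      fs, seed = derive_seed(seed, 5L))
  set.seed(derive_seed(seed, 6L))
  ern_samples <- ern_interf +
    matrix(stats::rnorm((n_rec + n_ref) * n_ern, sd = sigma),
           n_rec + n_ref, n_ern)
  empty_room <- as_empty_room(
    mcg_recording(ern_samples, sample_rate = fs,
                  channel_roles = c(rep("mcg", n_rec), rep("reference", n_ref))),
    acquisition_date = "synthetic")

  structure(list(
    recording = recording,
    empty_room = empty_room,
    truth = list(clean = clean_rec,
                 clean_reference = clean_ref,
                 interference = interf[seq_len(n_rec), , drop = FALSE],
                 interference_reference = interf[n_rec + seq_len(n_ref), ,
                                                 drop = FALSE],
                 r_peaks = cm$r_peaks,
                 spatial_patterns = config$scenario$spatial_patterns,
                 source_waveform = cm$waveform,
                 moment_scale = cm$moment_scale,
                 leak_gain = leak_gain),
    config = config, seed = seed),
    class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> seed %d, %.0f s @ %g Hz, %d beats\n",
              x$seed, x$config$duration_s, x$config$sample_rate,
              length(x$truth$r_peaks)))
  invisible(x)
}
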