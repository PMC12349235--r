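#' Pipeline configuration
#'
#' Parameters for the fixed processing chain: digital filters ->
#' adaptive noise cancellation -> R detection / epoch averaging ->
#' signal-space projection -> metrics and maps. Stages can be toggled;
#' the stage order is fixed.
#'
#' @param filter a [filter_spec()].
#' @param anc_enabled run the ANC stage (default TRUE).
#' @param anc list of [fit_anc()] options (`taps`, `lambda`, `mode`, `step`).
#' @param ssp_enabled run the signal-space-projection stage (default TRUE).
#' @param pre_ms,post_ms epoch window around R (defaults 300 / 600).
#' @param q interference factor count (NULL = scree selection).
#' @param p signal factor count (NULL = evoked-variance dominance
#'   selection, capped at 4).
#' @param snr an [snr_definition()].
#' @param map_latencies_ms named latencies for the isofield maps
#'   (defaults: Q -25 ms, R 0 ms, QRS end +60 ms).
#' @param report_channel channel for the ANC suppression report
#'   (default `"MCG18"`, a central grid sensor).
#' @param out_dir optional directory for stage checkpoints (RDS).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = filter_spec(),
                            anc_enabled = TRUE,
                            anc = list(taps = 3L, lambda = 1e-3, mode = "ls"),
                            ssp_enabled = TRUE,
                            pre_ms = 300, post_ms = 600,
                            q = NULL, p = NULL,
                            snr = snr_definition(),
                            map_latencies_ms = c(q = -25, r = 0, qrs_end = 60),
                            report_channel = "MCG18",
                            out_dir = NULL) {
  structure(list(filter = filter, anc_enabled = anc_enabled, anc = anc,
                 ssp_enabled = ssp_enabled, pre_ms = pre_ms,
                 post_ms = post_ms, q = q, p = p, snr = snr,
                 map_latencies_ms = map_latencies_ms,
                 report_channel = report_channel, out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(serialize(cfg, NULL, version = 3), tf)
  unname(tools::md5sum(tf))
}

checkpoint <- function(obj, cfg, name) {
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(obj, file.path(cfg$out_dir, paste0(name, ".rds")))
  }
  invisible(obj)
}

with_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  attr(res, "stage_elapsed_s") <- proc.time()[["elapsed"]] - t0
  res
}

#' Run the full processing pipeline on one session
#'
#' Executes filters -> ANC -> R-synchronized averaging -> SSP, computes
#' the SNR at each of the three MCG stages (filters-only / +ANC / +SSP)
#' and for the averaged ECG, the ANC suppression report, and isofield
#' maps at the Q, R and QRS-end latencies. The reporting channel is
#' selected by maximum QRS amplitude on the final (cleanest) stage and
#' held fixed across stages so the per-stage SNRs are comparable.
#'
#' @param session a `synthetic_session`, or a list with elements
#'   `recording` and `empty_room` ([mcg_recording()] objects or file
#'   paths).
#' @param config a [pipeline_config()].
#' @param geometry array geometry for the maps (default
#'   [default_geometry()]).
#' @return an object of class `pipeline_result`: per-stage SNRs,
#'   averaged waveforms, fitted models, maps, R peaks, ANC report, and a
#'   run manifest (config hash, parameters, stage timings, skipped
#'   stages, package version).
#' @export
run_pipeline <- function(session, config = pipeline_config(),
                         geometry = default_geometry()) {
  rec <- session$recording
  ern <- session$empty_room
  if (is.character(rec)) rec <- load_recording(rec)
  if (is.character(ern)) ern <- load_recording(ern)
  timings <- c()
  note_time <- function(name, obj) {
    timings[[name]] <<- attr(obj, "stage_elapsed_s")
    attr(obj, "stage_elapsed_s") <- NULL
    obj
  }

  filt <- note_time("filters", with_stage("filters", {
    r <- apply_bandpass(rec, config$filter)
    apply_notch(r, config$filter)
  }))
  checkpoint(filt, config, "filtered")

  peaks <- note_time("r_detection",
                     with_stage("r_detection", detect_r_peaks(filt)))
  if (!length(peaks$peaks)) stopf("pipeline error: no R peaks detected")

  avg_filt <- with_stage("average_filters",
    average_epochs(extract_epochs(filt, peaks, config$pre_ms, config$post_ms)))
  avg_filt <- note_time("average_filters", avg_filt)

  anc_rep <- NULL
  if (config$anc_enabled) {
    cleaned <- note_time("anc", with_stage("anc", {
      af <- do.call(fit_anc, c(list(rec = filt), config$anc))
      apply_anc(filt, af)
    }))
    checkpoint(cleaned, config, "anc")
    win_s <- min(10, ncol(filt$samples) / filt$sample_rate / 4)
    anc_rep <- anc_report(filt, cleaned, config$report_channel,
                          window_s = win_s)
    avg_anc <- average_epochs(
      extract_epochs(cleaned, peaks, config$pre_ms, config$post_ms))
    rm(cleaned)
  } else {
    avg_anc <- avg_filt
  }
  checkpoint(avg_anc, config, "averaged")
  rm(filt); gc(FALSE)

  im <- sm <- den <- NULL
  if (config$ssp_enabled) {
    ssp <- note_time("ssp", with_stage("ssp", {
      ern_f <- apply_notch(apply_bandpass(ern, config$filter), config$filter)
      if (config$anc_enabled) {
        ern_af <- do.call(fit_anc, c(list(rec = ern_f), config$anc))
        ern_f <- apply_anc(ern_f, ern_af)
      }
      im <- fit_interference_model(ern_f, q = config$q,
                                   cov_scale = 1 / avg_anc$n_epochs_averaged)
      sm <- fit_signal_model(avg_anc, im, p = config$p)
      list(im = im, sm = sm, den = denoise(avg_anc, sm, im))
    }))
    im <- ssp$im; sm <- ssp$sm; den <- ssp$den
    checkpoint(den, config, "ssp")
  }

  final_wave <- if (!is.null(den)) den$waveform else avg_anc
  channel <- select_channel(final_wave, config$snr)
  snr <- c(filters = snr_db(avg_filt, config$snr, channel),
           anc = if (config$anc_enabled)
             snr_db(avg_anc, config$snr, channel) else NA_real_,
           ssp = if (config$ssp_enabled)
             snr_db(den$waveform, config$snr, channel) else NA_real_)
  ecg_ch <- which(avg_filt$channel_roles == "ecg")
  snr["ecg"] <- if (length(ecg_ch))
    snr_db(avg_filt, config$snr, ecg_ch[1]) else NA_real_

  maps <- lapply(config$map_latencies_ms, function(l)
    build_isofield_map(final_wave, geometry, l))

  manifest <- list(config_hash = config_hash(config),
                   config = config,
                   seed = session$seed %||% NA,
                   skipped_stages = c(if (!config$anc_enabled) "anc",
                                      if (!config$ssp_enabled) "ssp"),
                   n_epochs = avg_anc$n_epochs_averaged,
                   stage_timings_s = timings,
                   package_version = as.character(utils::packageVersion("stormmcg")),
                   r_version = R.version.string)

  structure(list(snr = snr, selected_channel = channel,
                 averaged = list(filters = avg_filt, anc = avg_anc,
                                 ssp = if (!is.null(den)) den$waveform),
                 denoised = den,
                 models = list(interference = im, signal = sm),
                 maps = maps, r_peaks = peaks, anc_report = anc_rep,
                 manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  channel %s; SNR [dB]: filters %.1f | ANC %s | SSP %s | ECG %s\n",
              x$selected_channel, x$snr["filters"],
              ifelse(is.na(x$snr["anc"]), "-", sprintf("%.1f", x$snr["anc"])),
              ifelse(is.na(x$snr["ssp"]), "-", sprintf("%.1f", x$snr["ssp"])),
              ifelse(is.na(x$snr["ecg"]), "-", sprintf("%.1f", x$snr["ecg"]))))
  if (length(x$manifest$skipped_stages))
    cat("  skipped:", paste(x$manifest$skipped_stages, collapse = ", "), "\n")
  invisible(x)
}

#' Batch-process multiple sessions into a cohort table
#'
#' Runs [run_pipeline()] on each session; failures are caught, logged
#' and excluded from the summary footer.
#'
#' @param sessions list of sessions (as accepted by [run_pipeline()]).
#' @param config shared [pipeline_config()].
#' @param geometry array geometry.
#' @param ids optional session labels.
#' @return an object of class `cohort_result`: `table` (one SNR row per
#'   successful session), `summary` (per-column mean +- SD via
#'   [summarize_cohort()]), `failures` (list of error messages), and
#'   `n_failed`.
#' @export
batch_run <- function(sessions, config = pipeline_config(),
                      geometry = default_geometry(), ids = NULL) {
  if (!length(sessions)) stopf("parameter error: empty session list")
  ids <- ids %||% sprintf("S%02d", seq_along(sessions))
  rows <- list(); failures <- list()
  for (k in seq_along(sessions)) {
    res <- tryCatch(run_pipeline(sessions[[k]], config, geometry),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[ids[k]]] <- conditionMessage(res)
    } else {
      rows[[ids[k]]] <- data.frame(session = ids[k],
                                   filters_db = res$snr[["filters"]],
                                   anc_db = res$snr[["anc"]],
                                   ssp_db = res$snr[["ssp"]],
                                   ecg_db = res$snr[["ecg"]])
    }
    rm(res); gc(FALSE)
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  summ <- NULL
  if (!is.null(tab) && nrow(tab) >= 2) {
    summ <- lapply(tab[, -1, drop = FALSE], function(col)
      if (all(is.finite(col))) summarize_cohort(col) else NULL)
  }
  structure(list(table = tab, summary = summ, failures = failures,
                 n_failed = length(failures)),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d sessions (%d failed)\n",
              if (is.null(x$table)) 0L else nrow(x$table), x$n_failed))
  if (!is.null(x$table)) print(x$table, row.names = FALSE)
  if (!is.null(x$summary))
    for (nm in names(x$summary))
      if (!is.null(x$summary[[nm]]))
        cat(sprintf("  %s: %s dB\n", nm, x$summary[[nm]]$label))
  invisible(x)
}
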