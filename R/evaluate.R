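# Robustness evaluation against synthetic ground truth: per-run error
# reports and the SNR sweep harness.

#' Score a pipeline run against synthetic ground truth
#'
#' Matches each ground-truth S2 response on the evaluated (circular
#' mapping) catheter to the pipeline detection of the same beat and
#' channel. Errors (LAT in ms, via absolute activation-sample difference;
#' amplitude in mV) are computed on matched pairs only; truth events
#' without a detection count as missed. The stimulating channel is always
#' excluded. Channels listed in `exclude` (e.g. the heavily
#' stimulus-overlapped channel used to probe the pipeline's limits) are
#' excluded from the error statistics, with their non-detections reported
#' separately.
#'
#' @param detections detection table from [runPipeline()].
#' @param truth `SyntheticProtocol$truth` ground-truth table.
#' @param exclude channel indices excluded from the error statistics.
#' @param catheter catheter label whose channels are evaluated.
#' @param snr_db annotation carried into the report.
#' @param fs sampling rate (Hz).
#' @return an `ErrorReport` list: counts, per-signal errors, their
#'   median/Q1/Q3, missed counts and fraction.
#' @export
scoreRun <- function(detections, truth, exclude = integer(0),
                     catheter = "PV", snr_db = NA_real_, fs = 1000) {
  tt <- truth[!is.na(truth$label) & truth$label == "S2" &
              truth$capture %in% TRUE & truth$catheter %in% catheter, ,
              drop = FALSE]
  stim_ch_missing <- setdiff(unique(tt$channel),
                             unique(detections$channel))
  eval_t <- tt[!(tt$channel %in% c(exclude, stim_ch_missing)), ,
               drop = FALSE]
  excl_t <- tt[tt$channel %in% exclude, , drop = FALSE]
  match_one <- function(row) {
    d <- detections[detections$channel == row$channel &
                    detections$label == "S2" &
                    detections$train == row$train, , drop = FALSE]
    if (nrow(d) == 0L || !isTRUE(d$detected[1])) return(c(NA_real_, NA_real_))
    c(.smp2ms(d$t_act[1] - row$t_act, fs), d$amplitude[1] - row$amplitude)
  }
  errs <- t(vapply(seq_len(nrow(eval_t)),
                   function(i) match_one(eval_t[i, ]), numeric(2)))
  lat_err <- errs[, 1]; amp_err <- errs[, 2]
  matched <- !is.na(lat_err)
  rel_amp <- amp_err[matched] / eval_t$amplitude[matched]
  excl_missed <- if (nrow(excl_t)) {
    sum(vapply(seq_len(nrow(excl_t)),
               function(i) is.na(match_one(excl_t[i, ])[1]), logical(1)))
  } else 0L
  q <- function(v) if (length(v)) quantile(v, c(.25, .5, .75), names = FALSE)
                   else rep(NA_real_, 3)
  structure(list(
    snr_db = snr_db,
    n_evaluable = nrow(eval_t),
    n_matched = sum(matched),
    missed = sum(!matched),
    missed_fraction = if (nrow(eval_t)) sum(!matched) / nrow(eval_t) else NA,
    lat_error_ms = lat_err[matched],
    amp_error_mv = amp_err[matched],
    rel_amp_error = rel_amp,
    lat_q = q(lat_err[matched]),
    abs_lat_q = q(abs(lat_err[matched])),
    amp_q = q(amp_err[matched]),
    abs_amp_q = q(abs(amp_err[matched])),
    excluded_channels = exclude,
    excluded_missed = excl_missed),
    class = "ErrorReport")
}

#' @export
print.ErrorReport <- function(x, ...) {
  cat(sprintf(paste0("ErrorReport (SNR %s dB): %d/%d matched, %d missed",
                     " (%.1f%%)\n"),
              format(x$snr_db), x$n_matched, x$n_evaluable, x$missed,
              100 * x$missed_fraction))
  cat(sprintf("  |LAT| error ms  Q1/med/Q3: %.3f / %.3f / %.3f\n",
              x$abs_lat_q[1], x$abs_lat_q[2], x$abs_lat_q[3]))
  cat(sprintf("  |amp| error mV  Q1/med/Q3: %.4f / %.4f / %.4f\n",
              x$abs_amp_q[1], x$abs_amp_q[2], x$abs_amp_q[3]))
  if (length(x$excluded_channels))
    cat("  excluded channel(s):",
        paste(x$excluded_channels, collapse = ", "), "with",
        x$excluded_missed, "non-detections\n")
  invisible(x)
}

#' Channels whose ground-truth overlap with the stimulation exceeds a bound
#'
#' @param truth ground-truth table.
#' @param threshold overlap fraction bound.
#' @return channel indices.
#' @export
overlapChannels <- function(truth, threshold = 0.5) {
  ov <- stats::aggregate(overlap ~ channel,
                         data = truth[!is.na(truth$overlap), ], FUN = max)
  ov$channel[ov$overlap > threshold]
}

#' SNR sweep: robustness study over noise levels
#'
#' For every SNR x seed combination, simulates the default (or given)
#' protocol, adds spectrum noise scaled to the target SNR plus baseline
#' wander, runs the full pipeline, and scores it against the ground truth.
#' Individual run failures are recorded and the sweep continues.
#'
#' @param snr_grid_db SNR levels in dB.
#' @param seeds integer seeds; each defines one noise realization.
#' @param spec,layout,waveforms,model generator settings.
#' @param noise_spec a [noiseSpec()].
#' @param exclude_overlap exclude channels whose true overlap with the
#'   stimulus exceeds 50% from the error statistics.
#' @param fs sampling rate (Hz).
#' @param wander add baseline wander.
#' @return list: `reports` (per run), `summary` (tidy data frame with one
#'   row per run).
#' @export
snrSweep <- function(snr_grid_db = c(40, 30, 20, 10, 0),
                     seeds = 1:3, spec = protocolSpec(),
                     layout = catheterLayout(), waveforms = waveformSpec(),
                     model = restitutionModel(), noise_spec = noiseSpec(),
                     exclude_overlap = TRUE, fs = 1000, wander = TRUE) {
  .stop_if_not(length(snr_grid_db) > 0, "empty SNR grid")
  sim0 <- buildProtocol(spec, layout, waveforms, model, fs)
  excl <- if (exclude_overlap) overlapChannels(sim0$truth) else integer(0)
  reports <- list(); rows <- list()
  for (snr in snr_grid_db) for (sd_i in seeds) {
    tag <- sprintf("snr%g_seed%d", snr, sd_i)
    res <- try({
      sim <- addProtocolNoise(sim0, snr, noise_spec, seed = sd_i,
                              wander = wander)
      run <- runPipeline(sim$recording)
      scoreRun(run$detections, sim$truth, exclude = excl, snr_db = snr)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      rows[[tag]] <- data.frame(snr_db = snr, seed = sd_i, failed = TRUE,
                                n_evaluable = NA, missed = NA,
                                median_abs_lat_ms = NA,
                                median_abs_amp_mv = NA)
      reports[[tag]] <- attr(res, "condition")$message
    } else {
      reports[[tag]] <- res
      rows[[tag]] <- data.frame(snr_db = snr, seed = sd_i, failed = FALSE,
                                n_evaluable = res$n_evaluable,
                                missed = res$missed,
                                median_abs_lat_ms = res$abs_lat_q[2],
                                median_abs_amp_mv = res$abs_amp_q[2])
    }
  }
  list(reports = reports, summary = do.call(rbind, rows))
}
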