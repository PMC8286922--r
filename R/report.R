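#' Raster plot with firing-rate overlay
#'
#' Scatter of (spike time, neuron index) for one population of one run,
#' with the (optionally multi-run averaged) firing-rate curve overlaid
#' in green, mirroring the standard raster-plus-rate panel.
#'
#' @param record A `spike_record` (the raster shows this single run).
#' @param population Population name.
#' @param rate Optional `firing_rate_series` to overlay (e.g. a 20-run
#'   average); defaults to this run's own 50 ms rate.
#' @param window Time interval; defaults to the record window.
#' @return Invisibly, the rate series drawn.
#' @export
plot_raster <- function(record, population, rate = NULL, window = NULL) {
  if (is.null(window)) window <- record$record_window
  ev <- record$events
  ev <- ev[ev$population == population & ev$time_ms >= window[1] &
             ev$time_ms < window[2], ]
  if (is.null(rate)) rate <- firing_rate(record, population,
                                         window = window)
  graphics::plot(ev$time_ms, ev$neuron, pch = ".", cex = 1.5,
                 xlab = "time (ms)", ylab = "neuron",
                 main = population, xlim = window,
                 ylim = c(0, record$sizes[[population]]))
  if (max(rate$rate_hz) > 0) {
    sc <- record$sizes[[population]] / max(rate$rate_hz)
    graphics::lines(rate$time_ms, rate$rate_hz * sc, col = "darkgreen",
                    lwd = 2)
    graphics::axis(4, at = pretty(rate$rate_hz) * sc,
                   labels = pretty(rate$rate_hz))
  }
  invisible(rate)
}

#' Spectrogram and power-histogram panel
#'
#' @param summary A [spectral_summary()].
#' @param max_freq_hz Upper frequency shown.
#' @export
plot_spectral <- function(summary, max_freq_hz = 60) {
  keep <- summary$frequencies <= max_freq_hz
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::image(summary$segment_times_ms,
                  summary$frequencies[keep],
                  summary$spectrogram[, keep, drop = FALSE],
                  xlab = "time (ms)", ylab = "frequency (Hz)",
                  main = paste(summary$population, "spectrogram"))
  graphics::barplot(summary$power_histogram[keep][-1],
                    names.arg = round(summary$frequencies[keep][-1], 1),
                    xlab = "frequency (Hz)", ylab = "power",
                    main = "power histogram")
}

#' Render a report for a batch of scenario runs
#'
#' One raster-with-rate figure per population (raster from the first
#' repetition, rate curve averaged across repetitions), one spectrogram
#' plus power-histogram figure per population (from the averaged rate),
#' and a summary table of dominant frequency, band, mean rate and
#' synchrony index. Missing/failed repetitions are listed in the
#' manifest warnings and the partial report is still produced.
#'
#' @param records List of `spike_record`s (failed reps may be error
#'   conditions).
#' @param out_dir Output directory (created if needed).
#' @param manifest Optional [run_manifest()] echoed alongside.
#' @return data.frame summary table (also written as TSV), invisibly.
#' @export
render_report <- function(records, out_dir, manifest = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- vapply(records, inherits, logical(1), what = "spike_record")
  if (!any(ok)) stop("no successful repetitions to report")
  if (any(!ok))
    message(sum(!ok), " repetition(s) missing; partial report produced")
  recs <- records[ok]
  first <- recs[[1]]
  rows <- list()
  for (p in names(first$sizes)) {
    avg50 <- average_rates(lapply(recs, firing_rate, population = p))
    avg2 <- average_rates(lapply(recs, firing_rate, population = p,
                                 window_ms = 2, stride_ms = 2))
    ss <- spectral_summary(avg2)
    grDevices::png(file.path(out_dir, paste0("raster_", p, ".png")),
                   width = 900, height = 500)
    plot_raster(first, p, rate = avg50)
    grDevices::dev.off()
    grDevices::png(file.path(out_dir, paste0("spectrum_", p, ".png")),
                   width = 900, height = 450)
    plot_spectral(ss)
    grDevices::dev.off()
    sy <- synchrony_index(first, p)
    rows[[p]] <- data.frame(population = p,
                            mean_rate_hz = mean(avg50$rate_hz),
                            dominant_freq_hz = ss$dominant_frequency,
                            band = ss$band %||% NA_character_,
                            synchrony = as.numeric(sy))
  }
  tab <- do.call(rbind, rows)
  write.table(tab, file.path(out_dir, "summary.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (!is.null(manifest))
    yaml::write_yaml(list(seeds = manifest$seeds,
                          version = manifest$version,
                          started = manifest$started),
                     file.path(out_dir, "manifest.yaml"))
  invisible(tab)
}
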