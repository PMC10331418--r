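# Plain-text import/export of the package's containers.

#' Waveform CSV I/O
#'
#' Waveforms are written as two-column CSV (`time_s`, `amplitude`); the
#' sampling rate is recovered from the time column on reading.
#'
#' @param w a [waveform()].
#' @param path file path.
#' @return `read_waveform()` returns a [waveform()]; the writers return
#'   their input invisibly.
#' @export
write_waveform <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  write.csv(data.frame(time_s = wf_time(w), amplitude = w$samples),
            path, row.names = FALSE)
  invisible(w)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("time_s", "amplitude") %in% names(d)), nrow(d) >= 2)
  waveform(d$amplitude, rate = 1 / mean(diff(d$time_s)))
}

#' EOD template CSV I/O
#'
#' Templates are written as CSV with columns `k`, `amplitude`, `phase`.
#'
#' @param template an [eod_template()].
#' @param path file path.
#' @return `read_eod_template()` returns an [eod_template()].
#' @export
write_eod_template <- function(template, path) {
  stopifnot(inherits(template, "eod_template"))
  write.csv(as.data.frame(template), path, row.names = FALSE)
  invisible(template)
}

#' @rdname write_eod_template
#' @export
read_eod_template <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("k", "amplitude", "phase") %in% names(d)))
  d <- d[order(d$k), ]
  eod_template(d$amplitude, d$phase)
}

#' Spike-train text I/O
#'
#' Spike trains are written as one spike time (seconds) per line, with the
#' trial duration on a `# duration:` header line.
#'
#' @param st a [spike_train()].
#' @param path file path.
#' @return `read_spike_train()` returns a [spike_train()].
#' @export
write_spike_train <- function(st, path) {
  stopifnot(inherits(st, "spike_train"))
  writeLines(c(sprintf("# duration: %.17g", st$duration),
               sprintf("%.17g", st$times)), path)
  invisible(st)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(path) {
  lines <- readLines(path)
  dur <- as.numeric(sub("^# duration:\\s*", "", lines[1]))
  body <- lines[-1]
  spike_train(as.numeric(body[nzchar(body)]), dur)
}

#' Tuning-curve CSV I/O
#'
#' Columns `fstim_hz`, `fstim_rel`, `fresp_hz`, `aresp_hz`, `fexp_hz`; the
#' carrier frequency is recovered from `fstim_hz / fstim_rel`.
#'
#' @param tc a [tuning_curve()].
#' @param path file path.
#' @return `read_tuning_curve()` returns a [tuning_curve()].
#' @export
write_tuning_curve <- function(tc, path) {
  stopifnot(inherits(tc, "tuning_curve"))
  write.csv(as.data.frame(tc), path, row.names = FALSE)
  invisible(tc)
}

#' @rdname write_tuning_curve
#' @export
read_tuning_curve <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("fstim_hz", "fstim_rel", "fresp_hz", "aresp_hz") %in% names(d)))
  tuning_curve(d$fstim_hz, d$fresp_hz, d$aresp_hz,
               f_eod = d$fstim_hz[1] / d$fstim_rel[1])
}

#' Peak-prediction CSV export
#'
#' Columns `frequency_hz`, `amplitude_rel`, `order`.
#'
#' @param peaks a `"peak_prediction"` from [predict_peaks()].
#' @param path file path.
#' @return The input, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_prediction"))
  write.csv(data.frame(frequency_hz = peaks$freq, amplitude_rel = peaks$amp_rel,
                       order = peaks$order), path, row.names = FALSE)
  invisible(peaks)
}

#' Power-spectrum CSV export
#'
#' Columns `freq_hz`, `density`.
#'
#' @param ps a `"power_spectrum"`.
#' @param path file path.
#' @return The input, invisibly.
#' @export
write_power_spectrum <- function(ps, path) {
  stopifnot(inherits(ps, "power_spectrum"))
  write.csv(data.frame(freq_hz = ps$freq, density = ps$power),
            path, row.names = FALSE)
  invisible(ps)
}

#' Frequency-trace CSV export
#'
#' Columns `time_s`, `f_eod_hz`.
#'
#' @param trace a [frequency_trace()].
#' @param path file path.
#' @return The input, invisibly.
#' @export
write_frequency_trace <- function(trace, path) {
  stopifnot(inherits(trace, "frequency_trace"))
  write.csv(data.frame(time_s = trace$time, f_eod_hz = trace$freq),
            path, row.names = FALSE)
  invisible(trace)
}
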