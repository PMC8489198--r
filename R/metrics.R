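# Post-processing: spike detection, oscillation metrics, release accounting,
# and tabular writers.

#' Detect spikes as upward threshold crossings
#'
#' A spike is an upward crossing of `threshold` separated from the previous
#' spike by at least `refractory` ms. Spike times are linearly interpolated at
#' the crossing; amplitudes are the local maxima following each crossing.
#'
#' @param time time grid (ms), strictly increasing.
#' @param v membrane-potential trace (mV), same length.
#' @param threshold crossing threshold (mV).
#' @param refractory minimum inter-spike separation (ms).
#' @return A `spike_train` list: `times`, `count`, `mean_isi`, `mean_amplitude`.
#' @export
#' @examples
#' t <- seq(0, 100, by = 0.1)
#' detect_spikes(t, 30 * sin(2 * pi * t / 20) - 10)$count
detect_spikes <- function(time, v, threshold = 0, refractory = 2) {
  stopifnot(length(time) == length(v), !is.unsorted(time, strictly = TRUE))
  n <- length(v)
  if (n < 2) {
    return(structure(list(times = numeric(0), count = 0L, mean_isi = NA_real_,
                          mean_amplitude = NA_real_), class = "spike_train"))
  }
  up <- which(v[-n] < threshold & v[-1] >= threshold)
  times <- numeric(0); amps <- numeric(0)
  last <- -Inf
  for (i in up) {
    frac <- (threshold - v[i]) / (v[i + 1] - v[i])
    tc <- time[i] + frac * (time[i + 1] - time[i])
    if (tc - last >= refractory) {
      times <- c(times, tc)
      last <- tc
      # peak within the refractory window after the crossing
      jmax <- min(n, i + max(1L, which.max(time[i:n] >= tc + refractory)))
      amps <- c(amps, max(v[i:jmax]))
    }
  }
  structure(list(times = times, count = length(times),
                 mean_isi = if (length(times) > 1) mean(diff(times)) else NA_real_,
                 mean_amplitude = if (length(amps)) mean(amps) else NA_real_),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes", x$count))
  if (x$count > 1) cat(sprintf(", mean ISI %.3g ms", x$mean_isi))
  cat("\n")
  invisible(x)
}

#' Cumulative per-pathway release over a window
#'
#' Trapezoidal integrals of each release-rate trace (`R_CL`, `R_Cm`, `R_CN`)
#' over `[window[1], window[2]]`, plus each pathway's fraction of the total.
#' Released-exosome "concentration" is operationalized as the time integral of
#' the dimensionless release rate (rate x ms); the fractions are unit-free.
#'
#' @param result a `sim_result` carrying release traces.
#' @param window numeric `c(from, to)` in ms; defaults to the full run.
#' @return A `release_breakdown` list: `cumulative` (named), `fractions`
#'   (named, summing to 1 when the total is positive), `window`.
#' @export
release_breakdown <- function(result, window = NULL) {
  stopifnot(inherits(result, "sim_result"))
  if (is.null(result$release)) {
    stop("variant '", result$variant, "' carries no release traces")
  }
  tt <- result$time
  if (is.null(window)) window <- range(tt)
  if (window[1] < min(tt) - 1e-9 || window[2] > max(tt) + 1e-9 ||
      window[2] <= window[1]) {
    stop("window outside the simulated range")
  }
  keep <- tt >= window[1] & tt <= window[2]
  t2 <- tt[keep]
  cum <- vapply(c("R_CL", "R_Cm", "R_CN"),
                function(k) .trapz(t2, result$release[keep, k]), 0)
  total <- sum(cum)
  frac <- if (total > 0) cum / total else setNames(rep(NA_real_, 3), names(cum))
  structure(list(cumulative = cum, fractions = frac, total = total,
                 window = window), class = "release_breakdown")
}

#' @export
print.release_breakdown <- function(x, ...) {
  cat(sprintf("<release_breakdown> window [%.6g, %.6g] ms, total %.4g (rate x ms)\n",
              x$window[1], x$window[2], x$total))
  print(round(rbind(cumulative = x$cumulative, fraction = x$fractions), 4))
  invisible(x)
}

#' Oscillation metrics of a slow concentration trace
#'
#' Characterizes a (possibly oscillatory) trace by peak counting: peaks are
#' local maxima exceeding a prominence threshold (10% of the trace range).
#' Frequency is `(n_peaks - 1) / (time of last - first peak)` in Hz (time in
#' ms); amplitude is mean peak minus mean trough; baseline is the trough mean.
#' Non-oscillatory traces (< 2 peaks, or range below `eps`) report zero
#' amplitude/frequency and the trace mean as baseline, with
#' `oscillatory = FALSE`.
#'
#' @param time time grid (ms).
#' @param x trace (e.g. cytosolic Ca2+, uM).
#' @param window optional `c(from, to)` ms restriction.
#' @param eps absolute range below which the trace counts as constant.
#' @return List: `amplitude`, `frequency_hz`, `baseline`, `n_peaks`,
#'   `oscillatory`.
#' @export
oscillation_metrics <- function(time, x, window = NULL, eps = 1e-6) {
  stopifnot(length(time) == length(x))
  if (!is.null(window)) {
    keep <- time >= window[1] & time <= window[2]
    time <- time[keep]; x <- x[keep]
  }
  flat <- list(amplitude = 0, frequency_hz = 0, baseline = mean(x),
               n_peaks = 0L, oscillatory = FALSE)
  if (length(x) < 3 || diff(range(x)) < eps) return(flat)
  rng <- diff(range(x))
  thr <- min(x) + 0.1 * rng
  # local maxima above the prominence floor, separated by a dip below the
  # midline to suppress ripple
  mid <- min(x) + 0.5 * rng
  peaks <- integer(0); troughs <- numeric(0)
  armed <- TRUE; cur_min <- x[1]
  for (i in 2:(length(x) - 1)) {
    if (x[i] < mid) { cur_min <- min(cur_min, x[i]) }
    if (armed && x[i] >= x[i - 1] && x[i] > x[i + 1] && x[i] > mid) {
      peaks <- c(peaks, i); troughs <- c(troughs, cur_min)
      armed <- FALSE
    }
    if (!armed && x[i] < mid) { armed <- TRUE; cur_min <- x[i] }
  }
  if (length(peaks) < 2) return(flat)
  pk <- x[peaks]
  tr <- if (length(troughs) > 1) troughs[-1] else troughs # dips between peaks
  freq <- 1000 * (length(peaks) - 1) / (time[peaks[length(peaks)]] - time[peaks[1]])
  list(amplitude = mean(pk) - mean(tr), frequency_hz = freq,
       baseline = mean(tr), n_peaks = length(peaks), oscillatory = TRUE)
}

#' Write a simulation result to disk
#'
#' CSV (RFC-4180, '.' decimal, mandatory header) with columns `t_ms`, then one
#' column per state variable (the membrane potential as `v_m_mV`), then the
#' release-rate columns where present; a JSON sidecar `<path>.meta.json`
#' carries the run metadata and assumption log. `format = "json"` writes a
#' single JSON document with traces and metadata. [read_result()] round-trips
#' the traces exactly.
#'
#' @param result a `sim_result`.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, format = c("csv", "json")) {
  stopifnot(inherits(result, "sim_result"))
  format <- match.arg(format)
  st <- result$states
  cn <- colnames(st)
  cn[cn == "v_m"] <- "v_m_mV"
  df <- data.frame(t_ms = result$time, st, check.names = FALSE)
  names(df) <- c("t_ms", cn)
  if (!is.null(result$release)) {
    df <- cbind(df, as.data.frame(result$release))
  }
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(result$metadata, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    jsonlite::write_json(list(traces = df, metadata = result$metadata),
                         path, dataframe = "columns", digits = NA,
                         auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

#' Read back a written simulation result
#' @param path file written by [write_result()].
#' @param format `"csv"` or `"json"`.
#' @return List with `traces` (data.frame) and `metadata` (list; for CSV, read
#'   from the sidecar if present).
#' @export
read_result <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    traces <- utils::read.csv(path, check.names = FALSE)
    meta_path <- paste0(path, ".meta.json")
    metadata <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
    list(traces = traces, metadata = metadata)
  } else {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    list(traces = as.data.frame(x$traces), metadata = x$metadata)
  }
}
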