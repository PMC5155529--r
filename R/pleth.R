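#' Pressure trace from a head-out pneumotachograph
#'
#' Container for the raw flow signal (mV) recorded at the mask, with optional
#' condition epochs and a movement-artifact mask. The raw trace is never
#' filtered or smoothed by this package; the only processing applied to it is
#' integration into a volume waveform (see [integrate_flow()]).
#'
#' @param samples numeric vector of flow samples in mV.
#' @param sampling_rate_hz sampling rate in Hz (> 0).
#' @param epochs `data.frame` with columns `label`, `start_s`, `end_s`;
#'   labels must come from `acclimation`, `room_air`, `hypoxia`,
#'   `hypercapnia`, `recovery`. Intervals are half-open `[start, end)`,
#'   non-overlapping and ordered.
#' @param artifact_mask `data.frame` with columns `start_s`, `end_s` and
#'   optionally `label`, marking movement artifacts to exclude.
#' @param temperature_c optional chamber-temperature channel, same length as
#'   `samples`.
#' @return An object of class `pressure_trace`.
#' @export
pressure_trace <- function(samples, sampling_rate_hz, epochs = NULL,
                           artifact_mask = NULL, temperature_c = NULL) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop_input("`samples` must be a non-empty numeric vector")
  check_scalar_num(sampling_rate_hz, "sampling_rate_hz", 0, strict_lower = TRUE)
  dur <- length(samples) / sampling_rate_hz
  epochs <- check_epochs(epochs, dur)
  artifact_mask <- check_intervals(artifact_mask, dur, "artifact_mask")
  if (!is.null(temperature_c) && length(temperature_c) != length(samples))
    stop_input("`temperature_c` must match `samples` in length")
  structure(list(samples = as.numeric(samples),
                 sampling_rate_hz = sampling_rate_hz,
                 epochs = epochs, artifact_mask = artifact_mask,
                 temperature_c = temperature_c),
            class = "pressure_trace")
}

epoch_labels <- c("acclimation", "room_air", "hypoxia", "hypercapnia",
                  "recovery")

check_epochs <- function(epochs, duration_s) {
  if (is.null(epochs)) return(NULL)
  epochs <- as.data.frame(epochs)
  need <- c("label", "start_s", "end_s")
  if (!all(need %in% names(epochs)))
    stop_input("epochs need columns %s", paste(need, collapse = ", "))
  bad <- setdiff(epochs$label, epoch_labels)
  if (length(bad))
    stop_input("unknown epoch label(s): %s", paste(bad, collapse = ", "))
  check_intervals(epochs[c("start_s", "end_s", "label")], duration_s, "epochs")
  if (nrow(epochs) > 1L) {
    o <- order(epochs$start_s)
    if (any(epochs$end_s[o][-nrow(epochs)] > epochs$start_s[o][-1L] + 1e-9))
      stop_input("epochs must be non-overlapping")
    epochs <- epochs[o, , drop = FALSE]
  }
  rownames(epochs) <- NULL
  epochs
}

check_intervals <- function(x, duration_s, what) {
  if (is.null(x) || NROW(x) == 0L) return(x)
  x <- as.data.frame(x)
  if (!all(c("start_s", "end_s") %in% names(x)))
    stop_input("%s needs columns start_s, end_s", what)
  if (any(!is.finite(x$start_s)) || any(!is.finite(x$end_s)) ||
      any(x$start_s >= x$end_s))
    stop_input("%s intervals must have start_s < end_s", what)
  if (any(x$start_s < -1e-9) || any(x$end_s > duration_s + 1e-9))
    stop_input("%s intervals must lie within [0, %g]", what, duration_s)
  x
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("<pressure_trace> %d samples @ %g Hz (%.1f s)\n",
              length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz))
  if (!is.null(x$epochs))
    cat("  epochs:", paste(x$epochs$label, collapse = ", "), "\n")
  if (NROW(x$artifact_mask))
    cat("  artifact intervals:", nrow(x$artifact_mask), "\n")
  invisible(x)
}

trace_duration <- function(trace) length(trace$samples) / trace$sampling_rate_hz

#' Integrate a flow trace into a relative volume waveform
#'
#' Cumulative trapezoidal integration of the pneumotachograph flow channel.
#' The raw pressure trace is left untouched; optional drift correction is
#' applied to the integrated waveform only, so that breath peak heights are
#' measured against a stable baseline.
#'
#' @param trace a [pressure_trace()].
#' @param drift_correction `"rolling_quantile"` (default; subtract a
#'   baseline tracked as the running 10th percentile of the volume
#'   waveform, robust to the breath duty cycle), `"rolling_median"`
#'   (subtract a running median; biased when pulses occupy more than half
#'   the window), `"linear"` (subtract the least-squares line), or
#'   `"none"`.
#' @param window_s baseline-estimation window in seconds.
#' @return An object of class `volume_waveform`: fields `samples` (mV·s),
#'   `sampling_rate_hz`, `drift_corrected`.
#' @export
integrate_flow <- function(trace,
                           drift_correction = c("rolling_quantile",
                                                "rolling_median", "linear",
                                                "none"),
                           window_s = 2) {
  if (!inherits(trace, "pressure_trace"))
    stop_input("`trace` must be a pressure_trace")
  drift_correction <- match.arg(drift_correction)
  x <- trace$samples
  n <- length(x)
  if (n < 2L) stop_input("trace too short to integrate")
  dt <- 1 / trace$sampling_rate_hz
  v <- c(0, cumsum((x[-1L] + x[-n]) / 2) * dt)
  if (drift_correction == "rolling_quantile") {
    # blockwise low quantile + running min across one window, interpolated:
    # tracks the inter-breath baseline regardless of pulse duty cycle
    block <- max(1L, as.integer(round(window_s * trace$sampling_rate_hz / 8)))
    grp <- (seq_len(n) - 1L) %/% block
    q10 <- vapply(split(v, grp), quantile, numeric(1), probs = 0.10,
                  names = FALSE)
    nb <- length(q10)
    if (nb >= 3L) {
      run <- vapply(seq_len(nb), function(i)
        min(q10[max(1L, i - 4L):min(nb, i + 4L)]), numeric(1))
    } else run <- q10
    centers <- (tapply(seq_len(n), grp, mean) - 1) / trace$sampling_rate_hz
    base <- stats::approx(as.numeric(centers),
                          run, xout = (seq_len(n) - 1) /
                            trace$sampling_rate_hz, rule = 2)$y
    v <- v - base
  } else if (drift_correction == "rolling_median") {
    k <- floor(window_s * trace$sampling_rate_hz / 2) * 2 + 1
    k <- max(3L, min(as.integer(k), if (n %% 2L) n else n - 1L))
    # reflect the waveform at both ends so edge medians see a full window
    h <- (k - 1L) %/% 2L
    vp <- c(v[(h + 1L):2L], v, v[(n - 1L):(n - h)])
    base <- runmed(vp, k, endrule = "median")[(h + 1L):(h + n)]
    v <- v - base
  } else if (drift_correction == "linear") {
    t <- seq_len(n)
    fit <- stats::lm.fit(cbind(1, t), v)
    v <- fit$residuals
  }
  structure(list(samples = as.numeric(v),
                 sampling_rate_hz = trace$sampling_rate_hz,
                 drift_corrected = drift_correction),
            class = "volume_waveform")
}

#' Calibrate volume-waveform peak height against known-volume injections
#'
#' A calibration recording consists of repeated fixed-volume injections
#' (default 20 ul at 3 Hz) into the sealed, empty facemask. The trace is
#' integrated, injection pulses are detected as breaths, and the factor is
#' the injection volume divided by the mean pulse peak height.
#'
#' @param cal_trace a [pressure_trace()] of the calibration recording.
#' @param injection_volume_ul injected volume per pulse in microliters.
#' @param min_pulses minimum number of detectable pulses (default 3).
#' @return Object of class `calibration_factor` with fields `ul_per_mv`,
#'   `n_injections`, `injection_volume_ul`.
#' @export
calibrate <- function(cal_trace, injection_volume_ul = 20, min_pulses = 3L) {
  check_scalar_num(injection_volume_ul, "injection_volume_ul", 0,
                   strict_lower = TRUE)
  # calibration recordings are short and pulse-dominated; a linear detrend
  # of the integrated waveform is the stable choice there
  vol <- integrate_flow(cal_trace, "linear")
  pulses <- segment_breaths(vol)
  if (nrow(pulses$breaths) < min_pulses)
    stop_input("calibration error: only %d pulse(s) detected (need >= %d)",
               nrow(pulses$breaths), min_pulses)
  f <- injection_volume_ul / mean(pulses$breaths$amplitude_mv)
  structure(list(ul_per_mv = f, n_injections = nrow(pulses$breaths),
                 injection_volume_ul = injection_volume_ul),
            class = "calibration_factor")
}

#' @export
print.calibration_factor <- function(x, ...) {
  cat(sprintf("<calibration_factor> %.4g ul/mV from %d x %g ul injections\n",
              x$ul_per_mv, x$n_injections, x$injection_volume_ul))
  invisible(x)
}

#' Segment a volume waveform into breaths
#'
#' Hysteresis peak detection against a running amplitude scale: a breath is
#' opened when the waveform rises above `hi_frac` of the local amplitude
#' scale after having been below `lo_frac`, its peak is the maximum of the
#' excursion (earliest sample on ties), its amplitude is peak minus the
#' preceding trough, and its onset is the start of the upstroke (the last
#' sample near the preceding trough). Onsets closer than `refractory_s` to
#' the previous accepted onset are discarded. The amplitude scale and
#' baseline are robust quantiles computed over `scale_window_s` blocks.
#'
#' @param volume a `volume_waveform` from [integrate_flow()].
#' @param hi_frac,lo_frac hysteresis thresholds as fractions of the local
#'   amplitude scale.
#' @param refractory_s minimum onset-to-onset separation in seconds.
#' @param scale_window_s window for the running amplitude scale, seconds.
#' @return Object of class `breath_series`: `breaths` data.frame
#'   (`onset_s`, `peak_s`, `amplitude_mv`, `volume_ul` = NA until
#'   calibrated) and `ibis_s`, the onset-to-onset interbreath intervals.
#' @export
segment_breaths <- function(volume, hi_frac = 0.5, lo_frac = 0.25,
                            refractory_s = 0.1, scale_window_s = 10) {
  if (!inherits(volume, "volume_waveform"))
    stop_input("`volume` must be a volume_waveform")
  if (hi_frac <= lo_frac || lo_frac <= 0 || hi_frac >= 1)
    stop_input("need 0 < lo_frac < hi_frac < 1")
  v <- volume$samples
  fs <- volume$sampling_rate_hz
  n <- length(v)
  if (n < refractory_s * fs) stop_input("waveform shorter than refractory_s")

  # piecewise-constant baseline/scale per scale_window_s block
  block <- pmax(1L, as.integer(round(scale_window_s * fs)))
  grp <- (seq_len(n) - 1L) %/% block
  qs <- vapply(split(v, grp), quantile, numeric(2),
               probs = c(0.10, 0.99), names = FALSE)
  base <- qs[1L, grp + 1L]
  scale <- qs[2L, grp + 1L] - base
  flat <- scale <= max(1e-12, 1e-6 * max(abs(v)))

  hi <- base + hi_frac * scale
  lo <- base + lo_frac * scale
  state <- integer(n)
  state[v > hi & !flat] <- 1L
  state[v < lo | flat] <- -1L

  nz <- which(state != 0L)
  if (!length(nz)) return(empty_breath_series(fs))
  ss <- state[nz]
  prev <- c(-1L, ss[-length(ss)])
  cross <- nz[ss == 1L & prev == -1L]
  if (!length(cross)) return(empty_breath_series(fs))
  below <- nz[ss == -1L]

  onset_i <- peak_i <- integer(length(cross))
  amp <- numeric(length(cross))
  prev_end <- 1L
  keep <- logical(length(cross))
  last_onset <- -Inf
  for (k in seq_along(cross)) {
    ck <- cross[k]
    # end of excursion: first sample below lo after the crossing
    j <- below[below > ck]
    ek <- if (length(j)) j[1L] else n
    pk <- (ck:ek)[which.max(v[ck:ek])]          # earliest max on ties
    tr_rng <- prev_end:ck
    ti <- tr_rng[which.min(v[tr_rng])]
    trough <- v[ti]
    a <- v[pk] - trough
    # onset: extrapolate the upstroke back to the baseline. A breath pulse
    # starts quadratically, so crossing times of level c scale as sqrt(c);
    # from the last samples below 5% and 25% of the amplitude the zero
    # crossing is t1 - (t2 - t1) * sqrt(.05) / (sqrt(.25) - sqrt(.05)).
    rng <- ti:pk
    below1 <- rng[v[rng] <= trough + 0.05 * a]
    below2 <- rng[v[rng] <= trough + 0.25 * a]
    i1 <- if (length(below1)) below1[length(below1)] else ti
    i2 <- if (length(below2)) below2[length(below2)] else i1
    oi <- if (i2 > i1)
      max(ti, as.integer(round(i1 - 0.8090 * (i2 - i1)))) else i1
    if ((oi - 1L) / fs - last_onset >= refractory_s) {
      keep[k] <- TRUE
      onset_i[k] <- oi; peak_i[k] <- pk; amp[k] <- a
      last_onset <- (oi - 1L) / fs
    }
    prev_end <- ek
  }
  b <- data.frame(onset_s = (onset_i[keep] - 1L) / fs,
                  peak_s = (peak_i[keep] - 1L) / fs,
                  amplitude_mv = amp[keep],
                  volume_ul = NA_real_)
  structure(list(breaths = b, ibis_s = diff(b$onset_s),
                 sampling_rate_hz = fs),
            class = "breath_series")
}

empty_breath_series <- function(fs) {
  structure(list(breaths = data.frame(onset_s = numeric(0),
                                      peak_s = numeric(0),
                                      amplitude_mv = numeric(0),
                                      volume_ul = numeric(0)),
                 ibis_s = numeric(0), sampling_rate_hz = fs),
            class = "breath_series")
}

#' @export
print.breath_series <- function(x, ...) {
  cat(sprintf("<breath_series> %d breaths", nrow(x$breaths)))
  if (length(x$ibis_s))
    cat(sprintf(", median IBI %.3f s", median(x$ibis_s)))
  cat("\n")
  invisible(x)
}

#' Apply a calibration factor to a breath series
#'
#' Fills `volume_ul = amplitude_mv * ul_per_mv` for every breath.
#'
#' @param series a `breath_series`.
#' @param cal a `calibration_factor`.
#' @return The series with `volume_ul` populated.
#' @export
apply_calibration <- function(series, cal) {
  if (!inherits(cal, "calibration_factor"))
    stop_input("`cal` must be a calibration_factor")
  series$breaths$volume_ul <- series$breaths$amplitude_mv * cal$ul_per_mv
  series
}

#' Select artifact-free analysis windows within a condition epoch
#'
#' Two policies mirror standard practice: `ventilation` takes maximal
#' artifact-free runs of at least `min_segment_s` (10 s) within the last
#' `tail_s` (300 s) of the epoch and flags the result insufficient when the
#' cumulative coverage is below `min_total_s` (60 s); `pattern` takes
#' artifact-free runs of at least `min_segment_s` anywhere in the epoch, in
#' chronological order, capped at `pattern_cap_s` (600 s) cumulative.
#'
#' @param trace a [pressure_trace()] with epochs.
#' @param epoch_label which condition epoch to analyse.
#' @param policy `"ventilation"` or `"pattern"`.
#' @param min_segment_s,min_total_s,tail_s,pattern_cap_s policy parameters in
#'   seconds.
#' @return Object of class `analysis_windows`: `segments` data.frame
#'   (`start_s`, `end_s`), `cumulative_s`, `policy`, `insufficient` flag.
#' @export
select_windows <- function(trace, epoch_label,
                           policy = c("ventilation", "pattern"),
                           min_segment_s = 10, min_total_s = 60,
                           tail_s = 300, pattern_cap_s = 600) {
  policy <- match.arg(policy)
  if (!epoch_label %in% epoch_labels)
    stop_input("unknown epoch label '%s'", epoch_label)
  if (is.null(trace$epochs) || !epoch_label %in% trace$epochs$label)
    stop_input("epoch '%s' not present in trace", epoch_label)
  ep <- trace$epochs[trace$epochs$label == epoch_label, ][1L, ]
  lo <- if (policy == "ventilation") max(ep$start_s, ep$end_s - tail_s)
        else ep$start_s
  runs <- complement_intervals(trace$artifact_mask, lo, ep$end_s)
  runs <- runs[runs$end_s - runs$start_s >= min_segment_s - 1e-9, ,
               drop = FALSE]
  if (policy == "pattern" && nrow(runs)) {
    len <- runs$end_s - runs$start_s
    cum <- cumsum(len)
    over <- which(cum > pattern_cap_s)
    if (length(over)) {
      k <- over[1L]
      excess <- cum[k] - pattern_cap_s
      runs <- runs[seq_len(k), , drop = FALSE]
      runs$end_s[k] <- runs$end_s[k] - excess
    }
  }
  cumulative <- sum(runs$end_s - runs$start_s)
  structure(list(segments = runs, cumulative_s = cumulative, policy = policy,
                 insufficient = cumulative < min_total_s),
            class = "analysis_windows")
}

# maximal subintervals of [lo, hi) not covered by mask
complement_intervals <- function(mask, lo, hi) {
  if (is.null(mask) || NROW(mask) == 0L)
    return(data.frame(start_s = lo, end_s = hi))
  m <- mask[order(mask$start_s), , drop = FALSE]
  s <- pmax(m$start_s, lo); e <- pmin(m$end_s, hi)
  keep <- s < e
  s <- s[keep]; e <- e[keep]
  starts <- c(lo, e)
  ends <- c(s, hi)
  # merge overlapping mask intervals by sweeping
  out <- data.frame(start_s = numeric(0), end_s = numeric(0))
  cur <- lo
  for (i in seq_along(s)) {
    if (s[i] > cur)
      out <- rbind(out, data.frame(start_s = cur, end_s = s[i]))
    cur <- max(cur, e[i])
  }
  if (cur < hi) out <- rbind(out, data.frame(start_s = cur, end_s = hi))
  out[out$end_s - out$start_s > 1e-12, , drop = FALSE]
}

# breaths whose onset falls inside any window segment [start, end)
breaths_in_windows <- function(series, windows) {
  if (!nrow(series$breaths)) return(series)
  keep <- rep(FALSE, nrow(series$breaths))
  for (i in seq_len(nrow(windows$segments))) {
    seg <- windows$segments[i, ]
    keep <- keep | (series$breaths$onset_s >= seg$start_s &
                    series$breaths$onset_s < seg$end_s)
  }
  b <- series$breaths[keep, , drop = FALSE]
  rownames(b) <- NULL
  # IBIs only between consecutive breaths within the same segment
  ibi <- diff(b$onset_s)
  if (length(ibi)) {
    seg_id <- segment_id(b$onset_s, windows$segments)
    ibi <- ibi[seg_id[-length(seg_id)] == seg_id[-1L]]
  }
  structure(list(breaths = b, ibis_s = ibi,
                 sampling_rate_hz = series$sampling_rate_hz),
            class = "breath_series")
}

segment_id <- function(onsets, segments) {
  id <- rep(NA_integer_, length(onsets))
  for (i in seq_len(nrow(segments)))
    id[onsets >= segments$start_s[i] & onsets < segments$end_s[i]] <- i
  id
}

#' Ventilation summary over selected analysis windows
#'
#' Respiratory rate is `V_f = 60 * n_breaths / cumulative_s` (breaths/min),
#' tidal volume `V_T` is the mean calibrated breath volume (ul), and minute
#' ventilation is their product `V_E = V_f * V_T` (ul/min).
#'
#' @param series a `breath_series` for the whole trace.
#' @param cal a `calibration_factor`.
#' @param windows `analysis_windows` (ventilation policy).
#' @param condition condition label carried into the summary.
#' @return Object of class `respiratory_summary` with fields `vf`, `vt`,
#'   `ve`, `n_breaths`, `condition` (apnea/CV fields are filled by
#'   [pattern_summary()]).
#' @export
ventilation_summary <- function(series, cal, windows, condition = NA_character_) {
  if (windows$insufficient)
    stop_input("analysis windows insufficient (cumulative %.1f s)",
               windows$cumulative_s)
  w <- breaths_in_windows(apply_calibration(series, cal), windows)
  n <- nrow(w$breaths)
  if (n == 0L) stop_input("no breaths inside analysis windows")
  vf <- 60 * n / windows$cumulative_s
  vt <- mean(w$breaths$volume_ul)
  structure(list(vf = vf, vt = vt, ve = vf * vt, n_breaths = n,
                 apnea_count = NA_real_, apnea_mean_length_s = NA_real_,
                 cv_ibi = NA_real_, cv_amplitude = NA_real_,
                 condition = condition),
            class = "respiratory_summary")
}

#' @export
print.respiratory_summary <- function(x, ...) {
  cat(sprintf("<respiratory_summary>%s\n",
              if (is.na(x$condition)) "" else paste0(" [", x$condition, "]")))
  cat(sprintf("  V_f %.1f breaths/min, V_T %.2f ul, V_E %.0f ul/min (n=%d)\n",
              x$vf, x$vt, x$ve, x$n_breaths))
  if (!is.na(x$apnea_count))
    cat(sprintf("  apneas %d (mean %.2f s), CV_IBI %.4f, CV_amp %.4f\n",
                x$apnea_count,
                if (x$apnea_count > 0) x$apnea_mean_length_s else NA,
                x$cv_ibi, x$cv_amplitude))
  invisible(x)
}

#' Breathing-pattern summary (apneas and variability) over pattern windows
#'
#' Computes apnea count and mean apnea length on the interbreath intervals
#' inside the pattern windows (IBIs spanning a window boundary are excluded),
#' plus the coefficient of variation of IBI and of breath amplitude.
#'
#' @param series a `breath_series` for the whole trace.
#' @param windows `analysis_windows` (pattern policy).
#' @param apnea_threshold_s apnea threshold in seconds (default 1.5; an IBI
#'   must be strictly longer to count).
#' @param cv_type passed to [variability_cv()].
#' @return List with `apnea_count`, `apnea_mean_length_s`, `cv_ibi`,
#'   `cv_amplitude`, `ibis_s`.
#' @export
pattern_summary <- function(series, windows, apnea_threshold_s = 1.5,
                            cv_type = c("se", "sd")) {
  cv_type <- match.arg(cv_type)
  w <- breaths_in_windows(series, windows)
  if (!length(w$ibis_s)) stop_input("no interbreath intervals in windows")
  ap <- detect_apneas(w$ibis_s, apnea_threshold_s)
  list(apnea_count = ap$count, apnea_mean_length_s = ap$mean_length_s,
       cv_ibi = variability_cv(w$ibis_s, cv_type),
       cv_amplitude = variability_cv(w$breaths$amplitude_mv, cv_type),
       ibis_s = w$ibis_s)
}
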