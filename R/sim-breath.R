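#' Parameters for the breath-trace simulator
#'
#' Defaults describe a neonatal mouse at postnatal day 0.5 breathing room
#' air: 180 breaths/min, 10 ul tidal volume, 15% interbreath-interval CV,
#' a 5% per-breath apnea probability with apneic intervals drawn uniformly
#' from 1.8-3.0 s (strictly above the 1.5 s detection threshold so ground
#' truth is unambiguous), and flow noise one tenth of the volume-pulse
#' amplitude.
#'
#' @param duration_s trace length in seconds (> 0).
#' @param sampling_rate_hz sampling rate in Hz (>= 100).
#' @param vf_mean mean respiratory rate, breaths/min.
#' @param vt_ul mean tidal volume, microliters.
#' @param ibi_cv coefficient of variation of non-apneic interbreath
#'   intervals (Gamma distributed).
#' @param amp_cv coefficient of variation of breath amplitudes.
#' @param p_apnea probability that any given IBI is an apnea.
#' @param apnea_ibi_range_s length-2 range (low > 1.5) of apneic IBIs,
#'   drawn uniformly.
#' @param noise_sd Gaussian noise SD added to the flow channel, mV.
#' @param artifact_rate_per_min Poisson rate of movement-artifact bursts.
#' @param cal_factor_ul_per_mv true calibration factor: microliters of
#'   volume per mV of integrated peak height.
#' @param seed integer seed; all randomness in one call flows from it.
#' @return List of class `breath_sim_params`.
#' @export
breath_sim_params <- function(duration_s = 600, sampling_rate_hz = 1000,
                              vf_mean = 180, vt_ul = 10, ibi_cv = 0.15,
                              amp_cv = 0.1, p_apnea = 0.05,
                              apnea_ibi_range_s = c(1.8, 3.0),
                              noise_sd = 0.1, artifact_rate_per_min = 0,
                              cal_factor_ul_per_mv = 10, seed = 1L) {
  check_scalar_num(duration_s, "duration_s", 0, strict_lower = TRUE)
  check_scalar_num(sampling_rate_hz, "sampling_rate_hz", 100)
  check_scalar_num(vf_mean, "vf_mean", 0, strict_lower = TRUE)
  check_scalar_num(vt_ul, "vt_ul", 0, strict_lower = TRUE)
  check_scalar_num(ibi_cv, "ibi_cv", 0)
  check_scalar_num(amp_cv, "amp_cv", 0)
  check_scalar_num(p_apnea, "p_apnea", 0, upper = 1 - 1e-12)
  if (length(apnea_ibi_range_s) != 2L ||
      apnea_ibi_range_s[1] <= 1.5 ||
      apnea_ibi_range_s[2] < apnea_ibi_range_s[1])
    stop_input("apnea_ibi_range_s must be (low, high) with low > 1.5")
  check_scalar_num(noise_sd, "noise_sd", 0)
  check_scalar_num(artifact_rate_per_min, "artifact_rate_per_min", 0)
  check_scalar_num(cal_factor_ul_per_mv, "cal_factor_ul_per_mv", 0,
                   strict_lower = TRUE)
  structure(list(duration_s = duration_s,
                 sampling_rate_hz = sampling_rate_hz, vf_mean = vf_mean,
                 vt_ul = vt_ul, ibi_cv = ibi_cv, amp_cv = amp_cv,
                 p_apnea = p_apnea, apnea_ibi_range_s = apnea_ibi_range_s,
                 noise_sd = noise_sd,
                 artifact_rate_per_min = artifact_rate_per_min,
                 cal_factor_ul_per_mv = cal_factor_ul_per_mv,
                 seed = as.integer(seed)),
            class = "breath_sim_params")
}

#' Simulate a pneumotachograph recording with known ground truth
#'
#' Each breath is modelled as a raised-sine volume pulse: breath `i` with
#' onset `t_i`, amplitude `A_i` mV (`vt_ul / cal_factor` scaled by
#' multiplicative Gaussian noise of CV `amp_cv`) and duration
#' `T_i = min(0.6 * IBI_i, 0.4 s)` contributes volume
#' `A_i * sin^2(pi (t - t_i) / T_i)` on `[t_i, t_i + T_i)`. The emitted flow
#' channel is the analytic derivative of that volume model plus Gaussian
#' noise, so integrating the trace recovers the volume pulses and each
#' breath's net flow integral is exactly zero before noise. Interbreath
#' intervals are Gamma with mean `60 / vf_mean` and CV `ibi_cv`, replaced by
#' Uniform(`apnea_ibi_range_s`) draws with probability `p_apnea`. Movement
#' artifacts are high-amplitude broadband bursts added to the flow and
#' recorded in the artifact mask. A separate calibration trace holds
#' injection pulses of `cal_volume_ul` (20 ul) at `cal_rate_hz` (3 Hz).
#'
#' @param params a [breath_sim_params()].
#' @param epoch_label condition label for the single epoch spanning the
#'   trace (default `"room_air"`).
#' @param n_cal_pulses number of calibration injection pulses.
#' @param cal_volume_ul injected volume per calibration pulse, ul.
#' @param cal_rate_hz calibration injection rate, Hz.
#' @return List with `trace` ([pressure_trace()] with epoch and artifact
#'   mask), `cal_trace` (calibration recording), and `truth`: onsets,
#'   IBIs, per-IBI apnea flags, amplitudes (mV), volumes (ul), realized
#'   `true_vf` (breaths/min) and `true_vt` (ul).
#' @export
sim_breath_trace <- function(params, epoch_label = "room_air",
                             n_cal_pulses = 10L, cal_volume_ul = 20,
                             cal_rate_hz = 3) {
  stopifnot(inherits(params, "breath_sim_params"))
  with_seed(params$seed, {
    p <- params
    fs <- p$sampling_rate_hz
    mean_ibi <- 60 / p$vf_mean
    t_max <- p$duration_s
    # draw onsets forward from a small fixed offset
    onsets <- numeric(0); ibis <- numeric(0); apnea <- logical(0)
    t <- 0.05
    default_T <- min(0.6 * mean_ibi, 0.4)
    while (t + default_T <= t_max) {
      onsets <- c(onsets, t)
      is_ap <- runif(1) < p$p_apnea
      ibi <- if (is_ap) {
        runif(1, p$apnea_ibi_range_s[1], p$apnea_ibi_range_s[2])
      } else if (p$ibi_cv > 0) {
        shape <- 1 / p$ibi_cv^2
        rgamma(1, shape = shape, rate = shape / mean_ibi)
      } else mean_ibi
      ibis <- c(ibis, ibi); apnea <- c(apnea, is_ap)
      t <- t + ibi
    }
    nb <- length(onsets)
    if (nb == 0L) stop_input("duration too short for a single breath")
    ibis <- ibis[-nb]; apnea <- apnea[-nb]  # IBI i = onset i+1 - onset i

    amp_mean <- p$vt_ul / p$cal_factor_ul_per_mv
    amps <- amp_mean * pmax(rnorm(nb, 1, p$amp_cv), 0.05)
    durs <- pmin(0.6 * c(ibis, mean_ibi), 0.4)

    flow <- breath_flow_signal(onsets, amps, durs, t_max, fs)
    if (p$noise_sd > 0)
      flow <- flow + rnorm(length(flow), 0, p$noise_sd)

    mask <- NULL
    n_art <- if (p$artifact_rate_per_min > 0)
      rpois(1, p$artifact_rate_per_min * t_max / 60) else 0L
    if (n_art > 0) {
      centers <- sort(runif(n_art, 1, t_max - 1))
      widths <- runif(n_art, 0.5, 2)
      a_start <- pmax(centers - widths / 2, 0)
      a_end <- pmin(centers + widths / 2, t_max)
      for (i in seq_len(n_art)) {
        idx <- (floor(a_start[i] * fs) + 1L):ceiling(a_end[i] * fs)
        idx <- idx[idx >= 1L & idx <= length(flow)]
        flow[idx] <- flow[idx] +
          rnorm(length(idx), 0, 10 * amp_mean * pi / min(durs))
      }
      mask <- data.frame(start_s = pmax(a_start - 0.05, 0),
                         end_s = pmin(a_end + 0.05, t_max),
                         label = "movement")
    }

    trace <- pressure_trace(flow, fs,
                            epochs = data.frame(label = epoch_label,
                                                start_s = 0, end_s = t_max),
                            artifact_mask = mask,
                            temperature_c = rep(36, length(flow)))

    # calibration recording: fixed-volume pulses, same noise level
    cal_amp <- cal_volume_ul / p$cal_factor_ul_per_mv
    cal_T <- min(0.6 / cal_rate_hz, 0.4)
    cal_onsets <- 0.5 + (seq_len(n_cal_pulses) - 1L) / cal_rate_hz
    cal_dur <- cal_onsets[n_cal_pulses] + cal_T + 0.5
    cal_flow <- breath_flow_signal(cal_onsets, rep(cal_amp, n_cal_pulses),
                                   rep(cal_T, n_cal_pulses), cal_dur, fs)
    if (p$noise_sd > 0)
      cal_flow <- cal_flow + rnorm(length(cal_flow), 0, p$noise_sd)
    cal_trace <- pressure_trace(cal_flow, fs)

    span <- onsets[nb] - onsets[1L]
    truth <- list(breath_onsets_s = onsets, ibis_s = ibis,
                  apnea_flags = apnea, amplitudes_mv = amps,
                  volumes_ul = amps * p$cal_factor_ul_per_mv,
                  true_vf = 60 * (nb - 1) / span,
                  true_vt = mean(amps * p$cal_factor_ul_per_mv),
                  pulse_durations_s = durs)
    list(trace = trace, cal_trace = cal_trace, truth = truth)
  })
}

# analytic derivative of the raised-sine volume pulses, evaluated on the
# sample grid; vectorized per breath
breath_flow_signal <- function(onsets, amps, durs, duration_s, fs) {
  n <- as.integer(round(duration_s * fs))
  flow <- numeric(n)
  tgrid0 <- 0  # sample i is at time (i-1)/fs
  for (i in seq_along(onsets)) {
    i0 <- floor(onsets[i] * fs) + 1L
    i1 <- min(ceiling((onsets[i] + durs[i]) * fs) + 1L, n)
    if (i0 > n) next
    tt <- ((i0:i1) - 1L) / fs - onsets[i]
    inside <- tt >= 0 & tt < durs[i]
    f <- numeric(length(tt))
    f[inside] <- amps[i] * (pi / durs[i]) * sin(2 * pi * tt[inside] / durs[i])
    flow[i0:i1] <- flow[i0:i1] + f
  }
  flow
}
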