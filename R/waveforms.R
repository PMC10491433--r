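#' Generate a multi-channel waveform template
#'
#' Somatic templates are biphasic (negative trough then positive peak) with a
#' Gaussian spatial amplitude decay (SD ~ 2 channels) and no systematic
#' peak-time shift across channels. Axonal templates are triphasic
#' (positive-negative-positive) with a wider spatial spread (SD ~ 5 channels)
#' and a linear peak-time shift across channels reflecting action-potential
#' propagation along the axon.
#'
#' @param kind `"axonal"` or `"somatic"`.
#' @param n_channels number of probe channels (>= 8).
#' @param fs waveform sample rate, samples/s (default 30000).
#' @param seed RNG seed.
#' @param peak_channel 0-based channel of maximum amplitude (default middle
#'   of the probe).
#' @param n_samples samples per channel (default 81, 2.7 ms at 30 kHz).
#' @return list: `waveform` (channels x samples matrix), `peak_channel`
#'   (0-based), `fs`.
#' @export
generate_waveform_template <- function(kind = c("somatic", "axonal"),
                                       n_channels = 32, fs = 30000,
                                       seed = NULL, peak_channel = NULL,
                                       n_samples = 81) {
  kind <- match.arg(kind)
  rc_assert(n_channels >= 8, "need at least 8 channels", "rc_parameter_error")
  if (is.null(peak_channel)) peak_channel <- n_channels %/% 2
  with_seed(seed, {
    t_ms <- (seq_len(n_samples) - 1) / fs * 1000
    gauss <- function(mu, sdv) exp(-(t_ms - mu)^2 / (2 * sdv^2))
    # per-template shape jitter: same distribution for every somatic unit,
    # so single-channel features do not separate cell classes
    trough_t <- 0.9 + stats::rnorm(1, 0, 0.05)
    peak_dt <- 0.5 + stats::rnorm(1, 0, 0.08)
    amp <- 80 * exp(stats::rnorm(1, 0, 0.2))
    if (kind == "somatic") {
      shape <- -gauss(trough_t, 0.12) + 0.45 * gauss(trough_t + peak_dt, 0.25)
      spatial_sd <- 2
      shift_per_ch <- 0
    } else {
      shape <- 0.35 * gauss(trough_t - 0.3, 0.1) - gauss(trough_t, 0.1) +
        0.5 * gauss(trough_t + peak_dt * 0.8, 0.2)
      spatial_sd <- 5
      shift_per_ch <- 0.03 * sign(stats::rnorm(1))   # ms per channel
    }
    ch <- seq_len(n_channels) - 1
    decay <- exp(-(ch - peak_channel)^2 / (2 * spatial_sd^2))
    wf <- matrix(0, n_channels, n_samples)
    for (c in seq_len(n_channels)) {
      shift <- shift_per_ch * (ch[c] - peak_channel)
      wf[c, ] <- amp * decay[c] *
        stats::approx(t_ms, shape, xout = t_ms - shift, rule = 2)$y
    }
    wf <- wf + stats::rnorm(length(wf), sd = 0.01 * amp)
    list(waveform = wf, peak_channel = as.integer(peak_channel), fs = fs)
  })
}

#' Extract classification features from a multi-channel waveform
#'
#' Single-channel features (at the peak channel, the channel of maximum
#' peak-to-peak amplitude): trough and peak amplitudes, peak-to-trough
#' duration, amplitude (trough-to-peak span), peak-to-trough ratio, and the
#' number of phases (sign-alternating excursions exceeding 20% of the maximum
#' absolute amplitude). Multi-channel features: spatial spread (number of
#' channels whose peak-to-peak amplitude exceeds 25% of the peak channel's)
#' and propagation slope (linear fit of per-channel trough time against
#' channel index over the spread channels, ms/channel).
#'
#' @param waveform channels x samples matrix (>= 8 channels).
#' @param fs sample rate, samples/s.
#' @return list of class `waveform_features`.
#' @export
waveform_features <- function(waveform, fs) {
  rc_assert(is.matrix(waveform) && nrow(waveform) >= 8,
            "waveform must be a matrix with >= 8 channels")
  ptp <- apply(waveform, 1, function(x) max(x) - min(x))
  if (max(ptp) == 0) rc_stop("flat waveform", "rc_validation_error")
  peak_ch <- which.max(ptp)
  w <- waveform[peak_ch, ]
  i_trough <- which.min(w)
  after <- if (i_trough < length(w)) w[(i_trough + 1):length(w)] else NA
  i_peak <- if (all(is.na(after)) || max(after) <= 0) which.max(w)
            else i_trough + which.max(after)
  trough_amp <- w[i_trough]
  peak_amp <- w[i_peak]
  duration_ms <- abs(i_peak - i_trough) / fs * 1000
  amplitude <- peak_amp - trough_amp
  ratio <- abs(peak_amp) / abs(trough_amp)
  # phases: excursions beyond 20% of max |amplitude|, counted as
  # sign-alternating runs
  thr <- 0.2 * max(abs(w))
  sgn <- sign(w) * (abs(w) > thr)
  sgn <- sgn[sgn != 0]
  n_phases <- if (length(sgn)) 1L + sum(diff(sgn) != 0) else 0L
  spread_ch <- which(ptp > 0.25 * ptp[peak_ch])
  spread <- length(spread_ch)
  slope <- 0
  if (spread >= 3) {
    tt <- apply(waveform[spread_ch, , drop = FALSE], 1, which.min) / fs * 1000
    slope <- unname(stats::coef(stats::lm(tt ~ spread_ch))[2])
  }
  structure(list(peak_channel = peak_ch - 1L, trough_amp = trough_amp,
                 peak_amp = peak_amp, duration_ms = duration_ms,
                 amplitude = amplitude, peak_to_trough_ratio = ratio,
                 n_phases = n_phases, spread = spread,
                 propagation_slope = slope),
            class = "waveform_features")
}

#' Classify a waveform as an axonal or somatic signal
#'
#' Afferent axonal action potentials are triphasic, spatially extended and
#' propagate along the probe; somatic action potentials are biphasic and
#' spatially compact. A template is called axonal iff it is triphasic with a
#' wide spread, or shows a clear propagation slope.
#'
#' @param features a [waveform_features()].
#' @param spread_threshold minimum spread (channels) for the triphasic rule
#'   (default 6).
#' @param slope_threshold minimum |propagation slope| in ms/channel
#'   (default 0.01).
#' @return `"RGC_AXON"` or `"SC_SOMA"`.
#' @export
classify_axonal_vs_somatic <- function(features, spread_threshold = 6,
                                       slope_threshold = 0.01) {
  if ((features$n_phases >= 3 && features$spread >= spread_threshold) ||
        abs(features$propagation_slope) >= slope_threshold) "RGC_AXON"
  else "SC_SOMA"
}
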