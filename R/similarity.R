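#' Spike-triggered-average spatiotemporal receptive field
#'
#' For each lag L, averages over spikes the indicator map of sparse-noise
#' targets (of the requested polarity) active at time (spike - L); the mean
#' stimulus map is subtracted, so a stimulus-independent unit converges to a
#' zero field. Acausal (negative) lags provide the noise reference for the
#' signal-to-noise gate.
#'
#' @param train a [spike_train()].
#' @param events sparse-noise target table from [sparse_noise_events()]
#'   (`time_s`, `x`, `y`, `polarity`).
#' @param polarity `"light"` or `"dark"`.
#' @param lags_ms lag offsets, ms (default causal 0-250 in 25 ms steps plus
#'   acausal -100-0, matching the 100 ms frame granularity).
#' @param grid_dim grid size `c(nx, ny)` (default `c(24, 14)`).
#' @param frame_s frame duration, s (default 0.1).
#' @param min_spikes minimum spikes within the sparse-noise period
#'   (default 100).
#' @return object of class `strf`: `values` (lag x ny x nx array), `lags_ms`,
#'   `polarity`, `n_spikes`.
#' @export
compute_sta_strf <- function(train, events, polarity = c("light", "dark"),
                             lags_ms = c(seq(-100, -25, by = 25),
                                         seq(0, 250, by = 25)),
                             grid_dim = c(24, 14), frame_s = 0.1,
                             min_spikes = 100) {
  polarity <- match.arg(polarity)
  ev <- events[events$polarity == polarity, ]
  rc_assert(nrow(ev) > 0, "no sparse-noise events of requested polarity")
  period <- range(ev$time_s)
  spk <- train$times[train$times >= period[1] & train$times <= period[2] + frame_s]
  if (length(spk) < min_spikes)
    rc_stop(sprintf("only %d spikes in the sparse-noise period (need %d)",
                    length(spk), min_spikes), "rc_validation_error")
  nx <- grid_dim[1]; ny <- grid_dim[2]
  # frame-indexed target maps: onsets are shared between the (possibly
  # multiple) targets of a frame
  onsets <- sort(unique(ev$time_s))
  cellof <- (ev$y - 1) * nx + ev$x
  fidx <- match(ev$time_s, onsets)
  # mean stimulus map (targets per cell / number of frames)
  mean_map <- tabulate(cellof, nx * ny) / length(onsets)
  vals <- array(0, dim = c(length(lags_ms), ny, nx))
  for (li in seq_along(lags_ms)) {
    tq <- spk - ms(lags_ms[li])
    fi <- findInterval(tq, onsets)
    ok <- fi >= 1
    ok[ok] <- tq[ok] < onsets[fi[ok]] + frame_s
    acc <- numeric(nx * ny)
    if (any(ok)) {
      # spikes per frame at this lag, spread onto each frame's target cells
      cnt <- tabulate(fi[ok], length(onsets))
      w <- cnt[fidx]
      agg <- rowsum(w, cellof)
      acc[as.integer(rownames(agg))] <- agg
    }
    avg <- acc / length(spk) - mean_map * (sum(ok) / length(spk))
    vals[li, , ] <- matrix(avg, ny, nx, byrow = TRUE)
  }
  structure(list(values = vals, lags_ms = lags_ms, polarity = polarity,
                 n_spikes = length(spk), grid_dim = grid_dim),
            class = "strf")
}

#' Signal-to-noise ratio of a receptive field, and the SNR > 8 gate
#'
#' SNR is the maximum absolute value over causal lags divided by the
#' standard deviation over acausal (negative) lags, which contain no
#' stimulus-locked signal.
#'
#' @param strf an object from [compute_sta_strf()].
#' @param threshold gate threshold (default 8).
#' @return list: `snr`, `pass` (`snr > threshold`), `degenerate` (zero
#'   acausal SD).
#' @export
strf_snr <- function(strf, threshold = 8) {
  causal <- strf$lags_ms >= 0
  rc_assert(any(!causal), "need acausal lags for the noise estimate")
  noise_sd <- stats::sd(strf$values[!causal, , ])
  peak <- max(abs(strf$values[causal, , ]))
  if (noise_sd == 0) {
    warning("zero acausal SD: SNR reported as Inf")
    return(list(snr = Inf, pass = TRUE, degenerate = TRUE))
  }
  snr <- peak / noise_sd
  list(snr = snr, pass = snr > threshold, degenerate = FALSE)
}

#' Location of the peak of a receptive field
#' @param strf an object from [compute_sta_strf()].
#' @return list `x`, `y`, `lag_ms`, `sign` at the causal absolute maximum.
#' @export
strf_peak <- function(strf) {
  causal <- which(strf$lags_ms >= 0)
  v <- strf$values[causal, , , drop = FALSE]
  i <- arrayInd(which.max(abs(v)), dim(v))
  list(x = i[3], y = i[2], lag_ms = strf$lags_ms[causal[i[1]]],
       sign = sign(v[i]))
}

#' Peri-stimulus time histogram
#'
#' Trial-averaged firing rate aligned to stimulus onsets.
#'
#' @param train a [spike_train()].
#' @param trial_onsets trial onset times, s.
#' @param duration_s trial duration, s.
#' @param bin_ms bin width, ms (default 10).
#' @return list: `rate` (spikes/s per bin), `bin_left_s`, `n_trials`.
#' @export
psth <- function(train, trial_onsets, duration_s, bin_ms = 10) {
  rc_assert(length(trial_onsets) >= 1, "need at least one trial")
  bin <- ms(bin_ms)
  nb <- ceiling(duration_s / bin - 1e-9)
  counts <- numeric(nb)
  for (on in trial_onsets) {
    rel <- train$times[train$times >= on & train$times < on + nb * bin] - on
    if (length(rel)) {
      b <- floor(rel / bin + 1e-12) + 1L
      counts <- counts + tabulate(b, nb)
    }
  }
  list(rate = counts / length(trial_onsets) / bin,
       bin_left_s = (seq_len(nb) - 1) * bin, n_trials = length(trial_onsets))
}

#' Pearson correlation between two response vectors
#'
#' Receptive fields are flattened over (lag, row, column) before correlating.
#'
#' @param a,b numeric vectors, arrays, or `strf` objects of equal length.
#' @return Pearson r, or `NA` with a warning when either input has zero
#'   variance.
#' @export
response_correlation <- function(a, b) {
  if (inherits(a, "strf")) a <- a$values
  if (inherits(b, "strf")) b <- b$values
  a <- as.vector(a); b <- as.vector(b)
  rc_assert(length(a) == length(b) && length(a) >= 3,
            "responses must have equal length >= 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance response: correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Functional-similarity index of a connected pair
#'
#' Averages five response correlations between the presynaptic and
#' postsynaptic unit: receptive fields under dark and light sparse noise
#' (r_SD, r_SL) and trial-averaged rates under the movie, its phase-scrambled
#' surrogate, and a checkerboard stimulus (r_NM, r_PSM, r_Chk). Pairs in
#' which either unit fails the receptive-field SNR gate are excluded from
#' similarity analyses (not from connectivity).
#'
#' @param responses_pre,responses_post named lists with elements `strf_sd`,
#'   `strf_sl` (strf or array) and `psth_nm`, `psth_psm`, `psth_chk`
#'   (rate vectors).
#' @param snr_pass_pre,snr_pass_post SNR-gate booleans for the two units.
#' @return list of class `similarity_result`: `r_sd`, `r_sl`, `r_nm`,
#'   `r_psm`, `r_chk`, `index` (their mean), `snr_pass`, `valid`.
#' @export
similarity_index <- function(responses_pre, responses_post,
                             snr_pass_pre = TRUE, snr_pass_post = TRUE) {
  gate <- isTRUE(snr_pass_pre) && isTRUE(snr_pass_post)
  rs <- c(
    r_sd = response_correlation(responses_pre$strf_sd, responses_post$strf_sd),
    r_sl = response_correlation(responses_pre$strf_sl, responses_post$strf_sl),
    r_nm = response_correlation(responses_pre$psth_nm, responses_post$psth_nm),
    r_psm = response_correlation(responses_pre$psth_psm, responses_post$psth_psm),
    r_chk = response_correlation(responses_pre$psth_chk, responses_post$psth_chk))
  valid <- gate && all(is.finite(rs))
  structure(list(r_sd = rs[["r_sd"]], r_sl = rs[["r_sl"]], r_nm = rs[["r_nm"]],
                 r_psm = rs[["r_psm"]], r_chk = rs[["r_chk"]],
                 index = if (all(is.finite(rs))) mean(rs) else NA_real_,
                 snr_pass = gate, valid = valid),
            class = "similarity_result")
}

#' Per-unit responses needed for the similarity index
#'
#' Computes both sparse-noise receptive fields and the three repeated-
#' stimulus PSTHs for one unit of a session, plus the SNR gate.
#'
#' @param session an [session()].
#' @param unit_id unit to analyse.
#' @param psth_bin_ms PSTH bin, ms.
#' @param min_spikes minimum spikes for the receptive-field estimate.
#' @param snr_threshold receptive-field SNR gate (default 8).
#' @return named list `strf_sd`, `strf_sl`, `psth_nm`, `psth_psm`,
#'   `psth_chk`, `snr`, `snr_pass`, or `NULL` when the unit has too few
#'   spikes for a receptive field.
#' @export
unit_responses <- function(session, unit_id, psth_bin_ms = 10,
                           min_spikes = 100, snr_threshold = 8) {
  tr <- session$trains[[unit_id]]
  ev <- sparse_noise_events(session)
  res <- tryCatch({
    sd_f <- compute_sta_strf(tr, ev, "dark", min_spikes = min_spikes)
    sl_f <- compute_sta_strf(tr, ev, "light", min_spikes = min_spikes)
    list(sd = sd_f, sl = sl_f)
  }, rc_validation_error = function(e) NULL)
  if (is.null(res)) return(NULL)
  snr <- max(strf_snr(res$sd, snr_threshold)$snr,
             strf_snr(res$sl, snr_threshold)$snr)
  trials <- list(nm = "natural_movie", psm = "scrambled_movie", chk = "checkerboard")
  ps <- lapply(trials, function(st) {
    on <- trial_onsets(session, st)
    if (!length(on)) return(NULL)
    dur <- if (length(on) > 1) min(diff(on)) else session$t_stop - on
    psth(tr, on, dur, psth_bin_ms)$rate
  })
  list(strf_sd = res$sd, strf_sl = res$sl,
       psth_nm = ps$nm, psth_psm = ps$psm, psth_chk = ps$chk,
       snr = snr, snr_pass = snr > snr_threshold)
}
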