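#' Monosynaptic-detection and connection-strength parameters
#'
#' Windows are in milliseconds, half-open on the lag grid (a window
#' `(0.4, 3.5)` at 0.1 ms bins covers the 31 bins with left edges
#' 0.4 ... 3.4).
#'
#' @param detect_window_ms peak search window, ms (default `c(0.5, 3.5)`).
#' @param n_consecutive required consecutive super-threshold bins (default 5).
#' @param k_sd threshold multiple over the baseline SD (default 4).
#' @param baseline_flanks_ms two flank windows on the corrected correlogram
#'   used for the threshold baseline statistics.
#' @param efficacy_baseline_window_ms local baseline window for the efficacy
#'   estimate (default `c(-1, 0.4)`).
#' @param efficacy_peak_window_ms peak integration window for efficacy
#'   (default `c(0.4, 3.5)`).
#' @param contribution_window_ms causal window, relative to each postsynaptic
#'   spike, searched for a preceding presynaptic spike (default `c(-3, -0.5)`).
#' @param efficacy_mode `"raw"` (raw correlogram with the local baseline
#'   window, the default) or `"corrected"` (jitter-corrected counts).
#' @return list of class `detection_params`.
#' @export
detection_params <- function(detect_window_ms = c(0.5, 3.5),
                             n_consecutive = 5,
                             k_sd = 4,
                             baseline_flanks_ms = list(c(-50, -0.5), c(4.5, 50)),
                             efficacy_baseline_window_ms = c(-1, 0.4),
                             efficacy_peak_window_ms = c(0.4, 3.5),
                             contribution_window_ms = c(-3, -0.5),
                             efficacy_mode = c("raw", "corrected")) {
  rc_assert(n_consecutive >= 1, "n_consecutive must be >= 1", "rc_parameter_error")
  rc_assert(detect_window_ms[1] < detect_window_ms[2] &&
              efficacy_baseline_window_ms[1] < efficacy_baseline_window_ms[2] &&
              efficacy_peak_window_ms[1] < efficacy_peak_window_ms[2] &&
              contribution_window_ms[1] < contribution_window_ms[2],
            "windows must be well ordered", "rc_parameter_error")
  structure(list(detect_window_ms = detect_window_ms,
                 n_consecutive = as.integer(n_consecutive), k_sd = k_sd,
                 baseline_flanks_ms = baseline_flanks_ms,
                 efficacy_baseline_window_ms = efficacy_baseline_window_ms,
                 efficacy_peak_window_ms = efficacy_peak_window_ms,
                 contribution_window_ms = contribution_window_ms,
                 efficacy_mode = match.arg(efficacy_mode)),
            class = "detection_params")
}

#' Detect a monosynaptic connection from a corrected correlogram
#'
#' A pair is connected iff at least `n_consecutive` consecutive bins inside
#' the detection window exceed baseline mean + `k_sd` x baseline SD, where
#' the baseline statistics are taken over the corrected counts in the flank
#' windows. The latency is the bin-centre lag of the corrected-correlogram
#' maximum inside the detection window (earliest bin on ties).
#'
#' @param ccg a `ccg_result` from [corrected_ccg()].
#' @param params a [detection_params()].
#' @return list: `connected`, `threshold`, `latency_ms` (`NA` when not
#'   connected), `peak_area` (corrected counts summed over the detection
#'   window), `baseline_mean`, `baseline_sd`.
#' @export
detect_connection <- function(ccg, params = detection_params()) {
  rc_assert(ccg$params$bin_ms <= 0.2, "detection requires bins <= 0.2 ms",
            "rc_parameter_error")
  flank_idx <- unlist(lapply(params$baseline_flanks_ms,
                             function(w) ccg_bins_in(ccg, w[1], w[2])))
  base <- ccg$corrected[flank_idx]
  mu <- mean(base)
  sdv <- stats::sd(base)
  flagged_sd <- FALSE
  if (!is.finite(sdv) || sdv == 0) { sdv <- .Machine$double.eps; flagged_sd <- TRUE }
  thr <- mu + params$k_sd * sdv
  det_idx <- ccg_bins_in(ccg, params$detect_window_ms[1], params$detect_window_ms[2])
  vals <- ccg$corrected[det_idx]
  over <- vals > thr
  runs <- rle(over)
  connected <- any(runs$values & runs$lengths >= params$n_consecutive)
  latency <- NA_real_
  if (connected) {
    imax <- det_idx[which.max(vals)]   # which.max takes the earliest tie
    latency <- ccg$lag_left_ms[imax] + ccg$params$bin_ms / 2
  }
  list(connected = connected, threshold = thr, latency_ms = latency,
       peak_area = sum(vals), baseline_mean = mu, baseline_sd = sdv,
       degenerate_sd = flagged_sd)
}

#' Synaptic efficacy of an ordered pair
#'
#' Probability that a presynaptic spike triggers a postsynaptic spike:
#' the baseline-corrected correlogram peak area divided by the number of
#' presynaptic reference spikes. The per-bin baseline is the mean count over
#' the local baseline window; small negative values on noise-dominated pairs
#' are reported as computed, not clipped.
#'
#' @param ccg a `ccg_result` (or the list returned by [compute_ccg()], in
#'   which case only `"raw"` mode is available).
#' @param params a [detection_params()].
#' @return Efficacy as a fraction (1 = every presynaptic spike is followed
#'   by a postsynaptic spike in the peak window).
#' @export
efficacy <- function(ccg, params = detection_params()) {
  if (ccg$n_pre == 0)
    rc_stop("efficacy undefined: no presynaptic spikes", "rc_parameter_error")
  counts <- switch(params$efficacy_mode,
                   raw = ccg$raw,
                   corrected = {
                     rc_assert(!is.null(ccg$corrected),
                               "corrected mode requires a jitter-corrected correlogram")
                     ccg$corrected
                   })
  b_idx <- ccg_bins_in(ccg, params$efficacy_baseline_window_ms[1],
                       params$efficacy_baseline_window_ms[2])
  p_idx <- ccg_bins_in(ccg, params$efficacy_peak_window_ms[1],
                       params$efficacy_peak_window_ms[2])
  baseline_per_bin <- mean(counts[b_idx])
  area <- sum(counts[p_idx] - baseline_per_bin)
  area / ccg$n_pre
}

#' Connection contribution
#'
#' Fraction of postsynaptic spikes preceded by at least one presynaptic
#' spike within the causal window (default 0.5-3 ms before the postsynaptic
#' spike). A contribution of 1 means every postsynaptic spike follows a
#' presynaptic spike.
#'
#' @param pre,post [spike_train()]s.
#' @param params a [detection_params()] (uses `contribution_window_ms`).
#' @param exclusions optional [epoch_set()].
#' @return Fraction in `[0, 1]`.
#' @export
contribution <- function(pre, post, params = detection_params(), exclusions = NULL) {
  pre_t <- apply_exclusions(pre, exclusions)$train$times
  post_t <- apply_exclusions(post, exclusions)$train$times
  if (!length(post_t))
    rc_stop("contribution undefined: no postsynaptic spikes", "rc_parameter_error")
  if (!length(pre_t)) return(0)
  w <- ms(params$contribution_window_ms)   # e.g. c(-0.003, -0.0005)
  a <- post_t + w[1]; b <- post_t + w[2]
  n_in <- findInterval(b + 1e-12, pre_t) - findInterval(a - 1e-12, pre_t)
  mean(n_in > 0)
}

#' Scan every ordered RGC -> SC pair of a session
#'
#' Computes the jitter-corrected correlogram, detection verdict, latency,
#' efficacy and contribution for every pair with a presynaptic unit labeled
#' `RGC` and a postsynaptic unit labeled `SC_EXN` or `SC_IN`. Units named in
#' `exclude_pre` (e.g. LED-responsive axons flagged by
#' [flag_led_responsive_rgc()]) are dropped from the presynaptic side.
#'
#' @param session an [session()] with labeled units.
#' @param ccg_par a [ccg_params()].
#' @param det_par a [detection_params()].
#' @param exclude_pre character vector of presynaptic unit ids to skip.
#' @param channel_pitch_um probe channel pitch for the distance column
#'   (default 20).
#' @param connected_only drop undetected pairs from the result (default
#'   `FALSE`).
#' @return data frame, one row per ordered pair, sorted by (pre, post) peak
#'   channel: `pre_id`, `post_id`, `post_class`, `connected`, `latency_ms`,
#'   `efficacy`, `contribution`, `peak_area`, `threshold`, `n_pre`, `n_post`,
#'   `channel_distance_um`.
#' @export
scan_all_pairs <- function(session, ccg_par = ccg_params(),
                           det_par = detection_params(),
                           exclude_pre = character(0),
                           channel_pitch_um = 20,
                           connected_only = FALSE) {
  u <- session$units
  pre_ids <- setdiff(units_with_label(session, "RGC"), exclude_pre)
  post_ids <- units_with_label(session, c("SC_EXN", "SC_IN"))
  if (!length(pre_ids)) {
    warning("no (non-excluded) RGC units in session: empty pair table")
    return(empty_pair_table())
  }
  chan <- stats::setNames(u$peak_channel, u$unit_id)
  lab <- stats::setNames(u$label, u$unit_id)
  grid <- expand.grid(pre_id = pre_ids, post_id = post_ids,
                      stringsAsFactors = FALSE)
  grid <- grid[order(chan[grid$pre_id], chan[grid$post_id]), ]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pre <- session$trains[[grid$pre_id[i]]]
    post <- session$trains[[grid$post_id[i]]]
    cc <- corrected_ccg(pre, post, ccg_par, session$exclusions)
    det <- detect_connection(cc, det_par)
    eff <- if (cc$n_pre > 0) efficacy(cc, det_par) else NA_real_
    ctr <- if (cc$n_post > 0) contribution(pre, post, det_par, session$exclusions)
           else NA_real_
    data.frame(pre_id = grid$pre_id[i], post_id = grid$post_id[i],
               post_class = unname(lab[grid$post_id[i]]),
               connected = det$connected, latency_ms = det$latency_ms,
               efficacy = eff, contribution = ctr,
               peak_area = det$peak_area, threshold = det$threshold,
               n_pre = cc$n_pre, n_post = cc$n_post,
               channel_distance_um = abs(chan[grid$pre_id[i]] -
                                           chan[grid$post_id[i]]) * channel_pitch_um)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (connected_only) out <- out[out$connected, ]
  out
}

empty_pair_table <- function() {
  data.frame(pre_id = character(0), post_id = character(0),
             post_class = character(0), connected = logical(0),
             latency_ms = numeric(0), efficacy = numeric(0),
             contribution = numeric(0), peak_area = numeric(0),
             threshold = numeric(0), n_pre = integer(0), n_post = integer(0),
             channel_distance_um = numeric(0))
}
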