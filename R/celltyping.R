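#' Light-modulation test for one unit
#'
#' Compares per-pulse spike counts in a response window after pulse onset
#' against equal-length pre-pulse baseline windows with a one-sided paired
#' Wilcoxon signed-rank test for an increase. Onset latency is the first
#' 1 ms bin of the pulse-aligned PSTH exceeding the pre-pulse baseline mean
#' + 3 SD.
#'
#' @param train a [spike_train()].
#' @param pulses pulse table rows (`onset_s`, `duration_s`, `protocol`); use
#'   one protocol at a time.
#' @param response_window_ms response window after onset, ms (default: the
#'   pulse duration).
#' @param baseline_window_ms pre-onset baseline window, ms (default: equal
#'   to the response window).
#' @return list of class `light_response`: `baseline_rate`, `pulse_rate`,
#'   `rate_ratio`, `onset_latency_ms`, `p_value`, `n_pulses`, `low_power`
#'   (< 20 pulses), `protocol`.
#' @export
light_modulation_test <- function(train, pulses, response_window_ms = NULL,
                                  baseline_window_ms = NULL) {
  n <- nrow(pulses)
  rc_assert(n >= 1, "no pulses supplied")
  low_power <- n < 20
  if (low_power) warning("fewer than 20 pulses: low-power light-modulation test")
  rw <- if (is.null(response_window_ms)) pulses$duration_s[1]
        else ms(response_window_ms)
  bw <- if (is.null(baseline_window_ms)) rw else ms(baseline_window_ms)
  t <- train$times
  count_in <- function(a, b) findInterval(b, t) - findInterval(a, t)
  resp <- count_in(pulses$onset_s, pulses$onset_s + rw)
  base <- count_in(pulses$onset_s - bw, pulses$onset_s)
  pulse_rate <- mean(resp) / rw
  baseline_rate <- mean(base) / bw
  if (sum(resp) + sum(base) == 0) {
    warning("silent unit: light-modulation test undefined")
    return(structure(list(baseline_rate = 0, pulse_rate = 0,
                          rate_ratio = NA_real_, onset_latency_ms = NA_real_,
                          p_value = NA_real_, n_pulses = n,
                          low_power = low_power,
                          protocol = pulses$protocol[1] %||% NA_character_),
                     class = "light_response"))
  }
  p <- if (all(resp == base)) 1
       else suppressWarnings(stats::wilcox.test(resp, base, paired = TRUE,
                                                alternative = "greater",
                                                exact = FALSE)$p.value)
  # onset latency from a 1 ms pulse-aligned PSTH
  nb_b <- max(1L, round(to_ms(bw)))
  nb_r <- max(1L, round(to_ms(rw)))
  rel <- unlist(lapply(pulses$onset_s, function(on) {
    s <- t[t >= on - bw & t < on + rw] - on
    s
  }))
  edges_idx <- floor(to_ms(rel)) + nb_b + 1L
  hist_all <- tabulate(edges_idx[edges_idx >= 1 & edges_idx <= nb_b + nb_r],
                       nb_b + nb_r)
  base_bins <- hist_all[seq_len(nb_b)]
  thr <- mean(base_bins) + 3 * stats::sd(base_bins)
  post_bins <- hist_all[(nb_b + 1):(nb_b + nb_r)]
  onset <- which(post_bins > thr)[1]
  structure(list(baseline_rate = baseline_rate, pulse_rate = pulse_rate,
                 rate_ratio = if (baseline_rate > 0) pulse_rate / baseline_rate
                              else NA_real_,
                 onset_latency_ms = if (length(onset) && !is.na(onset))
                   onset - 0.5 else NA_real_,
                 p_value = p, n_pulses = n, low_power = low_power,
                 protocol = pulses$protocol[1] %||% NA_character_),
            class = "light_response")
}

#' Classify one SC unit from its light responses
#'
#' A unit is inhibitory (`SC_IN`) iff the spontaneous-protocol test shows a
#' significant increase (p < `p_threshold`) with rate ratio >=
#' `ratio_threshold` and onset latency <= `latency_max_ms`, corroborated by
#' an increase in the checkerboard protocol. It is excitatory (`SC_EXN`) iff
#' not light-modulated AND located within the light-activated channel range.
#' Everything else (outside the range, or conflicting protocols) is
#' `EXCLUDED`.
#'
#' @param response_spont `light_response` from the spontaneous (100 ms pulse)
#'   protocol.
#' @param response_chk `light_response` from the checkerboard (1000 ms pulse)
#'   protocol, or `NULL` (flagged, spontaneous-only rule applies).
#' @param in_range is the unit's peak channel inside the light-activated
#'   range ([light_activated_range()])?
#' @param p_threshold,ratio_threshold,latency_max_ms tagging criterion.
#' @return `"SC_IN"`, `"SC_EXN"` or `"EXCLUDED"`.
#' @export
classify_sc_unit <- function(response_spont, response_chk = NULL, in_range,
                             p_threshold = 0.001, ratio_threshold = 1.5,
                             latency_max_ms = 20) {
  modulated <- function(r, check_latency = TRUE) {
    !is.null(r) && is.finite(r$p_value) && r$p_value < p_threshold &&
      is.finite(r$rate_ratio) && r$rate_ratio >= ratio_threshold &&
      (!check_latency || (is.finite(r$onset_latency_ms) &&
                            r$onset_latency_ms <= latency_max_ms))
  }
  increased <- function(r) !is.null(r) && is.finite(r$rate_ratio) && r$rate_ratio > 1
  spont_in <- modulated(response_spont)
  if (spont_in) {
    corroborated <- is.null(response_chk) || increased(response_chk)
    if (corroborated) return("SC_IN")
    return("EXCLUDED")   # opposite direction across protocols
  }
  # not tagged: excitatory only when inside the light-activated range and
  # not weakly-but-significantly modulated in either protocol
  weak_mod <- (!is.null(response_spont) && is.finite(response_spont$p_value) &&
                 response_spont$p_value < p_threshold &&
                 is.finite(response_spont$rate_ratio) &&
                 response_spont$rate_ratio >= ratio_threshold)
  if (isTRUE(in_range) && !weak_mod) return("SC_EXN")
  "EXCLUDED"
}

#' Light-activated channel range
#'
#' The probe span reached by the optogenetic stimulation, defined by the
#' minimum and maximum peak channel of the tagged (light-activated) units.
#'
#' @param tagged_peak_channels peak channels of tagged units.
#' @return `c(ch_min, ch_max)`.
#' @export
light_activated_range <- function(tagged_peak_channels) {
  rc_assert(length(tagged_peak_channels) >= 1,
            "no tagged units: light-activated range undefined")
  range(tagged_peak_channels)
}

#' Flag retinal axons responding to the light pulse
#'
#' Retinal axons should not respond to the optogenetic pulse; those that do
#' (light artifacts or mislabeled units) are excluded from the connectivity
#' scan. The spontaneous-protocol tagging criterion is reused.
#'
#' @param session an [session()].
#' @param rgc_ids RGC unit ids (default: all units labeled RGC).
#' @param ... thresholds passed to [classify_sc_unit()]'s criterion.
#' @return named logical vector: `TRUE` = exclude.
#' @export
flag_led_responsive_rgc <- function(session, rgc_ids = NULL, ...) {
  if (is.null(rgc_ids)) rgc_ids <- units_with_label(session, "RGC")
  spont <- session$pulses[session$pulses$protocol == "spontaneous_100ms", ]
  if (!nrow(spont)) {
    warning("session has no spontaneous-protocol pulses: no RGC flagged")
    return(stats::setNames(rep(FALSE, length(rgc_ids)), rgc_ids))
  }
  out <- vapply(rgc_ids, function(id) {
    r <- light_modulation_test(session$trains[[id]], spont)
    classify_sc_unit(r, response_chk = NULL, in_range = TRUE, ...) == "SC_IN"
  }, TRUE)
  stats::setNames(out, rgc_ids)
}

#' Optotagging-based classification of all SC units of a session
#'
#' Runs [light_modulation_test()] under both protocols for every
#' (non-retinal) unit, derives the light-activated channel range from the
#' tagged units, and assigns `SC_IN` / `SC_EXN` / `EXCLUDED` labels.
#'
#' @param session an [session()].
#' @param unit_ids units to classify (default: all units not labeled RGC).
#' @param p_threshold,ratio_threshold,latency_max_ms tagging criterion.
#' @return data frame: `unit_id`, `label`, `rate_ratio_spont`, `p_spont`,
#'   `latency_ms`, `rate_ratio_chk`, `in_range`, `peak_channel`.
#' @export
classify_session_units <- function(session, unit_ids = NULL,
                                   p_threshold = 0.001, ratio_threshold = 1.5,
                                   latency_max_ms = 20) {
  if (is.null(unit_ids))
    unit_ids <- session$units$unit_id[session$units$label != "RGC"]
  spont <- session$pulses[session$pulses$protocol == "spontaneous_100ms", ]
  chk <- session$pulses[session$pulses$protocol == "checkerboard_1000ms", ]
  rc_assert(nrow(spont) > 0, "session has no spontaneous-protocol pulses")
  resp_s <- lapply(unit_ids, function(id)
    light_modulation_test(session$trains[[id]], spont))
  resp_c <- if (nrow(chk)) lapply(unit_ids, function(id)
    light_modulation_test(session$trains[[id]], chk)) else
      vector("list", length(unit_ids))
  tagged <- vapply(seq_along(unit_ids), function(i)
    classify_sc_unit(resp_s[[i]], resp_c[[i]], in_range = TRUE,
                     p_threshold, ratio_threshold, latency_max_ms) == "SC_IN",
    TRUE)
  chan <- stats::setNames(session$units$peak_channel, session$units$unit_id)
  if (!any(tagged)) {
    warning("no light-activated units: range undefined, all units EXCLUDED")
    rng <- c(Inf, -Inf)
  } else rng <- light_activated_range(chan[unit_ids[tagged]])
  in_range <- chan[unit_ids] >= rng[1] & chan[unit_ids] <= rng[2]
  label <- vapply(seq_along(unit_ids), function(i)
    classify_sc_unit(resp_s[[i]], resp_c[[i]], in_range[i],
                     p_threshold, ratio_threshold, latency_max_ms), "")
  data.frame(
    unit_id = unit_ids, label = label,
    rate_ratio_spont = vapply(resp_s, function(r) r$rate_ratio, 0),
    p_spont = vapply(resp_s, function(r) r$p_value, 0),
    latency_ms = vapply(resp_s, function(r) r$onset_latency_ms, 0),
    rate_ratio_chk = vapply(resp_c, function(r)
      if (is.null(r)) NA_real_ else r$rate_ratio, 0),
    in_range = unname(in_range), peak_channel = unname(chan[unit_ids]))
}
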