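# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation available so that they cannot share a
# bug with the implementation they check.

# brute-force lag histogram by double loop (only for small trains)
brute_ccg <- function(pre, post, bin_ms = 0.1, window_ms = 50) {
  nb <- as.integer(round(2 * window_ms / bin_ms))
  counts <- integer(nb)
  for (tp in pre) {
    for (tq in post) {
      lag_ms <- (tq - tp) * 1000
      if (lag_ms >= -window_ms && lag_ms < window_ms) {
        b <- floor((lag_ms + window_ms) / bin_ms + 1e-9) + 1L
        if (b >= 1 && b <= nb) counts[b] <- counts[b] + 1L
      }
    }
  }
  counts
}

# textbook product-moment correlation
brute_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# a tiny hand-assembled session: 2 units with a handful of spikes
tiny_session <- function() {
  tr <- list(
    u1 = spike_train("u1", c(0.5, 1.0, 2.5), 0, 10),
    u2 = spike_train("u2", c(0.2, 4.4), 0, 10))
  units <- data.frame(unit_id = c("u1", "u2"), peak_channel = c(3L, 8L),
                      label = c("RGC", "SC_EXN"))
  wf <- list(u1 = matrix(rnorm(16 * 10), 16, 10))
  session(tr, units, waveforms = wf, channel_count = 16, t_start = 0, t_stop = 10,
          pulses = data.frame(onset_s = 1, duration_s = 0.1,
                              protocol = "spontaneous_100ms"),
          stim_events = data.frame(stimulus = "natural_movie",
                                   event_type = "trial_onset", time_s = 5,
                                   payload = "{\"trial\":1}"),
          exclusions = epoch_set(6, 7))
}

# hand-constructed corrected-correlogram result with a given corrected
# vector (defaults: standard 0.1 ms / 50 ms grid)
fake_ccg <- function(corrected, raw = NULL, n_pre = 1000L,
                     params = ccg_params()) {
  nb <- as.integer(round(2 * params$window_ms / params$bin_ms))
  stopifnot(length(corrected) == nb)
  if (is.null(raw)) raw <- pmax(round(corrected), 0)
  structure(list(lag_left_ms = -params$window_ms +
                   (seq_len(nb) - 1) * params$bin_ms,
                 raw = raw, expected = raw - corrected, corrected = corrected,
                 n_pre = n_pre, n_post = sum(raw), params = params),
            class = "ccg_result")
}
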