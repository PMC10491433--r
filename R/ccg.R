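#' Cross-correlogram parameters
#'
#' @param bin_ms lag bin width, ms (default 0.1).
#' @param window_ms half width of the lag range, ms (default 50; lags span
#'   `[-window, +window)` in half-open bins).
#' @param jitter_window_ms width of the fixed consecutive jitter windows, ms
#'   (default 10).
#' @param n_jitter number of jitter resamples averaged into the expected
#'   correlogram (default 100).
#' @param jitter_both jitter both trains instead of only the reference
#'   (presynaptic) train (default `FALSE`).
#' @param seed RNG seed for the jitter resamples.
#' @return list of class `ccg_params`.
#' @export
ccg_params <- function(bin_ms = 0.1, window_ms = 50, jitter_window_ms = 10,
                       n_jitter = 100, jitter_both = FALSE, seed = 1L) {
  rc_assert(bin_ms > 0 && window_ms > 0, "bin and window must be positive",
            "rc_parameter_error")
  rc_assert(abs(window_ms / bin_ms - round(window_ms / bin_ms)) < 1e-9,
            "window_ms must be a multiple of bin_ms", "rc_parameter_error")
  rc_assert(jitter_window_ms > 0, "jitter window must be positive", "rc_parameter_error")
  rc_assert(n_jitter >= 1, "n_jitter must be >= 1", "rc_parameter_error")
  structure(list(bin_ms = bin_ms, window_ms = window_ms,
                 jitter_window_ms = jitter_window_ms,
                 n_jitter = as.integer(n_jitter),
                 jitter_both = isTRUE(jitter_both), seed = seed),
            class = "ccg_params")
}

# left edges of the lag grid, in ms
ccg_lag_edges <- function(params) {
  n <- as.integer(round(2 * params$window_ms / params$bin_ms))
  -params$window_ms + (seq_len(n) - 1) * params$bin_ms
}

# raw lag histogram: counts of (t_post - t_pre) per half-open bin.
# pre/post are plain numeric vectors in seconds, sorted.
ccg_count <- function(pre, post, bin_ms, window_ms) {
  nb <- as.integer(round(2 * window_ms / bin_ms))
  if (!length(pre) || !length(post)) return(integer(nb))
  w <- ms(window_ms)
  lo <- findInterval(pre - w, post)        # post[lo] <= pre - w < post[lo+1]
  hi <- findInterval(pre + w, post)
  npair <- hi - lo
  take <- npair > 0
  if (!any(take)) return(integer(nb))
  idx <- sequence(npair[take]) + rep(lo[take], npair[take])
  lag_ms <- to_ms(post[idx] - rep(pre[take], npair[take]))
  b <- floor((lag_ms + window_ms) / bin_ms + 1e-9) + 1L
  tabulate(b[b >= 1L & b <= nb], nb)
}

#' Raw cross-correlogram between two spike trains
#'
#' Positive lags mean the target (postsynaptic) spike follows the reference
#' (presynaptic) spike. Every reference spike is a trigger; exclusion epochs
#' are removed from both trains before counting.
#'
#' @param pre,post [spike_train()]s sharing a recording span.
#' @param params a [ccg_params()].
#' @param exclusions optional [epoch_set()].
#' @return list with `lag_left_ms` (left bin edges), `raw` (counts),
#'   `n_pre`, `n_post`.
#' @export
compute_ccg <- function(pre, post, params = ccg_params(), exclusions = NULL) {
  pre_t <- apply_exclusions(pre, exclusions)$train$times
  post_t <- apply_exclusions(post, exclusions)$train$times
  if (!length(pre_t)) warning("empty reference train: all-zero correlogram")
  list(lag_left_ms = ccg_lag_edges(params),
       raw = ccg_count(pre_t, post_t, params$bin_ms, params$window_ms),
       n_pre = length(pre_t), n_post = length(post_t))
}

# jitter a plain time vector within fixed consecutive windows anchored at
# t_start; per-window spike counts are preserved by construction
jitter_times <- function(times, t_start, t_stop, jitter_window_s) {
  if (!length(times)) return(times)
  k <- floor((times - t_start) / jitter_window_s)
  lo <- t_start + k * jitter_window_s
  hi <- pmin(lo + jitter_window_s, t_stop)
  sort(stats::runif(length(times), lo, hi))
}

#' Interval-jitter resample of a spike train
#'
#' Partitions the time axis into fixed consecutive windows anchored at
#' `t_start` and redraws each spike uniformly within its own window. Spike
#' counts per window are preserved exactly, so rate covariation slower than
#' the window survives while millisecond-scale synchrony is destroyed.
#'
#' @param train a [spike_train()].
#' @param jitter_window_ms window width, ms (default 10).
#' @param seed optional RNG seed.
#' @return A jittered [spike_train()].
#' @export
jitter_spike_train <- function(train, jitter_window_ms = 10, seed = NULL) {
  rc_assert(jitter_window_ms > 0, "jitter window must be positive", "rc_parameter_error")
  with_seed(seed, {
    out <- train
    out$times <- jitter_times(train$times, train$t_start, train$t_stop,
                              ms(jitter_window_ms))
    out
  })
}

#' Jitter-corrected cross-correlogram
#'
#' Computes the raw correlogram and an expected correlogram under the
#' interval-jitter null (mean over `n_jitter` resamples of the reference
#' train, or of both trains when `jitter_both`), and their difference.
#' The corrected correlogram is flat for pairs whose raw correlation stems
#' from rate comodulation slower than the jitter window, while a monosynaptic
#' millisecond-latency peak survives.
#'
#' @inheritParams compute_ccg
#' @return Object of class `ccg_result` with fields `lag_left_ms`, `raw`,
#'   `expected`, `corrected`, `n_pre`, `n_post`, `params`.
#' @export
corrected_ccg <- function(pre, post, params = ccg_params(), exclusions = NULL) {
  pre_f <- apply_exclusions(pre, exclusions)$train
  post_f <- apply_exclusions(post, exclusions)$train
  raw <- ccg_count(pre_f$times, post_f$times, params$bin_ms, params$window_ms)
  jw <- ms(params$jitter_window_ms)
  acc <- numeric(length(raw))
  with_seed(params$seed, {
    for (j in seq_len(params$n_jitter)) {
      pj <- jitter_times(pre_f$times, pre_f$t_start, pre_f$t_stop, jw)
      qj <- if (params$jitter_both)
        jitter_times(post_f$times, post_f$t_start, post_f$t_stop, jw)
      else post_f$times
      acc <- acc + ccg_count(pj, qj, params$bin_ms, params$window_ms)
    }
  })
  expected <- acc / params$n_jitter
  structure(list(lag_left_ms = ccg_lag_edges(params), raw = raw,
                 expected = expected, corrected = raw - expected,
                 n_pre = length(pre_f$times), n_post = length(post_f$times),
                 params = params),
            class = "ccg_result")
}

#' @export
print.ccg_result <- function(x, ...) {
  cat(sprintf("<ccg_result> %d bins of %.2f ms on [%.0f, %.0f) ms; n_pre=%d n_post=%d\n",
              length(x$raw), x$params$bin_ms, -x$params$window_ms,
              x$params$window_ms, x$n_pre, x$n_post))
  invisible(x)
}

# indices of bins whose half-open [left, left+bin) support lies inside
# the half-open window [lo, hi)
ccg_bins_in <- function(ccg, lo_ms, hi_ms) {
  bin <- ccg$params$bin_ms %||% diff(ccg$lag_left_ms[1:2])
  eps <- 1e-9
  which(ccg$lag_left_ms >= lo_ms - eps & ccg$lag_left_ms + bin <= hi_ms + eps)
}

#' Write / read a correlogram result as CSV + JSON sidecar
#'
#' @param ccg a `ccg_result`.
#' @param path base path; writes `<path>.csv` and `<path>.json`.
#' @export
write_ccg <- function(ccg, path) {
  write_csv_plain(data.frame(lag_left_ms = sprintf("%.6f", ccg$lag_left_ms),
                             raw = ccg$raw,
                             expected = sprintf("%.9f", ccg$expected),
                             corrected = sprintf("%.9f", ccg$corrected)),
                  paste0(path, ".csv"))
  jsonlite::write_json(list(n_pre = ccg$n_pre, n_post = ccg$n_post,
                            params = unclass(ccg$params)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
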