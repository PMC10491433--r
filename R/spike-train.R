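#' Spike train of a single sorted unit
#'
#' The universal input of the pipeline: the sorted event times of one unit,
#' in seconds, together with the recording span over which the unit was
#' observed.
#'
#' @param unit_id character scalar identifying the unit.
#' @param times numeric vector of spike times in seconds, nondecreasing,
#'   all within `[t_start, t_stop]`.
#' @param t_start,t_stop recording span in seconds, `t_stop > t_start`.
#' @return An object of class `spike_train` (list with fields `unit_id`,
#'   `times`, `t_start`, `t_stop`).
#' @export
spike_train <- function(unit_id, times, t_start = 0, t_stop = NULL) {
  times <- as.double(times)
  rc_assert(is.character(unit_id) && length(unit_id) == 1,
            "unit_id must be a single string")
  if (is.null(t_stop)) t_stop <- if (length(times)) max(times) else t_start + 1
  rc_assert(t_stop > t_start, sprintf("t_stop must exceed t_start for unit %s", unit_id))
  if (length(times)) {
    rc_assert(!is.unsorted(times),
              sprintf("spike times of unit %s are not sorted", unit_id))
    rc_assert(times[1] >= t_start && times[length(times)] <= t_stop,
              sprintf("spike times of unit %s fall outside [t_start, t_stop]", unit_id))
  }
  structure(list(unit_id = unit_id, times = times,
                 t_start = as.double(t_start), t_stop = as.double(t_stop)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d spikes on [%.3f, %.3f] s (%.2f spikes/s)\n",
              x$unit_id, length(x$times), x$t_start, x$t_stop,
              length(x$times) / (x$t_stop - x$t_start)))
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$times)

#' Mean firing rate of a spike train (spikes/s)
#' @param train a [spike_train()].
#' @export
firing_rate <- function(train) length(train$times) / (train$t_stop - train$t_start)

#' Set of non-overlapping time epochs
#'
#' Epochs are half-open intervals `[start, stop)` in seconds. Overlapping or
#' abutting input intervals are merged on construction.
#'
#' @param start,stop numeric vectors of equal length; `start < stop` pairwise.
#' @return An `epoch_set`: data frame with columns `start`, `stop`.
#' @export
epoch_set <- function(start = numeric(0), stop = numeric(0)) {
  rc_assert(length(start) == length(stop), "start and stop must have equal length")
  start <- as.double(start); stop <- as.double(stop)
  rc_assert(all(start < stop), "every epoch must satisfy start < stop")
  if (length(start)) {
    o <- order(start)
    start <- start[o]; stop <- stop[o]
    # merge overlaps
    ms_ <- numeric(0); me <- numeric(0)
    cs <- start[1]; ce <- stop[1]
    for (i in seq_along(start)[-1]) {
      if (start[i] <= ce) ce <- max(ce, stop[i])
      else { ms_ <- c(ms_, cs); me <- c(me, ce); cs <- start[i]; ce <- stop[i] }
    }
    start <- c(ms_, cs); stop <- c(me, ce)
  }
  structure(data.frame(start = start, stop = stop), class = c("epoch_set", "data.frame"))
}

#' Total duration covered by an epoch set (seconds)
#' @param epochs an [epoch_set()].
#' @export
epoch_duration <- function(epochs) {
  if (is.null(epochs) || nrow(epochs) == 0) return(0)
  sum(epochs$stop - epochs$start)
}

# TRUE for times inside any epoch (half-open [start, stop))
in_epochs <- function(times, epochs) {
  if (is.null(epochs) || nrow(epochs) == 0 || length(times) == 0)
    return(logical(length(times)))
  # epochs are disjoint and sorted: a time is inside iff the most recent
  # start at or before it has its stop after it
  i <- findInterval(times, epochs$start)
  inside <- i >= 1
  inside[inside] <- times[inside] < epochs$stop[i[inside]]
  inside
}

#' Remove spikes falling inside exclusion epochs
#'
#' Used to drop optogenetic-stimulation periods before any correlation
#' analysis. Epochs are half-open `[start, stop)`.
#'
#' @param train a [spike_train()].
#' @param epochs an [epoch_set()] (may be `NULL` or empty: identity).
#' @return A list with `train` (filtered [spike_train()]) and
#'   `effective_duration_s` = recording span minus total excluded time
#'   overlapping the span.
#' @export
apply_exclusions <- function(train, epochs) {
  span <- train$t_stop - train$t_start
  if (is.null(epochs) || nrow(epochs) == 0)
    return(list(train = train, effective_duration_s = span))
  keep <- !in_epochs(train$times, epochs)
  ov <- pmin(epochs$stop, train$t_stop) - pmax(epochs$start, train$t_start)
  excl <- sum(pmax(ov, 0))
  out <- train
  out$times <- train$times[keep]
  list(train = out, effective_duration_s = span - excl)
}

#' Remove double-counted spikes within a tolerance
#'
#' Partitions the train into runs of spikes chained by consecutive gaps of
#' at most `tol_ms` and keeps only the first spike of each run, so a chained
#' burst of near-coincident events collapses to its first member. Default
#' tolerance 0.16 ms, the double-counting window used when curating sorted
#' units.
#'
#' @param train a [spike_train()].
#' @param tol_ms tolerance in milliseconds (default 0.16).
#' @return A deduplicated [spike_train()].
#' @export
remove_duplicate_spikes <- function(train, tol_ms = 0.16) {
  rc_assert(tol_ms >= 0, "tolerance must be nonnegative", "rc_parameter_error")
  t <- train$times
  if (length(t) < 2) return(train)
  out <- train
  out$times <- t[c(TRUE, diff(t) > ms(tol_ms))]
  out
}

#' Inter-spike-interval violation ratio
#'
#' Fraction of spikes whose preceding inter-spike interval is shorter than
#' the refractory period; units exceeding a small ratio (default exclusion
#' criterion 0.05%) are flagged by quality control as contaminated.
#'
#' @param train a [spike_train()].
#' @param refractory_ms refractory period in milliseconds (default 1.5).
#' @return Fraction in `[0, 1]`.
#' @export
isi_violation_ratio <- function(train, refractory_ms = 1.5) {
  n <- length(train$times)
  if (n < 2) {
    warning("fewer than 2 spikes: ISI violation ratio reported as 0")
    return(0)
  }
  sum(diff(train$times) < ms(refractory_ms)) / n
}

#' Unit-level quality control
#'
#' Applies duplicate-spike removal and the ISI-violation exclusion rule.
#'
#' @param train a [spike_train()].
#' @param dup_tol_ms duplicate window, ms.
#' @param refractory_ms refractory period, ms.
#' @param max_violation maximum admissible ISI-violation ratio (default
#'   0.0005, i.e. 0.05%).
#' @return list with `train` (deduplicated), `isi_ratio`, `pass` (logical).
#' @export
qc_unit <- function(train, dup_tol_ms = 0.16, refractory_ms = 1.5,
                    max_violation = 5e-4) {
  train <- remove_duplicate_spikes(train, dup_tol_ms)
  ratio <- if (length(train$times) >= 2)
    sum(diff(train$times) < ms(refractory_ms)) / length(train$times) else 0
  list(train = train, isi_ratio = ratio, pass = ratio <= max_violation)
}

#' Detect multi-unit activity events by double-sided threshold crossing
#'
#' Events are excursions of the band-passed voltage trace beyond
#' `k_sd` robust standard deviations (median absolute deviation scaled by
#' 1.4826) on either side, with a 0.5 ms lockout between events.
#'
#' @param trace numeric voltage trace (one channel).
#' @param fs sampling rate, samples/s.
#' @param k_sd threshold multiple (default 4).
#' @param lockout_ms minimum separation between events, ms (default 0.5).
#' @return Numeric vector of event times in seconds (time of first
#'   super-threshold sample of each excursion).
#' @export
detect_mua_events <- function(trace, fs, k_sd = 4, lockout_ms = 0.5) {
  rc_assert(fs > 0, "fs must be positive", "rc_parameter_error")
  rc_assert(all(is.finite(trace)), "trace must be finite")
  sd_r <- stats::mad(trace, constant = 1.4826)
  if (sd_r == 0) return(numeric(0))
  thr <- k_sd * sd_r
  over <- abs(trace - stats::median(trace)) > thr
  if (!any(over)) return(numeric(0))
  # first sample of each excursion
  starts <- which(over & !c(FALSE, over[-length(over)]))
  t <- (starts - 1) / fs
  # lockout sweep
  keep <- logical(length(t)); last <- -Inf
  lock <- ms(lockout_ms)
  for (i in seq_along(t)) {
    if (t[i] - last >= lock) { keep[i] <- TRUE; last <- t[i] }
  }
  t[keep]
}
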