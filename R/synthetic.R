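#' Planted synapse parameters
#'
#' @param efficacy_base probability `p1` in `[0,1]` that a non-facilitated
#'   presynaptic spike triggers a postsynaptic spike.
#' @param facilitation multiplier `f >= 0` applied when the triggering spike's
#'   preceding inter-spike interval is at most `facilitation_isi_ms`;
#'   `p1 * f` is clipped to 1.
#' @param facilitation_isi_ms facilitation gate, ms (default 30, matching the
#'   paired-spike analysis window).
#' @param latency_mean_ms,latency_sd_ms transmission-latency distribution,
#'   truncated to (0.5, 3.5) ms.
#' @param background_rate postsynaptic Poisson background, spikes/s.
#' @return list of class `synapse_params`.
#' @export
synapse_params <- function(efficacy_base, facilitation = 1,
                           facilitation_isi_ms = 30,
                           latency_mean_ms = 1.5, latency_sd_ms = 0.4,
                           background_rate = 5) {
  rc_assert(efficacy_base >= 0 && efficacy_base <= 1,
            "efficacy_base must be in [0,1]", "rc_parameter_error")
  rc_assert(facilitation >= 0, "facilitation must be >= 0", "rc_parameter_error")
  rc_assert(latency_mean_ms > 0.5 && latency_mean_ms < 3.5,
            "latency mean must lie in (0.5, 3.5) ms", "rc_parameter_error")
  rc_assert(background_rate >= 0, "background rate must be >= 0", "rc_parameter_error")
  structure(list(efficacy_base = efficacy_base, facilitation = facilitation,
                 facilitation_isi_ms = facilitation_isi_ms,
                 latency_mean_ms = latency_mean_ms, latency_sd_ms = latency_sd_ms,
                 background_rate = background_rate),
            class = "synapse_params")
}

# remove spikes closer than `refractory_s` to the previous retained spike
refractory_filter <- function(times, refractory_s) {
  if (length(times) < 2 || refractory_s <= 0) return(times)
  keep <- logical(length(times)); last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory_s) { keep[i] <- TRUE; last <- times[i] }
  }
  times[keep]
}

# piecewise-constant inhomogeneous Poisson sampler on a grid.
# rate: vector of rates (spikes/s) per grid cell of width dt starting at t0.
sim_inhom_poisson <- function(rate, dt, t0 = 0) {
  lam <- rate * dt
  n <- stats::rpois(length(lam), lam)
  tot <- sum(n)
  if (tot == 0) return(numeric(0))
  cell <- rep(seq_along(lam), n)
  sort(t0 + (cell - 1) * dt + stats::runif(tot) * dt)
}

#' Simulate a retinal ganglion cell spike train
#'
#' (Inhomogeneous) Poisson process thinned by an absolute refractory period.
#' With a constant rate the retained process is a renewal process with rate
#' `rate / (1 + rate * refractory)`.
#'
#' @param rate mean driving rate, spikes/s.
#' @param duration_s train duration, s.
#' @param refractory_ms absolute refractory period, ms (default 1.5).
#' @param rate_signal optional time-varying gain: list with `t` (s) and
#'   `gain` (dimensionless multiplier), linearly interpolated.
#' @param seed RNG seed.
#' @param t_start start of the recording span (default 0).
#' @return A [spike_train()].
#' @export
simulate_rgc_train <- function(rate, duration_s, refractory_ms = 1.5,
                               rate_signal = NULL, seed = NULL, t_start = 0) {
  rc_assert(rate >= 0, "rate must be >= 0", "rc_parameter_error")
  with_seed(seed, {
    if (rate == 0) {
      return(spike_train("rgc", numeric(0), t_start, t_start + duration_s))
    }
    if (is.null(rate_signal)) {
      n <- stats::rpois(1, rate * duration_s)
      t <- sort(stats::runif(n, t_start, t_start + duration_s))
    } else {
      dt <- 0.005
      grid <- seq(t_start, t_start + duration_s - dt / 2, by = dt)
      g <- stats::approx(rate_signal$t, rate_signal$gain, xout = grid + dt / 2,
                         rule = 2)$y
      t <- sim_inhom_poisson(pmax(rate * g, 0), dt, t_start)
    }
    t <- refractory_filter(t, ms(refractory_ms))
    spike_train("rgc", t, t_start, t_start + duration_s)
  })
}

# draw triggered postsynaptic spikes for a presynaptic spike vector under
# the hard-ISI facilitation gate; returns times + parent indices
trigger_spikes <- function(pre_times, params) {
  n <- length(pre_times)
  if (n == 0) return(list(times = numeric(0), parent = integer(0)))
  prev_isi <- c(Inf, diff(pre_times))
  p <- ifelse(prev_isi <= ms(params$facilitation_isi_ms),
              pmin(1, params$efficacy_base * params$facilitation),
              params$efficacy_base)
  hit <- stats::runif(n) < p
  k <- sum(hit)
  lat <- rtruncnorm(k, ms(params$latency_mean_ms), ms(params$latency_sd_ms),
                    ms(0.5), ms(3.5))
  list(times = pre_times[hit] + lat, parent = which(hit))
}

# merge triggered and background postsynaptic spikes. Background spikes
# within the refractory period of any triggered spike are dropped (a real
# neuron cannot fire twice within its refractory period, and the triggered
# spike carries the planted efficacy), and the surviving background is
# refractory-filtered against itself. Triggered spikes are never removed.
merge_sc_spikes <- function(trig_times, trig_parent, bg_times,
                            refractory_s = 1.5e-3) {
  if (length(bg_times) && length(trig_times)) {
    st <- sort(trig_times)
    i <- findInterval(bg_times, st)
    d_lo <- ifelse(i >= 1, bg_times - st[pmax(i, 1)], Inf)
    d_hi <- ifelse(i < length(st), st[pmin(i + 1, length(st))] - bg_times, Inf)
    bg_times <- bg_times[pmin(d_lo, d_hi) >= refractory_s]
  }
  bg_times <- refractory_filter(bg_times, refractory_s)
  times <- c(trig_times, bg_times)
  parent <- c(trig_parent, rep(NA_integer_, length(bg_times)))
  o <- order(times)
  list(times = times[o], parent = parent[o])
}

#' Simulate a postsynaptic train coupled to a given presynaptic train
#'
#' Each presynaptic spike independently triggers one postsynaptic spike with
#' probability `efficacy_base` (or `min(1, efficacy_base * facilitation)`
#' when its preceding inter-spike interval is at most the facilitation gate),
#' after a transmission latency drawn from a normal distribution truncated to
#' (0.5, 3.5) ms. Independent Poisson background spikes are merged in; every
#' postsynaptic spike carries a parent label (presynaptic spike index, or
#' `NA` for background).
#'
#' @param rgc presynaptic [spike_train()].
#' @param params a [synapse_params()].
#' @param seed RNG seed.
#' @return list: `sc` ([spike_train()]), `truth` (list with `params`,
#'   `parent` aligned to `sc$times`, and `n_pre`).
#' @export
simulate_connected_pair <- function(rgc, params, seed = NULL) {
  with_seed(seed, {
    trig <- trigger_spikes(rgc$times, params)
    keep <- trig$times <= rgc$t_stop
    trig$times <- trig$times[keep]; trig$parent <- trig$parent[keep]
    dur <- rgc$t_stop - rgc$t_start
    nbg <- stats::rpois(1, params$background_rate * dur)
    bg <- sort(stats::runif(nbg, rgc$t_start, rgc$t_stop))
    m <- merge_sc_spikes(trig$times, trig$parent, bg)
    list(sc = spike_train("sc", m$times, rgc$t_start, rgc$t_stop),
         truth = list(params = params, parent = m$parent,
                      n_pre = length(rgc$times)))
  })
}

# stationary Ornstein-Uhlenbeck sample on a grid (unit variance)
ou_signal <- function(n, dt, tau) {
  a <- exp(-dt / tau)
  x <- numeric(n)
  x[1] <- stats::rnorm(1)
  innov <- stats::rnorm(n - 1, sd = sqrt(1 - a^2))
  for (i in seq_len(n - 1)) x[i + 1] <- a * x[i] + innov[i]
  x
}

#' Simulate a comodulated but unconnected pair of spike trains
#'
#' Two conditionally independent Poisson trains sharing a smoothed common
#' log-rate signal: their raw cross-correlogram shows a broad (much wider
#' than 10 ms) elevation with no millisecond peak — the confound the
#' interval-jitter correction is designed to remove.
#'
#' @param rate_a,rate_b mean rates, spikes/s.
#' @param timescale_ms correlation timescale of the shared signal, ms.
#' @param gain log-rate modulation depth (0 = independent).
#' @param duration_s duration, s.
#' @param seed RNG seed.
#' @return list of two [spike_train()]s `a`, `b`.
#' @export
simulate_comodulated_pair <- function(rate_a, rate_b, timescale_ms = 200,
                                      gain = 1, duration_s = 600, seed = NULL) {
  rc_assert(gain >= 0, "gain must be >= 0", "rc_parameter_error")
  with_seed(seed, {
    dt <- 0.005
    n <- ceiling(duration_s / dt)
    mult <- if (gain > 0) exp(gain * ou_signal(n, dt, ms(timescale_ms)) - gain^2 / 2)
            else rep(1, n)
    a <- sim_inhom_poisson(rate_a * mult, dt)
    b <- sim_inhom_poisson(rate_b * mult, dt)
    list(a = spike_train("a", a, 0, duration_s),
         b = spike_train("b", b, 0, duration_s))
  })
}
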