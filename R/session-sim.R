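#' Configuration of a synthetic recording session
#'
#' Defaults mirror the recording protocol the pipeline targets: optotagging
#' with 100 ms pulses at 2 Hz under a black screen and 1000 ms pulses over a
#' checkerboard (30 LED-on / 30 LED-off trials); sparse-noise receptive-field
#' mapping on a 24 x 14 grid with 100 ms frames, 2 targets per frame and 20
#' trials per position and polarity; and repeated 10 s movie stimuli (30
#' trials each). Firing-rate ranges are typical of retinal axons (high rates)
#' and collicular neurons (inhibitory above excitatory).
#'
#' @param seed RNG seed (mandatory).
#' @param n_rgc,n_exn,n_in unit counts per class.
#' @param rgc_rate_range,exn_rate_range,in_rate_range baseline-rate ranges,
#'   spikes/s.
#' @param connectivity `NULL` for the default wiring (RGC `i` onto SC `i`,
#'   alternating excitatory/inhibitory targets, efficacies drawn from
#'   `efficacy_range`, facilitation 1.7 onto excitatory and 1.3 onto
#'   inhibitory targets), or a data frame with columns `pre`, `post`
#'   (unit indices within class vectors are not used - give unit ids),
#'   `efficacy_base`, `facilitation`, `latency_mean_ms`, `latency_sd_ms`.
#' @param efficacy_range range for drawn efficacies under default wiring.
#' @param comod_gain,comod_timescale_ms shared slow log-rate comodulation
#'   applied to every unit (the connectivity confound).
#' @param n_pulses,pulse_rate_hz,pulse_duration_s spontaneous optotagging
#'   protocol.
#' @param in_gain,in_onset_latency_ms firing-rate gain of inhibitory units
#'   during light pulses and its onset latency.
#' @param chk_led_trials,chk_led_pulse_s,chk_led_trial_s checkerboard
#'   optotagging protocol (`chk_led_trials` LED-on and as many LED-off
#'   trials).
#' @param checkerboard_trials,checkerboard_trial_s plain checkerboard
#'   repeats used for response correlations.
#' @param sparse_grid,frame_s,targets_per_frame,trials_per_position
#'   sparse-noise protocol.
#' @param movie_trials,movie_trial_s repeated movie protocol (applies to the
#'   movie and its phase-scrambled surrogate).
#' @param rf_sd_cells,rf_gain,rf_lag_ms,movie_gain,post_rf_offset planted
#'   receptive-field model: Gaussian spatial RF (SD in grid cells),
#'   log-linear stimulus drive with an 80 ms response lag; postsynaptic RFs
#'   sit within `post_rf_offset` cells of their presynaptic RGC's RF.
#' @param n_led_rgc number of RGC axons planted with a light-artifact
#'   response (to exercise the exclusion rule).
#' @param baseline_s extra spontaneous (stimulus-free) recording time, s
#'   (default 0).
#' @param channel_count probe channels.
#' @param with_optotagging,with_checkerboard,with_sparse_noise,with_movies
#'   include the corresponding protocol segments.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_rgc = 6, n_exn = 8, n_in = 4,
                       rgc_rate_range = c(8, 25),
                       exn_rate_range = c(2, 8),
                       in_rate_range = c(4, 12),
                       connectivity = NULL,
                       efficacy_range = c(0.1, 0.3),
                       comod_gain = 0.3, comod_timescale_ms = 200,
                       n_pulses = 400, pulse_rate_hz = 2, pulse_duration_s = 0.1,
                       in_gain = 3, in_onset_latency_ms = 5,
                       chk_led_trials = 30, chk_led_pulse_s = 1, chk_led_trial_s = 2,
                       checkerboard_trials = 30, checkerboard_trial_s = 2,
                       sparse_grid = c(24, 14), frame_s = 0.1,
                       targets_per_frame = 2, trials_per_position = 20,
                       movie_trials = 30, movie_trial_s = 10,
                       rf_sd_cells = 1.5, rf_gain = 1.2, rf_lag_ms = 80,
                       movie_gain = 0.8, post_rf_offset = 1,
                       n_led_rgc = 0,
                       baseline_s = 0,
                       channel_count = 64,
                       with_optotagging = TRUE, with_checkerboard = TRUE,
                       with_sparse_noise = TRUE, with_movies = TRUE) {
  if (missing(seed)) rc_stop("sim_config requires a seed", "rc_parameter_error")
  cfg <- as.list(environment())
  rc_assert(all(c(rgc_rate_range, exn_rate_range, in_rate_range) >= 0),
            "rates must be >= 0", "rc_parameter_error")
  structure(cfg, class = "sim_config")
}

# scatter-add `val[k]` over `ncell` grid cells starting at index i0[k];
# intervals are assumed non-overlapping
add_cells <- function(vec, i0, ncell, val) {
  idx <- as.vector(outer(0:(ncell - 1), i0, "+"))
  v <- rep(val, each = ncell)
  ok <- idx >= 1 & idx <= length(vec)
  vec[idx[ok]] <- vec[idx[ok]] + v[ok]
  vec
}

# gaussian RF weight of grid positions (x, y) for center (cx, cy)
rf_weight <- function(x, y, cx, cy, sdv) {
  exp(-((x - cx)^2 + (y - cy)^2) / (2 * sdv^2))
}

#' Simulate a full synthetic session with ground truth
#'
#' Composes every statistical structure the pipeline assumes: refractory
#' high-rate retinal trains driven by planted Gaussian receptive fields
#' through a log-linear rate model with an 80 ms response lag; collicular
#' trains made of stimulus-driven background spikes plus synaptically
#' triggered spikes with planted efficacy, truncated (0.5, 3.5) ms latency
#' and hard-gate facilitation; shared slow rate comodulation across all
#' units; pulse-locked rate increases in inhibitory units during optotagging
#' (with onset latency); axonal templates for retinal axons and somatic
#' templates for collicular units; and populated pulse / stimulus-event /
#' exclusion tables. Everything planted is returned as ground truth.
#'
#' @param config a [sim_config()].
#' @return list: `session` ([session()]), `truth` (list with `units`,
#'   `pairs`, `parents` per postsynaptic unit, `light_range_channels`).
#' @export
simulate_session <- function(config) {
  cfg <- config
  with_seed(cfg$seed, {
    dt <- 0.005
    gap <- 1
    cursor <- 0
    segs <- list()
    seg_add <- function(name, dur) {
      s <- list(name = name, start = cursor, stop = cursor + dur)
      segs[[name]] <<- s
      cursor <<- cursor + dur + gap
      s
    }
    pulses <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                         protocol = character(0))
    ev <- list()
    if (cfg$baseline_s > 0) seg_add("baseline", cfg$baseline_s)
    if (cfg$with_optotagging) {
      s <- seg_add("opto_spont", cfg$n_pulses / cfg$pulse_rate_hz)
      on <- s$start + (seq_len(cfg$n_pulses) - 1) / cfg$pulse_rate_hz + 0.1
      pulses <- rbind(pulses, data.frame(onset_s = on,
                                         duration_s = cfg$pulse_duration_s,
                                         protocol = "spontaneous_100ms"))
      s <- seg_add("opto_chk", 2 * cfg$chk_led_trials * cfg$chk_led_trial_s)
      tr_on <- s$start + (seq_len(2 * cfg$chk_led_trials) - 1) * cfg$chk_led_trial_s
      led <- rep(c(TRUE, FALSE), cfg$chk_led_trials)
      pulses <- rbind(pulses, data.frame(onset_s = tr_on[led] + 0.2,
                                         duration_s = cfg$chk_led_pulse_s,
                                         protocol = "checkerboard_1000ms"))
      ev$chk_led <- data.frame(
        stimulus = "checkerboard_led", event_type = "trial_onset",
        time_s = tr_on,
        payload = vapply(seq_along(tr_on), function(i)
          jsonlite::toJSON(list(trial = i, led = led[i]), auto_unbox = TRUE), ""))
    }
    if (cfg$with_checkerboard) {
      s <- seg_add("checkerboard", cfg$checkerboard_trials * cfg$checkerboard_trial_s)
      tr_on <- s$start + (seq_len(cfg$checkerboard_trials) - 1) * cfg$checkerboard_trial_s
      ev$chk <- data.frame(stimulus = "checkerboard", event_type = "trial_onset",
                           time_s = tr_on,
                           payload = sprintf("{\"trial\":%d}", seq_along(tr_on)))
    }
    gx <- cfg$sparse_grid[1]; gy <- cfg$sparse_grid[2]
    frames <- NULL
    if (cfg$with_sparse_noise) {
      n_pos <- gx * gy
      reps <- n_pos * cfg$trials_per_position
      mk_frames <- function(pol) {
        pos <- sample(rep(seq_len(n_pos), cfg$trials_per_position))
        k <- cfg$targets_per_frame
        nf <- floor(reps / k)
        m <- matrix(pos[seq_len(nf * k)], nrow = k)
        data.frame(polarity = pol, x1 = (m[1, ] - 1) %% gx + 1,
                   y1 = (m[1, ] - 1) %/% gx + 1,
                   x2 = (m[2, ] - 1) %% gx + 1, y2 = (m[2, ] - 1) %/% gx + 1)
      }
      frames <- rbind(mk_frames("light"), mk_frames("dark"))
      frames <- frames[sample(nrow(frames)), ]
      s <- seg_add("sparse_noise", nrow(frames) * cfg$frame_s)
      frames$onset <- s$start + (seq_len(nrow(frames)) - 1) * cfg$frame_s
      ev$sn <- data.frame(
        stimulus = "sparse_noise", event_type = "frame_target",
        time_s = rep(frames$onset, each = 2),
        payload = as.vector(rbind(
          sprintf("{\"x\":%d,\"y\":%d,\"polarity\":\"%s\"}",
                  frames$x1, frames$y1, frames$polarity),
          sprintf("{\"x\":%d,\"y\":%d,\"polarity\":\"%s\"}",
                  frames$x2, frames$y2, frames$polarity))))
    }
    movie_onsets <- list()
    if (cfg$with_movies) {
      for (nm in c("natural_movie", "scrambled_movie")) {
        s <- seg_add(nm, cfg$movie_trials * cfg$movie_trial_s)
        tr_on <- s$start + (seq_len(cfg$movie_trials) - 1) * cfg$movie_trial_s
        movie_onsets[[nm]] <- tr_on
        ev[[nm]] <- data.frame(stimulus = nm, event_type = "trial_onset",
                               time_s = tr_on,
                               payload = sprintf("{\"trial\":%d}", seq_along(tr_on)))
      }
    }
    t_stop <- cursor
    rc_assert(t_stop > 0, "config defines no recording segments",
              "rc_parameter_error")
    nT <- ceiling(t_stop / dt)
    grid_t <- (seq_len(nT) - 1) * dt

    # shared slow comodulation (connectivity confound)
    comod <- if (cfg$comod_gain > 0)
      exp(cfg$comod_gain * ou_signal(nT, dt, ms(cfg$comod_timescale_ms)) -
            cfg$comod_gain^2 / 2)
    else rep(1, nT)

    # stimulus movies on the sparse-noise grid, 10 Hz frames
    npix <- gx * gy
    frame_dt <- 0.1
    mk_movie <- function(nframes) {
      m <- matrix(0, npix, nframes)
      for (p in seq_len(npix)) m[p, ] <- ou_signal(nframes, frame_dt, 0.2)
      m
    }
    movies <- list()
    if (cfg$with_movies) {
      nf <- round(cfg$movie_trial_s / frame_dt)
      movies$natural_movie <- mk_movie(nf)
      movies$scrambled_movie <- mk_movie(nf)
    }
    chk_movie <- NULL
    if (cfg$with_checkerboard || cfg$with_optotagging) {
      nf <- round(max(cfg$checkerboard_trial_s, cfg$chk_led_trial_s) / frame_dt)
      chk_movie <- matrix(sample(c(-1, 1), npix * nf, replace = TRUE), npix, nf)
    }

    # unit metadata and planted truth
    n_sc <- cfg$n_exn + cfg$n_in
    ids <- c(sprintf("rgc%02d", seq_len(cfg$n_rgc)),
             sprintf("exn%02d", seq_len(cfg$n_exn)),
             sprintf("in%02d", seq_len(cfg$n_in)))
    cls <- c(rep("RGC", cfg$n_rgc), rep("SC_EXN", cfg$n_exn), rep("SC_IN", cfg$n_in))
    runif_range <- function(n, r) stats::runif(n, r[1], r[2])
    base_rate <- c(runif_range(cfg$n_rgc, cfg$rgc_rate_range),
                   runif_range(cfg$n_exn, cfg$exn_rate_range),
                   runif_range(cfg$n_in, cfg$in_rate_range))
    chan <- sample(8:(cfg$channel_count - 9), length(ids), replace = TRUE)
    light_factor <- ifelse(cls == "SC_IN", cfg$in_gain, 1)
    if (cfg$n_led_rgc > 0)
      light_factor[seq_len(min(cfg$n_led_rgc, cfg$n_rgc))] <- 2
    rf_x <- stats::runif(length(ids), 3, gx - 2)
    rf_y <- stats::runif(length(ids), 2, gy - 1)
    rf_pol <- sample(c(-1, 1), length(ids), replace = TRUE)

    # wiring
    if (is.null(cfg$connectivity)) {
      sc_ids <- ids[cls != "RGC"]
      # alternate excitatory / inhibitory targets so both classes are wired
      sc_alt <- c(rbind(ids[cls == "SC_EXN"][seq_len(min(cfg$n_exn, cfg$n_in))],
                        ids[cls == "SC_IN"][seq_len(min(cfg$n_exn, cfg$n_in))]))
      sc_alt <- c(sc_alt, setdiff(sc_ids, sc_alt))
      k <- min(cfg$n_rgc, n_sc)
      pairs <- data.frame(pre = ids[cls == "RGC"][seq_len(k)],
                          post = sc_alt[seq_len(k)],
                          efficacy_base = runif_range(k, cfg$efficacy_range))
      pairs$facilitation <- ifelse(grepl("^in", pairs$post), 1.3, 1.7)
      pairs$latency_mean_ms <- stats::runif(k, 1.2, 2.2)
      pairs$latency_sd_ms <- 0.3
    } else if (is.null(cfg$connectivity) || nrow(cfg$connectivity) == 0) {
      pairs <- data.frame(pre = character(0), post = character(0),
                          efficacy_base = numeric(0), facilitation = numeric(0),
                          latency_mean_ms = numeric(0),
                          latency_sd_ms = numeric(0))
    } else {
      pairs <- cfg$connectivity
      if (is.null(pairs$latency_mean_ms)) pairs$latency_mean_ms <- 1.5
      if (is.null(pairs$latency_sd_ms)) pairs$latency_sd_ms <- 0.3
      if (is.null(pairs$facilitation)) pairs$facilitation <- 1
    }
    # postsynaptic units sit close to their presynaptic axon, in space and RF
    for (i in seq_len(nrow(pairs))) {
      ip <- match(pairs$pre[i], ids); is_ <- match(pairs$post[i], ids)
      chan[is_] <- pmin(pmax(chan[ip] + sample(-3:3, 1), 0), cfg$channel_count - 1)
      rf_x[is_] <- pmin(pmax(rf_x[ip] + stats::rnorm(1, 0, cfg$post_rf_offset), 1), gx)
      rf_y[is_] <- pmin(pmax(rf_y[ip] + stats::rnorm(1, 0, cfg$post_rf_offset), 1), gy)
      rf_pol[is_] <- rf_pol[ip]
    }

    px <- (seq_len(npix) - 1) %% gx + 1
    py <- (seq_len(npix) - 1) %/% gx + 1
    lag <- ms(cfg$rf_lag_ms)

    # per-unit drive -> rate -> spikes
    trains <- list(); parents <- list()
    for (i in seq_along(ids)) {
      drive <- numeric(nT)
      rf_map <- rf_weight(px, py, rf_x[i], rf_y[i], cfg$rf_sd_cells)
      rf_unit <- rf_map / sqrt(sum(rf_map^2))
      if (cfg$with_sparse_noise) {
        s_f <- ifelse(frames$polarity == "light", 1, -1)
        val <- cfg$rf_gain * s_f * rf_pol[i] *
          (rf_weight(frames$x1, frames$y1, rf_x[i], rf_y[i], cfg$rf_sd_cells) +
             rf_weight(frames$x2, frames$y2, rf_x[i], rf_y[i], cfg$rf_sd_cells))
        i0 <- floor((frames$onset + lag) / dt) + 1
        drive <- add_cells(drive, i0, round(cfg$frame_s / dt), val)
      }
      if (cfg$with_movies) {
        for (nm in names(movies)) {
          dframe <- cfg$movie_gain * rf_pol[i] *
            as.vector(crossprod(rf_unit, movies[[nm]]))
          on <- movie_onsets[[nm]]
          i0 <- floor((rep(on, each = length(dframe)) +
                         (seq_along(dframe) - 1) * frame_dt + lag) / dt) + 1
          drive <- add_cells(drive, i0, round(frame_dt / dt),
                             rep(dframe, length(on)))
        }
      }
      chk_drive <- function(onsets, trial_s) {
        nf <- round(trial_s / frame_dt)
        dframe <- cfg$movie_gain * rf_pol[i] *
          as.vector(crossprod(rf_unit, chk_movie[, seq_len(nf), drop = FALSE]))
        i0 <- floor((rep(onsets, each = nf) +
                       (seq_len(nf) - 1) * frame_dt + lag) / dt) + 1
        add_cells(drive, i0, round(frame_dt / dt), rep(dframe, length(onsets)))
      }
      if (cfg$with_checkerboard)
        drive <- chk_drive(ev$chk$time_s, cfg$checkerboard_trial_s)
      if (cfg$with_optotagging && !is.null(ev$chk_led))
        drive <- chk_drive(ev$chk_led$time_s, cfg$chk_led_trial_s)
      light_mult <- rep(1, nT)
      if (cfg$with_optotagging && light_factor[i] != 1 && nrow(pulses) > 0) {
        onl <- pulses$onset_s + ms(cfg$in_onset_latency_ms)
        for (p in seq_along(onl)) {
          i0 <- floor(onl[p] / dt) + 1
          i1 <- min(nT, floor((onl[p] + pulses$duration_s[p]) / dt))
          if (i1 >= i0) light_mult[i0:i1] <- light_factor[i]
        }
      }
      rate <- pmin(base_rate[i] * comod * exp(pmin(drive, 3)) * light_mult, 500)
      if (cls[i] == "RGC") {
        t <- refractory_filter(sim_inhom_poisson(rate, dt), ms(1.5))
        trains[[ids[i]]] <- spike_train(ids[i], t[t < t_stop], 0, t_stop)
      } else {
        bg <- sim_inhom_poisson(rate, dt)
        j <- which(pairs$post == ids[i])
        if (length(j) == 1 && !is.null(trains[[pairs$pre[j]]])) {
          sp <- synapse_params(pairs$efficacy_base[j], pairs$facilitation[j],
                               latency_mean_ms = pairs$latency_mean_ms[j],
                               latency_sd_ms = pairs$latency_sd_ms[j],
                               background_rate = 0)
          trig <- trigger_spikes(trains[[pairs$pre[j]]]$times, sp)
          keep <- trig$times < t_stop
          m <- merge_sc_spikes(trig$times[keep], trig$parent[keep], bg[bg < t_stop])
          trains[[ids[i]]] <- spike_train(ids[i], m$times, 0, t_stop)
          parents[[ids[i]]] <- m$parent
        } else {
          bg <- refractory_filter(bg, ms(1.5))
          trains[[ids[i]]] <- spike_train(ids[i], bg[bg < t_stop], 0, t_stop)
        }
      }
    }

    # waveform templates: axonal for retinal axons, somatic for SC units
    waveforms <- list()
    for (i in seq_along(ids)) {
      wf <- generate_waveform_template(
        if (cls[i] == "RGC") "axonal" else "somatic",
        n_channels = cfg$channel_count, seed = NULL, peak_channel = chan[i])
      waveforms[[ids[i]]] <- wf$waveform
    }

    mean_rate_movie <- rep(NA_real_, length(ids))
    if (cfg$with_movies) {
      s <- segs$natural_movie
      mean_rate_movie <- vapply(trains, function(tr)
        sum(tr$times >= s$start & tr$times < s$stop) / (s$stop - s$start), 0)
    }

    excl <- if (cfg$with_optotagging)
      epoch_set(c(segs$opto_spont$start, segs$opto_chk$start),
                c(segs$opto_spont$stop, segs$opto_chk$stop))
    else epoch_set()

    units <- data.frame(unit_id = ids, peak_channel = chan, label = cls,
                        mean_rate_movie = mean_rate_movie)
    stim_events <- do.call(rbind, ev)
    if (is.null(stim_events))
      stim_events <- data.frame(stimulus = character(0), event_type = character(0),
                                time_s = numeric(0), payload = character(0))
    rownames(stim_events) <- NULL
    stim_events <- stim_events[order(stim_events$time_s), ]
    ses <- session(trains = trains, units = units, waveforms = waveforms,
                   waveform_fs = 30000, pulses = pulses,
                   stim_events = stim_events, exclusions = excl,
                   channel_count = cfg$channel_count, t_start = 0, t_stop = t_stop)
    in_chan <- chan[cls == "SC_IN"]
    truth <- list(
      units = data.frame(unit_id = ids, true_class = cls, base_rate = base_rate,
                         peak_channel = chan, rf_x = rf_x, rf_y = rf_y,
                         rf_sd = cfg$rf_sd_cells, rf_polarity = rf_pol,
                         rf_gain = cfg$rf_gain, light_factor = light_factor),
      pairs = pairs,
      parents = parents,
      light_range_channels = if (length(in_chan)) range(in_chan) else c(NA, NA))
    list(session = ses, truth = truth)
  })
}

#' Write ground truth of a synthetic session as JSON
#' @param truth the `truth` element returned by [simulate_session()].
#' @param path session directory (writes `ground_truth.json`).
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, file.path(path, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read ground truth written by [write_ground_truth()]
#' @param path session directory.
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(file.path(path, "ground_truth.json"),
                            simplifyVector = TRUE)
  gt$parents <- lapply(gt$parents, function(p) {
    p <- as.integer(p); p
  })
  gt
}
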