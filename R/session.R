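#' Recording-session container
#'
#' Holds everything one analysis run needs: spike trains, unit metadata
#' (peak channel, multi-channel waveform template, class label), the
#' optogenetic pulse table, stimulus event tables, and exclusion epochs.
#'
#' @param trains named list of [spike_train()] (names = unit ids).
#' @param units data frame with columns `unit_id`, `peak_channel` (0-based),
#'   `label` (one of RGC, SC_EXN, SC_IN, UNCLASSIFIED, EXCLUDED) and
#'   optionally `mean_rate_movie`.
#' @param waveforms named list of channel x sample matrices (may be empty).
#' @param waveform_fs waveform sample rate, samples/s.
#' @param pulses data frame `onset_s`, `duration_s`, `protocol`.
#' @param stim_events data frame `stimulus`, `event_type`, `time_s`,
#'   `payload` (JSON string per row).
#' @param exclusions an [epoch_set()].
#' @param channel_count number of probe channels.
#' @param t_start,t_stop recording span (seconds).
#' @return An object of class `sc_session`.
#' @export
session <- function(trains, units, waveforms = list(), waveform_fs = 30000,
                    pulses = NULL, stim_events = NULL, exclusions = epoch_set(),
                    channel_count = 384, t_start = 0, t_stop = NULL) {
  labels_ok <- c("RGC", "SC_EXN", "SC_IN", "UNCLASSIFIED", "EXCLUDED")
  if (is.null(pulses))
    pulses <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                         protocol = character(0))
  if (is.null(stim_events))
    stim_events <- data.frame(stimulus = character(0), event_type = character(0),
                              time_s = numeric(0), payload = character(0))
  rc_assert(all(c("unit_id", "peak_channel", "label") %in% names(units)),
            "units table must have unit_id, peak_channel, label")
  if (is.null(units$mean_rate_movie)) units$mean_rate_movie <- NA_real_
  rc_assert(all(units$label %in% labels_ok),
            sprintf("unit labels must be one of %s", paste(labels_ok, collapse = ", ")))
  rc_assert(all(units$peak_channel >= 0 & units$peak_channel < channel_count),
            "peak_channel outside probe channel count")
  rc_assert(all(names(trains) %in% units$unit_id) &&
              all(vapply(trains, function(tr) tr$unit_id, "") == names(trains)),
            "every train must have a matching unit metadata row")
  if (is.null(t_stop)) {
    t_stop <- max(c(vapply(trains, function(tr) tr$t_stop, 0), t_start + 1))
  }
  rc_assert(nrow(pulses) == 0 ||
              all(pulses$onset_s >= t_start & pulses$onset_s + pulses$duration_s <= t_stop),
            "pulse times outside recording span")
  rc_assert(nrow(stim_events) == 0 ||
              all(stim_events$time_s >= t_start & stim_events$time_s <= t_stop),
            "stimulus event times outside recording span")
  structure(list(trains = trains, units = units, waveforms = waveforms,
                 waveform_fs = waveform_fs, pulses = pulses,
                 stim_events = stim_events, exclusions = exclusions,
                 channel_count = as.integer(channel_count),
                 t_start = as.double(t_start), t_stop = as.double(t_stop)),
            class = "sc_session")
}

#' @export
print.sc_session <- function(x, ...) {
  tab <- table(factor(x$units$label,
                      c("RGC", "SC_EXN", "SC_IN", "UNCLASSIFIED", "EXCLUDED")))
  cat(sprintf("<sc_session> %d units on [%.1f, %.1f] s; %s; %d pulses, %d stimulus events\n",
              length(x$trains), x$t_start, x$t_stop,
              paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
              nrow(x$pulses), nrow(x$stim_events)))
  invisible(x)
}

#' Unit ids carrying a given label
#' @param session an [session()].
#' @param label label or vector of labels.
#' @export
units_with_label <- function(session, label) {
  session$units$unit_id[session$units$label %in% label]
}

fmt_time <- function(x) sprintf("%.9f", x)

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
}

#' Write a session directory
#'
#' Lays a session out as `manifest.json` plus RFC-4180 CSV tables
#' (`spikes.csv`, `pulses.csv`, `stim_events.csv`, `exclusions.csv`) and
#' per-unit waveform matrices under `waveforms/` with a `waveforms.json`
#' sidecar giving the sample rate. Times are written with 9 decimal digits,
#' so a write/read round trip preserves them to 1 ns.
#'
#' @param session an [session()].
#' @param path directory to create/overwrite.
#' @export
write_session <- function(session, path) {
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE)
  if (!ok) rc_stop(sprintf("cannot create session directory %s", path), "rc_io_error")
  u <- session$units
  manifest <- list(
    format = "retinoconn-session/1",
    channel_count = session$channel_count,
    t_start = session$t_start, t_stop = session$t_stop,
    units = lapply(seq_len(nrow(u)), function(i) list(
      unit_id = u$unit_id[i], peak_channel = as.integer(u$peak_channel[i]),
      label = u$label[i],
      mean_rate_movie = if (is.na(u$mean_rate_movie[i])) NULL else u$mean_rate_movie[i]
    )),
    files = list(spikes = "spikes.csv", pulses = "pulses.csv",
                 stim_events = "stim_events.csv", exclusions = "exclusions.csv",
                 waveforms = "waveforms")
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  spk <- do.call(rbind, lapply(session$trains, function(tr)
    if (length(tr$times)) data.frame(unit_id = tr$unit_id, time_s = fmt_time(tr$times)) else NULL))
  if (is.null(spk)) spk <- data.frame(unit_id = character(0), time_s = character(0))
  write_csv_plain(spk, file.path(path, "spikes.csv"))
  write_csv_plain(data.frame(onset_s = fmt_time(session$pulses$onset_s),
                             duration_s = fmt_time(session$pulses$duration_s),
                             protocol = session$pulses$protocol),
                  file.path(path, "pulses.csv"))
  write_csv_plain(data.frame(stimulus = session$stim_events$stimulus,
                             event_type = session$stim_events$event_type,
                             time_s = fmt_time(session$stim_events$time_s),
                             payload = session$stim_events$payload),
                  file.path(path, "stim_events.csv"))
  write_csv_plain(data.frame(start_s = fmt_time(session$exclusions$start),
                             stop_s = fmt_time(session$exclusions$stop)),
                  file.path(path, "exclusions.csv"))
  wfdir <- file.path(path, "waveforms")
  if (!dir.exists(wfdir)) dir.create(wfdir)
  for (id in names(session$waveforms)) {
    utils::write.table(format(session$waveforms[[id]], digits = 9, trim = TRUE,
                              scientific = FALSE),
                       file.path(wfdir, paste0(id, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(list(sample_rate = session$waveform_fs,
                            channel_offset = 0,
                            units = as.list(names(session$waveforms))),
                       file.path(wfdir, "waveforms.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_csv_checked <- function(path, required, file_label) {
  if (!file.exists(path))
    rc_stop(sprintf("missing session file: %s", path), "rc_format_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing))
    rc_stop(sprintf("%s: missing columns %s", file_label,
                    paste(missing, collapse = ", ")), "rc_format_error")
  bad <- which(!stats::complete.cases(df[required]))
  if (length(bad))
    rc_stop(sprintf("%s: malformed row(s) at data line %s", file_label,
                    paste(utils::head(bad, 5), collapse = ", ")), "rc_format_error")
  df
}

#' Read a session directory
#'
#' Inverse of [write_session()]; validates the manifest, all tables and the
#' per-unit spike ordering, reporting the offending file (and row) on error.
#'
#' @param path session directory containing `manifest.json`.
#' @return An [session()].
#' @export
read_session <- function(path) {
  mpath <- file.path(path, "manifest.json")
  if (!file.exists(mpath))
    rc_stop(sprintf("no manifest.json in %s", path), "rc_format_error")
  m <- jsonlite::read_json(mpath)
  if (!identical(m$format, "retinoconn-session/1"))
    rc_stop("unrecognized session format tag in manifest.json", "rc_format_error")
  units <- do.call(rbind, lapply(m$units, function(x) data.frame(
    unit_id = x$unit_id, peak_channel = as.integer(x$peak_channel),
    label = x$label,
    mean_rate_movie = if (length(x$mean_rate_movie) != 1 ||
                            is.na(x$mean_rate_movie)) NA_real_
                      else as.double(x$mean_rate_movie)
  )))
  if (is.null(units))
    units <- data.frame(unit_id = character(0), peak_channel = integer(0),
                        label = character(0), mean_rate_movie = numeric(0))
  spk <- read_csv_checked(file.path(path, m$files$spikes),
                          c("unit_id", "time_s"), "spikes.csv")
  spk$time_s <- as.double(spk$time_s)
  t_start <- as.double(m$t_start); t_stop <- as.double(m$t_stop)
  trains <- lapply(units$unit_id, function(id) {
    tt <- spk$time_s[spk$unit_id == id]
    if (is.unsorted(tt))
      rc_stop(sprintf("spikes.csv: unsorted spike times for unit %s", id),
              "rc_validation_error")
    spike_train(id, tt, t_start, t_stop)
  })
  names(trains) <- units$unit_id
  pls <- read_csv_checked(file.path(path, m$files$pulses),
                          c("onset_s", "duration_s", "protocol"), "pulses.csv")
  pls$onset_s <- as.double(pls$onset_s); pls$duration_s <- as.double(pls$duration_s)
  ste <- read_csv_checked(file.path(path, m$files$stim_events),
                          c("stimulus", "event_type", "time_s", "payload"),
                          "stim_events.csv")
  ste$time_s <- as.double(ste$time_s)
  exc <- read_csv_checked(file.path(path, m$files$exclusions),
                          c("start_s", "stop_s"), "exclusions.csv")
  wfdir <- file.path(path, m$files$waveforms)
  waveforms <- list(); waveform_fs <- 30000
  sidecar <- file.path(wfdir, "waveforms.json")
  if (file.exists(sidecar)) {
    wj <- jsonlite::read_json(sidecar)
    waveform_fs <- as.double(wj$sample_rate)
    for (id in unlist(wj$units)) {
      waveforms[[id]] <- as.matrix(utils::read.csv(
        file.path(wfdir, paste0(id, ".csv")), header = FALSE))
      dimnames(waveforms[[id]]) <- NULL
    }
  }
  session(trains = trains, units = units, waveforms = waveforms,
          waveform_fs = waveform_fs, pulses = pls,
          stim_events = ste[, c("stimulus", "event_type", "time_s", "payload")],
          exclusions = epoch_set(as.double(exc$start_s), as.double(exc$stop_s)),
          channel_count = as.integer(m$channel_count),
          t_start = t_start, t_stop = t_stop)
}

#' Parse sparse-noise target events from a session
#'
#' Expands the JSON payload of `sparse_noise` frame-target rows into columns.
#'
#' @param session an [session()].
#' @return data frame `time_s`, `x`, `y`, `polarity`.
#' @export
sparse_noise_events <- function(session) {
  ev <- session$stim_events
  ev <- ev[ev$stimulus == "sparse_noise" & ev$event_type == "frame_target", ]
  if (!nrow(ev))
    return(data.frame(time_s = numeric(0), x = integer(0), y = integer(0),
                      polarity = character(0)))
  pl <- lapply(ev$payload, jsonlite::fromJSON)
  data.frame(time_s = ev$time_s,
             x = vapply(pl, function(p) as.integer(p$x), 1L),
             y = vapply(pl, function(p) as.integer(p$y), 1L),
             polarity = vapply(pl, function(p) as.character(p$polarity), ""))
}

#' Trial onsets of a repeated stimulus
#' @param session an [session()].
#' @param stimulus stimulus name, e.g. `"natural_movie"`.
#' @export
trial_onsets <- function(session, stimulus) {
  ev <- session$stim_events
  sort(ev$time_s[ev$stimulus == stimulus & ev$event_type == "trial_onset"])
}
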