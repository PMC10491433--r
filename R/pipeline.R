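#' Run the full analysis pipeline on one session
#'
#' Executes quality control, optotagging cell typing, the RGC -> SC
#' connectivity scan, paired-spike dynamics, functional similarity, and the
#' population summaries, writing one CSV per stage plus a JSON summary and a
#' parameter log.
#'
#' @param config either a path to a JSON config file or a list. Recognised
#'   fields: `session_dir` (directory to read) or `simulate` (a list of
#'   [sim_config()] arguments, requires `seed`); `out_dir` (required);
#'   `ccg` / `detection` / `pair_selection` lists overriding the
#'   corresponding parameter defaults; `use_true_labels` (default `TRUE`
#'   when ground truth is available, otherwise labels come from
#'   optotagging + waveform classification); `min_pairs`, `snr_threshold`.
#' @return Invisibly, the summary list; side effect: files under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  rc_assert(!is.null(config$out_dir), "config must name out_dir")
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log_lines <- c(sprintf("retinoconn pipeline %s", format(Sys.time(), "%Y-%m-%d")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      rc_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              "rc_stage_error"))
  }

  truth <- NULL
  ses <- stage("input", {
    if (!is.null(config$simulate)) {
      cfg <- do.call(sim_config, config$simulate)
      log_lines <- c(log_lines, sprintf("simulated session, seed=%s", cfg$seed))
      st <- simulate_session(cfg)
      truth <- st$truth
      st$session
    } else {
      rc_assert(!is.null(config$session_dir), "config must name session_dir or simulate")
      read_session(config$session_dir)
    }
  })
  if (length(ses$trains) == 0) rc_stop("empty session", "rc_validation_error")

  ccg_par <- do.call(ccg_params, config$ccg %||% list())
  det_par <- do.call(detection_params, config$detection %||% list())
  sel_par <- do.call(pair_selection_params, config$pair_selection %||% list())
  min_pairs <- config$min_pairs %||% 50
  snr_thr <- config$snr_threshold %||% 8

  # --- QC ------------------------------------------------------------
  qc <- stage("qc", {
    rows <- lapply(names(ses$trains), function(id) {
      q <- qc_unit(ses$trains[[id]])
      ses$trains[[id]] <<- q$train
      data.frame(unit_id = id, n_spikes = length(q$train$times),
                 isi_violation = q$isi_ratio, qc_pass = q$pass)
    })
    do.call(rbind, rows)
  })
  write_csv_plain(qc, file.path(out, "qc.csv"))

  # --- cell typing ----------------------------------------------------
  typing <- stage("cell_typing", {
    wf_class <- vapply(names(ses$waveforms), function(id)
      classify_axonal_vs_somatic(waveform_features(ses$waveforms[[id]],
                                                   ses$waveform_fs)), "")
    has_pulses <- nrow(ses$pulses[ses$pulses$protocol == "spontaneous_100ms", ]) > 0
    if (has_pulses) {
      sc_ids <- names(wf_class)[wf_class == "SC_SOMA"]
      cl <- classify_session_units(ses, sc_ids)
      cl$waveform_class <- unname(wf_class[cl$unit_id])
      rgc_ids <- names(wf_class)[wf_class == "RGC_AXON"]
      led <- flag_led_responsive_rgc(ses, rgc_ids)
      list(sc = cl, led_responsive = names(led)[led], wf_class = wf_class)
    } else list(sc = NULL, led_responsive = character(0), wf_class = wf_class)
  })
  use_true <- isTRUE(config$use_true_labels %||% !is.null(truth))
  if (!use_true && !is.null(typing$sc)) {
    lab <- stats::setNames(typing$sc$label, typing$sc$unit_id)
    ses$units$label <- ifelse(
      ses$units$unit_id %in% names(typing$wf_class)[typing$wf_class == "RGC_AXON"],
      "RGC", ifelse(ses$units$unit_id %in% names(lab),
                    unname(lab[ses$units$unit_id]), "UNCLASSIFIED"))
  }
  if (!is.null(typing$sc))
    write_csv_plain(typing$sc, file.path(out, "cell_typing.csv"))

  # --- connectivity scan ---------------------------------------------
  pairs <- stage("connectivity", {
    scan_all_pairs(ses, ccg_par, det_par, exclude_pre = typing$led_responsive)
  })
  write_csv_plain(pairs, file.path(out, "connectivity.csv"))
  conn <- pairs[pairs$connected, ]

  # --- paired-spike dynamics ------------------------------------------
  psr_tab <- stage("paired_spike", {
    if (!nrow(conn)) return(NULL)
    rows <- lapply(seq_len(nrow(conn)), function(i) {
      ps <- paired_spike_analysis(ses$trains[[conn$pre_id[i]]],
                                  ses$trains[[conn$post_id[i]]],
                                  sel_par, ccg_par, det_par,
                                  ses$exclusions, min_pairs)
      data.frame(pre_id = conn$pre_id[i], post_id = conn$post_id[i],
                 post_class = conn$post_class[i], n_pairs = ps$n_pairs,
                 eff_first = ps$eff_first, eff_second = ps$eff_second,
                 psr = ps$psr, low_n = ps$low_n,
                 isi_group = sprintf("%g-%g", sel_par$isi_min_ms,
                                     sel_par$isi_max_ms))
    })
    do.call(rbind, rows)
  })
  if (!is.null(psr_tab)) write_csv_plain(psr_tab, file.path(out, "paired_spike.csv"))

  # --- functional similarity ------------------------------------------
  sim_tab <- stage("similarity", {
    if (!nrow(conn) || !nrow(sparse_noise_events(ses))) return(NULL)
    resp <- list()
    get_resp <- function(id) {
      if (is.null(resp[[id]]))
        resp[[id]] <<- unit_responses(ses, id, snr_threshold = snr_thr)
      resp[[id]]
    }
    rows <- lapply(seq_len(nrow(conn)), function(i) {
      ra <- get_resp(conn$pre_id[i]); rb <- get_resp(conn$post_id[i])
      if (is.null(ra) || is.null(rb) || is.null(ra$psth_nm) || is.null(rb$psth_nm))
        return(NULL)
      s <- suppressWarnings(similarity_index(ra, rb, ra$snr_pass, rb$snr_pass))
      data.frame(pre_id = conn$pre_id[i], post_id = conn$post_id[i],
                 post_class = conn$post_class[i], r_sd = s$r_sd, r_sl = s$r_sl,
                 r_nm = s$r_nm, r_psm = s$r_psm, r_chk = s$r_chk,
                 index = s$index, snr_pre = ra$snr, snr_post = rb$snr,
                 snr_pass = s$snr_pass)
    })
    rows <- Filter(Negate(is.null), rows)
    if (length(rows)) do.call(rbind, rows) else NULL
  })
  if (!is.null(sim_tab)) write_csv_plain(sim_tab, file.path(out, "similarity.csv"))

  # --- summaries -------------------------------------------------------
  summary <- stage("summary", {
    cls_counts <- as.list(table(ses$units$label))
    by_class_summ <- function(df, col) {
      if (is.null(df) || !nrow(df)) return(NULL)
      lapply(split(df[[col]], df$post_class), function(v)
        if (sum(is.finite(v))) unclass(summarize_group(v)) else NULL)
    }
    rates <- vapply(ses$trains, firing_rate, 0)
    rate_by_class <- lapply(split(rates, ses$units$label[
      match(names(rates), ses$units$unit_id)]), function(v)
        unclass(summarize_group(v)))
    list(
      units = cls_counts,
      n_pairs_tested = nrow(pairs),
      n_connected = nrow(conn),
      connected_by_class = as.list(table(conn$post_class)),
      firing_rate = rate_by_class,
      efficacy = by_class_summ(conn, "efficacy"),
      contribution = by_class_summ(conn, "contribution"),
      psr = by_class_summ(psr_tab, "psr"),
      similarity = by_class_summ(
        if (!is.null(sim_tab)) sim_tab[sim_tab$snr_pass, ] else NULL, "index"),
      led_responsive_rgc = typing$led_responsive)
  })
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(log_lines,
                 sprintf("ccg: bin=%g ms window=%g ms jitter=%g ms n_jitter=%d seed=%s",
                         ccg_par$bin_ms, ccg_par$window_ms,
                         ccg_par$jitter_window_ms, ccg_par$n_jitter,
                         ccg_par$seed),
                 sprintf("pairs tested=%d connected=%d", nrow(pairs), nrow(conn)))
  writeLines(log_lines, file.path(out, "pipeline.log"))
  invisible(summary)
}
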