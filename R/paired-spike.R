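#' Spike-pair selection parameters
#'
#' @param isi_min_ms,isi_max_ms admissible inter-spike interval between the
#'   first and second spike of a pair, ms (default 5-30; the alternate
#'   preset 2-30 includes high-frequency units).
#' @param dead_time_ms required silent period before the first spike, ms
#'   (default 30).
#' @return list of class `pair_selection_params`.
#' @export
pair_selection_params <- function(isi_min_ms = 5, isi_max_ms = 30,
                                  dead_time_ms = 30) {
  rc_assert(isi_min_ms > 0 && isi_min_ms < isi_max_ms,
            "need 0 < isi_min < isi_max", "rc_parameter_error")
  rc_assert(dead_time_ms > 0, "dead time must be positive", "rc_parameter_error")
  structure(list(isi_min_ms = isi_min_ms, isi_max_ms = isi_max_ms,
                 dead_time_ms = dead_time_ms),
            class = "pair_selection_params")
}

#' Select first/second presynaptic spike pairs
#'
#' A consecutive spike pair (s_i, s_{i+1}) qualifies iff the inter-spike
#' interval lies within `[isi_min, isi_max]`, no spike occurs in the dead
#' time before s_i, and s_i lies at least one dead time after the start of
#' the recording (otherwise the silence is unobservable).
#'
#' @param train a [spike_train()].
#' @param params a [pair_selection_params()].
#' @return list of aligned vectors `first`, `second` (times in seconds).
#' @export
select_spike_pairs <- function(train, params = pair_selection_params()) {
  t <- train$times
  n <- length(t)
  if (n < 2) return(list(first = numeric(0), second = numeric(0)))
  isi <- diff(t)
  prev_gap <- c(Inf, isi)[seq_len(n - 1)]    # gap before s_i
  ok <- isi >= ms(params$isi_min_ms) & isi <= ms(params$isi_max_ms) &
    prev_gap >= ms(params$dead_time_ms) &
    t[seq_len(n - 1)] >= train$t_start + ms(params$dead_time_ms)
  list(first = t[which(ok)], second = t[which(ok) + 1])
}

#' Efficacies triggered on first and second spikes, and the paired-spike ratio
#'
#' Correlograms are recomputed triggered on the first-spike and second-spike
#' sets of the selected pairs, and the efficacy estimator is applied to each
#' with its own trigger count; the paired-spike ratio (PSR) is the
#' second-spike efficacy over the first-spike efficacy. PSR > 1 indicates
#' paired-spike enhancement (facilitation).
#'
#' @param first,second aligned trigger time vectors from
#'   [select_spike_pairs()].
#' @param post postsynaptic [spike_train()].
#' @param ccg_par a [ccg_params()].
#' @param det_par a [detection_params()] (efficacy windows).
#' @param exclusions optional [epoch_set()].
#' @param min_pairs reporting floor: below it the result is flagged
#'   (`low_n = TRUE`), not dropped (default 50).
#' @return list of class `paired_spike_result`: `eff_first`, `eff_second`,
#'   `psr` (`NA` when `eff_first <= 0`), `n_pairs`, `low_n`, `psr_defined`.
#' @export
paired_spike_efficacies <- function(first, second, post,
                                    ccg_par = ccg_params(),
                                    det_par = detection_params(),
                                    exclusions = NULL, min_pairs = 50) {
  rc_assert(length(first) == length(second), "first/second must be aligned")
  n <- length(first)
  span <- c(post$t_start, post$t_stop)
  eff_of <- function(tt) {
    tr <- spike_train("trigger", tt, span[1], span[2])
    cc <- compute_ccg(tr, post, ccg_par, exclusions)
    if (cc$n_pre == 0) return(NA_real_)
    efficacy(cc, det_par)
  }
  eff1 <- if (n) eff_of(first) else NA_real_
  eff2 <- if (n) eff_of(second) else NA_real_
  defined <- is.finite(eff1) && eff1 > 0 && is.finite(eff2)
  structure(list(eff_first = eff1, eff_second = eff2,
                 psr = if (defined) eff2 / eff1 else NA_real_,
                 n_pairs = n, low_n = n < min_pairs, psr_defined = defined),
            class = "paired_spike_result")
}

#' Paired-spike analysis of one connected pair
#'
#' Convenience wrapper: selects spike pairs on the presynaptic train and
#' computes [paired_spike_efficacies()] against the postsynaptic train.
#'
#' @param pre,post [spike_train()]s.
#' @param sel_par a [pair_selection_params()].
#' @inheritParams paired_spike_efficacies
#' @export
paired_spike_analysis <- function(pre, post, sel_par = pair_selection_params(),
                                  ccg_par = ccg_params(),
                                  det_par = detection_params(),
                                  exclusions = NULL, min_pairs = 50) {
  pre_f <- apply_exclusions(pre, exclusions)$train
  sel <- select_spike_pairs(pre_f, sel_par)
  paired_spike_efficacies(sel$first, sel$second, post, ccg_par, det_par,
                          exclusions, min_pairs)
}

#' Population summary of paired-spike ratios
#'
#' @param results data frame with columns `psr`, `eff_first` and optionally
#'   `post_class`; rows with undefined PSR are excluded.
#' @return list: `n`, `frac_enhanced` (PSR > 1), `mean_psr`, `sd_psr`,
#'   `by_class` (per-class mean/sd/n), `log_correlation`
#'   (Pearson r and p of log eff_first vs log PSR).
#' @export
population_psr <- function(results) {
  ok <- is.finite(results$psr) & results$psr > 0
  if (!any(ok)) rc_stop("no valid paired-spike results", "rc_validation_error")
  r <- results[ok, ]
  by_class <- NULL
  if (!is.null(r$post_class)) {
    by_class <- do.call(rbind, lapply(split(r, r$post_class), function(g)
      data.frame(post_class = g$post_class[1], n = nrow(g),
                 mean_psr = mean(g$psr), sd_psr = stats::sd(g$psr))))
    rownames(by_class) <- NULL
  }
  logcor <- list(r = NA_real_, p = NA_real_)
  pos <- r$eff_first > 0 & r$psr > 0
  if (sum(pos) >= 3 && stats::sd(log(r$eff_first[pos])) > 0 &&
        stats::sd(log(r$psr[pos])) > 0) {
    ct <- stats::cor.test(log(r$eff_first[pos]), log(r$psr[pos]))
    logcor <- list(r = unname(ct$estimate), p = ct$p.value)
  }
  list(n = nrow(r), frac_enhanced = mean(r$psr > 1),
       mean_psr = mean(r$psr), sd_psr = stats::sd(r$psr),
       by_class = by_class, log_correlation = logcor)
}
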