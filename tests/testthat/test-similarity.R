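make_events <- function(n_frames = 2000, seed = 101, gx = 24, gy = 14,
                        hot_cell = NULL, hot_every = NULL) {
  set.seed(seed)
  ev <- data.frame(time_s = rep((seq_len(n_frames) - 1) * 0.1, each = 2) + 10,
                   x = sample(gx, 2 * n_frames, replace = TRUE),
                   y = sample(gy, 2 * n_frames, replace = TRUE),
                   polarity = rep(sample(c("light", "dark"), n_frames,
                                         replace = TRUE), each = 2))
  if (!is.null(hot_cell)) {
    # make one grid cell recur regularly among the light frames
    hot <- which(ev$polarity == "light" & seq_len(nrow(ev)) %% 2 == 1)
    hot <- hot[seq(1, length(hot), by = hot_every)]
    ev$x[hot] <- hot_cell[1]; ev$y[hot] <- hot_cell[2]
  }
  ev
}

test_that("the spike-triggered average localizes a stimulus-locked unit", {
  ev <- make_events(hot_cell = c(5, 7), hot_every = 6)
  # unit fires 100 ms after every light target at (5, 7), nowhere else
  on <- ev$time_s[ev$polarity == "light" & ev$x == 5 & ev$y == 7]
  tr <- spike_train("u", sort(on + 0.1), 0, max(ev$time_s) + 1)
  expect_gt(length(tr$times), 100)
  strf <- compute_sta_strf(tr, ev, "light")
  pk <- strf_peak(strf)
  expect_equal(pk$x, 5)
  expect_equal(pk$y, 7)
  # frames stay on for 100 ms, so the triggering frame is active at any lag
  # within one frame duration of the true 100 ms offset
  expect_true(pk$lag_ms >= 25 && pk$lag_ms <= 100)
  expect_gt(strf_snr(strf)$snr, 8)
})

test_that("a stimulus-independent unit has no receptive field and shrinks with n", {
  ev <- make_events(seed = 102)
  span <- range(ev$time_s)
  set.seed(103)
  snr_at <- function(n) {
    tr <- spike_train("u", sort(runif(n, span[1], span[2])), 0, span[2] + 1)
    s <- compute_sta_strf(tr, ev, "light")
    list(snr = strf_snr(s)$snr, peak = max(abs(s$values)))
  }
  a <- snr_at(500); b <- snr_at(5000)
  expect_false(a$snr > 8)
  expect_false(b$snr > 8)
  expect_lt(b$peak, a$peak)           # STA converges to zero with spike count

  too_few <- spike_train("u", c(20, 30), 0, span[2] + 1)
  expect_error(compute_sta_strf(too_few, ev, "light"),
               class = "rc_validation_error")
})

test_that("planted receptive fields are recovered within one grid cell", {
  st <- simulate_session(sim_config(seed = 104, n_rgc = 3, n_exn = 2, n_in = 1,
                                    with_optotagging = FALSE,
                                    with_checkerboard = FALSE,
                                    with_movies = FALSE))
  ev <- sparse_noise_events(st$session)
  tru <- st$truth$units
  hits <- 0
  for (id in c("rgc01", "rgc02", "rgc03")) {
    u <- tru[tru$unit_id == id, ]
    pol <- if (u$rf_polarity > 0) "light" else "dark"
    strf <- compute_sta_strf(st$session$trains[[id]], ev, pol)
    if (!strf_snr(strf)$pass) next
    pk <- strf_peak(strf)
    expect_lte(max(abs(pk$x - u$rf_x), abs(pk$y - u$rf_y)), 1.6)
    expect_equal(pk$sign, 1)   # preferred polarity gives a positive peak
    hits <- hits + 1
  }
  expect_gte(hits, 2)
})

test_that("the PSTH averages counts over trials into spikes per second", {
  onsets <- (0:29) * 10
  silent <- spike_train("u", numeric(0), 0, 300)
  expect_true(all(psth(silent, onsets, 10)$rate == 0))

  one <- spike_train("u", onsets + 0.5, 0, 300)
  p <- psth(one, onsets, 10, bin_ms = 10)
  expect_equal(sum(p$rate > 0), 1)
  expect_equal(max(p$rate), 100)       # 1 spike / 30 trials / 10 ms * 30
  expect_equal(which.max(p$rate), 51)  # bin [0.5, 0.51) s

  set.seed(105)
  busy <- spike_train("u", sort(runif(3000, 0, 300)), 0, 300)
  p2 <- psth(busy, onsets, 10, bin_ms = 10)
  expect_equal(sum(p2$rate) * 0.01, 3000 / 30, tolerance = 1e-9)
})

test_that("response correlations match the textbook formula and its limits", {
  v <- c(1, 5, 2, 8, 3)
  expect_equal(response_correlation(v, v), 1.0)
  expect_equal(response_correlation(v, -v), -1.0)
  a <- c(1, 2, 3, 4); b <- c(2, 4, 7, 8)
  expect_equal(response_correlation(a, b), brute_pearson(a, b))
  # affine invariance
  expect_equal(response_correlation(3 * a - 2, b), response_correlation(a, b))
  expect_warning(r0 <- response_correlation(rep(1, 5), v))
  expect_true(is.na(r0))
})

test_that("the similarity index is exactly the mean of its five correlations", {
  set.seed(106)
  mk <- function() list(strf_sd = rnorm(50), strf_sl = rnorm(50),
                        psth_nm = rnorm(100), psth_psm = rnorm(100),
                        psth_chk = rnorm(100))
  a <- mk()
  s_same <- similarity_index(a, a)
  expect_equal(s_same$index, 1.0)

  b <- mk()
  s <- similarity_index(a, b)
  expect_identical(s$index, mean(c(s$r_sd, s$r_sl, s$r_nm, s$r_psm, s$r_chk)))
  # independent noise: index near zero
  idx <- replicate(20, similarity_index(mk(), mk())$index)
  expect_lt(max(abs(idx)), 0.3)
  expect_lt(abs(mean(idx)), 0.15)

  # SNR gate marks the pair invalid but still reports correlations
  s_gated <- similarity_index(a, b, snr_pass_pre = FALSE)
  expect_false(s_gated$valid)
  expect_false(s_gated$snr_pass)
})

test_that("similarity rises with planted receptive-field overlap", {
  idx_at <- function(offset, seed) {
    st <- simulate_session(sim_config(
      seed = seed, n_rgc = 2, n_exn = 2, n_in = 0, post_rf_offset = offset,
      trials_per_position = 4, movie_trials = 8, checkerboard_trials = 10,
      with_optotagging = FALSE))
    vals <- vapply(seq_len(nrow(st$truth$pairs)), function(i) {
      ra <- unit_responses(st$session, st$truth$pairs$pre[i], min_spikes = 30)
      rb <- unit_responses(st$session, st$truth$pairs$post[i], min_spikes = 30)
      if (is.null(ra) || is.null(rb)) return(NA_real_)
      similarity_index(ra, rb)$index
    }, 0)
    mean(vals, na.rm = TRUE)
  }
  close_ <- idx_at(0.3, 107)
  far <- idx_at(6, 108)
  expect_gt(close_, far)
})
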