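test_that("the five-consecutive-bin rule separates real peaks from noise", {
  set.seed(71)
  noise <- rnorm(1000, 0, 1)
  cc <- fake_ccg(noise)
  # plant 6 consecutive bins at 50 in (1.0, 1.6) ms: left edges 1.0 ... 1.5
  hot <- which(cc$lag_left_ms >= 1.0 - 1e-9 & cc$lag_left_ms < 1.6 - 1e-9)
  expect_length(hot, 6)
  cc$corrected[hot] <- 50
  cc$corrected[hot[3]] <- 60                 # unique maximum
  det <- detect_connection(cc)
  expect_true(det$connected)
  expect_equal(det$latency_ms, cc$lag_left_ms[hot[3]] + 0.05)

  # only 4 consecutive super-threshold bins: not connected
  cc2 <- fake_ccg(noise)
  cc2$corrected[hot[1:4]] <- 50
  expect_false(detect_connection(cc2)$connected)

  # a flat degenerate correlogram is flagged, not crashed
  cc3 <- fake_ccg(rep(0, 1000))
  det3 <- detect_connection(cc3)
  expect_true(det3$degenerate_sd)
  expect_false(det3$connected)
})

test_that("efficacy reproduces the hand arithmetic and its forced limits", {
  # 14 baseline bins at count 2; 31 peak bins totalling 160; n_pre = 1000
  raw <- rep(0L, 1000)
  cc <- fake_ccg(numeric(1000), raw = raw, n_pre = 1000L)
  base_idx <- ccg_bins_in(cc, -1, 0.4)
  peak_idx <- ccg_bins_in(cc, 0.4, 3.5)
  expect_length(base_idx, 14)
  expect_length(peak_idx, 31)
  cc$raw[base_idx] <- 2L
  cc$raw[peak_idx] <- c(rep(5L, 30), 10L)    # sums to 160
  expect_equal(efficacy(cc), (160 - 31 * 2) / 1000)
  expect_equal(efficacy(cc), 0.098)

  # perfect relay: post = pre + 1.5 ms
  set.seed(72)
  pre <- spike_train("pre", sort(runif(5000, 0, 600)), 0, 600)
  post <- spike_train("post", pre$times + 0.0015, 0, 600.01)
  eff <- efficacy(compute_ccg(pre, post))
  expect_equal(eff, 1.0, tolerance = 0.02)

  expect_error(efficacy(fake_ccg(numeric(1000), n_pre = 0L)),
               class = "rc_parameter_error")
})

test_that("planted efficacy is recovered from long recordings", {
  rgc <- simulate_rgc_train(10, 1800, seed = 73)
  pp <- simulate_connected_pair(rgc, synapse_params(0.25, background_rate = 5),
                                seed = 74)
  cc <- compute_ccg(rgc, pp$sc)
  se <- sqrt(0.25 * 0.75 / cc$n_pre)
  expect_lt(abs(efficacy(cc) - 0.25), 3 * se + 0.005)
})

test_that("contribution counts preceded postsynaptic spikes", {
  pre <- spike_train("pre", c(8, 28, 100) / 1000, 0, 1)
  post <- spike_train("post", c(10, 20, 30, 40) / 1000, 0, 1)
  expect_equal(contribution(pre, post), 2 / 4)

  # forced limit: every post spike follows a pre spike by 1.5 ms
  set.seed(75)
  p <- sort(runif(2000, 0, 300))
  expect_equal(contribution(spike_train("a", p, 0, 300),
                            spike_train("b", p + 0.0015, 0, 300.1)), 1.0)

  # invariance to a global shift of both trains
  sh <- 11.3
  expect_equal(contribution(spike_train("a", p + sh, 0, 320),
                            spike_train("b", p + 0.0015 + sh, 0, 320)), 1.0)

  expect_error(contribution(pre, spike_train("b", numeric(0), 0, 1)),
               class = "rc_parameter_error")
})

test_that("contribution matches the ground-truth fraction plus chance coincidences", {
  rgc <- simulate_rgc_train(10, 1800, seed = 76)
  pp <- simulate_connected_pair(rgc, synapse_params(0.5, background_rate = 7.4),
                                seed = 77)
  f_trig <- mean(!is.na(pp$truth$parent))
  rate_pre <- length(rgc$times) / 1800
  # analytic oracle: triggered spikes are counted iff their latency lies in
  # the [-3, -0.5] ms window; background spikes only by chance coincidence
  q <- (pnorm(3, 1.5, 0.4) - pnorm(0.5, 1.5, 0.4)) /
    (pnorm(3.5, 1.5, 0.4) - pnorm(0.5, 1.5, 0.4))
  chance <- 1 - exp(-rate_pre * 0.0025)
  expected <- f_trig * (q + (1 - q) * chance) + (1 - f_trig) * chance
  obs <- contribution(rgc, pp$sc)
  se <- sqrt(expected * (1 - expected) / length(pp$sc$times))
  expect_lt(abs(obs - expected), 3 * se + 0.01)
})

test_that("the pair scan recovers planted wiring with labeled latencies", {
  cfg <- sim_config(seed = 78, n_rgc = 4, n_exn = 3, n_in = 2, baseline_s = 600,
                    with_optotagging = FALSE, with_checkerboard = FALSE,
                    with_sparse_noise = FALSE, with_movies = FALSE)
  st <- simulate_session(cfg)
  pairs <- scan_all_pairs(st$session, ccg_params(seed = 79))
  expect_equal(nrow(pairs), 4 * 5)
  tru <- st$truth$pairs
  key <- paste(pairs$pre_id, pairs$post_id)
  planted <- paste(tru$pre, tru$post)
  expect_true(all(pairs$connected[key %in% planted]))
  expect_lte(sum(pairs$connected[!key %in% planted]), 1)
  # latency recovery within 0.3 ms of the planted mean
  for (i in seq_len(nrow(tru))) {
    row <- pairs[pairs$pre_id == tru$pre[i] & pairs$post_id == tru$post[i], ]
    expect_lt(abs(row$latency_ms - tru$latency_mean_ms[i]), 0.3)
  }
  # sorted by peak channel and annotated with distance
  chan <- setNames(st$session$units$peak_channel, st$session$units$unit_id)
  expect_true(!is.unsorted(chan[pairs$pre_id]))
  expect_equal(pairs$channel_distance_um,
               abs(chan[pairs$pre_id] - chan[pairs$post_id]) * 20,
               ignore_attr = TRUE)

  # LED-responsive axons can be excluded from the scan
  sub <- scan_all_pairs(st$session, ccg_params(seed = 79),
                        exclude_pre = "rgc01")
  expect_false("rgc01" %in% sub$pre_id)

  ses_norgc <- st$session
  ses_norgc$units$label[ses_norgc$units$label == "RGC"] <- "EXCLUDED"
  expect_warning(empty <- scan_all_pairs(ses_norgc))
  expect_equal(nrow(empty), 0)
})
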