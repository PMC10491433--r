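test_that("simulate_rgc_train obeys rate, refractoriness and the seed", {
  expect_length(simulate_rgc_train(0, 100, seed = 1)$times, 0)

  # refractory-thinned Poisson is a renewal process with rate
  # lambda / (1 + lambda * tau)
  rate <- 20; dur <- 600; tau <- 0.0015
  tr <- simulate_rgc_train(rate, dur, seed = 2)
  expected <- rate * dur / (1 + rate * tau)
  expect_lt(abs(length(tr$times) - expected), 3 * sqrt(rate * dur))
  expect_true(all(diff(tr$times) >= tau - 1e-12))

  expect_identical(simulate_rgc_train(15, 60, seed = 5)$times,
                   simulate_rgc_train(15, 60, seed = 5)$times)

  # a time-varying gain modulates the realized rate
  sig <- list(t = c(0, 50, 100), gain = c(0.2, 0.2, 2))
  tr2 <- simulate_rgc_train(rate, 100, rate_signal = sig, seed = 3)
  n_lo <- sum(tr2$times < 40)
  n_hi <- sum(tr2$times > 80)
  expect_gt(n_hi, n_lo)
})

test_that("simulate_connected_pair plants the requested efficacy and latencies", {
  # forced limit: every presynaptic spike triggers, no background
  rgc <- simulate_rgc_train(10, 100, seed = 4)
  pp <- simulate_connected_pair(rgc, synapse_params(1, background_rate = 0),
                                seed = 5)
  expect_equal(length(pp$sc$times), length(rgc$times))
  lags <- (pp$sc$times - rgc$times[pp$truth$parent]) * 1000
  expect_true(all(lags > 0.5 & lags < 3.5))

  # binomial oracle at p = 0.3
  rgc <- simulate_rgc_train(10, 1000, seed = 6)
  n <- length(rgc$times)
  expect_gt(n, 9000)
  pp <- simulate_connected_pair(rgc, synapse_params(0.3, background_rate = 0),
                                seed = 7)
  n_trig <- sum(!is.na(pp$truth$parent))
  expect_lt(abs(n_trig - 0.3 * n), 3 * sqrt(n * 0.3 * 0.7))
})

test_that("facilitation raises the trigger probability only for short-ISI spikes", {
  rgc <- simulate_rgc_train(30, 1200, seed = 8)   # high rate: many short ISIs
  pp <- simulate_connected_pair(
    rgc, synapse_params(0.2, facilitation = 1.7, background_rate = 0), seed = 9)
  trig <- rep(FALSE, length(rgc$times))
  trig[pp$truth$parent] <- TRUE
  prev_isi <- c(Inf, diff(rgc$times))
  fac <- prev_isi <= 0.030
  p_fac <- mean(trig[fac]); p_plain <- mean(trig[!fac])
  se <- function(p, n) sqrt(p * (1 - p) / n)
  expect_lt(abs(p_fac - 0.34), 3 * se(0.34, sum(fac)))
  expect_lt(abs(p_plain - 0.20), 3 * se(0.20, sum(!fac)))
})

test_that("comodulated pairs share a slow rate signal and are reproducible", {
  s1 <- simulate_comodulated_pair(20, 15, 200, 1, 120, seed = 10)
  s2 <- simulate_comodulated_pair(20, 15, 200, 1, 120, seed = 10)
  expect_identical(s1$a$times, s2$a$times)
  expect_identical(s1$b$times, s2$b$times)

  # shared slow gain: 1 s binned counts correlate strongly
  ca <- tabulate(floor(s1$a$times) + 1, 120)
  cb <- tabulate(floor(s1$b$times) + 1, 120)
  expect_gt(cor(ca, cb), 0.5)

  # gain 0: independent
  s0 <- simulate_comodulated_pair(20, 15, 200, 0, 120, seed = 11)
  c0a <- tabulate(floor(s0$a$times) + 1, 120)
  c0b <- tabulate(floor(s0$b$times) + 1, 120)
  expect_lt(abs(cor(c0a, c0b)), 0.3)
})

test_that("waveform templates have the advertised phase structure", {
  som <- generate_waveform_template("somatic", 32, seed = 12)
  axo <- generate_waveform_template("axonal", 32, seed = 13)
  fs <- waveform_features(som$waveform, som$fs)
  fa <- waveform_features(axo$waveform, axo$fs)
  expect_equal(fs$n_phases, 2L)
  expect_gte(fa$n_phases, 3L)
  expect_gt(fa$spread, fs$spread)
  expect_gt(abs(fa$propagation_slope), 0)
  expect_equal(fs$peak_channel, som$peak_channel)

  again <- generate_waveform_template("axonal", 32, seed = 13)
  expect_identical(axo$waveform, again$waveform)
})

test_that("simulated sessions honour their config and record ground truth", {
  cfg <- sim_config(seed = 21, n_rgc = 3, n_exn = 4, n_in = 2, n_pulses = 60,
                    trials_per_position = 2, movie_trials = 3,
                    chk_led_trials = 5, checkerboard_trials = 5)
  st <- simulate_session(cfg)
  tru <- st$truth

  # class composition is exact
  expect_equal(sum(tru$units$true_class == "SC_IN"), 2)
  expect_equal(sum(tru$units$true_class == "SC_EXN"), 4)
  expect_equal(mean(tru$units$true_class[tru$units$true_class != "RGC"] == "SC_IN"),
               2 / 6)

  # every planted transmission latency lies in (0.5, 3.5) ms
  for (post in names(tru$parents)) {
    pre_id <- tru$pairs$pre[tru$pairs$post == post]
    par <- tru$parents[[post]]
    trig <- which(!is.na(par))
    lags <- (st$session$trains[[post]]$times[trig] -
               st$session$trains[[pre_id]]$times[par[trig]]) * 1000
    expect_true(all(lags > 0.5 & lags < 3.5))
  }

  # determinism under the seed
  st2 <- simulate_session(cfg)
  expect_identical(st$session$trains$rgc01$times, st2$session$trains$rgc01$times)
  expect_identical(st$truth$pairs$efficacy_base, st2$truth$pairs$efficacy_base)

  # exclusion epochs cover the optotagging protocols
  expect_true(all(in_epochs(st$session$pulses$onset_s, st$session$exclusions)))
})

test_that("a zero-connection config yields no detectable pairs", {
  cfg <- sim_config(seed = 31, n_rgc = 3, n_exn = 3, n_in = 0,
                    connectivity = data.frame(), baseline_s = 300,
                    with_optotagging = FALSE, with_checkerboard = FALSE,
                    with_sparse_noise = FALSE, with_movies = FALSE)
  st <- simulate_session(cfg)
  pairs <- scan_all_pairs(st$session, ccg_params(seed = 32))
  expect_equal(nrow(pairs), 9)
  expect_lte(sum(pairs$connected), 1)   # false-positive allowance
})
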