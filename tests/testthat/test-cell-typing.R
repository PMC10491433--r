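# build a train with a multiplicative rate gain during pulse windows
pulse_train <- function(base_rate, gain, pulses, dur, seed,
                        latency_s = 0.005) {
  set.seed(seed)
  dt <- 0.001
  n <- ceiling(dur / dt)
  rate <- rep(base_rate, n)
  for (i in seq_len(nrow(pulses))) {
    i0 <- floor((pulses$onset_s[i] + latency_s) / dt) + 1
    i1 <- min(n, floor((pulses$onset_s[i] + pulses$duration_s[i] + latency_s) / dt))
    rate[i0:i1] <- base_rate * gain
  }
  t <- retinoconn:::sim_inhom_poisson(rate, dt)
  spike_train("u", t[t < dur], 0, dur)
}

spont_pulses <- function(n = 400) {
  data.frame(onset_s = (seq_len(n) - 1) * 0.5 + 0.2, duration_s = 0.1,
             protocol = "spontaneous_100ms")
}

test_that("light modulation test recovers a planted gain with short latency", {
  pls <- spont_pulses(400)
  dur <- max(pls$onset_s) + 1
  tagged <- pulse_train(8, 3, pls, dur, seed = 111)
  r <- light_modulation_test(tagged, pls)
  expect_lt(abs(r$rate_ratio - 3), 0.5)
  expect_lt(r$p_value, 1e-6)
  expect_lte(r$onset_latency_ms, 20)

  # an unmodulated unit is not significant in most realizations
  hits <- sum(vapply(1:20, function(k) {
    un <- pulse_train(8, 1, pls, dur, seed = 200 + k)
    light_modulation_test(un, pls)$p_value < 0.05
  }, TRUE))
  expect_lte(hits, 4)

  # silent unit: flagged, not an error
  expect_warning(r0 <- light_modulation_test(
    spike_train("u", numeric(0), 0, dur), pls))
  expect_true(is.na(r0$rate_ratio))

  expect_warning(light_modulation_test(tagged, pls[1:5, ]), "low-power")
})

test_that("SC classification follows the tagging and range rules", {
  sig <- structure(list(baseline_rate = 8, pulse_rate = 24, rate_ratio = 3,
                        onset_latency_ms = 5, p_value = 1e-9, n_pulses = 400,
                        low_power = FALSE, protocol = "spontaneous_100ms"),
                   class = "light_response")
  flat <- structure(list(baseline_rate = 8, pulse_rate = 8.2, rate_ratio = 1.02,
                         onset_latency_ms = NA_real_, p_value = 0.6,
                         n_pulses = 400, low_power = FALSE,
                         protocol = "spontaneous_100ms"),
                    class = "light_response")
  down <- structure(list(baseline_rate = 8, pulse_rate = 4, rate_ratio = 0.5,
                         onset_latency_ms = NA_real_, p_value = 0.9,
                         n_pulses = 60, low_power = FALSE,
                         protocol = "checkerboard_1000ms"),
                    class = "light_response")
  up <- structure(list(baseline_rate = 8, pulse_rate = 20, rate_ratio = 2.5,
                       onset_latency_ms = 8, p_value = 1e-4, n_pulses = 60,
                       low_power = FALSE, protocol = "checkerboard_1000ms"),
                  class = "light_response")
  expect_equal(classify_sc_unit(sig, up, in_range = TRUE), "SC_IN")
  expect_equal(classify_sc_unit(sig, up, in_range = FALSE), "SC_IN")
  # corroboration fails: opposite direction across protocols
  expect_equal(classify_sc_unit(sig, down, in_range = TRUE), "EXCLUDED")
  expect_equal(classify_sc_unit(flat, down, in_range = TRUE), "SC_EXN")
  # outside the light-activated range: never EXN
  expect_equal(classify_sc_unit(flat, down, in_range = FALSE), "EXCLUDED")
})

test_that("light-activated range is the span of tagged peak channels", {
  expect_equal(light_activated_range(c(50, 120, 200)), c(50, 200))
  expect_equal(light_activated_range(75), c(75, 75))
  expect_error(light_activated_range(integer(0)), class = "rc_validation_error")
})

test_that("session-level optotagging classifies planted cell types", {
  st <- simulate_session(sim_config(seed = 112, n_rgc = 2, n_exn = 6, n_in = 3,
                                    with_checkerboard = FALSE,
                                    with_sparse_noise = FALSE,
                                    with_movies = FALSE))
  cl <- classify_session_units(st$session)
  tru <- st$truth$units
  truth_lab <- tru$true_class[match(cl$unit_id, tru$unit_id)]
  # all planted inhibitory units tagged
  expect_true(all(cl$label[truth_lab == "SC_IN"] == "SC_IN"))
  # no excitatory unit tagged inhibitory
  expect_true(all(cl$label[truth_lab == "SC_EXN"] != "SC_IN"))
  # out-of-range units are never excitatory
  expect_true(all(cl$label[!cl$in_range] != "SC_EXN"))
})

test_that("LED-responsive retinal axons are flagged and others are not", {
  st <- simulate_session(sim_config(seed = 113, n_rgc = 3, n_exn = 2, n_in = 2,
                                    n_led_rgc = 1,
                                    with_checkerboard = FALSE,
                                    with_sparse_noise = FALSE,
                                    with_movies = FALSE))
  fl <- flag_led_responsive_rgc(st$session)
  expect_true(fl[["rgc01"]])
  expect_false(any(fl[c("rgc02", "rgc03")]))

  nopulse <- st$session
  nopulse$pulses <- nopulse$pulses[0, ]
  expect_warning(fl0 <- flag_led_responsive_rgc(nopulse))
  expect_false(any(fl0))
})

test_that("waveform features follow their definitions and scale invariance", {
  fs <- 30000
  n <- 61
  t_ms <- (seq_len(n) - 1) / fs * 1000
  shape <- numeric(n)
  shape[which.min(abs(t_ms - 0.30))] <- -80
  shape[which.min(abs(t_ms - 0.80))] <- 40
  # smooth slightly so excursions are well defined
  shape <- stats::filter(shape, rep(1 / 3, 3), sides = 2)
  shape[is.na(shape)] <- 0
  wf <- matrix(0, 9, n)
  wf[5, ] <- shape
  wf[4, ] <- 0.5 * shape; wf[6, ] <- 0.5 * shape
  f <- waveform_features(wf, fs)
  expect_equal(f$duration_ms, 0.5, tolerance = 0.04)
  expect_equal(f$amplitude, 120 * 1 / 3, tolerance = 2)
  expect_equal(f$peak_to_trough_ratio, 0.5, tolerance = 0.01)
  expect_equal(f$n_phases, 2L)

  f2 <- waveform_features(3.7 * wf, fs)
  expect_equal(f2$peak_to_trough_ratio, f$peak_to_trough_ratio)
  expect_equal(f2$duration_ms, f$duration_ms)
  expect_equal(f2$n_phases, f$n_phases)
  expect_equal(f2$spread, f$spread)
  expect_equal(f2$propagation_slope, f$propagation_slope)

  expect_error(waveform_features(matrix(0, 9, n), fs),
               class = "rc_validation_error")
})

test_that("axonal and somatic templates are classified by their multi-channel profile", {
  labs <- vapply(1:30, function(k) {
    kind <- if (k %% 2 == 0) "axonal" else "somatic"
    wf <- generate_waveform_template(kind, 32, seed = 300 + k)
    paste(kind, classify_axonal_vs_somatic(waveform_features(wf$waveform, wf$fs)))
  }, "")
  expect_true(all(labs %in% c("axonal RGC_AXON", "somatic SC_SOMA")))

  # the stated rule on hand-made features
  feat <- structure(list(n_phases = 2L, spread = 2, propagation_slope = 0),
                    class = "waveform_features")
  expect_equal(classify_axonal_vs_somatic(feat), "SC_SOMA")
})
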