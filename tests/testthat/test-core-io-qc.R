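test_that("apply_exclusions removes in-epoch spikes and reports effective duration", {
  tr <- spike_train("u", c(1, 2, 3), 0, 10)
  res <- apply_exclusions(tr, epoch_set(1.5, 2.5))
  expect_equal(res$train$times, c(1, 3))
  expect_equal(res$effective_duration_s, 9)

  # empty epoch set is the identity
  res0 <- apply_exclusions(tr, epoch_set())
  expect_identical(res0$train$times, tr$times)
  expect_equal(res0$effective_duration_s, 10)

  # uniform spikes: retained count follows the covered fraction
  set.seed(41)
  t1k <- spike_train("u", sort(runif(1000, 0, 100)), 0, 100)
  ep <- epoch_set(c(10, 40, 70, 90), c(15, 45, 75, 95))  # 20 s covered
  res <- apply_exclusions(t1k, ep)
  expect_equal(res$effective_duration_s, 80)
  # binomial oracle: n=1000, p=0.8, 3 SE = 3*sqrt(1000*0.8*0.2) = 38
  expect_lt(abs(length(res$train$times) - 800), 38)
})

test_that("apply_exclusions never adds spikes and removals sum over disjoint epochs", {
  set.seed(7)
  for (k in 1:10) {
    tr <- spike_train("u", sort(runif(200, 0, 50)), 0, 50)
    ep <- epoch_set(c(5, 20, 35), c(8, 26, 40))
    res <- apply_exclusions(tr, ep)
    expect_lte(length(res$train$times), length(tr$times))
    per_epoch <- vapply(seq_len(nrow(ep)), function(i)
      length(tr$times) - length(apply_exclusions(tr, ep[i, ])$train$times), 0)
    expect_equal(sum(per_epoch), length(tr$times) - length(res$train$times))
  }
})

test_that("duplicate-spike removal collapses runs to their first member and is idempotent", {
  tr <- spike_train("u", c(10.00, 10.10, 30.00) / 1000, 0, 1)
  expect_equal(remove_duplicate_spikes(tr, 0.16)$times, c(10, 30) / 1000)

  # chained run collapses to the first spike
  tr2 <- spike_train("u", c(5.00, 5.10, 5.20) / 1000, 0, 1)
  expect_equal(remove_duplicate_spikes(tr2, 0.16)$times, 5 / 1000)

  # all gaps above tolerance: unchanged
  tr3 <- spike_train("u", (1:20) / 100, 0, 1)
  expect_identical(remove_duplicate_spikes(tr3)$times, tr3$times)

  # idempotence on random near-coincident trains
  set.seed(11)
  for (k in 1:5) {
    t <- sort(c(runif(100, 0, 1), runif(100, 0, 1) + 1e-5))
    tr <- spike_train("u", t, 0, 2)
    once <- remove_duplicate_spikes(tr)
    expect_identical(remove_duplicate_spikes(once)$times, once$times)
  }
  expect_error(remove_duplicate_spikes(tr, -1), class = "rc_parameter_error")
})

test_that("ISI violation ratio counts short preceding intervals", {
  tr <- spike_train("u", c(0, 1, 10, 20) / 1000, 0, 1)
  expect_equal(isi_violation_ratio(tr, 1.5), 1 / 4)

  regular <- spike_train("u", (1:100) / 100, 0, 2)
  expect_equal(isi_violation_ratio(regular), 0)

  # invariance to a global time shift
  shifted <- spike_train("u", c(0, 1, 10, 20) / 1000 + 5, 0, 10)
  expect_equal(isi_violation_ratio(shifted, 1.5), 1 / 4)

  expect_warning(r <- isi_violation_ratio(spike_train("u", 0.5, 0, 1)))
  expect_equal(r, 0)
})

test_that("ISI violation ratio of a Poisson train matches the exponential-ISI law", {
  # P(ISI < 1.5 ms) = 1 - exp(-rate * 0.0015) for exponential intervals
  set.seed(17)
  rate <- 50; dur <- 600
  t <- cumsum(rexp(rate * dur * 1.2, rate))
  t <- t[t < dur]
  tr <- spike_train("u", t, 0, dur)
  p <- 1 - exp(-rate * 0.0015)
  se <- sqrt(p * (1 - p) / length(t))
  expect_lt(abs(isi_violation_ratio(tr) - p), 3 * se + 1 / length(t))
})

test_that("MUA detection recovers planted deflections and respects the threshold", {
  fs <- 30000
  set.seed(3)
  n <- fs %/% 5
  trace <- rnorm(n)
  planted <- sort(sample(seq(500, n - 500, by = 450), 10))
  trace[planted] <- 6 * sample(c(-1, 1), 10, replace = TRUE)
  ev <- detect_mua_events(trace, fs, k_sd = 4)
  planted_t <- (planted - 1) / fs
  # every planted event recovered within 0.5 ms, no extras
  expect_equal(length(ev), 10)
  expect_true(all(vapply(planted_t, function(p) min(abs(ev - p)) < 5e-4, TRUE)))

  expect_identical(detect_mua_events(numeric(1000), fs), numeric(0))
  expect_identical(detect_mua_events(trace, fs, k_sd = 100), numeric(0))

  # event count is nonincreasing in the threshold
  counts <- vapply(c(3, 4, 5, 6, 8), function(k)
    length(detect_mua_events(trace, fs, k)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("session write/read round trip preserves the data model", {
  ses <- tiny_session()
  dir <- withr::local_tempdir()
  write_session(ses, dir)
  back <- read_session(dir)
  expect_equal(names(back$trains), names(ses$trains))
  for (id in names(ses$trains))
    expect_equal(back$trains[[id]]$times, ses$trains[[id]]$times, tolerance = 1e-9)
  expect_equal(back$units$label, ses$units$label)
  expect_equal(back$pulses$onset_s, ses$pulses$onset_s)
  expect_equal(as.data.frame(back$exclusions), as.data.frame(ses$exclusions))
  expect_equal(back$waveforms$u1, ses$waveforms$u1, tolerance = 1e-6)

  # repeated writes are byte-identical
  dir2 <- withr::local_tempdir()
  write_session(back, dir2)
  dir3 <- withr::local_tempdir()
  write_session(back, dir3)
  for (f in c("spikes.csv", "pulses.csv", "stim_events.csv", "exclusions.csv"))
    expect_identical(readLines(file.path(dir2, f)), readLines(file.path(dir3, f)))
})

test_that("simulated sessions survive a write/read round trip", {
  st <- simulate_session(sim_config(seed = 99, n_rgc = 2, n_exn = 2, n_in = 1,
                                    n_pulses = 40, trials_per_position = 1,
                                    movie_trials = 2, chk_led_trials = 3,
                                    checkerboard_trials = 3))
  dir <- withr::local_tempdir()
  write_session(st$session, dir)
  write_ground_truth(st$truth, dir)
  back <- read_session(dir)
  for (id in names(st$session$trains))
    expect_equal(back$trains[[id]]$times, st$session$trains[[id]]$times,
                 tolerance = 1e-9)
  expect_equal(nrow(back$stim_events), nrow(st$session$stim_events))
  gt <- read_ground_truth(dir)
  expect_equal(gt$pairs$efficacy_base, st$truth$pairs$efficacy_base,
               tolerance = 1e-12)
})

test_that("malformed session directories are rejected with informative errors", {
  dir <- withr::local_tempdir()
  expect_error(read_session(dir), class = "rc_format_error")

  ses <- tiny_session()
  write_session(ses, dir)
  unlink(file.path(dir, "spikes.csv"))
  expect_error(read_session(dir), "spikes", class = "rc_format_error")

  write_session(ses, dir)
  # corrupt the spike order of u1
  spk <- read.csv(file.path(dir, "spikes.csv"))
  spk$time_s[1:2] <- rev(spk$time_s[1:2])
  write.csv(spk, file.path(dir, "spikes.csv"), row.names = FALSE)
  expect_error(read_session(dir), "unsorted", class = "rc_validation_error")
})

test_that("qc_unit flags contaminated units under the 0.05% rule", {
  clean <- spike_train("u", cumsum(rep(0.02, 500)), 0, 11)
  expect_true(qc_unit(clean)$pass)
  dirty <- spike_train("u", sort(c(cumsum(rep(0.02, 500)),
                                   cumsum(rep(0.02, 500)) + 0.001)), 0, 11)
  q <- qc_unit(dirty)
  expect_false(q$pass)
  expect_gt(q$isi_ratio, 5e-4)
})
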