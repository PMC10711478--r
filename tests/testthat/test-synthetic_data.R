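test_that("agent parameters are validated", {
  expect_error(agent_params(alpha = 0), "alpha")
  expect_error(agent_params(alpha = 0.6, kappa_stim = 2), "kappa_stim")
  expect_error(agent_params(lap_rate = -1), "lap_rate")
  expect_s3_class(agent_params(), "agent_params")
})

test_that("the same seed reproduces a session byte-for-byte", {
  run <- function() {
    set.seed(99)
    simulate_session(agent_params(), sim_config("CRL", "W"))
  }
  a <- run(); b <- run()
  expect_identical(a$log$events, b$log$events)
  expect_identical(a$V, b$V)
})

test_that("an indifferent agent matches the Bernoulli closed form", {
  # beta = 0 pokes every feeder with p = 1/2 independent of value, so
  # P(correct lap) = (1/2)(1/2)^3 = 0.0625 and P(rule lap) = 4 x that.
  set.seed(41)
  rates <- t(replicate(300, {
    sim <- simulate_session(null_agent(), sim_config("FRL", "N"))
    m <- session_metrics(segment_laps(sim$log))
    c(m$correct_response_rate, m$rule_learning_rate, m$n_laps)
  }))
  n_laps_total <- sum(rates[, 3])
  se_c <- sqrt(0.0625 * (1 - 0.0625) / n_laps_total)
  se_r <- sqrt(0.25 * 0.75 / n_laps_total)
  expect_lt(abs(mean(rates[, 1]) - 0.0625), 3 * se_c)
  expect_lt(abs(mean(rates[, 2]) - 0.25), 3 * se_r)
})

test_that("stimulation events honor the condition trigger semantics", {
  set.seed(42)
  for (cond in c("pre", "post", "opposite")) {
    sim <- simulate_session(agent_params(kappa_stim = 1.5),
                            sim_config("CRL", "N", stim_condition = cond,
                                       stim_duration = "long_40ms"))
    ev <- sim$log$events
    onsets <- ev$t[ev$kind == "stim_on"]
    offs <- ev$t[ev$kind == "stim_off"]
    expect_equal(length(onsets), length(offs))
    expect_true(length(onsets) > 0)
    # 20 pulses per 1-s burst, 40 ms each: duty cycle 4/5
    expect_equal(unique(round(offs - onsets, 9)), 0.040)
    first_pulse <- onsets[c(TRUE, diff(onsets) > 0.1)]
    per_burst <- as.numeric(table(findInterval(onsets, first_pulse)))
    expect_true(all(per_burst == 20))
    expect_equal(stim_duty_cycle(40, 20), 4 / 5)
    trigger <- switch(cond,
      pre = ev$t[ev$kind == "beam_cross" & ev$device == "sN"],
      post = ev$t[ev$kind == "reward_delivered"],
      opposite = ev$t[ev$kind == "beam_cross" & ev$device == "sS"])
    expect_true(all(first_pulse %in% round(trigger, 9) |
                      first_pulse %in% trigger))
  }
})

test_that("CRL cohorts redraw the rewarded feeder every session", {
  ex <- simulate_experiment(list(control = list(agent = agent_params(),
                                                n = 2)),
                            days = 2, task = "CRL", seed = 5)
  for (an in unique(ex$sessions$animal_id)) {
    rf <- ex$sessions$rewarded_feeder[ex$sessions$animal_id == an]
    expect_true(all(rf[-1] != rf[-length(rf)]))
  }
  fx <- simulate_experiment(list(control = list(agent = agent_params(),
                                                n = 1)),
                            days = 2, task = "FRL", seed = 5)
  expect_equal(length(unique(fx$sessions$rewarded_feeder)), 1)
})

test_that("session rates increase with the stimulation learning factor", {
  # scored as the analysis scores post-stim sessions, i.e. from the lap
  # after the first reward onward
  mean_rates <- function(kappa, seed) {
    ex <- simulate_experiment(
      list(g = list(agent = agent_params(kappa_stim = kappa),
                    stim_condition = "post",
                    stim_duration = "long_40ms", n = 3)),
      days = 1, task = "CRL", seed = seed)
    sm <- vapply(ex$logs, function(lg) {
      m <- session_metrics(segment_laps(lg))
      c(m$correct_response_rate, m$rule_learning_rate)
    }, c(correct = 0, rule = 0))
    rowMeans(sm, na.rm = TRUE)
  }
  by_kappa <- sapply(c(1, 1.4, 1.9), function(k)
    rowMeans(sapply(1:10, function(s) mean_rates(k, 100 + s))))
  expect_true(all(diff(by_kappa["correct", ]) > -0.02))
  expect_true(all(diff(by_kappa["rule", ]) > -0.02))
  expect_gt(by_kappa["correct", 3], by_kappa["correct", 1])
  expect_gt(by_kappa["rule", 3], by_kappa["rule", 1])
})

test_that("lesion presets cut measured running speed about in half", {
  measure <- function(agent, seed) {
    set.seed(seed)
    mean(sapply(1:8, function(i) {
      sim <- simulate_session(agent, sim_config("FRL", "N"))
      m <- session_metrics(segment_laps(sim$log))
      m$mean_speed_cm_s
    }), na.rm = TRUE)
  }
  ctrl <- measure(group_preset("control"), 7)
  les <- measure(group_preset("lesioned"), 7)
  expect_lt(abs(les / ctrl - 0.5), 0.12)
})

test_that("the 30-min burst protocol emits 180 onsets", {
  pr <- stim_protocol(total_min = 30, cycle_s = 10)
  expect_length(pr$onsets, 180)
  tr <- simulate_photometry(photo_model("GCaMP6f", "short_10ms",
                                        noise_sd = 0), pr, seed = 1)
  expect_length(tr$onsets, 180)
  expect_equal(diff(tr$onsets)[1], 10)
})

test_that("photometry kernels recover their amplitude through the PETH", {
  sq <- simulate_photometry(photo_model("GCaMP6f", "long_40ms",
                                        amplitude_pct = 10, noise_sd = 0,
                                        shape = "square"),
                            stim_protocol(total_min = 3), seed = 2)
  ph <- phase_means(compute_peth(sq))
  expect_equal(unname(ph$mean[["stim"]]), 10, tolerance = 1e-9)
  expect_equal(unname(ph$mean[["late"]]), 0, tolerance = 1e-9)

  set.seed(3)
  noisy <- simulate_photometry(photo_model("GCaMP6f", "long_40ms",
                                           amplitude_pct = 10, noise_sd = 1,
                                           shape = "square"),
                               stim_protocol(total_min = 30), seed = 3)
  phn <- phase_means(compute_peth(noisy))
  sem <- 1 / sqrt(180 * 10)   # noise sd 1% over 180 trials x 10 bins
  expect_lt(abs(phn$mean[["stim"]] - 10), 3 * sem * 2)

  zero <- simulate_photometry(photo_model("GRAB_DA2h", "short_10ms",
                                          amplitude_pct = 0, noise_sd = 0.5),
                              stim_protocol(total_min = 3), seed = 4)
  phz <- phase_means(compute_peth(zero))
  expect_lt(abs(phz$mean[["stim"]]), 0.5)
})

test_that("long bursts evoke larger sustained responses than short", {
  ph_for <- function(kind, dur) {
    tr <- simulate_photometry(photo_model(kind, dur, noise_sd = 0.5),
                              stim_protocol(total_min = 5),
                              seed = 11)
    phase_means(compute_peth(tr))$mean
  }
  g_long <- ph_for("GCaMP6f", "long_40ms")
  g_short <- ph_for("GCaMP6f", "short_10ms")
  expect_gt(g_long[["stim"]], g_short[["stim"]])
  expect_gt(g_long[["early"]], g_short[["early"]])
  expect_gt(g_long[["late"]], g_short[["late"]])
})

test_that("single-state pose models classify to their own state", {
  fast <- simulate_pose(list(constant = 5), duration_s = 60, seed = 6)
  s_fast <- state_summary(classify_states(compute_speed(fast$track)))
  expect_equal(unname(s_fast$percent["ambulation"]), 100)

  still <- simulate_pose(list(constant = 0), duration_s = 60, seed = 6)
  s_still <- state_summary(classify_states(compute_speed(still$track)))
  expect_equal(unname(s_still$percent["immobility"]), 100)

  # positions stay inside the arena
  r <- sqrt(fast$track$x^2 + fast$track$y^2)
  expect_lt(max(r), 31 / 2)
})
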