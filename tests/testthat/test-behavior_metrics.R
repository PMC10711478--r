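test_that("lap choices implement the correct / rule definitions", {
  laps <- make_laps(list(c("S", "S"), c("S", "E"), c("E", "E"),
                         character(0)),
                    rewarded = "S")
  ch <- lap_choices(laps)
  expect_equal(ch$is_correct, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(ch$is_rule, c(TRUE, FALSE, TRUE, FALSE))
  # correct implies rule everywhere
  expect_true(all(!ch$is_correct | ch$is_rule))
  # unknown feeder labels are rejected
  bad <- make_laps(list("Q"), rewarded = "S")
  expect_error(lap_choices(bad), "unknown feeder")
})

test_that("session rates divide flag counts by the total lap count", {
  ch <- lap_choices(make_laps(list("S", c("S", "E"), "E", "S"),
                              rewarded = "S"))
  r <- session_rates(ch)
  expect_equal(r$correct_response_rate, 0.5)
  expect_equal(r$rule_learning_rate, 0.75)
  expect_equal(r$n_laps, 4)

  perfect <- session_rates(lap_choices(make_laps(
    rep(list("N"), 10), rewarded = "N")))
  expect_equal(perfect$correct_response_rate, 1)
  expect_equal(perfect$rule_learning_rate, 1)

  empty_pokes <- session_rates(lap_choices(make_laps(
    rep(list(character(0)), 4), rewarded = "N")))
  expect_equal(empty_pokes$correct_response_rate, 0)
  expect_equal(empty_pokes$rule_learning_rate, 0)

  expect_error(session_rates(lap_choices(make_laps(list(), "N"))),
               "no complete laps")
})

test_that("rates are invariant under permutation of lap order", {
  sets <- list("N", c("N", "E"), "W", character(0), c("S", "S"))
  r1 <- session_rates(lap_choices(make_laps(sets, "N")))
  set.seed(4)
  for (i in 1:5) {
    r2 <- session_rates(lap_choices(make_laps(sample(sets), "N")))
    expect_equal(r2, r1)
  }
})

test_that("running speed is distance over sensor-to-poke latency", {
  sc <- list(stats::setNames(c(10, NA, NA, NA), FEEDERS),
             stats::setNames(c(10, NA, NA, NA), FEEDERS))
  laps <- make_laps(list("N", "N"), rewarded = "N", sensor_cross = sc)
  laps[[1]]$pokes$t <- 13    # 15 cm in 3 s
  laps[[2]]$pokes$t <- 11    # 15 cm in 1 s
  v <- running_speeds(laps)
  expect_equal(as.numeric(v), c(5, 15))

  # poke preceding the crossing is invalid; missing events are skipped
  laps[[1]]$pokes$t <- 9
  laps[[2]]$sensor_cross["N"] <- NA
  v2 <- running_speeds(laps)
  expect_length(v2, 0)
  expect_equal(attr(v2, "n_invalid"), 1L)
  expect_equal(attr(v2, "n_skipped"), 1L)
})

test_that("speeds scale inversely with a uniform time dilation", {
  sc <- list(stats::setNames(c(5, NA, NA, NA), FEEDERS))
  laps <- make_laps(list("N"), "N", sensor_cross = sc)
  laps[[1]]$pokes$t <- 8
  v1 <- as.numeric(running_speeds(laps))
  laps[[1]]$pokes$t <- laps[[1]]$pokes$t * 3
  laps[[1]]$sensor_cross["N"] <- 15
  v3 <- as.numeric(running_speeds(laps))
  expect_equal(v3, v1 / 3)
  expect_true(all(v1 > 0))
})

test_that("post-stim filter returns the suffix after the first reward", {
  laps <- make_laps(rep(list("N"), 10), "N",
                    rewarded_laps = c(FALSE, FALSE, TRUE, rep(TRUE, 7)))
  out <- post_stim_filter(laps)
  expect_length(out, 7)
  expect_equal(vapply(out, `[[`, integer(1), "index"), 4:10)

  first <- post_stim_filter(make_laps(rep(list("N"), 10), "N",
                                      rewarded_laps = c(TRUE, rep(FALSE, 9))))
  expect_length(first, 9)

  expect_warning(
    none <- post_stim_filter(make_laps(rep(list("E"), 5), "N",
                                       rewarded_laps = rep(FALSE, 5))),
    "no reward")
  expect_length(none, 0)
})

test_that("day aggregation averages sessions, skipping undefined rates", {
  sess <- data.frame(animal_id = "m1", day = 2,
                     correct_response_rate = c(0.5, 0.6, 0.7, 0.8),
                     rule_learning_rate = c(0.5, 0.7, 0.9, 0.9),
                     n_laps = c(10, 10, 9, 10),
                     mean_speed_cm_s = c(20, 22, 18, 20))
  d <- aggregate_day(sess)
  expect_equal(d$correct_response_rate, 0.65)
  expect_equal(d$n_sessions, 4)

  single <- aggregate_day(sess[2, ])
  expect_equal(single$rule_learning_rate, 0.7)

  sess$correct_response_rate[2] <- NA
  mixed <- aggregate_day(sess)
  expect_equal(mixed$correct_response_rate, mean(c(0.5, 0.7, 0.8)))
  expect_equal(mixed$n_defined_rates, 3L)

  expect_error(aggregate_day(sess[0, ]), "empty")
  sess$day <- c(1, 1, 2, 2)
  expect_error(aggregate_day(sess), "share")
})

test_that("session metrics apply the post-stim lap offset only when due", {
  set.seed(31)
  sim <- simulate_session(agent_params(kappa_stim = 1.5),
                          sim_config("CRL", "S", stim_condition = "post",
                                     stim_duration = "long_40ms"))
  laps <- segment_laps(sim$log)
  m_post <- session_metrics(laps)
  m_raw <- session_metrics(laps, apply_post_stim_rule = FALSE)
  expect_lte(m_post$n_laps_scored, m_raw$n_laps_scored)
  expect_equal(m_raw$n_laps_scored, m_raw$n_laps)
})
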