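#' Value-learning maze agent parameters
#'
#' The synthetic animal is a per-feeder Bernoulli-poke value learner:
#' it holds a value `V(f)` in `[0, 1]` for each feeder and, on each lap,
#' encounters the feeders in ring order and pokes feeder `f` with
#' probability `plogis(beta * (V(f) - poke_bias))`.  A poke at the
#' rewarded feeder delivers the reward and updates
#' `V(f) <- V(f) + alpha' * (1 - V(f))`; a poke at any other feeder
#' updates `V(f) <- V(f) + alpha' * (0 - V(f))`, with
#' `alpha' = alpha * kappa_stim` in sessions with active stimulation and
#' `alpha' = alpha` otherwise.  Independent per-feeder pokes (rather
#' than a single softmax choice) let multi-feeder laps occur, as real
#' exploratory nose-poking does.
#'
#' @param alpha value-learning rate in (0, 1).
#' @param beta choice steepness (>= 0).
#' @param poke_bias baseline poke propensity: the value level at which
#'   the poke probability is 0.5.
#' @param kappa_stim multiplicative learning-rate factor under
#'   stimulation (>= 1; 1 = no effect).
#' @param lap_rate laps initiated per minute (governs the inter-lap
#'   pause; low values push sessions against the 15-min bound).
#' @param speed_mean,speed_sd running speed (cm/s) for the
#'   sensor-to-feeder traverses.
#' @param v0 initial feeder value.
#' @return validated parameter list of class `agent_params`.
#' @export
agent_params <- function(alpha = 0.5, beta = 8, poke_bias = 0.35,
                         kappa_stim = 1, lap_rate = 3,
                         speed_mean = 20, speed_sd = 5, v0 = 0.25) {
  stopifnot(alpha > 0, alpha < 1, beta >= 0, kappa_stim >= 1,
            lap_rate > 0, speed_mean > 0, speed_sd >= 0,
            v0 >= 0, v0 <= 1)
  if (alpha * kappa_stim >= 1)
    stop("alpha * kappa_stim must stay below 1")
  structure(list(alpha = alpha, beta = beta, poke_bias = poke_bias,
                 kappa_stim = kappa_stim, lap_rate = lap_rate,
                 speed_mean = speed_mean, speed_sd = speed_sd, v0 = v0),
            class = "agent_params")
}

#' Simulation configuration for one session
#'
#' @param task `"FRL"` (fixed reward location) or `"CRL"` (changing
#'   reward location; the rewarded feeder is redrawn between sessions).
#' @param rewarded_feeder feeder label for this session.
#' @param stim_condition,stim_duration stimulation trigger and pulse
#'   width (see [session_log()]).
#' @param animal_id,day,session_index metadata.
#' @param max_laps,session_limit_s session bounds.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(task = c("FRL", "CRL"), rewarded_feeder = "N",
                       stim_condition = c("none", "pre", "post", "opposite"),
                       stim_duration = c("none", "short_10ms", "long_40ms"),
                       animal_id = "sim1", day = 1L, session_index = 1L,
                       max_laps = analysis_defaults()$max_laps,
                       session_limit_s = analysis_defaults()$session_limit_s) {
  structure(list(task = match.arg(task), rewarded_feeder = rewarded_feeder,
                 stim_condition = match.arg(stim_condition),
                 stim_duration = match.arg(stim_duration),
                 animal_id = animal_id, day = day,
                 session_index = session_index, max_laps = max_laps,
                 session_limit_s = session_limit_s),
            class = "sim_config")
}

# Feeder diametrically opposite a given one (by ring position).
opposite_feeder <- function(maze, feeder) {
  pos <- (maze$feeders[[feeder]] + maze$ring_length / 2) %% maze$ring_length
  names(maze$feeders)[which.min(abs(maze$feeders - pos))]
}

# One 1-s burst of 20-Hz pulses as stim_on/stim_off event pairs.
burst_events <- function(t0, stim_duration, burst_s = 1, freq_hz = 20) {
  pulse_s <- switch(stim_duration, short_10ms = 0.010, long_40ms = 0.040,
                    stop("no pulses for stim_duration 'none'"))
  on <- t0 + (seq_len(burst_s * freq_hz) - 1L) / freq_hz
  data.frame(t = as.vector(rbind(on, on + pulse_s)),
             device = "opto",
             kind = rep(c("stim_on", "stim_off"), times = length(on)))
}

#' Simulate one maze session
#'
#' Generates the full Arduino-style event stream of a session: a
#' `session_start`, beam crossings at every sensor in ring order with
#' traverse times from the agent's speed model, nose pokes and reward
#' deliveries from the value-learning policy, and stimulation pulse
#' pairs per the session's trigger condition (pre: at the rewarded
#' feeder's upstream sensor; post: at the rewarded poke; opposite: at
#' the opposite feeder's sensor).  The event stream is truncated at the
#' session time limit, and lap structure beyond the lap bound is left to
#' [segment_laps()] to enforce.
#'
#' @param agent an [agent_params()] object.
#' @param cfg a [sim_config()] object.
#' @param maze a [maze_config()].
#' @param V optional initial feeder-value vector (named by feeder),
#'   used to carry learning across sessions; defaults to `agent$v0`.
#' @return list with `log` (a [session_log()]), `V` (final values) and
#'   `truth` (per-lap data.frame of poked feeders and reward flags).
#' @export
simulate_session <- function(agent, cfg, maze = maze_config(), V = NULL) {
  stopifnot(inherits(agent, "agent_params"), inherits(cfg, "sim_config"))
  feeders <- names(maze$feeders)
  if (is.null(V)) V <- stats::setNames(rep(agent$v0, length(feeders)), feeders)
  stim_active <- cfg$stim_condition != "none"
  a_eff <- if (stim_active) agent$alpha * agent$kappa_stim else agent$alpha
  opp <- if (cfg$stim_condition == "opposite")
    opposite_feeder(maze, cfg$rewarded_feeder) else NA_character_

  # device tour in ring order from the boundary sensor
  bnd <- boundary_sensor(maze)
  ord <- order(ring_distance(maze$sensors[[bnd]], maze$sensors,
                             maze$ring_length))
  tour_feeders <- feeders[ord]
  limit <- cfg$session_limit_s
  # geometry: sensor -> feeder = offset; feeder -> next sensor = gap
  offs <- maze$sensor_offset_cm
  gaps <- vapply(seq_along(tour_feeders), function(i) {
    nxt <- tour_feeders[if (i == length(tour_feeders)) 1L else i + 1L]
    ring_distance(maze$feeders[[tour_feeders[i]]], maze$sensors[[nxt]],
                  maze$ring_length)
  }, numeric(1))

  ev_t <- 0; ev_d <- "maze"; ev_k <- "session_start"
  add <- function(t, d, k) {
    ev_t <<- c(ev_t, t); ev_d <<- c(ev_d, d); ev_k <<- c(ev_k, k)
  }
  clock <- 0
  truth <- list()
  n_complete <- 0L
  while (n_complete < cfg$max_laps && clock <= limit) {
    clock <- clock + stats::rexp(1, rate = agent$lap_rate / 60)
    lap_pokes <- character(0)
    lap_rewarded <- FALSE
    for (i in seq_along(tour_feeders)) {
      f <- tour_feeders[i]
      add(clock, maze$sensor_names[[f]], "beam_cross")
      if ((cfg$stim_condition == "pre" && f == cfg$rewarded_feeder) ||
          (cfg$stim_condition == "opposite" && f == opp)) {
        b <- burst_events(clock, cfg$stim_duration)
        for (j in seq_len(nrow(b))) add(b$t[j], b$device[j], b$kind[j])
      }
      v_leg <- max(stats::rnorm(1, agent$speed_mean, agent$speed_sd), 2)
      clock <- clock + offs / v_leg          # sensor -> feeder
      p_poke <- stats::plogis(agent$beta * (V[[f]] - agent$poke_bias))
      if (stats::runif(1) < p_poke) {
        n_pokes <- 1L + stats::rbinom(1, 1, 0.25)
        for (q in seq_len(n_pokes)) {
          add(clock, f, "nose_poke")         # first poke right at arrival
          if (f == cfg$rewarded_feeder) {
            if (!lap_rewarded) {
              add(clock + 0.1, f, "reward_delivered")
              if (cfg$stim_condition == "post") {
                b <- burst_events(clock + 0.1, cfg$stim_duration)
                for (j in seq_len(nrow(b))) add(b$t[j], b$device[j], b$kind[j])
              }
              lap_rewarded <- TRUE
              clock <- clock + 2            # consume the pellet
            }
            V[[f]] <- V[[f]] + a_eff * (1 - V[[f]])
          } else {
            V[[f]] <- V[[f]] + a_eff * (0 - V[[f]])
          }
          clock <- clock + stats::runif(1, 0.3, 0.8)   # handling time
        }
        lap_pokes <- c(lap_pokes, rep(f, n_pokes))
      }
      v_leg2 <- max(stats::rnorm(1, agent$speed_mean, agent$speed_sd), 2)
      clock <- clock + gaps[i] / v_leg2      # feeder -> next sensor
    }
    # closing boundary crossing of the lap
    if (clock <= limit) {
      n_complete <- n_complete + 1L
      truth[[n_complete]] <- data.frame(
        lap = n_complete,
        pokes = I(list(lap_pokes)), rewarded = lap_rewarded)
      if (n_complete == cfg$max_laps) add(clock, maze$sensor_names[[bnd]],
                                          "beam_cross")
    }
  }
  events <- data.frame(t = ev_t, device = ev_d, kind = ev_k)
  events <- events[order(events$t), ]
  events <- events[events$t <= limit, ]
  log <- session_log(events, animal_id = cfg$animal_id, day = cfg$day,
                     session_index = cfg$session_index, task = cfg$task,
                     rewarded_feeder = cfg$rewarded_feeder,
                     stim_condition = cfg$stim_condition,
                     stim_duration = cfg$stim_duration, maze = maze)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(lap = integer(), pokes = I(list()), rewarded = logical())
  list(log = log, V = V, truth = truth)
}

#' Group parameter presets for cohort simulation
#'
#' Control animals use the default agent; the lesioned preset models
#' catecholamine-deficient animals (slower learning, fewer lap starts,
#' halved running speed); the stimulated preset models long-duration
#' burst stimulation boosting the learning rate.
#'
#' @param group one of `"control"`, `"lesioned"`, `"stimulated"`.
#' @param base the control [agent_params()].
#' @param lesion_alpha_factor,lesion_lap_rate_factor,lesion_speed_factor
#'   multiplicative deficits of the lesioned preset.
#' @param kappa_stim learning-rate factor of the stimulated preset.
#' @return an [agent_params()] object.
#' @export
group_preset <- function(group = c("control", "lesioned", "stimulated"),
                         base = agent_params(),
                         lesion_alpha_factor = 0.5,
                         lesion_lap_rate_factor = 0.3,
                         lesion_speed_factor = 0.5,
                         kappa_stim = 1.9) {
  group <- match.arg(group)
  switch(group,
         control = base,
         lesioned = agent_params(alpha = base$alpha * lesion_alpha_factor,
                                 beta = base$beta,
                                 poke_bias = base$poke_bias,
                                 lap_rate = base$lap_rate *
                                   lesion_lap_rate_factor,
                                 speed_mean = base$speed_mean *
                                   lesion_speed_factor,
                                 speed_sd = base$speed_sd *
                                   lesion_speed_factor,
                                 v0 = base$v0),
         stimulated = agent_params(alpha = base$alpha, beta = base$beta,
                                   poke_bias = base$poke_bias,
                                   kappa_stim = kappa_stim,
                                   lap_rate = base$lap_rate,
                                   speed_mean = base$speed_mean,
                                   speed_sd = base$speed_sd, v0 = base$v0))
}

#' Simulate a multi-day cohort
#'
#' Runs `days * sessions_per_day` sessions per animal, carrying each
#' animal's feeder values across sessions.  In the CRL task the
#' rewarded feeder is redrawn for every session, uniformly among the
#' feeders other than the previous one (the location always shifts,
#' with no association preserved); in FRL it is fixed.
#'
#' @param groups named list: group label -> list with `agent` (an
#'   [agent_params()]), `n` (animals), and optionally `stim_condition`
#'   and `stim_duration`.
#' @param days,sessions_per_day cohort timeline (default 4 sessions per
#'   day).
#' @param task `"FRL"` or `"CRL"`.
#' @param maze a [maze_config()].
#' @param seed integer seed; all randomness flows from it.
#' @return list with `logs` (list of [session_log()]s) and `sessions`
#'   (data.frame: animal_id, group, day, session_index,
#'   rewarded_feeder, log index).
#' @export
simulate_experiment <- function(groups, days = 5, sessions_per_day = 4,
                                task = c("FRL", "CRL"),
                                maze = maze_config(), seed = NULL) {
  task <- match.arg(task)
  if (!is.null(seed)) set.seed(seed)
  feeders <- names(maze$feeders)
  logs <- list()
  rows <- list()
  for (gname in names(groups)) {
    gspec <- groups[[gname]]
    stim_condition <- gspec$stim_condition %||% "none"
    stim_duration <- gspec$stim_duration %||%
      (if (stim_condition == "none") "none" else "long_40ms")
    for (a in seq_len(gspec$n)) {
      animal <- sprintf("%s_%02d", gname, a)
      V <- NULL
      rewarded <- sample(feeders, 1)
      for (d in seq_len(days)) {
        for (s in seq_len(sessions_per_day)) {
          if (task == "CRL" && !(d == 1 && s == 1))
            rewarded <- sample(setdiff(feeders, rewarded), 1)
          cfg <- sim_config(task = task, rewarded_feeder = rewarded,
                            stim_condition = stim_condition,
                            stim_duration = stim_duration,
                            animal_id = animal, day = d, session_index = s)
          sim <- simulate_session(gspec$agent, cfg, maze = maze, V = V)
          V <- sim$V
          logs[[length(logs) + 1L]] <- sim$log
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = animal, group = gname, day = d, session_index = s,
            rewarded_feeder = rewarded, log = length(logs))
        }
      }
    }
  }
  list(logs = logs, sessions = do.call(rbind, rows))
}

#' Photometry response model
#'
#' Shape of the stimulation-evoked transient added to a constant
#' baseline with Gaussian noise.  The double-exponential kernel rises
#' during the 1-s burst and decays afterwards; the built-in presets
#' encode the qualitative sensor-by-duration pattern: calcium
#' (GCaMP6f) responses to long 40-ms-pulse bursts are larger and
#' sustained, short 10-ms-pulse bursts smaller and transient; dopamine
#' (GRAB_DA2h) responses are transient for both durations.
#'
#' @param sensor_kind `"GCaMP6f"` or `"GRAB_DA2h"`.
#' @param duration `"short_10ms"` or `"long_40ms"`.
#' @param amplitude_pct peak response in percent of baseline.
#' @param rise_s,decay_s kernel time constants.
#' @param baseline,noise_sd raw-signal baseline level and noise SD
#'   (arbitrary units).
#' @param shape `"double_exp"` or `"square"` (amplitude held for the
#'   burst, zero after — useful for closed-form checks).
#' @return list of class `photo_model`.
#' @export
photo_model <- function(sensor_kind = c("GCaMP6f", "GRAB_DA2h"),
                        duration = c("long_40ms", "short_10ms"),
                        amplitude_pct = NULL, rise_s = 0.1, decay_s = NULL,
                        baseline = 100, noise_sd = 1,
                        shape = c("double_exp", "square")) {
  sensor_kind <- match.arg(sensor_kind)
  duration <- match.arg(duration)
  shape <- match.arg(shape)
  preset <- list(
    GCaMP6f.long_40ms   = list(amp = 12, decay = 4.0),
    GCaMP6f.short_10ms  = list(amp = 5,  decay = 1.0),
    GRAB_DA2h.long_40ms = list(amp = 8,  decay = 1.0),
    GRAB_DA2h.short_10ms = list(amp = 4, decay = 0.8)
  )[[paste(sensor_kind, duration, sep = ".")]]
  amplitude_pct <- amplitude_pct %||% preset$amp
  decay_s <- decay_s %||% preset$decay
  stopifnot(amplitude_pct >= 0, decay_s > 0, rise_s > 0, baseline > 0,
            noise_sd >= 0)
  structure(list(sensor_kind = sensor_kind, duration = duration,
                 amplitude_pct = amplitude_pct, rise_s = rise_s,
                 decay_s = decay_s, baseline = baseline,
                 noise_sd = noise_sd, shape = shape),
            class = "photo_model")
}

#' Stimulation protocol for photometry simulation
#'
#' Repeated cycles of a 1-s burst of 20-Hz pulses followed by rest: the
#' default is the 30-min protocol of 10-s cycles, i.e. 180 stimulation
#' sessions.
#'
#' @param total_min,cycle_s,stim_s,freq_hz protocol constants.
#' @param fs photometry sampling rate (samples/s).
#' @param lead_in_s quiet time before the first onset.
#' @return list of class `stim_protocol` with `onsets`.
#' @export
stim_protocol <- function(total_min = 30, cycle_s = 10, stim_s = 1,
                          freq_hz = 20, fs = 100, lead_in_s = 2) {
  n <- stim_session_count(total_min, cycle_s)
  structure(list(total_min = total_min, cycle_s = cycle_s, stim_s = stim_s,
                 freq_hz = freq_hz, fs = fs, lead_in_s = lead_in_s,
                 n_sessions = n,
                 onsets = lead_in_s + cycle_s * (seq_len(n) - 1L)),
            class = "stim_protocol")
}

#' Simulate a photometry trace under burst stimulation
#'
#' 100-Hz trace = baseline + Gaussian noise + response kernel placed at
#' each stimulation onset.
#'
#' @param model a [photo_model()].
#' @param protocol a [stim_protocol()].
#' @param seed optional integer seed.
#' @return list with `t`, `R`, `onsets`, `fs`, `model`, `protocol`;
#'   directly consumable by [compute_peth()].
#' @export
simulate_photometry <- function(model, protocol = stim_protocol(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dur <- protocol$lead_in_s + protocol$cycle_s * protocol$n_sessions
  t <- seq(0, dur, by = 1 / protocol$fs)
  R <- model$baseline + stats::rnorm(length(t), 0, model$noise_sd)
  amp_raw <- model$amplitude_pct / 100 * model$baseline
  kernel <- function(s) {       # s >= 0, response in raw units
    if (model$shape == "square")
      return(ifelse(s < protocol$stim_s, amp_raw, 0))
    rise <- 1 - exp(-pmin(s, protocol$stim_s) / model$rise_s)
    decay <- exp(-pmax(s - protocol$stim_s, 0) / model$decay_s)
    amp_raw * rise * decay
  }
  for (on in protocol$onsets) {
    idx <- which(t >= on & t < on + protocol$cycle_s)
    R[idx] <- R[idx] + kernel(t[idx] - on)
  }
  list(t = t, R = R, onsets = protocol$onsets, fs = protocol$fs,
       model = model, protocol = protocol)
}

#' Three-state Markov speed model for pose simulation
#'
#' Generates alternating ambulation / immobility / fine-movement bouts
#' with per-state speed distributions chosen well clear of the 2 cm/s
#' classification threshold, and dwell times long for the two major
#' states so that boundary effects stay small.  Fine-movement bouts are
#' brief (under the 1-s immobility minimum) and occur between
#' ambulation bouts, as brief pauses with residual head movement.
#'
#' @param speed_mean,speed_sd named vectors over
#'   `ambulation`/`immobility`/`fine_movement` (cm/s).
#' @param dwell_mean_s named dwell means; fine-movement dwells are drawn
#'   uniform on `fine_dwell_range_s`.
#' @param p_amb_to_fine probability that an ambulation bout is followed
#'   by fine movement rather than immobility.
#' @param fine_dwell_range_s range of fine-movement dwells (s).
#' @return list of class `pose_state_model`.
#' @export
pose_state_model <- function(speed_mean = c(ambulation = 5,
                                            immobility = 0.1,
                                            fine_movement = 1.2),
                             speed_sd = c(ambulation = 1,
                                          immobility = 0.05,
                                          fine_movement = 0.2),
                             dwell_mean_s = c(ambulation = 20,
                                              immobility = 20),
                             p_amb_to_fine = 0.2,
                             fine_dwell_range_s = c(0.4, 0.8)) {
  structure(list(speed_mean = speed_mean, speed_sd = speed_sd,
                 dwell_mean_s = dwell_mean_s,
                 p_amb_to_fine = p_amb_to_fine,
                 fine_dwell_range_s = fine_dwell_range_s),
            class = "pose_state_model")
}

#' Simulate an open-field pose track
#'
#' Integrates neck-point positions from a three-state Markov speed
#' model inside a circular arena (diameter 31 cm), with a random-walk
#' heading reflected at the wall.  The ground-truth state of every
#' frame interval is returned alongside for recovery tests.
#'
#' @param model a [pose_state_model()], or a single-state list
#'   `list(constant = v)` for a constant-speed track.
#' @param duration_s,fps track length and frame rate.
#' @param arena_diam_cm arena diameter.
#' @param seed optional integer seed.
#' @return list with `track` (data.frame `frame`, `t`, `x`, `y`),
#'   `states` (factor per frame interval), `occupancy` (ground-truth
#'   fractions) and `model`.
#' @export
simulate_pose <- function(model = pose_state_model(), duration_s = 1800,
                          fps = 30, arena_diam_cm = 31, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration_s * fps))   # frame intervals
  if (!is.null(model$constant)) {
    states <- rep("constant", n)
    v <- rep(model$constant, n)
  } else {
    states <- character(0)
    st <- "ambulation"
    while (length(states) < n) {
      dwell <- switch(st,
        ambulation = stats::rgamma(1, shape = 2,
                                   scale = model$dwell_mean_s[["ambulation"]] / 2),
        immobility = stats::rgamma(1, shape = 2,
                                   scale = model$dwell_mean_s[["immobility"]] / 2),
        fine_movement = stats::runif(1, model$fine_dwell_range_s[1],
                                     model$fine_dwell_range_s[2]))
      k <- max(1L, as.integer(round(dwell * fps)))
      states <- c(states, rep(st, k))
      st <- switch(st,
        ambulation = if (stats::runif(1) < model$p_amb_to_fine)
          "fine_movement" else "immobility",
        fine_movement = "ambulation",
        immobility = "ambulation")
    }
    states <- states[seq_len(n)]
    v <- stats::rnorm(n, model$speed_mean[states], model$speed_sd[states])
    lo <- c(ambulation = 2.5, immobility = 0, fine_movement = 0.3)
    hi <- c(ambulation = Inf, immobility = 1.0, fine_movement = 1.9)
    v <- pmin(pmax(v, lo[states]), hi[states])
  }
  r_max <- arena_diam_cm / 2 - 1
  x <- numeric(n + 1); y <- numeric(n + 1)
  theta <- stats::runif(1, 0, 2 * pi)
  for (i in seq_len(n)) {
    theta <- theta + stats::rnorm(1, 0, 0.3)
    step <- v[i] / fps
    nx <- x[i] + step * cos(theta)
    ny <- y[i] + step * sin(theta)
    if (nx^2 + ny^2 > r_max^2) {           # turn toward the centre
      theta <- atan2(-y[i], -x[i]) + stats::rnorm(1, 0, 0.2)
      nx <- x[i] + step * cos(theta)
      ny <- y[i] + step * sin(theta)
    }
    x[i + 1] <- nx; y[i + 1] <- ny
  }
  frame <- 0:n
  track <- data.frame(frame = frame, t = frame / fps, x = x, y = y)
  attr(track, "fps") <- fps
  states <- factor(states, levels = unique(c("ambulation", "immobility",
                                             "fine_movement", states)))
  occ <- table(states) / n
  list(track = track, states = states,
       occupancy = stats::setNames(as.numeric(occ), names(occ)),
       model = model)
}
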