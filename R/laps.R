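#' Segment a session log into laps
#'
#' A lap is delimited by successive beam crossings of the boundary sensor
#' — the first sensor reached from the start position in the run
#' direction.  The session is bounded by whichever comes first: the
#' configured number of complete laps (default 10) or the session time
#' limit (default 900 s = 15 min) measured from the `session_start`
#' event.  A lap still in progress when the session is truncated is
#' returned with `complete = FALSE`; downstream metrics exclude
#' incomplete laps by default.
#'
#' Nose pokes are assigned to the lap whose time interval encloses them;
#' pokes before the first boundary crossing or after truncation belong to
#' no lap and are reported in the attributes (conservation is checked in
#' the test-suite, not silently assumed).
#'
#' @param log a [session_log()].
#' @param maze the [maze_config()].
#' @param max_laps,session_limit_s session bounds.
#' @return An object of class `maze_laps`: a list of laps, each a list
#'   with `index`, `t_start`, `t_end`, `complete`, `rewarded`, `pokes`
#'   (data.frame `feeder`, `t`) and `sensor_cross` (named vector, time of
#'   each feeder's upstream-sensor crossing within the lap, NA if
#'   absent).  Attributes: `rewarded_feeder`, `feeder_labels`,
#'   `n_pokes_unassigned`, `t0`, `order_violations` (count of
#'   out-of-ring-order sensor sequences, flagged but not rejected).
#' @export
segment_laps <- function(log, maze = maze_config(),
                         max_laps = analysis_defaults()$max_laps,
                         session_limit_s = analysis_defaults()$session_limit_s) {
  ev <- log$events
  i0 <- which(ev$kind == "session_start")
  if (!length(i0))
    stop("session log has no session_start event")
  t0 <- ev$t[i0[1]]
  bnd_feeder <- boundary_sensor(maze)
  bnd_device <- maze$sensor_names[[bnd_feeder]]
  cross_t <- ev$t[ev$kind == "beam_cross" & ev$device == bnd_device &
                    ev$t >= t0]

  pokes <- ev[ev$kind == "nose_poke", c("t", "device")]
  names(pokes) <- c("t", "feeder")
  rewards_t <- ev$t[ev$kind == "reward_delivered"]
  sensor_feeder <- stats::setNames(names(maze$sensor_names),
                                   unname(maze$sensor_names))

  make_lap <- function(idx, t_start, t_end, complete) {
    lp <- pokes[pokes$t >= t_start & pokes$t < t_end, , drop = FALSE]
    rownames(lp) <- NULL
    sc <- ev[ev$kind == "beam_cross" & ev$t >= t_start & ev$t < t_end, ]
    cross_map <- stats::setNames(rep(NA_real_, length(maze$feeders)),
                                 names(maze$feeders))
    for (f in names(maze$feeders)) {
      tt <- sc$t[sc$device == maze$sensor_names[[f]]]
      if (length(tt)) cross_map[[f]] <- tt[1]
    }
    list(index = idx, t_start = t_start, t_end = t_end, complete = complete,
         rewarded = any(rewards_t >= t_start & rewards_t < t_end),
         pokes = lp, sensor_cross = cross_map)
  }

  laps <- list()
  truncated <- FALSE
  if (length(cross_t) >= 2) {
    for (k in seq_len(length(cross_t) - 1L)) {
      if (length(laps) >= max_laps) { truncated <- TRUE; break }
      complete <- (cross_t[k + 1L] - t0) <= session_limit_s
      laps[[length(laps) + 1L]] <-
        make_lap(length(laps) + 1L, cross_t[k], cross_t[k + 1L], complete)
      if (!complete) { truncated <- TRUE; break }
    }
  }
  # in-progress tail lap after the last closing crossing, unless the
  # session was already truncated by the lap count or the time limit
  if (!truncated && length(cross_t) >= 1 && length(laps) < max_laps) {
    t_start <- cross_t[length(cross_t)]
    t_end <- min(max(ev$t), t0 + session_limit_s)
    if (t_end > t_start)
      laps[[length(laps) + 1L]] <-
        make_lap(length(laps) + 1L, t_start, t_end, FALSE)
  }
  # sensor order check: within each lap, crossings should follow ring order
  violations <- 0L
  for (lap in laps) {
    tt <- lap$sensor_cross[!is.na(lap$sensor_cross)]
    if (length(tt) >= 2) {
      pos <- ring_distance(maze$start_position,
                           maze$sensors[names(tt)], maze$ring_length)
      if (is.unsorted(tt[order(pos)])) violations <- violations + 1L
    }
  }
  n_in_laps <- sum(vapply(laps, function(l) nrow(l$pokes), integer(1)))
  structure(laps,
            class = "maze_laps",
            rewarded_feeder = log$rewarded_feeder,
            feeder_labels = names(maze$feeders),
            stim_condition = log$stim_condition,
            n_pokes_unassigned = nrow(pokes) - n_in_laps,
            t0 = t0,
            order_violations = violations)
}

#' Keep only complete laps
#'
#' @param laps a `maze_laps` object.
#' @return The same object restricted to laps with `complete = TRUE`.
#' @export
complete_laps <- function(laps) {
  keep <- vapply(laps, function(l) isTRUE(l$complete), logical(1))
  out <- laps[keep]
  attributes(out) <- c(attributes(out),
                       attributes(laps)[setdiff(names(attributes(laps)),
                                                c("names", "class"))])
  class(out) <- "maze_laps"
  out
}

#' @export
print.maze_laps <- function(x, ...) {
  n_complete <- sum(vapply(x, function(l) isTRUE(l$complete), logical(1)))
  cat(sprintf("Lap segmentation: %d laps (%d complete), rewarded feeder %s\n",
              length(x), n_complete, attr(x, "rewarded_feeder")))
  invisible(x)
}
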