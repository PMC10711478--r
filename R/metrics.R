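#' Per-lap feeder choices
#'
#' For each complete lap, the set of distinct feeders the animal poked.
#' A lap is *correct* when that set is exactly the rewarded feeder; it
#' satisfies the *rule* when exactly one feeder (any feeder) was chosen.
#' Correct therefore implies rule; a lap with no pokes satisfies neither.
#' Poke multiplicity is ignored — "chose" means at least one nose poke.
#'
#' @param laps a `maze_laps` object (incomplete laps are dropped).
#' @param rewarded_feeder feeder label; defaults to the one recorded in
#'   the lap segmentation.
#' @return data.frame with one row per complete lap: `lap_index`,
#'   `feeders` (comma-joined distinct labels), `n_distinct`,
#'   `is_correct`, `is_rule`.
#' @export
lap_choices <- function(laps, rewarded_feeder = attr(laps, "rewarded_feeder")) {
  labels <- attr(laps, "feeder_labels")
  if (!rewarded_feeder %in% labels)
    stop("unknown rewarded feeder: ", rewarded_feeder)
  laps <- complete_laps(laps)
  rows <- lapply(laps, function(l) {
    fs <- unique(l$pokes$feeder)
    bad <- setdiff(fs, labels)
    if (length(bad))
      stop("unknown feeder label in pokes: ", paste(bad, collapse = ", "))
    data.frame(lap_index = l$index,
               feeders = paste(sort(fs), collapse = ","),
               n_distinct = length(fs),
               is_correct = length(fs) == 1 && fs == rewarded_feeder,
               is_rule = length(fs) == 1)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lap_index = integer(), feeders = character(),
               n_distinct = integer(), is_correct = logical(),
               is_rule = logical())
  rownames(out) <- NULL
  out
}

#' Correct-response and rule-learning rates of a session
#'
#' The correct response rate is the number of laps in which only the
#' reward-providing feeder was chosen, divided by the total number of
#' laps; the rule learning rate is the number of laps in which exactly
#' one of the four feeders was chosen (rewarded or not), divided by the
#' total number of laps.  Laps with no pokes count in the denominator
#' only.
#'
#' @param choices output of [lap_choices()].
#' @return list with `correct_response_rate`, `rule_learning_rate`,
#'   `n_laps`.
#' @export
session_rates <- function(choices) {
  n <- nrow(choices)
  if (n == 0)
    stop("rates undefined: session has no complete laps")
  list(correct_response_rate = sum(choices$is_correct) / n,
       rule_learning_rate = sum(choices$is_rule) / n,
       n_laps = n)
}

#' Per-lap running speed toward the reward
#'
#' Speed over the fixed distance between a feeder's upstream sensor and
#' the feeder itself (15 cm): `distance / (t_poke - t_cross)`, using the
#' first poke at the rewarded feeder after its sensor crossing within
#' each complete lap.  Laps missing either event are skipped; laps where
#' the poke does not follow the crossing are flagged invalid and
#' excluded.
#'
#' @param laps a `maze_laps` object.
#' @param rewarded_feeder feeder label.
#' @param distance_cm sensor-to-feeder distance.
#' @return numeric vector of speeds (cm/s), one per usable lap, with
#'   attributes `n_skipped` and `n_invalid`.
#' @export
running_speeds <- function(laps,
                           rewarded_feeder = attr(laps, "rewarded_feeder"),
                           distance_cm = analysis_defaults()$sensor_offset_cm) {
  laps <- complete_laps(laps)
  speeds <- numeric(0)
  n_skipped <- 0L
  n_invalid <- 0L
  for (l in laps) {
    t_cross <- l$sensor_cross[[rewarded_feeder]]
    pk <- l$pokes$t[l$pokes$feeder == rewarded_feeder]
    if (is.na(t_cross) || !length(pk)) { n_skipped <- n_skipped + 1L; next }
    pk_after <- pk[pk > t_cross]
    if (!length(pk_after)) { n_invalid <- n_invalid + 1L; next }
    speeds <- c(speeds, distance_cm / (pk_after[1] - t_cross))
  }
  structure(speeds, n_skipped = n_skipped, n_invalid = n_invalid)
}

#' Drop laps up to and including the first rewarded lap
#'
#' Under post-reward stimulation the rates are computed starting from the
#' lap following the first reward acquisition, so that every scored lap
#' was preceded by at least one stimulation.  Returns the suffix of the
#' lap sequence after the first lap on which a reward was delivered; if
#' no reward was ever delivered, returns an empty lap list with a
#' warning.
#'
#' @param laps a `maze_laps` object.
#' @return a `maze_laps` object (suffix of the input).
#' @export
post_stim_filter <- function(laps) {
  rewarded <- vapply(laps, function(l) isTRUE(l$rewarded), logical(1))
  at <- attributes(laps)
  if (!any(rewarded)) {
    warning("no reward delivered in session; post-stim filter returns no laps")
    out <- laps[0]
  } else {
    out <- laps[seq_along(laps) > which(rewarded)[1]]
  }
  attributes(out) <- c(attributes(out),
                       at[setdiff(names(at), c("names", "class"))])
  class(out) <- "maze_laps"
  out
}

#' Session-level behavioral metrics
#'
#' Convenience wrapper computing rates, lap count and running speeds for
#' one session.  For post-stim sessions the lap sequence is first passed
#' through [post_stim_filter()].
#'
#' @param laps a `maze_laps` object from [segment_laps()].
#' @param apply_post_stim_rule apply the post-reward lap offset; defaults
#'   to TRUE exactly when the session's stimulation condition is "post".
#' @return one-row data.frame: `correct_response_rate`,
#'   `rule_learning_rate` (NA when no laps), `n_laps` (complete laps
#'   before any offset), `n_laps_scored`, `mean_speed_cm_s`, `n_speeds`.
#' @export
session_metrics <- function(laps,
                            apply_post_stim_rule =
                              identical(attr(laps, "stim_condition"), "post")) {
  n_laps <- length(complete_laps(laps))
  speeds <- running_speeds(laps)
  scored <- if (apply_post_stim_rule && n_laps > 0)
    suppressWarnings(post_stim_filter(laps)) else laps
  ch <- lap_choices(scored)
  if (nrow(ch) > 0) {
    r <- session_rates(ch)
    correct <- r$correct_response_rate
    rule <- r$rule_learning_rate
  } else {
    correct <- NA_real_
    rule <- NA_real_
  }
  data.frame(correct_response_rate = correct,
             rule_learning_rate = rule,
             n_laps = n_laps,
             n_laps_scored = nrow(ch),
             mean_speed_cm_s = if (length(speeds)) mean(speeds) else NA_real_,
             n_speeds = length(speeds))
}

#' Average session metrics within a day
#'
#' Four sessions are run per day; day-level values are the unweighted
#' arithmetic means of the session values for one subject.  Sessions
#' with an undefined rate (no scored laps) are excluded from that
#' field's mean only.
#'
#' @param sessions data.frame with one row per session, containing at
#'   least the columns produced by [session_metrics()] plus `animal_id`
#'   and `day` (all rows must share both).
#' @return one-row data.frame of day-level means with `n_sessions` and
#'   per-field `n_defined_*` counts.
#' @export
aggregate_day <- function(sessions) {
  if (!nrow(sessions))
    stop("aggregate_day: empty session table")
  if (length(unique(sessions$animal_id)) != 1 ||
      length(unique(sessions$day)) != 1)
    stop("aggregate_day: sessions must share animal_id and day")
  mean_def <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  data.frame(animal_id = sessions$animal_id[1],
             day = sessions$day[1],
             n_sessions = nrow(sessions),
             correct_response_rate = mean_def(sessions$correct_response_rate),
             rule_learning_rate = mean_def(sessions$rule_learning_rate),
             n_laps = mean_def(sessions$n_laps),
             mean_speed_cm_s = mean_def(sessions$mean_speed_cm_s),
             n_defined_rates = sum(!is.na(sessions$correct_response_rate)),
             n_defined_speeds = sum(!is.na(sessions$mean_speed_cm_s)))
}
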