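#' Session event log
#'
#' A session log couples session metadata (animal, day, session index,
#' task, rewarded feeder, stimulation condition) with the time-ordered
#' event stream recorded on the maze: beam crossings at the infrared
#' sensors, nose pokes and reward deliveries at the feeders, and
#' stimulation pulse edges.
#'
#' @param events data.frame with columns `t` (seconds, nondecreasing),
#'   `device` (sensor or feeder label) and `kind` (one of
#'   `session_start`, `beam_cross`, `nose_poke`, `reward_delivered`,
#'   `stim_on`, `stim_off`).
#' @param animal_id,day,session_index,task,rewarded_feeder,stim_condition,stim_duration
#'   session metadata; `task` is `"FRL"` (fixed reward location) or
#'   `"CRL"` (changing reward location); `stim_condition` one of `none`,
#'   `pre`, `post`, `opposite`; `stim_duration` one of `none`,
#'   `short_10ms`, `long_40ms`.
#' @param maze the [maze_config()] the log was recorded on, used to
#'   validate device labels.
#' @return An object of class `session_log`.
#' @export
session_log <- function(events, animal_id, day, session_index,
                        task = c("FRL", "CRL"),
                        rewarded_feeder,
                        stim_condition = c("none", "pre", "post", "opposite"),
                        stim_duration = c("none", "short_10ms", "long_40ms"),
                        maze = maze_config()) {
  task <- match.arg(task)
  stim_condition <- match.arg(stim_condition)
  stim_duration <- match.arg(stim_duration)
  if (stim_condition == "none" && stim_duration != "none")
    stop("stim_duration must be 'none' when stim_condition is 'none'")
  if (stim_condition != "none" && stim_duration == "none")
    stop("stim_duration required when stim_condition is set")
  if (!rewarded_feeder %in% names(maze$feeders))
    stop("unknown rewarded_feeder: ", rewarded_feeder)
  events <- validate_events(events, maze)
  structure(
    list(animal_id = animal_id, day = day, session_index = session_index,
         task = task, rewarded_feeder = rewarded_feeder,
         stim_condition = stim_condition, stim_duration = stim_duration,
         events = events),
    class = "session_log")
}

event_kinds <- c("session_start", "beam_cross", "nose_poke",
                 "reward_delivered", "stim_on", "stim_off")

validate_events <- function(events, maze) {
  stopifnot(is.data.frame(events),
            all(c("t", "device", "kind") %in% names(events)))
  events <- events[, c("t", "device", "kind")]
  events$t <- as.numeric(events$t)
  events$device <- as.character(events$device)
  events$kind <- as.character(events$kind)
  if (any(is.na(events$t)) || any(events$t < 0))
    stop("event times must be finite and >= 0")
  bad <- which(diff(events$t) < 0)
  if (length(bad))
    stop(sprintf("non-monotonic timestamp at event %d (t=%g after t=%g)",
                 bad[1] + 1L, events$t[bad[1] + 1L], events$t[bad[1]]))
  unknown <- setdiff(unique(events$kind), event_kinds)
  if (length(unknown))
    stop("unknown event kind: ", paste(unknown, collapse = ", "))
  feeder_labels <- names(maze$feeders)
  sensor_labels <- unname(maze$sensor_names)
  dev_ok <- rep(TRUE, nrow(events))
  dev_ok[events$kind == "beam_cross"] <-
    events$device[events$kind == "beam_cross"] %in% sensor_labels
  poke_like <- events$kind %in% c("nose_poke", "reward_delivered")
  dev_ok[poke_like] <- events$device[poke_like] %in% feeder_labels
  if (!all(dev_ok)) {
    i <- which(!dev_ok)[1]
    stop(sprintf("event %d: device '%s' not valid for kind '%s'",
                 i, events$device[i], events$kind[i]))
  }
  rownames(events) <- NULL
  events
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("Session log: animal %s, day %s, session %s (%s)\n",
              x$animal_id, x$day, x$session_index, x$task))
  cat(sprintf("  rewarded feeder %s; stim %s/%s; %d events over %.1f s\n",
              x$rewarded_feeder, x$stim_condition, x$stim_duration,
              nrow(x$events), diff(range(x$events$t))))
  invisible(x)
}

#' Read / write maze session logs
#'
#' Logs are comma-separated text with a metadata header of `#key: value`
#' lines (keys `animal_id`, `day`, `session_index`, `task`,
#' `rewarded_feeder`, `stim_condition`, `stim_duration`) followed by a
#' `t,device,kind` table, one event per row, times in seconds.
#'
#' @param path file path.
#' @param maze [maze_config()] used to validate device labels.
#' @return `read_session_log()`: a [session_log()].
#' @export
read_session_log <- function(path, maze = maze_config()) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- list()
  for (ln in lines[meta_idx]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  required <- c("animal_id", "day", "session_index", "task",
                "rewarded_feeder", "stim_condition", "stim_duration")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("session log '", path, "': missing metadata ",
         paste(missing, collapse = ", "))
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  body <- body[nzchar(trimws(body))]
  events <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  if (!all(c("t", "device", "kind") %in% names(events)))
    stop("session log '", path, "': expected header t,device,kind")
  session_log(events,
              animal_id = meta$animal_id,
              day = as.integer(meta$day),
              session_index = as.integer(meta$session_index),
              task = meta$task,
              rewarded_feeder = meta$rewarded_feeder,
              stim_condition = meta$stim_condition,
              stim_duration = meta$stim_duration,
              maze = maze)
}

#' @rdname read_session_log
#' @param log a [session_log()].
#' @return `write_session_log()`: `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  meta <- c(animal_id = log$animal_id, day = log$day,
            session_index = log$session_index, task = log$task,
            rewarded_feeder = log$rewarded_feeder,
            stim_condition = log$stim_condition,
            stim_duration = log$stim_duration)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s: %s", names(meta), meta), con)
  ev <- log$events
  ev$t <- format(ev$t, digits = 15, scientific = FALSE, trim = TRUE)
  utils::write.csv(ev, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
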