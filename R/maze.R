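#' Maze geometry configuration
#'
#' Describes the circular track: an ordered set of segments forming a ring,
#' four feeding stations labelled by compass direction, and one infrared
#' beam-break sensor per feeder placed a fixed distance upstream of it in
#' the run direction.  The default geometry is the eight-path maze: eight
#' 40-cm segments (320 cm ring), feeders at N/E/S/W, sensors 15 cm before
#' each feeder, clockwise running, start line at position 0.
#'
#' Track coordinates are cm clockwise from the start position on the
#' half-open ring `[0, ring_length)`.
#'
#' @param segments numeric vector of segment lengths in cm, in ring order.
#' @param feeders named numeric vector: feeder label -> track position (cm).
#' @param sensor_offset_cm distance from each sensor to its feeder along
#'   the run direction (cm).
#' @param start_position start-line position (cm).
#' @param run_direction currently only `"clockwise"`.
#' @return An object of class `maze_config`: a list with the fields above
#'   plus `ring_length`, `sensors` (named vector of sensor positions) and
#'   `sensor_names` (named map feeder label -> sensor device label).
#' @examples
#' mz <- maze_config()
#' mz$ring_length           # 320
#' mz$sensors[["N"]]        # 25 = feeder N at 40 minus 15 cm offset
#' @export
maze_config <- function(segments = rep(40, 8),
                        feeders = c(N = 40, E = 120, S = 200, W = 280),
                        sensor_offset_cm = analysis_defaults()$sensor_offset_cm,
                        start_position = 0,
                        run_direction = "clockwise") {
  if (!is.numeric(segments) || length(segments) < 1 || any(segments <= 0))
    stop("invalid field 'segments': must be positive lengths")
  ring_length <- sum(segments)
  if (is.null(names(feeders)) || anyDuplicated(names(feeders)))
    stop("invalid field 'feeders': labels must be unique and named")
  if (!is.numeric(feeders) || any(feeders < 0) || any(feeders >= ring_length))
    stop("invalid field 'feeders': positions must lie in [0, ring_length)")
  if (!is.numeric(sensor_offset_cm) || sensor_offset_cm <= 0 ||
      sensor_offset_cm >= ring_length)
    stop("invalid field 'sensor_offset_cm': must satisfy 0 < offset < ring_length")
  if (start_position < 0 || start_position >= ring_length)
    stop("invalid field 'start_position': must lie in [0, ring_length)")
  run_direction <- match.arg(run_direction, "clockwise")

  sensors <- (feeders - sensor_offset_cm) %% ring_length
  sensor_names <- stats::setNames(paste0("s", names(feeders)), names(feeders))
  structure(
    list(segments = segments, feeders = feeders,
         sensor_offset_cm = sensor_offset_cm,
         start_position = start_position, run_direction = run_direction,
         ring_length = ring_length, sensors = sensors,
         sensor_names = sensor_names),
    class = "maze_config")
}

#' @export
print.maze_config <- function(x, ...) {
  cat("Maze configuration:", length(x$segments), "segments,",
      "ring length", x$ring_length, "cm\n")
  cat("Feeders (cm):", paste(names(x$feeders), x$feeders, sep = "=",
                             collapse = ", "), "\n")
  cat("Sensor offset:", x$sensor_offset_cm, "cm upstream; run direction:",
      x$run_direction, "\n")
  invisible(x)
}

#' Read / write a maze configuration file
#'
#' The configuration file is YAML with keys `segments`, `feeders`,
#' `sensor_offset_cm`, `start_position`, `run_direction`; missing keys
#' other than `segments` and `feeders` take the defaults of
#' [maze_config()].
#'
#' @param path file path.
#' @return `read_maze_config()`: a validated [maze_config()] object.
#' @examples
#' cfg <- read_maze_config(system.file("extdata", "maze_eight_path.yaml",
#'                                     package = "optomaze"))
#' cfg$ring_length   # 320
#' @export
read_maze_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (field in c("segments", "feeders"))
    if (is.null(cfg[[field]]))
      stop(sprintf("maze config '%s': missing field '%s'", path, field))
  maze_config(
    segments = as.numeric(cfg$segments),
    feeders = unlist(cfg$feeders),
    sensor_offset_cm = cfg$sensor_offset_cm %||%
      analysis_defaults()$sensor_offset_cm,
    start_position = cfg$start_position %||% 0,
    run_direction = cfg$run_direction %||% "clockwise")
}

#' @rdname read_maze_config
#' @param maze a [maze_config()] object.
#' @return `write_maze_config()`: `path`, invisibly.
#' @export
write_maze_config <- function(maze, path) {
  yaml::write_yaml(
    list(segments = maze$segments, feeders = as.list(maze$feeders),
         sensor_offset_cm = maze$sensor_offset_cm,
         start_position = maze$start_position,
         run_direction = maze$run_direction),
    path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Clockwise distance from position a to position b on the ring.
ring_distance <- function(a, b, ring_length) (b - a) %% ring_length

# Boundary sensor used for lap segmentation: the first sensor reached
# from the start position in the run direction.
boundary_sensor <- function(maze) {
  d <- ring_distance(maze$start_position, maze$sensors, maze$ring_length)
  names(maze$feeders)[which.min(d)]
}
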