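#' Read a pose track
#'
#' Flat comma-separated `frame,t,x,y[,confidence]` with coordinates in
#' cm.  [read_pose_dlc()] reads the three-header-row export dialect of
#' markerless pose-estimation software (scorer / bodyparts / coords
#' rows, then one row per frame with x, y, likelihood triplets per body
#' part) and collapses it to the flat schema for one body part.
#'
#' @param path file path.
#' @return data.frame `frame`, `t`, `x`, `y` (and `confidence` if
#'   present), with attribute `fps` estimated from the timestamps.
#' @export
read_pose_track <- function(path) {
  d <- utils::read.csv(path)
  need <- c("frame", "t", "x", "y")
  if (!all(need %in% names(d)))
    stop("pose track '", path, "': expected header frame,t,x,y[,confidence]")
  validate_pose(d)
}

#' @rdname read_pose_track
#' @param bodypart body-part label to extract (default `"neck"`, the
#'   point used for speed classification).
#' @param fps frames per second used to derive `t` from frame numbers.
#' @export
read_pose_dlc <- function(path, bodypart = "neck", fps = 30) {
  hdr <- utils::read.csv(path, header = FALSE, nrows = 3,
                         colClasses = "character")
  body <- utils::read.csv(path, header = FALSE, skip = 3)
  parts <- as.character(unlist(hdr[2, -1]))
  coords <- as.character(unlist(hdr[3, -1]))
  sel <- which(parts == bodypart)
  if (!length(sel))
    stop("body part '", bodypart, "' not found in ", path)
  xcol <- sel[coords[sel] == "x"] + 1L
  ycol <- sel[coords[sel] == "y"] + 1L
  ccol <- sel[coords[sel] %in% c("likelihood", "confidence")] + 1L
  frame <- as.integer(body[[1]])
  out <- data.frame(frame = frame, t = frame / fps,
                    x = as.numeric(body[[xcol[1]]]),
                    y = as.numeric(body[[ycol[1]]]))
  if (length(ccol)) out$confidence <- as.numeric(body[[ccol[1]]])
  validate_pose(out)
}

validate_pose <- function(d) {
  if (any(!is.finite(d$x)) || any(!is.finite(d$y)))
    stop("pose track contains non-finite coordinates")
  if (any(diff(d$t) <= 0))
    stop("pose timestamps must be strictly increasing")
  attr(d, "fps") <- 1 / stats::median(diff(d$t))
  d
}

#' Frame-to-frame speed of a pose track
#'
#' Euclidean displacement between consecutive frames divided by the
#' frame interval.  The series has one value per frame interval; value
#' `i` covers `[t[i], t[i+1])`.
#'
#' @param track data.frame with `t`, `x`, `y` (see [read_pose_track()]).
#' @param smooth_width optional boxcar width in frames (odd; 0 = off).
#' @return list of class `speed_series`: `t` (interval start times),
#'   `dt` (median interval), `v` (cm/s).
#' @export
compute_speed <- function(track, smooth_width = 0) {
  stopifnot(nrow(track) >= 2)
  dt <- diff(track$t)
  if (any(dt == 0)) stop("duplicate timestamps in pose track")
  v <- sqrt(diff(track$x)^2 + diff(track$y)^2) / dt
  if (smooth_width > 1) {
    k <- rep(1 / smooth_width, smooth_width)
    sm <- stats::filter(v, k, sides = 2)
    v <- ifelse(is.na(sm), v, as.numeric(sm))
  }
  structure(list(t = track$t[-length(track$t)], dt = stats::median(dt), v = v),
            class = "speed_series")
}

#' Classify locomotion into ambulation / immobility / fine movement
#'
#' Velocity-threshold segmentation of a speed series: frames covered by
#' any half-second sliding window whose mean speed exceeds 2 cm/s are
#' *ambulation*; maximal remaining runs with speed strictly below
#' 2 cm/s lasting at least 1 s are *immobility*; everything else is
#' *fine movement*.  Precedence is ambulation > immobility > fine
#' movement; frames at exactly the threshold satisfy neither strict
#' criterion and can only be fine movement.  Tracks shorter than the
#' immobility minimum are returned as a single fine-movement segment
#' with a warning.
#'
#' @param speed a `speed_series` from [compute_speed()].
#' @param threshold_cm_s speed threshold (2 cm/s).
#' @param window_s sustained-window length for ambulation (0.5 s).
#' @param immobility_min_s minimum immobility run (1 s).
#' @return An object of class `state_segments`: data.frame `t_start`,
#'   `t_end`, `label`; non-overlapping, contiguous, covering the full
#'   track duration.  Attribute `frame_labels` holds the per-interval
#'   factor.
#' @export
classify_states <- function(speed,
                            threshold_cm_s =
                              analysis_defaults()$speed_threshold_cm_s,
                            window_s = analysis_defaults()$ambulation_window_s,
                            immobility_min_s =
                              analysis_defaults()$immobility_min_s) {
  v <- speed$v
  n <- length(v)
  dt <- speed$dt
  t_edges <- c(speed$t, speed$t[n] + dt)
  labels <- c("ambulation", "immobility", "fine_movement")
  if (n * dt < immobility_min_s) {
    warning("track shorter than ", immobility_min_s,
            " s; returning a single fine-movement segment")
    seg <- data.frame(t_start = t_edges[1], t_end = t_edges[n + 1],
                      label = "fine_movement")
    return(structure(seg, class = c("state_segments", "data.frame"),
                     frame_labels = factor(rep("fine_movement", n),
                                           levels = labels)))
  }
  w <- max(1L, as.integer(round(window_s / dt)))
  lab <- rep("fine_movement", n)
  if (n >= w) {
    wm <- as.numeric(stats::filter(v, rep(1 / w, w), sides = 1))  # mean of i-w+1..i
    pass_end <- which(!is.na(wm) & wm > threshold_cm_s)
    if (length(pass_end)) {
      # mark every frame covered by a passing window via interval deltas
      delta <- integer(n + 1L)
      starts <- pass_end - w + 1L
      delta[starts] <- delta[starts] + 1L
      delta[pass_end + 1L] <- delta[pass_end + 1L] - 1L
      covered <- cumsum(delta[seq_len(n)]) > 0L
      lab[covered] <- "ambulation"
    }
  }
  # immobility: maximal non-ambulation runs of v < threshold, >= 1 s
  cand <- lab != "ambulation" & v < threshold_cm_s
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] * dt >= immobility_min_s - 1e-9)
      lab[starts[i]:ends[i]] <- "immobility"
  }
  rl <- rle(lab)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  seg <- data.frame(t_start = t_edges[starts], t_end = t_edges[ends + 1L],
                    label = rl$values)
  structure(seg, class = c("state_segments", "data.frame"),
            frame_labels = factor(lab, levels = labels))
}

#' Occupancy and ambulation-bout summary of state segments
#'
#' @param segments a `state_segments` object.
#' @return list with `percent` (named vector over the three states,
#'   summing to 100), `total_s`, `ambulation_bouts` (durations, s) and
#'   `mean_ambulation_s`.
#' @export
state_summary <- function(segments) {
  dur <- segments$t_end - segments$t_start
  total <- sum(dur)
  labels <- c("ambulation", "immobility", "fine_movement")
  by_label <- vapply(labels, function(l) sum(dur[segments$label == l]),
                     numeric(1))
  bouts <- dur[segments$label == "ambulation"]
  list(percent = 100 * by_label / total,
       total_s = total,
       ambulation_bouts = bouts,
       mean_ambulation_s = if (length(bouts)) mean(bouts) else NA_real_)
}
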