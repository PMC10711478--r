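# Fixture builders used across the test files.

FEEDERS <- c("N", "E", "S", "W")

# Build a maze_laps object directly from per-lap poke lists.
# `poke_sets` is a list of character vectors (possibly with repeats),
# one per lap; `rewarded_laps` marks laps on which a reward fell.
make_laps <- function(poke_sets, rewarded = "N",
                      rewarded_laps = NULL,
                      sensor_cross = NULL,
                      stim_condition = "none") {
  n <- length(poke_sets)
  if (is.null(rewarded_laps))
    rewarded_laps <- vapply(poke_sets, function(p) rewarded %in% p,
                            logical(1))
  laps <- lapply(seq_len(n), function(i) {
    t0 <- (i - 1) * 60
    pokes <- poke_sets[[i]]
    pt <- if (length(pokes)) t0 + 10 + seq_along(pokes) else numeric(0)
    sc <- if (is.null(sensor_cross))
      stats::setNames(rep(NA_real_, 4), FEEDERS) else sensor_cross[[i]]
    list(index = i, t_start = t0, t_end = t0 + 60, complete = TRUE,
         rewarded = rewarded_laps[i],
         pokes = data.frame(t = pt, feeder = as.character(pokes)),
         sensor_cross = sc)
  })
  structure(laps, class = "maze_laps", rewarded_feeder = rewarded,
            feeder_labels = FEEDERS, stim_condition = stim_condition,
            n_pokes_unassigned = 0L, t0 = 0, order_violations = 0L)
}

# Minimal well-formed event log text.
write_toy_log <- function(path, rows,
                          meta = c(animal_id = "m1", day = 1,
                                   session_index = 1, task = "FRL",
                                   rewarded_feeder = "N",
                                   stim_condition = "none",
                                   stim_duration = "none")) {
  writeLines(c(sprintf("#%s: %s", names(meta), meta),
               "t,device,kind", rows), path)
  path
}

# Independent brute-force oracle for the trial-shuffle null: enumerate
# every permutation of the poke lap-label vector with a plain recursion
# and recompute both rates with per-lap loops.
oracle_shuffle_p <- function(poke_feeder, poke_lap, n_laps, rewarded,
                             metric) {
  rate_of <- function(lap_assign) {
    flags <- vapply(seq_len(n_laps), function(l) {
      fs <- unique(poke_feeder[lap_assign == l])
      if (metric == "rule") length(fs) == 1
      else length(fs) == 1 && fs == rewarded
    }, logical(1))
    sum(flags) / n_laps
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  all_assign <- unique(perms(poke_lap))
  nulls <- vapply(all_assign, rate_of, numeric(1))
  obs <- rate_of(poke_lap)
  sum(nulls >= obs - 1e-12) / length(nulls)
}

# Agent whose poke probability is exactly 0.5 per feeder independent of
# value (beta = 0): pokes carry no lap information.
null_agent <- function() agent_params(beta = 0)

# A Z-scored peth_matrix built directly from a numeric matrix, for
# exceedance tests.
make_z_matrix <- function(mat, params = peth_params()) {
  structure(mat, class = c("peth_matrix", "matrix"),
            bin_left = params$bin_left, params = params,
            onsets = seq_len(nrow(mat)), R0 = rep(100, nrow(mat)),
            dropped = data.frame(onset = numeric(0),
                                 reason = character(0)))
}

# Uniform-speed series covering `dur` seconds at `fps`.
make_speed <- function(v, fps = 30) {
  n <- length(v)
  structure(list(t = (seq_len(n) - 1) / fps, dt = 1 / fps, v = v),
            class = "speed_series")
}
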