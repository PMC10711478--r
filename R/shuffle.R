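#' Trial-shuffled chance distributions for the behavioral rates
#'
#' The chance level of the correct-response and rule-learning rates is
#' obtained by randomly shuffling the trial (lap) number of every nose
#' poke: each poke keeps its feeder identity but receives a lap label
#' drawn by uniformly permuting the original multiset of lap labels
#' across pokes.  Per-lap distinct-feeder sets are then rebuilt and the
#' rate recomputed.  This is the only reading of "shuffling the trial
#' number" that perturbs both rates, since they depend only on per-lap
#' feeder sets (reassigning intact laps would change neither).
#'
#' The p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_shuffles)`, so ties count
#' against significance and p is never zero.  The learning criterion is
#' met when the observed rate exceeds the entire shuffled distribution,
#' i.e. `p = 1/(n_shuffles+1)` (`< 0.001` at the default 1000 shuffles).
#'
#' @name permutation_null
NULL

# Extract the poke table of the complete laps: integer feeder ids,
# integer lap labels, lap count, rewarded feeder id.
poke_table <- function(laps, rewarded_feeder = attr(laps, "rewarded_feeder")) {
  labels <- attr(laps, "feeder_labels")
  laps <- complete_laps(laps)
  feeder <- integer(0)
  lap <- integer(0)
  for (i in seq_along(laps)) {
    f <- match(laps[[i]]$pokes$feeder, labels)
    if (anyNA(f)) stop("unknown feeder label in pokes")
    feeder <- c(feeder, f)
    lap <- c(lap, rep(i, length(f)))
  }
  list(feeder = feeder, lap = lap, n_laps = length(laps),
       n_feeders = length(labels),
       rewarded = match(rewarded_feeder, labels))
}

# Both rates for one or more lap-label assignments.  `lap_labels` is a
# vector (one assignment) or a matrix with one assignment per column.
rates_from_assignment <- function(feeder, lap_labels, n_laps, n_feeders,
                                  rewarded) {
  lap_labels <- as.matrix(lap_labels)
  n_assign <- ncol(lap_labels)
  P <- length(feeder)
  if (P == 0L) {
    z <- rep(0, max(1L, n_assign))
    return(list(correct = z, rule = z))
  }
  idx <- (as.vector(lap_labels) - 1L) * n_feeders + rep.int(feeder, n_assign) +
    rep((seq_len(n_assign) - 1L) * (n_feeders * n_laps), each = P)
  pres <- tabulate(idx, nbins = n_feeders * n_laps * n_assign) > 0L
  dim(pres) <- c(n_feeders, n_laps, n_assign)
  ndist <- matrix(colSums(pres), n_laps, n_assign)
  rew <- matrix(pres[rewarded, , ], n_laps, n_assign)
  list(correct = colSums(ndist == 1L & rew) / n_laps,
       rule = colSums(ndist == 1L) / n_laps)
}

#' Shuffle trial labels once
#'
#' One draw of the shuffling procedure: uniformly permute the lap labels
#' across the pokes of a session's complete laps and return the
#' resulting per-lap distinct-feeder sets.  Poke and lap counts are
#' conserved.
#'
#' @param laps a `maze_laps` object.
#' @return list with `feeder` (labels per poke), `lap` (shuffled lap
#'   label per poke) and `sets` (list, distinct feeder labels per lap).
#' @export
shuffle_once <- function(laps) {
  pt <- poke_table(laps)
  labels <- attr(laps, "feeder_labels")
  perm <- if (length(pt$lap)) pt$lap[sample.int(length(pt$lap))] else integer(0)
  sets <- lapply(seq_len(pt$n_laps), function(l)
    sort(unique(labels[pt$feeder[perm == l]])))
  list(feeder = labels[pt$feeder], lap = perm, sets = sets)
}

# One column per shuffle: a uniform permutation of the lap labels.
shuffle_label_matrix <- function(labels, n_shuffles) {
  P <- length(labels)
  if (P == 0L) return(matrix(integer(0), nrow = 0, ncol = n_shuffles))
  matrix(vapply(seq_len(n_shuffles), function(s) labels[sample.int(P)],
                integer(P)),
         nrow = P, ncol = n_shuffles)
}

# All distinct permutations of a label multiset (for exhaustive
# enumeration on toy sessions).  Returns a matrix, one assignment per
# column.
multiset_permutations <- function(labels) {
  uniq <- sort(unique(labels))
  counts <- as.integer(table(factor(labels, levels = uniq)))
  n <- length(labels)
  recurse <- function(counts, depth) {
    if (depth > n) return(matrix(integer(0), nrow = 0, ncol = 1))
    out <- NULL
    for (i in seq_along(uniq)) {
      if (counts[i] == 0L) next
      counts2 <- counts
      counts2[i] <- counts2[i] - 1L
      sub <- recurse(counts2, depth + 1L)
      out <- cbind(out, rbind(rep(uniq[i], ncol(sub)), sub))
    }
    out
  }
  recurse(counts, 1L)
}

#' Null distribution of a behavioral rate under trial shuffling
#'
#' @param laps a `maze_laps` object (complete laps are used).
#' @param metric `"correct"` or `"rule"`.
#' @param n_shuffles number of shuffles (default 1000).
#' @param seed optional integer seed for reproducibility; recorded in
#'   the result.
#' @param method `"mc"` (Monte Carlo over `n_shuffles` random
#'   permutations, add-one p) or `"exhaustive"` (enumerate every
#'   distinct assignment of the lap-label multiset; exact p, only
#'   feasible for toy sessions).
#' @return An object of class `shuffle_result`: list with
#'   `metric`, `observed`, `null_values`, `p_value`, `exceeds_all`,
#'   `n_shuffles`, `seed`, `method`.
#' @export
null_distribution <- function(laps, metric = c("correct", "rule"),
                              n_shuffles = analysis_defaults()$n_shuffles,
                              seed = NULL,
                              method = c("mc", "exhaustive")) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  if (method == "mc" && n_shuffles < 1)
    stop("n_shuffles must be >= 1")
  pt <- poke_table(laps)
  if (pt$n_laps < 1)
    stop("no complete laps to shuffle")
  obs <- rates_from_assignment(pt$feeder, pt$lap, pt$n_laps, pt$n_feeders,
                               pt$rewarded)[[metric]]
  if (!is.null(seed)) set.seed(seed)
  P <- length(pt$lap)
  if (method == "exhaustive") {
    assigns <- if (P) multiset_permutations(pt$lap) else
      matrix(integer(0), nrow = 0, ncol = 1)
    null_values <- rates_from_assignment(pt$feeder, assigns, pt$n_laps,
                                         pt$n_feeders, pt$rewarded)[[metric]]
    p <- sum(null_values >= obs - 1e-12) / length(null_values)
    n_shuffles <- length(null_values)
  } else {
    lab <- shuffle_label_matrix(pt$lap, n_shuffles)
    null_values <- rates_from_assignment(pt$feeder, lab, pt$n_laps,
                                         pt$n_feeders, pt$rewarded)[[metric]]
    p <- (1 + sum(null_values >= obs - 1e-12)) / (1 + n_shuffles)
  }
  structure(list(metric = metric, observed = obs,
                 null_values = null_values, p_value = p,
                 exceeds_all = obs > max(null_values) + 1e-12,
                 n_shuffles = n_shuffles, seed = seed, method = method),
            class = "shuffle_result")
}

#' @export
print.shuffle_result <- function(x, ...) {
  cat(sprintf(
    "Shuffled chance distribution (%s rate, %s, %d shuffles)\n",
    x$metric, x$method, x$n_shuffles))
  cat(sprintf("  observed %.3f; null max %.3f; p = %.4g%s\n",
              x$observed, max(x$null_values), x$p_value,
              if (x$exceeds_all) " (exceeds entire distribution)" else ""))
  invisible(x)
}

#' Learning criterion
#'
#' A session (or day) counts as learned when the observed rate exceeds
#' the entire shuffled distribution, i.e. p < 0.001 at 1000 shuffles.
#'
#' @param result a `shuffle_result`.
#' @return logical flag.
#' @export
learning_criterion <- function(result) {
  stopifnot(inherits(result, "shuffle_result"))
  isTRUE(result$exceeds_all)
}

#' Day-level chance band
#'
#' For the gray chance bands of the learning curves: per shuffle
#' iteration, shuffle every session of the day independently, average
#' the per-session shuffled rates, and collect the day-level values.
#' The band is the min..max of those values.
#'
#' @param day_laps list of `maze_laps` objects, one per session of the
#'   day.
#' @param metric,n_shuffles,seed as in [null_distribution()].
#' @return list with `observed` (day mean of observed rates),
#'   `null_values`, `band` (`c(min, max)`), `p_value` (add-one),
#'   `exceeds_all`.
#' @export
day_chance_band <- function(day_laps, metric = c("correct", "rule"),
                            n_shuffles = analysis_defaults()$n_shuffles,
                            seed = NULL) {
  metric <- match.arg(metric)
  if (!is.null(seed)) set.seed(seed)
  per_session <- lapply(day_laps, function(laps) {
    pt <- poke_table(laps)
    if (pt$n_laps < 1) return(NULL)
    obs <- rates_from_assignment(pt$feeder, pt$lap, pt$n_laps,
                                 pt$n_feeders, pt$rewarded)[[metric]]
    lab <- shuffle_label_matrix(pt$lap, n_shuffles)
    nv <- rates_from_assignment(pt$feeder, lab, pt$n_laps, pt$n_feeders,
                                pt$rewarded)[[metric]]
    list(observed = obs, null_values = nv)
  })
  per_session <- Filter(Negate(is.null), per_session)
  if (!length(per_session))
    stop("no session with complete laps in day")
  obs <- mean(vapply(per_session, `[[`, numeric(1), "observed"))
  nv <- rowMeans(vapply(per_session, `[[`, numeric(n_shuffles),
                        "null_values"))
  list(observed = obs, null_values = nv,
       band = c(min(nv), max(nv)),
       p_value = (1 + sum(nv >= obs - 1e-12)) / (1 + n_shuffles),
       exceeds_all = obs > max(nv) + 1e-12)
}
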