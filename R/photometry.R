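#' Peri-event analysis parameters
#'
#' Window and binning constants for the peri-event time histograms: 1 s
#' before to 8 s after stimulation onset, a 1-s baseline sampling window
#' immediately before onset, and a 0.1-s bin constant.
#'
#' @param pre_s,post_s window extent around onset (s).
#' @param bin_s bin width (s).
#' @param baseline_s baseline window length immediately pre-onset (s);
#'   must not exceed `pre_s`.
#' @return list of validated parameters with `n_bins` and `bin_left`
#'   (left bin edges relative to onset; bins are left-closed
#'   right-open).
#' @export
peth_params <- function(pre_s = analysis_defaults()$peth_pre_s,
                        post_s = analysis_defaults()$peth_post_s,
                        bin_s = analysis_defaults()$peth_bin_s,
                        baseline_s = analysis_defaults()$peth_baseline_s) {
  stopifnot(pre_s > 0, post_s > 0, bin_s > 0, baseline_s > 0)
  if (baseline_s > pre_s + 1e-9)
    stop("baseline_s must not exceed pre_s")
  n_bins <- (pre_s + post_s) / bin_s
  if (abs(n_bins - round(n_bins)) > 1e-6)
    stop("window length must be divisible by bin_s")
  n_bins <- as.integer(round(n_bins))
  list(pre_s = pre_s, post_s = post_s, bin_s = bin_s,
       baseline_s = baseline_s, n_bins = n_bins,
       bin_left = -pre_s + bin_s * (seq_len(n_bins) - 1L))
}

#' Read a photometry trace / stimulation onsets
#'
#' The trace is comma-separated `t,R` (seconds, raw fluorescence at a
#' nominal 100 Hz); onsets are TTL-style `t,label` rows.
#'
#' @param path file path.
#' @param jitter_tol allowed sampling jitter as a fraction of the median
#'   sample period before the trace is resampled onto a uniform grid by
#'   linear interpolation.
#' @return `read_photometry_trace()`: list with `t`, `R`, `fs`
#'   (samples/s) and `resampled` flag.
#' @export
read_photometry_trace <- function(path, jitter_tol = 0.1) {
  d <- utils::read.csv(path)
  if (!all(c("t", "R") %in% names(d)))
    stop("photometry trace '", path, "': expected header t,R")
  regularize_trace(d$t, d$R, jitter_tol = jitter_tol)
}

#' @rdname read_photometry_trace
#' @export
read_stim_onsets <- function(path) {
  d <- utils::read.csv(path)
  if (!"t" %in% names(d))
    stop("onset file '", path, "': expected a 't' column")
  as.numeric(d$t)
}

# Validate sampling regularity; resample by linear interpolation onto a
# uniform grid when jitter exceeds the tolerance.
regularize_trace <- function(t, R, jitter_tol = 0.1) {
  stopifnot(length(t) == length(R), length(t) >= 2)
  if (any(!is.finite(t)) || any(!is.finite(R)))
    stop("photometry trace contains non-finite values")
  dt <- diff(t)
  if (any(dt <= 0)) stop("photometry timestamps must be strictly increasing")
  period <- stats::median(dt)
  resampled <- FALSE
  if (max(abs(dt - period)) > jitter_tol * period) {
    tt <- seq(t[1], t[length(t)], by = period)
    R <- stats::approx(t, R, xout = tt)$y
    t <- tt
    resampled <- TRUE
  }
  list(t = t, R = R, fs = 1 / period, resampled = resampled)
}

#' Peri-event time histogram of percent dR/R0
#'
#' For each stimulation onset, the baseline R0 is the mean raw signal
#' over the baseline window immediately before onset; each bin value is
#' `100 * (mean R in bin - R0) / R0`.  Samples are assigned to
#' left-closed right-open bins by timestamp.  Trials without full
#' window coverage, with an empty bin, or with a non-positive baseline
#' are dropped and recorded.
#'
#' @param trace list with `t` and `R` (e.g. from
#'   [read_photometry_trace()] or [simulate_photometry()]).
#' @param onsets numeric vector of stimulation onset times (s); defaults
#'   to `trace$onsets` when present.
#' @param params a [peth_params()] list.
#' @return An object of class `peth_matrix`: numeric matrix, one row per
#'   usable trial, one column per bin, in percent dR/R0.  Attributes:
#'   `bin_left`, `params`, `onsets` (usable), `R0` (per-trial baseline
#'   means), `dropped` (data.frame of rejected trials with reasons).
#' @export
compute_peth <- function(trace, onsets = trace$onsets,
                         params = peth_params()) {
  t <- trace$t
  R <- trace$R
  if (is.null(onsets) || !length(onsets))
    stop("no stimulation onsets supplied")
  n_bins <- params$n_bins
  rows <- list()
  used <- numeric(0)
  R0s <- numeric(0)
  dropped <- list()
  for (on in onsets) {
    rel <- t - on
    keep <- rel >= -params$pre_s - 1e-9 & rel < params$post_s - 1e-9
    if (!any(keep) || min(rel) > -params$pre_s + 1e-9 ||
        max(rel) < params$post_s - 0.5 * params$bin_s) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(onset = on, reason = "incomplete_window")
      next
    }
    base <- R[rel >= -params$baseline_s - 1e-9 & rel < -1e-9]
    R0 <- mean(base)
    if (!is.finite(R0) || R0 <= 0) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(onset = on, reason = "nonpositive_baseline")
      next
    }
    bin <- floor((rel[keep] + params$pre_s) / params$bin_s + 1e-9) + 1L
    bin[bin > n_bins] <- n_bins
    m <- tapply(R[keep], factor(bin, levels = seq_len(n_bins)), mean)
    if (anyNA(m)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(onset = on, reason = "empty_bin")
      next
    }
    rows[[length(rows) + 1L]] <- 100 * (as.numeric(m) - R0) / R0
    used <- c(used, on)
    R0s <- c(R0s, R0)
  }
  if (!length(rows))
    stop("no usable trials: every onset was rejected")
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(onset = numeric(0), reason = character(0))
  if (nrow(dropped))
    warning(sprintf("%d of %d trials dropped (%s)", nrow(dropped),
                    length(onsets),
                    paste(unique(dropped$reason), collapse = ", ")))
  structure(do.call(rbind, rows), class = c("peth_matrix", "matrix"),
            bin_left = params$bin_left, params = params,
            onsets = used, R0 = R0s, dropped = dropped)
}

#' Z-score a PETH matrix against its per-trial baseline
#'
#' Per trial, `Z(bin) = (x(bin) - mean(baseline bins)) / sd(baseline
#' bins)` where the baseline bins are those entirely before onset within
#' the baseline window.  Baseline bins of each retained trial therefore
#' have mean 0 and SD 1.  Trials with zero baseline SD are dropped and
#' recorded.
#'
#' @param peth a `peth_matrix`.
#' @return a `peth_matrix` of Z-scores with the same attributes (plus
#'   updated `dropped`).
#' @export
zscore_peth <- function(peth) {
  bl <- attr(peth, "bin_left")
  params <- attr(peth, "params")
  base_cols <- which(bl >= -params$baseline_s - 1e-9 & bl < -1e-9)
  if (length(base_cols) < 2)
    stop("need at least 2 baseline bins to Z-score")
  x <- unclass(peth)
  mu <- rowMeans(x[, base_cols, drop = FALSE])
  sdv <- apply(x[, base_cols, drop = FALSE], 1, stats::sd)
  ok <- sdv > 0
  if (!any(ok))
    stop("no usable trials: zero baseline SD in every trial")
  dropped <- attr(peth, "dropped")
  if (any(!ok)) {
    warning(sprintf("%d trials dropped (zero baseline SD)", sum(!ok)))
    dropped <- rbind(dropped,
                     data.frame(onset = attr(peth, "onsets")[!ok],
                                reason = "zero_baseline_sd"))
  }
  z <- (x[ok, , drop = FALSE] - mu[ok]) / sdv[ok]
  structure(z, class = c("peth_matrix", "matrix"),
            bin_left = bl, params = params,
            onsets = attr(peth, "onsets")[ok],
            R0 = attr(peth, "R0")[ok], dropped = dropped)
}

#' Count trials whose Z score exceeds threshold in the response epoch
#'
#' A trial (stimulation session) is counted when the Z score exceeds the
#' threshold (strictly) in any bin lying entirely within the epoch — by
#' default 1.96 during the 1.5-s epoch commencing 0.05 s after
#' stimulation onset.  `rule = "mean"` instead thresholds the epoch-mean
#' Z per trial.
#'
#' @param z a Z-scored `peth_matrix`.
#' @param threshold Z threshold.
#' @param epoch_start_s,epoch_len_s epoch relative to onset (s).
#' @param rule `"any"` (default) or `"mean"`.
#' @return list with `count`, `n_trials`, `per_trial` (logical),
#'   `threshold`, `epoch`.
#' @export
count_exceedances <- function(z,
                              threshold = analysis_defaults()$z_threshold,
                              epoch_start_s = analysis_defaults()$epoch_start_s,
                              epoch_len_s = analysis_defaults()$epoch_len_s,
                              rule = c("any", "mean")) {
  rule <- match.arg(rule)
  bl <- attr(z, "bin_left")
  bw <- attr(z, "params")$bin_s
  epoch_end <- epoch_start_s + epoch_len_s
  cols <- which(bl >= epoch_start_s - 1e-9 & bl + bw <= epoch_end + 1e-9)
  if (!length(cols))
    stop("no bin lies entirely within the epoch")
  if (epoch_end > max(bl) + bw + 1e-9 || epoch_start_s < min(bl) - 1e-9)
    stop("epoch extends outside the peri-event window")
  xz <- unclass(z)[, cols, drop = FALSE]
  hit <- if (rule == "any") apply(xz > threshold, 1, any)
         else rowMeans(xz) > threshold
  list(count = sum(hit), n_trials = nrow(z), per_trial = unname(hit),
       threshold = threshold, epoch = c(epoch_start_s, epoch_end))
}

#' Phase averages of a PETH
#'
#' Mean percent dR/R0 during stimulation (0-1 s from onset) and the
#' early (2-5 s) and late (5-8 s) post-stimulation phases, per trial and
#' averaged across trials.  A bin contributes to a phase when its whole
#' interval lies inside the phase interval.
#'
#' @param peth a `peth_matrix` (percent dR/R0 or Z).
#' @param phases named list of `c(start, end)` intervals (s from onset).
#' @return list with `per_trial` (matrix trials x phases) and `mean`
#'   (named vector of trial-averaged phase means).
#' @export
phase_means <- function(peth,
                        phases = list(stim = c(0, 1), early = c(2, 5),
                                      late = c(5, 8))) {
  bl <- attr(peth, "bin_left")
  bw <- attr(peth, "params")$bin_s
  x <- unclass(peth)
  per <- sapply(phases, function(ph) {
    cols <- which(bl >= ph[1] - 1e-9 & bl + bw <= ph[2] + 1e-9)
    if (!length(cols))
      stop("phase [", ph[1], ",", ph[2], ") not covered by the PETH window")
    rowMeans(x[, cols, drop = FALSE])
  })
  per <- matrix(per, nrow = nrow(x),
                dimnames = list(NULL, names(phases)))
  list(per_trial = per, mean = colMeans(per))
}
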