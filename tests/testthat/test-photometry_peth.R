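# 100-Hz trace helper: R(t) from a function of time, one onset at `on`.
make_trace <- function(f, t_max = 12, on = 2, fs = 100) {
  t <- seq(0, t_max, by = 1 / fs)
  list(t = t, R = f(t), onsets = on)
}

test_that("peth window parameters validate and give 90 bins", {
  p <- peth_params()
  expect_equal(p$n_bins, 90L)
  expect_equal(p$bin_left[1], -1)
  expect_equal(p$bin_left[90], 7.9)
  expect_error(peth_params(baseline_s = 2, pre_s = 1), "baseline")
  expect_error(peth_params(bin_s = 0.13), "divisible")
})

test_that("percent dR/R0 is zero for constant signal and exact for steps", {
  const <- compute_peth(make_trace(function(t) rep(100, length(t))))
  expect_equal(max(abs(const)), 0)

  step <- compute_peth(make_trace(function(t)
    ifelse(t >= 2 & t < 3, 110, 100)))
  bl <- attr(step, "bin_left")
  expect_equal(unname(unclass(step)[1, bl >= 0 & bl < 1]), rep(10, 10))
  expect_equal(unname(unclass(step)[1, bl < 0]), rep(0, 10))
  expect_equal(ncol(step), 90)
})

test_that("trials without coverage or with bad baselines are rejected", {
  t <- seq(0, 12, by = 0.01)
  tr <- list(t = t, R = rep(100, length(t)), onsets = c(0.5, 2, 11.8))
  expect_warning(p <- compute_peth(tr), "dropped")
  expect_equal(nrow(p), 1)                # only the middle onset fits
  expect_equal(attr(p, "dropped")$reason, rep("incomplete_window", 2))

  neg <- make_trace(function(t) ifelse(t < 2, -5, 100))
  expect_error(suppressWarnings(compute_peth(neg)), "no usable trials")
})

test_that("percent dR/R0 is gain-invariant but offset-sensitive", {
  f <- function(t) 100 + 5 * sin(t)
  base <- compute_peth(make_trace(f))
  gain <- compute_peth(make_trace(function(t) 3.7 * f(t)))
  expect_equal(as.vector(gain), as.vector(base), tolerance = 1e-12)
  offset <- compute_peth(make_trace(function(t) f(t) + 50))
  expect_gt(max(abs(unclass(offset) - unclass(base))), 0.1)
})

test_that("Z-scoring gives baseline bins mean 0 / SD 1 per trial", {
  set.seed(8)
  tr <- simulate_photometry(photo_model("GCaMP6f", "long_40ms"),
                            stim_protocol(total_min = 2), seed = 8)
  z <- zscore_peth(compute_peth(tr))
  bl <- attr(z, "bin_left")
  base <- unclass(z)[, bl < 0]
  expect_equal(unname(rowMeans(base)), rep(0, nrow(z)), tolerance = 1e-10)
  expect_equal(unname(apply(base, 1, sd)), rep(1, nrow(z)),
               tolerance = 1e-10)
})

test_that("a hand-built trial Z-scores to hand-computed values", {
  # alternate whole 0.1-s bins between 10 and 10.2 a.u. in the baseline
  # so that the per-bin baseline mean and SD are known in closed form
  alt <- function(t) (floor(round(t * 10, 6)) %% 2 == 0) & t < 2
  f <- function(t) ifelse(t >= 2 & t < 3, 12, 10) + 0.2 * alt(t)
  p <- compute_peth(make_trace(f))
  z <- zscore_peth(p)
  bl <- attr(z, "bin_left")
  x <- unclass(p)[1, ]
  mu <- mean(x[bl < 0]); sdv <- sd(x[bl < 0])
  expect_equal(unclass(z)[1, ], (x - mu) / sdv)
  # constant post-onset signal equal to the baseline mean gives Z = 0
  f2 <- function(t) ifelse(t >= 2, 10.1, 10 + 0.2 * alt(t))
  z2 <- zscore_peth(compute_peth(make_trace(f2)))
  expect_equal(unname(unclass(z2)[1, bl >= 0]), rep(0, 80),
               tolerance = 1e-9)
  # zero baseline SD rejects the trial
  flat <- compute_peth(make_trace(function(t) ifelse(t >= 2, 12, 10)))
  expect_error(zscore_peth(flat), "zero baseline SD")
})

test_that("exceedance counting uses strict > on bins inside the epoch", {
  z0 <- make_z_matrix(matrix(0, nrow = 3, ncol = 90))
  expect_equal(count_exceedances(z0)$count, 0)

  m <- matrix(0, nrow = 2, ncol = 90)
  m[1, 16] <- 3.0                        # bin [0.5, 0.6): inside epoch
  z1 <- make_z_matrix(m)
  ex <- count_exceedances(z1)
  expect_equal(ex$count, 1)
  expect_equal(ex$per_trial, c(TRUE, FALSE))

  m2 <- matrix(0, nrow = 1, ncol = 90)
  m2[1, 16] <- 1.96                      # exactly at threshold: no hit
  expect_equal(count_exceedances(make_z_matrix(m2))$count, 0)

  m3 <- matrix(0, nrow = 1, ncol = 90)
  m3[1, 11] <- 5                         # bin [0.0, 0.1): outside epoch
  expect_equal(count_exceedances(make_z_matrix(m3))$count, 0)
  m3[1, 15] <- 5                         # bin [0.4, 0.5): inside
  expect_equal(count_exceedances(make_z_matrix(m3))$count, 1)

  expect_error(count_exceedances(z0, epoch_start_s = 8.5), "epoch")
  # epoch-mean variant
  expect_equal(count_exceedances(z1, rule = "mean")$count, 0)
})

test_that("phase means average the bins inside each phase window", {
  flat <- make_z_matrix(matrix(5, 2, 90))
  ph <- phase_means(flat)
  expect_equal(unname(ph$mean), c(5, 5, 5))

  step <- compute_peth(make_trace(function(t)
    ifelse(t >= 2 & t < 3, 110, 100)))
  ph2 <- phase_means(step)
  expect_equal(unname(ph2$mean), c(10, 0, 0))
})

test_that("phase means match analytic integrals of a decaying transient", {
  tau <- 1.5; A <- 8; on <- 2
  f <- function(t) 100 * (1 + A / 100 * exp(-pmax(t - on, 0) / tau) *
                            (t >= on))
  ph <- phase_means(compute_peth(make_trace(f)))
  analytic <- function(a, b) A * tau * (exp(-a / tau) - exp(-b / tau)) /
    (b - a)
  expect_equal(unname(ph$mean["stim"]), analytic(0, 1), tolerance = 0.01)
  expect_equal(unname(ph$mean["early"]), analytic(2, 5), tolerance = 0.01)
  expect_equal(unname(ph$mean["late"]), analytic(5, 8), tolerance = 0.02)
})

test_that("jittered traces are resampled onto a uniform grid", {
  set.seed(3)
  t <- cumsum(runif(1200, 0.005, 0.015))
  tr <- optomaze:::regularize_trace(t, rep(100, length(t)))
  expect_true(tr$resampled)
  expect_equal(length(unique(round(diff(tr$t), 12))), 1)
  even <- optomaze:::regularize_trace(seq(0, 10, 0.01), rep(1, 1001))
  expect_false(even$resampled)
  expect_error(optomaze:::regularize_trace(c(0, 0, 1), c(1, 2, 3)),
               "increasing")
})

test_that("photometry files round-trip through the readers", {
  tr <- simulate_photometry(photo_model("GRAB_DA2h", "short_10ms"),
                            stim_protocol(total_min = 1), seed = 4)
  fp <- withr::local_tempfile(fileext = ".csv")
  op <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(t = tr$t, R = tr$R), fp, row.names = FALSE)
  utils::write.csv(data.frame(t = tr$onsets, label = "stim"), op,
                   row.names = FALSE)
  back <- read_photometry_trace(fp)
  expect_equal(back$R, tr$R, tolerance = 1e-12)
  expect_equal(read_stim_onsets(op), tr$onsets)
  p1 <- compute_peth(back, read_stim_onsets(op))
  p2 <- compute_peth(tr)
  expect_equal(unclass(p1), unclass(p2), tolerance = 1e-9)
})
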