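test_that("mixed ANOVA F statistics match the sums-of-squares oracle", {
  # 2 groups x 2 days x 2 subjects per group
  d <- toy_table(c(3, 5, 4, 7, 6, 9, 5, 12), 2,
                 c(s1 = "a", s2 = "a", s3 = "b", s4 = "b"))
  got <- mixed_anova_gg(d, "value", "subject", "day", "group")
  want <- oracle_split_plot(d)
  expect_equal(got$F[got$effect == "group"], want$F_group)
  expect_equal(got$F[got$effect == "day"], want$F_day)
  expect_equal(got$F[got$effect == "group:day"], want$F_int)
  expect_equal(got$df1, c(1, 1, 1))
  expect_equal(got$df2, c(2, 2, 2))

  # a larger random 2 x 4-day x 5-subject table
  set.seed(21)
  gos <- setNames(rep(c("a", "b"), each = 5), paste0("s", 1:10))
  d2 <- toy_table(rnorm(40), 4, gos)
  got2 <- mixed_anova_gg(d2, "value", "subject", "day", "group")
  want2 <- oracle_split_plot(d2)
  expect_equal(got2$F[got2$effect == "group"], want2$F_group)
  expect_equal(got2$F[got2$effect == "day"], want2$F_day)
  expect_equal(got2$F[got2$effect == "group:day"], want2$F_int)
})

test_that("GG-corrected p agrees with the multivariate reference fit", {
  set.seed(22)
  gos <- setNames(rep(c("a", "b"), each = 6), paste0("s", 1:12))
  d <- toy_table(rnorm(48, sd = 1) + rep(1:4, each = 12) * 0.3, 4, gos)
  got <- mixed_anova_gg(d, "value", "subject", "day", "group")

  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  wide <- reshape(d, idvar = c("subject", "group"), timevar = "day",
                  direction = "wide")
  mlm <- lm(as.matrix(wide[, paste0("value.", 1:4)]) ~ group, data = wide)
  av <- car::Anova(mlm, idata = data.frame(day = factor(1:4)),
                   idesign = ~day, type = 3)
  s <- suppressWarnings(summary(av))
  expect_equal(got$F[got$effect == "day"],
               unname(s$univariate.tests["day", "F value"]),
               tolerance = 1e-8)
  expect_equal(got$epsilon_GG[got$effect == "day"],
               unname(s$pval.adjustments["day", "GG eps"]),
               tolerance = 1e-8)
  expect_equal(got$p_GG[got$effect == "day"],
               unname(s$pval.adjustments["day", "Pr(>F[GG])"]),
               tolerance = 1e-8)
  expect_equal(got$p_GG[got$effect == "group:day"],
               unname(s$pval.adjustments["group:day", "Pr(>F[GG])"]),
               tolerance = 1e-8)
})

test_that("two within-levels force GG epsilon to 1", {
  set.seed(23)
  gos <- setNames(rep(c("a", "b"), each = 4), paste0("s", 1:8))
  d <- toy_table(rnorm(16), 2, gos)
  got <- mixed_anova_gg(d, "value", "subject", "day", "group")
  expect_equal(got$epsilon_GG[got$effect == "day"], 1)
  expect_equal(got$p_GG[got$effect == "day"],
               got$p_uncorrected[got$effect == "day"])
})

test_that("ANOVA reduces to repeated measures without a between factor", {
  set.seed(24)
  d <- toy_table(rnorm(15), 3, setNames(rep("all", 5), paste0("s", 1:5)))
  got <- mixed_anova_gg(d, "value", "subject", "day", between = NULL)
  expect_equal(nrow(got), 1)
  expect_equal(got$df2, (5 - 1) * (3 - 1))
  ref <- summary(aov(value ~ factor(day) + Error(subject), data = d))
  F_ref <- ref[["Error: Within"]][[1]]["factor(day)", "F value"]
  expect_equal(got$F, unname(F_ref))
})

test_that("ANOVA is invariant to shifts and its p to positive scaling", {
  set.seed(25)
  gos <- setNames(rep(c("a", "b"), each = 3), paste0("s", 1:6))
  d <- toy_table(rnorm(18), 3, gos)
  base <- mixed_anova_gg(d, "value", "subject", "day", "group")
  d2 <- d; d2$value <- d2$value + 100
  expect_equal(mixed_anova_gg(d2, "value", "subject", "day", "group")$F,
               base$F, tolerance = 1e-8)
  d3 <- d; d3$value <- d3$value * 7
  expect_equal(mixed_anova_gg(d3, "value", "subject", "day", "group")$p_GG,
               base$p_GG, tolerance = 1e-8)
})

test_that("duplicating every subject preserves effects and grows df", {
  set.seed(26)
  gos <- setNames(rep(c("a", "b"), each = 3), paste0("s", 1:6))
  d <- toy_table(rnorm(18), 3, gos)
  d2 <- d; d2$subject <- paste0(d2$subject, "_copy")
  dd <- rbind(d, d2)
  a1 <- mixed_anova_gg(d, "value", "subject", "day", "group")
  a2 <- mixed_anova_gg(dd, "value", "subject", "day", "group")
  o2 <- oracle_split_plot(dd)
  expect_equal(a2$F[a2$effect == "day"], o2$F_day)
  expect_gt(a2$df2[a2$effect == "day"], a1$df2[a1$effect == "day"])
  expect_equal(sign(a2$F[a2$effect == "day"] - 0),
               sign(a1$F[a1$effect == "day"] - 0))
})

test_that("degenerate ANOVA inputs are rejected", {
  gos <- setNames(rep(c("a", "b"), each = 2), paste0("s", 1:4))
  d <- toy_table(rnorm(8), 2, gos)
  expect_error(mixed_anova_gg(d[-1, ], "value", "subject", "day", "group"),
               "incomplete")
  dconst <- d; dconst$value <- 5
  expect_error(mixed_anova_gg(dconst, "value", "subject", "day", "group"),
               "zero residual")
})

test_that("signed-rank p values match enumeration and the reference", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4))$p_value, 0.125)
  expect_equal(wilcoxon_signed_rank(c(2, 1, 5, 4, 3))$p_value, 0.0625)
  expect_equal(wilcoxon_signed_rank(c(3, -3, 1.5, -1.5))$p_value, 1)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "zero")
  zr <- wilcoxon_signed_rank(c(0, 1, 2, 3, 4))
  expect_equal(zr$n_zero_dropped, 1L)
  expect_equal(zr$p_value, 0.125)

  set.seed(31)
  for (i in 1:10) {
    n <- sample(4:11, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- wilcoxon_signed_rank(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(got$statistic, unname(ref$statistic))
  }
})

test_that("rank-sum p values match enumeration and the reference", {
  sep <- wilcoxon_rank_sum(c(10, 11, 12), c(1, 2, 3))
  expect_equal(sep$p_value, 0.1)           # 2 of choose(6,3)=20 splits
  expect_equal(sep$statistic, 9)
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "nonempty")

  set.seed(32)
  for (i in 1:10) {
    n <- sample(3:6, 1); m <- sample(3:6, 1)
    a <- rnorm(n); b <- rnorm(m)
    got <- wilcoxon_rank_sum(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(got$statistic, unname(ref$statistic))
  }
})

test_that("Bonferroni multiplies and caps", {
  expect_equal(bonferroni_adjust(c(0.02, 0.5), m = 3), c(0.06, 1))
  expect_equal(bonferroni_adjust(c(0.01, 0.02)), c(0.02, 0.04))
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), "m must")
})

test_that("the mixed ANOVA holds its nominal size on null cohorts", {
  set.seed(33)
  gos <- setNames(rep(c("a", "b"), each = 5), paste0("s", 1:10))
  rej <- replicate(300, {
    d <- toy_table(rnorm(30), 3, gos)
    res <- mixed_anova_gg(d, "value", "subject", "day", "group")
    res$p_GG[res$effect == "group"] < 0.05
  })
  rate <- mean(rej)
  se <- sqrt(0.05 * 0.95 / 300)
  expect_lt(rate, 0.05 + 3 * se)
  expect_gt(rate, 0.05 - 3 * se)
})
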