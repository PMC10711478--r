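# Independent split-plot sums-of-squares oracle written with explicit
# loops over deviations (no shared code with the implementation).
oracle_split_plot <- function(d) {
  subs <- unique(d$subject)
  days <- sort(unique(d$day))
  grps <- unique(d$group)
  g <- length(grps); k <- length(days); N <- length(subs)
  val <- function(s, dd) d$value[d$subject == s & d$day == dd]
  grand <- mean(d$value)
  sm <- sapply(subs, function(s) mean(d$value[d$subject == s]))
  gm <- sapply(grps, function(gg) mean(d$value[d$group == gg]))
  dm <- setNames(sapply(days, function(dd) mean(d$value[d$day == dd])),
                 days)
  grp_of <- sapply(subs, function(s) d$group[d$subject == s][1])
  ss_group <- 0
  for (gg in grps)
    ss_group <- ss_group + k * sum(grp_of == gg) * (gm[gg] - grand)^2
  ss_subj <- 0
  for (s in subs) ss_subj <- ss_subj + k * (sm[s] - gm[grp_of[s]])^2
  ss_day <- N * sum((dm - grand)^2)
  ss_int <- 0
  for (gg in grps) for (dd in days) {
    cm <- mean(d$value[d$group == gg & d$day == dd])
    ss_int <- ss_int + sum(grp_of == gg) *
      (cm - gm[gg] - dm[as.character(dd)] + grand)^2
  }
  ss_err <- 0
  for (s in subs) for (dd in days) {
    cm <- mean(d$value[d$group == grp_of[s] & d$day == dd])
    ss_err <- ss_err + (val(s, dd) - cm - sm[s] + gm[grp_of[s]])^2
  }
  list(F_group = unname((ss_group / (g - 1)) / (ss_subj / (N - g))),
       F_day = unname((ss_day / (k - 1)) / (ss_err / ((N - g) * (k - 1)))),
       F_int = unname((ss_int / ((g - 1) * (k - 1))) /
         (ss_err / ((N - g) * (k - 1)))))
}

toy_table <- function(values, n_days, groups_of_subject) {
  subs <- names(groups_of_subject)
  d <- expand.grid(subject = subs, day = seq_len(n_days),
                   stringsAsFactors = FALSE)
  d$group <- groups_of_subject[d$subject]
  d$value <- values
  d
}

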