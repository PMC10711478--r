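#!/usr/bin/env Rscript
# Inferential statistics over the day-level metrics: two-way mixed
# ANOVA (group x day, Greenhouse-Geisser corrected) for lap counts,
# running speed and both learning rates in the lesion cohorts, and for
# the stimulation cohort; Wilcoxon rank-sum comparisons of the final
# day with Bonferroni adjustment across the four outcomes.

library(optomaze)

in_dir <- file.path("results", "behavior")
out <- file.path("results", "stats")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

outcomes <- c("n_laps", "mean_speed_cm_s", "correct_response_rate",
              "rule_learning_rate")

all_anova <- list()
all_wilcox <- list()
for (cohort in c("lesion_frl", "lesion_crl", "stim_crl")) {
  days <- utils::read.csv(file.path(in_dir, paste0(cohort, "_days.csv")))
  for (v in outcomes) {
    d <- days[!is.na(days[[v]]), ]
    keep <- names(which(table(d$animal_id) == length(unique(d$day))))
    d <- d[d$animal_id %in% keep, ]
    a <- try(mixed_anova_gg(d, value = v, subject = "animal_id",
                            within = "day", between = "group"),
             silent = TRUE)
    if (!inherits(a, "try-error"))
      all_anova[[paste(cohort, v)]] <- cbind(cohort = cohort, outcome = v, a)
    last <- d[d$day == max(d$day), ]
    gs <- split(last[[v]], last$group)
    if (length(gs) == 2) {
      w <- wilcoxon_rank_sum(gs[[1]], gs[[2]])
      all_wilcox[[paste(cohort, v)]] <- data.frame(
        cohort = cohort, outcome = v, U = w$statistic,
        p = w$p_value, method = w$method)
    }
  }
}

anova_tab <- do.call(rbind, all_anova)
wilcox_tab <- do.call(rbind, all_wilcox)
# Bonferroni across the four outcomes within each cohort
wilcox_tab$p_bonferroni <- ave(wilcox_tab$p, wilcox_tab$cohort,
                               FUN = function(p) bonferroni_adjust(p))
rownames(anova_tab) <- rownames(wilcox_tab) <- NULL

utils::write.csv(anova_tab, file.path(out, "anova.csv"), row.names = FALSE)
utils::write.csv(wilcox_tab, file.path(out, "wilcoxon.csv"),
                 row.names = FALSE)

sig <- anova_tab[anova_tab$effect == "group" & anova_tab$p_GG < 0.05, ]
message("group effects with GG-corrected p < 0.05:")
for (i in seq_len(nrow(sig)))
  message(sprintf("  %s / %s: F(%g,%g) = %.1f, p = %.3g", sig$cohort[i],
                  sig$outcome[i], sig$df1[i], sig$df2[i], sig$F[i],
                  sig$p_GG[i]))
message("tables under ", out)
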