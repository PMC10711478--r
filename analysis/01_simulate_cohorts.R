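#!/usr/bin/env Rscript
# Simulate the study's behavioral cohorts with the value-learning maze
# agent and archive the raw event logs that the later steps ingest:
#   - a lesion cohort (7 control vs 12 dopamine-deficient animals) run
#     on the fixed-reward-location task for 5 days x 4 sessions;
#   - the same cohort on the changing-reward-location task;
#   - stimulation cohorts (control vs long-burst post-stim, n = 6 each)
#     on the changing-reward-location task.

library(optomaze)

out <- file.path("results", "cohorts")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

write_cohort <- function(sim, name) {
  dir.create(file.path(out, name), showWarnings = FALSE)
  for (i in seq_along(sim$logs)) {
    lg <- sim$logs[[i]]
    write_session_log(lg, file.path(out, name, sprintf(
      "%s_d%02d_s%d.csv", lg$animal_id, lg$day, lg$session_index)))
  }
  utils::write.csv(sim$sessions, file.path(out, paste0(name, "_index.csv")),
                   row.names = FALSE)
  message(sprintf("%s: %d sessions written", name, length(sim$logs)))
}

lesion_groups <- list(
  control = list(agent = group_preset("control"), n = 7),
  lesioned = list(agent = group_preset("lesioned"), n = 12))

write_cohort(simulate_experiment(lesion_groups, days = 5, task = "FRL",
                                 seed = 20001), "lesion_frl")
write_cohort(simulate_experiment(lesion_groups, days = 5, task = "CRL",
                                 seed = 20002), "lesion_crl")

stim_groups <- list(
  control = list(agent = group_preset("control"), n = 6),
  stimulated = list(agent = group_preset("stimulated"),
                    stim_condition = "post", stim_duration = "long_40ms",
                    n = 6))
write_cohort(simulate_experiment(stim_groups, days = 5, task = "CRL",
                                 seed = 20003), "stim_crl")

message("done; logs under ", out)
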