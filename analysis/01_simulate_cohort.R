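#!/usr/bin/env Rscript
# Build the synthetic study cohort used throughout the analysis: 231
# participants (117 women, 114 men), integer ages 19-93, and four
# populations with known truth -- a flat control, a smooth sigmoidal
# decline, a sex-specific level shift, and a sex-divergent slope (a true
# age x sex interaction).  The cohort and its ground-truth sidecar go to
# results/cohort/.

library(immunospline)

seed <- 20240901
out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

config <- cohort_config(
  populations = list(
    flat = list(trajectory = traj_constant(500),
                noise = noise_lognormal(0.4)),
    logistic_decline = list(
      trajectory = traj_logistic_decline(600, 300, midpoint = 55, width = 8),
      noise = noise_lognormal(0.4)),
    sex_shift = list(
      trajectory = traj_by_sex(
        female = traj_piecewise_linear(c(19, 40, 42, 68, 70, 93),
                                       c(500, 500, 700, 700, 500, 500)),
        male = traj_constant(500)),
      noise = noise_lognormal(0.4)),
    interaction = list(
      trajectory = traj_by_sex(
        female = traj_piecewise_linear(c(19, 20, 60, 93),
                                       c(700, 700, 380, 380)),
        male = traj_constant(700)),
      noise = noise_lognormal(0.4))),
  n_female = 117, n_male = 114, seed = seed)

sim <- simulate_cohort(config)
write_simulated_cohort(sim, file.path(out_dir, "cohort.tsv"))

cat(sprintf("cohort: %d participants (%d female, %d male), ages %d-%d\n",
            nrow(sim$cohort), sum(sim$cohort$sex == "female"),
            sum(sim$cohort$sex == "male"), min(sim$cohort$age),
            max(sim$cohort$age)))
cat("true interaction window (derivative difference != 0):\n")
print(true_significant_regions(sim$truth, 19:93, "derivative-difference",
                               population = "interaction"))
cat("wrote", file.path(out_dir, "cohort.tsv"), "and ground-truth sidecar\n")
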