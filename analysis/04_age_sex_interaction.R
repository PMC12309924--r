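#!/usr/bin/env Rscript
# Age x sex interaction: the difference of the sex-specific first
# derivatives, f'_female(age) - f'_male(age), with its 95% bootstrap
# band.  Ages where that band excludes zero are ages at which women's
# and men's counts change at significantly different rates.  Also
# renders the three-panel figure (female derivative, male derivative,
# difference) per population.  Writes to results/interaction/.

library(immunospline)

cohort_path <- "results/cohort/cohort.tsv"
if (!file.exists(cohort_path)) stop("run analysis/01_simulate_cohort.R first")

res <- run_pipeline(pipeline_config(
  input = cohort_path,
  analyses = c("within-sex", "interaction"),
  spar = 0.8, level = 0.95, n_boot = 2000,
  seed = 20240904,
  out_dir = "results/interaction"))

int <- res$regions[res$regions$statistic == "derivative-difference", ]
cat("\nsignificant age x sex interaction regions:\n")
print(as.data.frame(int))
cat("\nOnly the interaction population has a true divergence window\n")
cat("(female slope -8 vs male slope 0 on ages 20-60, direction\n")
cat("male-higher because the female derivative is more negative).\n")
cat("With ~115 participants per sex the difference statistic is noisy;\n")
cat("detected windows are typically narrower than the true one.\n")
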