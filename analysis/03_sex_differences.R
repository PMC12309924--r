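#!/usr/bin/env Rscript
# Sex comparison of mean counts: female and male curves fitted
# separately, the female-minus-male level difference bootstrapped with
# stratified (within-sex) resampling, and the population x age matrix of
# significant differences -- the heatmap-style summary.  Writes to
# results/sex_differences/.

library(immunospline)

cohort_path <- "results/cohort/cohort.tsv"
if (!file.exists(cohort_path)) stop("run analysis/01_simulate_cohort.R first")

res <- run_pipeline(pipeline_config(
  input = cohort_path,
  analyses = c("within-sex", "sex-comparison"),
  spar = 0.8, level = 0.95, n_boot = 2000,
  seed = 20240903,
  out_dir = "results/sex_differences"))

lev <- res$regions[res$regions$statistic == "curve-difference", ]
cat("\nage ranges with significantly different mean counts:\n")
print(as.data.frame(lev))
cat("\nOnly the sex_shift population carries a true female-higher window\n")
cat("(ages ~42-68); flat and logistic_decline are shared between sexes.\n")
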