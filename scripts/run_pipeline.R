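#!/usr/bin/env Rscript
# Thin command-line wrapper over the package pipeline: generates (or loads)
# a cohort, runs the five-model experiment and writes all artifacts.
#   Rscript scripts/run_pipeline.R --seed 1 --out runs/demo [--cohort-dir d]
#   [--n-boot 0] [--no-combat-pooled] [--models Clinical,Combined] [--write-cohort]

suppressMessages({library(radiopcr); library(optparse)})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "runs/latest"),
  make_option("--cohort-dir", type = "character", default = NULL,
              help = "write the generated cohort (NIfTI + CSV) here"),
  make_option("--models", type = "character",
              default = "Clinical,Radiomic,Combined,ComBat_Radiomic,ComBat_Combined"),
  make_option("--n-boot", type = "integer", default = 0L),
  make_option("--no-combat-pooled", action = "store_true", default = FALSE),
  make_option("--robustness", action = "store_true", default = FALSE,
              help = "replay test scoring with simulated observer-2 masks")
)))

cohort <- generate_cohort(cohort_config(), seed = opts$seed)
if (!is.null(opts$`cohort-dir`)) write_cohort(cohort, opts$`cohort-dir`)
ex <- run_experiment(cohort, seed = opts$seed,
                     models = strsplit(opts$models, ",")[[1]],
                     n_boot = opts$`n-boot`,
                     combat_pooled = !opts$`no-combat-pooled`,
                     verbose = TRUE)
print(ex)
write_experiment(ex, opts$out)
if (opts$robustness) {
  rb <- evaluate_robustness(ex, cohort, seed = opts$seed + 1L)
  write.csv(rb$report, file.path(opts$out, "robustness.csv"), row.names = FALSE)
  message(sprintf("robustness subset median Dice: %.2f", median(rb$dice)))
}
message("artifacts in ", opts$out)
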