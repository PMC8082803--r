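#!/usr/bin/env Rscript
# Apply the embedded clock to the simulated cohorts (reading them back from
# disk, as one would with real array exports) and summarize accuracy with
# the three standard metrics: mean +/- SD of (DNAm GA - GA), the median
# absolute difference, and the Pearson correlation with chronological GA.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

sim_dir <- out_path("sim")
metrics <- list()
for (nm in c("cordblood_like", "null")) {
  betas <- read_beta_matrix(file.path(sim_dir, paste0(nm, "_betas.csv")))
  pheno <- read_phenotypes(file.path(sim_dir,
                                     paste0(nm, "_phenotypes.csv")))
  clock <- read_clock_table(file.path(sim_dir, paste0(nm, "_clock.csv")))
  est <- apply_clock(clock, betas)
  stopifnot(identical(est$sample_id, pheno$sample_id))
  perf <- clock_metrics(est, pheno$ga_weeks)
  metrics[[nm]] <- list(clock = clock$name, n = perf$n,
                        mean_delta = perf$mean_delta,
                        sd_delta = perf$sd_delta, mad = perf$mad,
                        r = perf$r, r_p = perf$r_p)
  data.table::fwrite(est, out_path(paste0("ages_", nm, ".csv")))
  log_stage("clock-metrics",
            "%s: mean(delta)=%.3f SD=%.3f MAD=%.3f r=%.3f (n=%d)",
            nm, perf$mean_delta, perf$sd_delta, perf$mad, perf$r, perf$n)
}
jsonlite::write_json(metrics, out_path("clock_metrics.json"),
                     auto_unbox = TRUE, digits = NA)
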