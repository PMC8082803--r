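#!/usr/bin/env Rscript
# Cross-tissue concordance on the simulated two-tissue cohort: Pearson
# correlations of DNAm GA and of EAAR between tissues from the same
# individuals, and a paired t / Wilcoxon signed-rank test on the EAAR
# differences gated by Shapiro-Wilk normality.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

sim_dir <- out_path("sim")
tissues <- c("cord_blood", "placenta_fetal")
pe <- lapply(tissues, function(tt) {
  betas <- read_beta_matrix(file.path(sim_dir,
                                      paste0("xt_", tt, "_betas.csv")))
  pheno <- read_phenotypes(file.path(sim_dir,
                                     paste0("xt_", tt,
                                            "_phenotypes.csv")))
  clock <- read_clock_table(file.path(sim_dir,
                                      paste0("xt_", tt, "_clock.csv")))
  cohort_eaar(list(betas = betas, phenotypes = pheno), clock)
})
res <- cross_tissue_concordance(pe[[1]]$estimates, pe[[2]]$estimates,
                                pe[[1]]$eaar, pe[[2]]$eaar,
                                tissues = tissues)
scatter <- merge(
  stats::setNames(pe[[1]]$eaar[c("individual_id", "eaar")],
                  c("individual_id", "eaar_a")),
  stats::setNames(pe[[2]]$eaar[c("individual_id", "eaar")],
                  c("individual_id", "eaar_b")))
data.table::fwrite(scatter, out_path("crosstissue_scatter.csv"))
jsonlite::write_json(
  list(tissues = tissues, n = res$n,
       r_dnamga = res$r_dnamga, p_dnamga = res$p_dnamga,
       r_eaar = res$r_eaar, p_eaar = res$p_eaar,
       shapiro_p = res$shapiro_p, paired = res$paired,
       t_test = res$t_test, wilcoxon = res$wilcoxon,
       eaar_mean = res$eaar_mean, eaar_sd = res$eaar_sd),
  out_path("crosstissue.json"), auto_unbox = TRUE, digits = NA)
log_stage("cross-tissue",
          "n=%d matched; r(DNAmGA)=%.3f p=%.3g; r(EAAR)=%.3f p=%.3g; %s p=%.3g",
          res$n, res$r_dnamga, res$p_dnamga, res$r_eaar, res$p_eaar,
          res$paired$method, res$paired$p)
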