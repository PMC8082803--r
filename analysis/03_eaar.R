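#!/usr/bin/env Rscript
# Epigenetic age acceleration residuals: regress DNAm GA on chronological
# GA, cell-type proportions and the two ancestry components, per cohort.
# Positive residuals = acceleration. Residuals stay in weeks here; they are
# z-standardized only at the entry of the selection stage.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

sim_dir <- out_path("sim")
for (nm in c("cordblood_like", "null")) {
  pheno <- read_phenotypes(file.path(sim_dir,
                                     paste0(nm, "_phenotypes.csv")))
  est <- data.table::fread(out_path(paste0("ages_", nm, ".csv")),
                           data.table = FALSE)
  cells <- pheno[attr(pheno, "cell_cols")]
  ea <- compute_eaar(est$dnam_ga_weeks, pheno$ga_weeks, cells,
                     pheno[c("C1", "C2")], sample_id = pheno$sample_id)
  out <- data.frame(sample_id = ea$sample_id, tissue = pheno$tissue[1],
                    eaar_weeks = ea$eaar)
  data.table::fwrite(out, out_path(paste0("eaar_", nm, ".csv")))
  jsonlite::write_json(
    list(design = attr(ea, "design"),
         reference_cell = attr(ea, "reference_cell"),
         n_complete = attr(ea, "n_complete"),
         n_dropped = attr(ea, "n_dropped"),
         mean_weeks = mean(ea$eaar), sd_weeks = sd(ea$eaar)),
    out_path(paste0("eaar_", nm, "_design.json")),
    auto_unbox = TRUE, digits = NA)
  log_stage("eaar", "%s: n=%d complete, SD=%.3f weeks, reference=%s",
            nm, attr(ea, "n_complete"), sd(ea$eaar),
            attr(ea, "reference_cell"))
}
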