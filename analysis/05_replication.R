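#!/usr/bin/env Rscript
# Cross-cohort replication by coefficient transfer: the median coefficients
# of the discovery cohort's stable variables predict EAAR in an independent
# cohort generated with the same planted effects; the one-tailed Pearson
# correlation between predicted and observed EAAR quantifies replication.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

sel <- jsonlite::read_json(out_path("vip_selection_cordblood_like.json"),
                           simplifyVector = TRUE)
coefs <- with(subset(sel$summary, variable %in% sel$stable_variables),
              stats::setNames(median, variable))
log_stage("replicate", "transferring %d coefficients: %s",
          length(coefs), paste(names(coefs), collapse = ", "))

cfg <- scenario_cordblood_like(n = 400, cohort_id = "REPL")
coh <- generate_cohort(cfg, seed = SEED + 500000L)
pe <- cohort_eaar(coh, cfg$clock)
ph <- as.data.frame(coh$phenotypes)
vars <- attr(coh$phenotypes, "predictors")$name
Xb <- apply(ph[match(pe$eaar$sample_id, ph$sample_id), vars], 2,
            zstandardize)
pred <- predict_external(coefs, Xb)
res <- correlate_one_tailed(pred, pe$eaar$eaar)
jsonlite::write_json(
  list(r = res$r, p_one_tailed = res$p, n = res$n,
       coefficients = as.list(coefs), discovery_seed = SEED,
       replication_seed = SEED + 500000L),
  out_path("replication.json"), auto_unbox = TRUE, digits = NA)
log_stage("replicate", "one-tailed r=%.3f, p=%.4g (n=%d)", res$r, res$p,
          res$n)
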