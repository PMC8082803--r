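# Shared plumbing for the analysis drivers: argument parsing, output
# locations, logging. Every script accepts --seed <int> and --out-dir <dir>
# (defaults: 1, results/).

suppressPackageStartupMessages(library(gestaar))

.args <- commandArgs(trailingOnly = TRUE)
arg_value <- function(flag, default) {
  i <- which(.args == flag)
  if (length(i) && i[1] + 1 <= length(.args)) .args[i[1] + 1] else default
}
SEED <- as.integer(arg_value("--seed", "1"))
OUT_DIR <- arg_value("--out-dir", "results")
dir.create(OUT_DIR, recursive = TRUE, showWarnings = FALSE)

log_stage <- function(stage, ...) {
  cat(sprintf("[%s] seed=%d %s\n", stage, SEED, sprintf(...)))
}

out_path <- function(...) file.path(OUT_DIR, ...)
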