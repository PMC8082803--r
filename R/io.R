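#' Construct a validated beta-value matrix
#'
#' A beta matrix stores DNA methylation beta values (methylated fraction per
#' CpG, in \[0,1\]) with CpGs as rows and samples as columns, the usual
#' series-matrix layout. Missing values are allowed and preserved as `NA`;
#' out-of-range values are rejected.
#'
#' @param values Numeric matrix, CpGs in rows, samples in columns.
#' @param cpg_ids Character vector of unique CpG identifiers (row names).
#' @param sample_ids Character vector of unique sample identifiers (column
#'   names).
#' @return A numeric matrix of class `beta_matrix` with `dimnames` set.
#' @export
beta_matrix <- function(values, cpg_ids = rownames(values),
                        sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("beta values must be numeric")
  if (is.null(cpg_ids) || is.null(sample_ids))
    stop("cpg_ids and sample_ids are required")
  if (length(cpg_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("dimnames do not match matrix dimensions")
  dup <- cpg_ids[duplicated(cpg_ids)]
  if (length(dup))
    stop("duplicate CpG id(s): ", paste(unique(dup), collapse = ", "))
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("beta out of range [0,1] at CpG '%s', sample '%s' (%g)",
                 cpg_ids[bad[1, 1]], sample_ids[bad[1, 2]],
                 values[bad[1, , drop = FALSE]]))
  dimnames(values) <- list(cpg_ids, sample_ids)
  class(values) <- c("beta_matrix", class(values))
  values
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d CpGs x %d samples, %d missing cells\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

.sep_for <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a beta-value matrix from delimited text
#'
#' Expects the first column to hold CpG identifiers and the remaining columns
#' one sample each (set `orientation = "samples_as_rows"` for transposed
#' exports). Delimiter is chosen by extension (`.csv` comma, `.tsv`/`.txt`
#' tab). Non-numeric cells and out-of-range betas are errors; empty cells
#' become `NA`.
#'
#' @param path Path to a CSV/TSV file.
#' @param orientation `"cpgs_as_rows"` (default) or `"samples_as_rows"`.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path,
                             orientation = c("cpgs_as_rows",
                                             "samples_as_rows")) {
  orientation <- match.arg(orientation)
  dt <- data.table::fread(path, sep = .sep_for(path), header = TRUE,
                          data.table = FALSE, colClasses = list(
                            character = 1L))
  if (ncol(dt) < 2L) stop("need an id column plus at least one data column")
  ids <- dt[[1L]]
  num <- dt[-1L]
  for (j in seq_along(num)) {
    col <- num[[j]]
    if (!is.numeric(col)) {
      suppress <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & col != "" & is.na(suppress))
      if (length(bad))
        stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                     bad[1L], names(num)[j], col[bad[1L]]))
      num[[j]] <- suppress
    }
  }
  m <- as.matrix(num)
  if (orientation == "cpgs_as_rows") {
    beta_matrix(m, cpg_ids = ids, sample_ids = colnames(m))
  } else {
    beta_matrix(t(m), cpg_ids = colnames(m), sample_ids = ids)
  }
}

#' Write a beta-value matrix to delimited text
#'
#' @param x A [beta_matrix()].
#' @param path Output path; delimiter chosen by extension.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path) {
  stopifnot(inherits(x, "beta_matrix"))
  dt <- data.table::data.table(cpg = rownames(x))
  dt <- cbind(dt, data.table::as.data.table(unclass(x)))
  data.table::fwrite(dt, path, sep = .sep_for(path))
  invisible(path)
}

#' Construct a linear epigenetic clock model
#'
#' A clock is a named linear predictor over CpG beta values:
#' `age = intercept + sum_j w_j * beta_j`, in its native unit (`weeks` or
#' `days`). Clocks in days are converted to weeks (factor 1/7) when applied.
#'
#' @param name Clock name (non-empty string).
#' @param intercept Intercept in the clock's native unit.
#' @param weights Named numeric vector, CpG id -> weight; finite, non-empty.
#' @param unit `"weeks"` or `"days"`.
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(name, intercept, weights, unit = c("weeks", "days")) {
  unit <- match.arg(unit)
  if (!nzchar(name)) stop("clock name must be non-empty")
  if (!length(weights)) stop("clock weights must be non-empty")
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("clock weights must be named by CpG id")
  dup <- names(weights)[duplicated(names(weights))]
  if (length(dup))
    stop("duplicate CpG in clock: ", paste(unique(dup), collapse = ", "))
  if (!all(is.finite(weights)) || !is.finite(intercept))
    stop("clock coefficients must be finite")
  structure(list(name = name, intercept = unname(intercept),
                 weights = weights, unit = unit),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> '%s': %d CpGs, intercept %.4g, unit %s\n",
              x$name, length(x$weights), x$intercept, x$unit))
  invisible(x)
}

#' Read a clock coefficient table
#'
#' Format: an initial metadata line `#clock=<name>;unit=<weeks|days>`,
#' then a two-column CSV `cpg,weight` containing one reserved row with
#' `cpg = "(Intercept)"`.
#'
#' @param path Path to the clock CSV.
#' @return A [clock_model()].
#' @export
read_clock_table <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first,
                  regexec("^#clock=([^;]+);unit=(weeks|days)\\s*$", first))[[1]]
  if (length(m) != 3L)
    stop("missing metadata line '#clock=<name>;unit=<weeks|days>' in ", path)
  dt <- data.table::fread(path, skip = 1L, header = TRUE,
                          data.table = FALSE,
                          colClasses = list(character = 1L))
  if (!all(c("cpg", "weight") %in% names(dt)))
    stop("clock table needs columns 'cpg' and 'weight'")
  ic <- dt$cpg == "(Intercept)"
  if (!any(ic)) stop("clock table is missing the '(Intercept)' row")
  intercept <- dt$weight[ic][1L]
  w <- dt$weight[!ic]
  names(w) <- dt$cpg[!ic]
  clock_model(m[2], intercept, w, unit = m[3])
}

#' Write a clock coefficient table
#'
#' @param clock A [clock_model()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_clock_table <- function(clock, path) {
  stopifnot(inherits(clock, "clock_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#clock=%s;unit=%s", clock$name, clock$unit), con)
  writeLines("cpg,weight", con)
  writeLines(sprintf("%s,%.17g", c("(Intercept)", names(clock$weights)),
                     c(clock$intercept, unname(clock$weights))), con)
  invisible(path)
}

#' Predictor schema for birth- and pregnancy-related variables
#'
#' The default set covers the 13 birth/pregnancy predictors used in the main
#' models (child sex, birth weight, birth length, head circumference,
#' maternal age, maternal BMI, maternal smoking, parity, delivery mode,
#' induced labor, maternal diabetes, hypertensive disorders, maternal mental
#' disorders); maternal alcohol use can be added as a 14th.
#'
#' @param include_alcohol Add `alcohol_use` (binary) to the schema.
#' @return A data.frame with columns `name` and `type`
#'   (`"binary"`/`"continuous"`).
#' @export
default_predictor_schema <- function(include_alcohol = FALSE) {
  s <- data.frame(
    name = c("child_sex", "birth_weight", "birth_length",
             "head_circumference", "maternal_age", "maternal_bmi",
             "maternal_smoking", "parity", "delivery_mode", "induced_labor",
             "maternal_diabetes", "hypertensive_disorder",
             "mental_disorders"),
    type = c("binary", "continuous", "continuous", "continuous",
             "continuous", "continuous", "binary", "binary", "binary",
             "binary", "binary", "binary", "binary"),
    stringsAsFactors = FALSE)
  if (include_alcohol)
    s <- rbind(s, data.frame(name = "alcohol_use", type = "binary"))
  s
}

.tissue_levels <- c("cvs", "placenta_fetal", "placenta_decidual", "cord_blood")

#' Read a phenotype sample sheet
#'
#' One row per (individual, tissue). Required columns: `sample_id`,
#' `individual_id`, `cohort_id`, `tissue`, `ga_weeks`, the predictor columns
#' of `schema`, at least two cell-proportion columns prefixed `cell_prefix`,
#' and ancestry components `C1`, `C2`. Binary predictors must be coded 0/1;
#' cell proportions are renormalized when their sum is within 1e-3 of 1 and
#' rejected otherwise.
#'
#' @param path CSV/TSV path.
#' @param schema Predictor schema, see [default_predictor_schema()].
#' @param cell_prefix Prefix identifying cell-proportion columns.
#' @return A data.frame of class `phenotype_table` with attributes
#'   `predictors` (the schema) and `cell_cols`.
#' @export
read_phenotypes <- function(path, schema = default_predictor_schema(),
                            cell_prefix = "cell_") {
  dt <- data.table::fread(path, sep = .sep_for(path), header = TRUE,
                          data.table = FALSE)
  phenotype_table(dt, schema = schema, cell_prefix = cell_prefix)
}

#' Validate a phenotype data.frame
#'
#' @param df Data frame with the columns described in [read_phenotypes()].
#' @inheritParams read_phenotypes
#' @return A validated `phenotype_table`.
#' @export
phenotype_table <- function(df, schema = default_predictor_schema(),
                            cell_prefix = "cell_") {
  need <- c("sample_id", "individual_id", "cohort_id", "tissue", "ga_weeks",
            schema$name, "C1", "C2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype sheet missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$tissue), .tissue_levels)
  if (length(bad))
    stop("unknown tissue label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(.tissue_levels, collapse = ", "), ")")
  if (any(!is.na(df$ga_weeks) & df$ga_weeks <= 0))
    stop("ga_weeks must be positive")
  for (v in schema$name[schema$type == "binary"]) {
    x <- df[[v]]
    bad <- which(!is.na(x) & !(x %in% c(0, 1)))
    if (length(bad))
      stop(sprintf("binary predictor '%s' has non-{0,1} value %g at row %d",
                   v, x[bad[1L]], bad[1L]))
  }
  cell_cols <- grep(paste0("^", cell_prefix), names(df), value = TRUE)
  if (length(cell_cols) < 2L)
    stop("need at least two cell-proportion columns with prefix '",
         cell_prefix, "'")
  cp <- as.matrix(df[cell_cols])
  if (any(!is.na(cp) & cp < 0)) stop("cell proportions must be non-negative")
  s <- rowSums(cp)
  off <- which(!is.na(s) & abs(s - 1) > 1e-3)
  if (length(off))
    stop(sprintf("cell proportions sum to %.6f at row %d (|sum-1| > 1e-3)",
                 s[off[1L]], off[1L]))
  renorm <- which(!is.na(s) & abs(s - 1) > 1e-6)
  if (length(renorm))
    df[renorm, cell_cols] <- cp[renorm, , drop = FALSE] / s[renorm]
  key <- paste(df$individual_id, df$tissue)
  if (anyDuplicated(key))
    stop("duplicate (individual, tissue) row: ", key[duplicated(key)][1L])
  attr(df, "predictors") <- schema
  attr(df, "cell_cols") <- cell_cols
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Write a phenotype sheet
#'
#' @param df A `phenotype_table` (or plain data.frame).
#' @param path Output path; delimiter chosen by extension.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(df, path) {
  data.table::fwrite(as.data.frame(df), path, sep = .sep_for(path))
  invisible(path)
}

#' Write a run manifest
#'
#' Records the RNG seed, a hash of the serialized configuration and md5
#' checksums of input files, enough to reproduce deterministic stages
#' bit-identically.
#'
#' @param path Output JSON path.
#' @param seed Integer seed used for the run.
#' @param config Arbitrary configuration object (serialized into the hash).
#' @param inputs Character vector of input file paths to checksum.
#' @param extra Optional named list merged into the manifest.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, seed, config = NULL,
                               inputs = character(), extra = list()) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  manifest <- c(list(
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_md5 = unname(tools::md5sum(tmp)),
    inputs = as.list(stats::setNames(
      unname(tools::md5sum(inputs[file.exists(inputs)])),
      inputs[file.exists(inputs)]))
  ), extra)
  unlink(tmp)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
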