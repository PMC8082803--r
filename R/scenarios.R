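#' Built-in simulation scenarios
#'
#' Three configurations used throughout the tests and analysis scripts:
#'
#' * `scenario_null()` — global null: no predictor affects acceleration
#'   (`gamma = 0`); used to check false-selection control.
#' * `scenario_cordblood_like()` — five planted standardized effects on the
#'   predictors found stable in term cord blood (maternal smoking, birth
#'   length, delivery mode, maternal mental disorders positive; female sex
#'   negative), all |standardized effect| >= 0.2; used for power and
#'   coefficient-recovery checks.
#' * `scenario_crosstissue()` — two term tissues with shared individuals,
#'   no planted predictor effects, and a configurable cross-tissue
#'   acceleration correlation `rho` (pass the result to
#'   [generate_multi_tissue()]).
#'
#' The planted weekly effects of `scenario_cordblood_like()` are 0.30
#' (smoking, birth length) and 0.25 (delivery mode, mental disorders, sex,
#' the last negative) with `sigma_a = 0.8`, chosen so the total acceleration
#' variance is close to 1 week^2 and the standardized effects are ~0.29 and
#' ~0.25.
#'
#' @param n Cohort size.
#' @param include_alcohol Add alcohol use to the predictor set.
#' @param ... Passed to [sim_config()].
#' @return A `sim_config` (or, for `scenario_crosstissue`, a named list of
#'   two configs suitable for [generate_multi_tissue()]).
#' @export
scenario_null <- function(n = 400, include_alcohol = FALSE, ...) {
  sim_config(n = n, tissue = "cord_blood", gamma = NULL,
             include_alcohol = include_alcohol, ...)
}

#' @rdname scenario_null
#' @export
scenario_cordblood_like <- function(n = 400, include_alcohol = FALSE, ...) {
  sim_config(n = n, tissue = "cord_blood",
             gamma = c(maternal_smoking = 0.30, birth_length = 0.30,
                       delivery_mode = 0.25, mental_disorders = 0.25,
                       child_sex = -0.25),
             include_alcohol = include_alcohol, ...)
}

#' @rdname scenario_null
#' @param tissues Two tissue names.
#' @export
scenario_crosstissue <- function(n = 350,
                                 tissues = c("cord_blood",
                                             "placenta_fetal"), ...) {
  stats::setNames(lapply(tissues, function(tt)
    sim_config(n = n, tissue = tt, ...)), tissues)
}

#' Generate a cohort and run the full selection pipeline on it
#'
#' Convenience driver: [generate_cohort()], [cohort_eaar()], then
#' [run_vip()] of the birth/pregnancy predictors on the EAAR.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (used for both generation and bootstrapping).
#' @param B Bootstrap count.
#' @param ... Further arguments to [run_vip()].
#' @return List with `cohort`, `pipeline` (see [cohort_eaar()]) and
#'   `vip_run`.
#' @export
vip_cohort_run <- function(config, seed, B = 200, ...) {
  cohort <- generate_cohort(config, seed)
  pipeline <- cohort_eaar(cohort, config$clock)
  ph <- as.data.frame(cohort$phenotypes)
  vars <- attr(cohort$phenotypes, "predictors")$name
  X <- ph[match(pipeline$eaar$sample_id, ph$sample_id), vars]
  run <- run_vip(X, pipeline$eaar$eaar, B = B, seed = seed, ...)
  list(cohort = cohort, pipeline = pipeline, vip_run = run)
}

#' Clock estimates and EAAR for a generated cohort
#'
#' Convenience pipeline for a cohort from [generate_cohort()] (or one
#' element of [generate_multi_tissue()]): applies the embedding clock to
#' the beta matrix and residualizes the estimates on GA, cell proportions
#' and ancestry.
#'
#' @param cohort List with `betas` and `phenotypes`.
#' @param clock The [clock_model()] to apply (the one embedded by the
#'   generating config).
#' @return List with `estimates` (the [apply_clock()] table plus
#'   `individual_id`) and `eaar` (the [compute_eaar()] table plus
#'   `individual_id`).
#' @export
cohort_eaar <- function(cohort, clock) {
  est <- apply_clock(clock, cohort$betas)
  ph <- as.data.frame(cohort$phenotypes)
  stopifnot(identical(est$sample_id, ph$sample_id))
  cell_cols <- attr(cohort$phenotypes, "cell_cols")
  ea <- compute_eaar(est$dnam_ga_weeks, ph$ga_weeks, ph[cell_cols],
                     ph[c("C1", "C2")], sample_id = ph$sample_id)
  idx <- match(est$sample_id, ph$sample_id)
  est$individual_id <- ph$individual_id[idx]
  ea$individual_id <- ph$individual_id[match(ea$sample_id, ph$sample_id)]
  list(estimates = est, eaar = ea)
}
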