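#' Apply a linear epigenetic clock to a beta matrix
#'
#' Estimates DNA methylation gestational age (DNAm GA) per sample as
#' `intercept + sum_j w_j * beta_j` over the clock CpGs found in the matrix.
#' Clock CpGs absent from the matrix are excluded from the calculation under
#' the default policy (the established practice when applying published
#' clocks to arrays missing some probes; remaining weights are not
#' renormalized). Under `missing_policy = "strict"` any absent CpG is an
#' error. Samples with missing beta values among the retained CpGs are
#' dropped with a warning. Clocks in days are converted to weeks.
#'
#' @param clock A [clock_model()].
#' @param betas A [beta_matrix()].
#' @param missing_policy `"exclude"` (default) or `"strict"`.
#' @return A data.frame with columns `sample_id`, `clock`, `dnam_ga_weeks`,
#'   `n_cpgs_used`, `n_cpgs_missing`.
#' @export
apply_clock <- function(clock, betas,
                        missing_policy = c("exclude", "strict")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(clock, "clock_model"), inherits(betas, "beta_matrix"))
  present <- names(clock$weights) %in% rownames(betas)
  if (!any(present))
    stop("none of the ", length(clock$weights),
         " clock CpGs are present in the beta matrix")
  if (missing_policy == "strict" && !all(present))
    stop("clock CpG(s) absent from beta matrix: ",
         paste(names(clock$weights)[!present], collapse = ", "))
  w <- clock$weights[present]
  sub <- unclass(betas)[names(w), , drop = FALSE]
  ok <- colSums(is.na(sub)) == 0L
  if (!all(ok))
    warning(sum(!ok), " sample(s) dropped: missing beta values among ",
            "retained clock CpGs (", paste(head(colnames(sub)[!ok], 5),
                                           collapse = ", "), ")")
  sub <- sub[, ok, drop = FALSE]
  age <- clock$intercept + drop(crossprod(sub, w))
  if (clock$unit == "days") age <- age / 7
  data.frame(sample_id = colnames(sub),
             clock = clock$name,
             dnam_ga_weeks = unname(age),
             n_cpgs_used = sum(present),
             n_cpgs_missing = sum(!present),
             stringsAsFactors = FALSE)
}

#' Clock accuracy metrics
#'
#' The three standard accuracy summaries for an epigenetic clock, computed on
#' paired DNAm GA and chronological GA (weeks): the mean (and SD) of the raw
#' difference `delta = DNAm GA - GA`, the median absolute difference
#' `median(|delta|)` (reported as MAD; note this is the median of absolute
#' differences, not the median absolute deviation from the median), and the
#' Pearson correlation of DNAm GA with GA, with its two-sided p-value.
#'
#' @param dnam_ga Numeric vector of DNAm GA (weeks), or the data.frame
#'   returned by [apply_clock()] (column `dnam_ga_weeks` is used).
#' @param ga_weeks Chronological gestational age (weeks), same order.
#' @return A list of class `clock_performance`: `mean_delta`, `sd_delta`,
#'   `mad`, `r`, `r_p`, `n`. When either vector has zero variance `r` is `NA`
#'   and `r_flag` explains why.
#' @export
clock_metrics <- function(dnam_ga, ga_weeks) {
  if (is.data.frame(dnam_ga)) dnam_ga <- dnam_ga$dnam_ga_weeks
  ok <- is.finite(dnam_ga) & is.finite(ga_weeks)
  dnam_ga <- dnam_ga[ok]; ga_weeks <- ga_weeks[ok]
  n <- length(dnam_ga)
  if (n < 3L) stop("need at least 3 paired finite observations, got ", n)
  delta <- dnam_ga - ga_weeks
  out <- list(mean_delta = mean(delta),
              sd_delta = sd(delta),
              mad = median(abs(delta)),
              r = NA_real_, r_p = NA_real_, r_flag = NA_character_,
              n = n)
  if (var(dnam_ga) == 0 || var(ga_weeks) == 0) {
    out$r_flag <- "zero variance: correlation undefined"
  } else {
    ct <- cor.test(dnam_ga, ga_weeks, method = "pearson")
    out$r <- unname(ct$estimate)
    out$r_p <- ct$p.value
  }
  class(out) <- "clock_performance"
  out
}

#' @export
print.clock_performance <- function(x, ...) {
  cat(sprintf(
    "<clock_performance> n=%d  mean(delta)=%.3f  SD=%.3f  MAD=%.3f  r=%s\n",
    x$n, x$mean_delta, x$sd_delta, x$mad,
    if (is.na(x$r)) paste0("NA (", x$r_flag, ")") else sprintf("%.3f", x$r)))
  invisible(x)
}
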