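#' Predict EAAR in an external cohort from transferred coefficients
#'
#' Linear score `X %*% coefs` with no intercept: both the coefficients
#' (standardized scale, e.g. the medians of a [coefficient_summary()]) and
#' the external predictors are on the z-standardized scale, the latter
#' standardized within the external cohort.
#'
#' @param coefs Named numeric vector of standardized coefficients.
#' @param X_external Matrix or data.frame of z-standardized predictors with
#'   column names covering `names(coefs)`.
#' @return Numeric vector of predicted (standardized) EAAR.
#' @export
predict_external <- function(coefs, X_external) {
  X <- as.matrix(X_external)
  if (is.null(names(coefs)) || is.null(colnames(X)))
    stop("coefs and X_external columns must be named")
  missing <- setdiff(names(coefs), colnames(X))
  if (length(missing))
    stop("coefficient name(s) absent from external predictors: ",
         paste(missing, collapse = ", "))
  drop(X[, names(coefs), drop = FALSE] %*% coefs)
}

#' One-tailed Pearson correlation (positive association)
#'
#' Pearson r with a one-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom,
#' upper tail (alternative: the correlation is positive). Used to test
#' whether coefficients transferred from one cohort predict observed EAAR
#' in another.
#'
#' @param pred Predicted values.
#' @param obs Observed values, same order.
#' @return List of class `one_tailed_cor`: `r`, `p`, `n`, `df`.
#' @export
correlate_one_tailed <- function(pred, obs) {
  ok <- is.finite(pred) & is.finite(obs)
  pred <- pred[ok]; obs <- obs[ok]
  n <- length(pred)
  if (n < 3L) stop("need at least 3 paired finite observations")
  if (var(pred) == 0 || var(obs) == 0)
    stop("zero variance: correlation undefined")
  r <- cor(pred, obs)
  p <- if (r >= 1) 0 else if (r <= -1) 1 else
    pt(r * sqrt((n - 2) / (1 - r^2)), df = n - 2, lower.tail = FALSE)
  structure(list(r = r, p = p, n = n, df = n - 2L),
            class = "one_tailed_cor")
}

#' @export
print.one_tailed_cor <- function(x, ...) {
  cat(sprintf("<one_tailed_cor> r = %.3f, one-tailed p = %.4g, n = %d\n",
              x$r, x$p, x$n))
  invisible(x)
}

#' Cross-tissue concordance of epigenetic age and acceleration
#'
#' For individuals with both tissues available: Pearson correlations (with
#' two-sided p) between the tissues' DNAm GA values and between their EAAR
#' values, and a paired location test on the EAAR differences. The paired
#' test is gated by Shapiro-Wilk normality of the differences at alpha =
#' 0.05: normal -> paired Student's t test, otherwise paired Wilcoxon
#' signed-rank (zero differences dropped, as is standard for signed ranks).
#' Both test results are always reported so the gate is auditable.
#'
#' @param estimates_a,estimates_b Data frames with columns `individual_id`
#'   and `dnam_ga_weeks` for tissues A and B.
#' @param eaar_a,eaar_b Data frames with columns `individual_id` and `eaar`
#'   (weeks) for tissues A and B.
#' @param tissues Length-2 character vector of tissue labels for reporting.
#' @return List of class `cross_tissue_result`: `n`, `r_dnamga`,
#'   `p_dnamga`, `r_eaar`, `p_eaar`, `paired` (chosen method, statistic,
#'   p), `shapiro_p`, `t_test`, `wilcoxon`, `eaar_mean`, `eaar_sd`.
#' @export
cross_tissue_concordance <- function(estimates_a, estimates_b,
                                     eaar_a, eaar_b,
                                     tissues = c("A", "B")) {
  pick <- function(df, col) {
    if (anyDuplicated(df$individual_id))
      stop("duplicate tissue sample for individual(s): ",
           paste(unique(df$individual_id[duplicated(df$individual_id)]),
                 collapse = ", "))
    stats::setNames(df[[col]], df$individual_id)
  }
  ga_a <- pick(estimates_a, "dnam_ga_weeks")
  ga_b <- pick(estimates_b, "dnam_ga_weeks")
  ea <- pick(eaar_a, "eaar")
  eb <- pick(eaar_b, "eaar")
  ids <- Reduce(intersect, list(names(ga_a), names(ga_b), names(ea),
                                names(eb)))
  n <- length(ids)
  if (n < 3L) stop("fewer than 3 matched individuals with both tissues")
  ga_a <- ga_a[ids]; ga_b <- ga_b[ids]; ea <- ea[ids]; eb <- eb[ids]

  ct_ga <- cor.test(ga_a, ga_b, method = "pearson")
  ct_ea <- cor.test(ea, eb, method = "pearson")
  d <- ea - eb
  if (all(d == 0)) {
    shapiro_p <- NA_real_
    tt <- wt <- NULL
    paired <- list(method = "none", statistic = NA_real_, p = NA_real_,
                   note = "all paired differences are zero: no difference")
  } else {
    shapiro_p <- shapiro.test(d)$p.value
    tt <- t.test(ea, eb, paired = TRUE)
    wt <- suppressWarnings(wilcox.test(ea, eb, paired = TRUE))
    use_t <- shapiro_p >= 0.05
    chosen <- if (use_t) tt else wt
    paired <- list(method = if (use_t) "t" else "wilcoxon",
                   statistic = unname(chosen$statistic),
                   p = chosen$p.value,
                   note = sprintf(
                     "Shapiro-Wilk p = %.3g -> %s test", shapiro_p,
                     if (use_t) "paired t" else "paired Wilcoxon signed-rank"))
  }
  structure(list(
    tissues = tissues, n = n,
    r_dnamga = unname(ct_ga$estimate), p_dnamga = ct_ga$p.value,
    r_eaar = unname(ct_ea$estimate), p_eaar = ct_ea$p.value,
    paired = paired, shapiro_p = shapiro_p,
    t_test = if (!is.null(tt))
      list(statistic = unname(tt$statistic), p = tt$p.value),
    wilcoxon = if (!is.null(wt))
      list(statistic = unname(wt$statistic), p = wt$p.value),
    eaar_mean = c(mean(ea), mean(eb)),
    eaar_sd = c(sd(ea), sd(eb))),
    class = "cross_tissue_result")
}

#' @export
print.cross_tissue_result <- function(x, ...) {
  cat(sprintf("<cross_tissue_result> %s vs %s, n = %d matched\n",
              x$tissues[1], x$tissues[2], x$n))
  cat(sprintf("  DNAm GA: r = %.3f, p = %.3g\n", x$r_dnamga, x$p_dnamga))
  cat(sprintf("  EAAR:    r = %.3f, p = %.3g\n", x$r_eaar, x$p_eaar))
  cat(sprintf("  paired %s test: p = %.3g (%s)\n", x$paired$method,
              x$paired$p, x$paired$note))
  invisible(x)
}
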