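#' Z-standardize a vector
#'
#' Centers to mean 0 and scales to SD 1 (n-1 denominator). Constant vectors
#' are an error: a predictor without variation carries no information and
#' would break penalized fits downstream.
#'
#' @param x Numeric vector without missing values.
#' @return Standardized numeric vector.
#' @export
zstandardize <- function(x) {
  if (anyNA(x)) stop("zstandardize: missing values not allowed")
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("zstandardize: constant vector (SD = 0)")
  (x - mean(x)) / s
}

#' Epigenetic age acceleration residuals (EAAR)
#'
#' EAAR is the residual from an ordinary-least-squares regression of DNAm GA
#' on chronological GA, the estimated cell-type proportions of the tissue,
#' and the first two genetic-ancestry components. A positive residual means
#' the methylation profile looks older than the chronological age
#' (acceleration); negative means deceleration. Residuals are returned in
#' weeks.
#'
#' One cell-type proportion column (the alphabetically last name) is dropped
#' as the reference category: proportions sum to one, so the full set is
#' collinear with the intercept. The residuals are invariant to which column
#' is dropped (the design column space is identical).
#'
#' Only complete cases enter the fit; incomplete samples are dropped and
#' counted in `n_dropped`.
#'
#' @param dnam_ga Numeric vector of DNAm GA (weeks) or the output of
#'   [apply_clock()].
#' @param ga Chronological GA (weeks), same order. For first-trimester CVS
#'   supply the GA at sampling; for term tissues the GA at birth.
#' @param cell_props Matrix or data.frame of non-negative cell-type
#'   proportions (named columns).
#' @param ancestry Matrix or data.frame with two ancestry components.
#' @param sample_id Optional sample identifiers.
#' @return A data.frame of class `eaar` with columns `sample_id`, `eaar`
#'   and attributes `design` (regressor names), `reference_cell`,
#'   `n_complete`, `n_dropped`.
#' @export
compute_eaar <- function(dnam_ga, ga, cell_props, ancestry,
                         sample_id = NULL) {
  if (is.data.frame(dnam_ga)) {
    if (is.null(sample_id)) sample_id <- dnam_ga$sample_id
    dnam_ga <- dnam_ga$dnam_ga_weeks
  }
  cell_props <- as.matrix(cell_props)
  ancestry <- as.matrix(ancestry)
  if (is.null(colnames(cell_props)))
    stop("cell_props must have named columns")
  if (ncol(ancestry) != 2L) stop("ancestry must have exactly two columns")
  if (is.null(colnames(ancestry))) colnames(ancestry) <- c("C1", "C2")
  if (is.null(sample_id)) sample_id <- as.character(seq_along(dnam_ga))
  n <- length(dnam_ga)
  stopifnot(length(ga) == n, nrow(cell_props) == n, nrow(ancestry) == n)

  ref <- sort(colnames(cell_props))[ncol(cell_props)]
  keep_cells <- cell_props[, setdiff(colnames(cell_props), ref),
                           drop = FALSE]
  X <- cbind(ga = ga, keep_cells, ancestry)
  cc <- complete.cases(X) & is.finite(dnam_ga)
  n_drop <- sum(!cc)
  Xc <- cbind(`(Intercept)` = 1, X[cc, , drop = FALSE])
  y <- dnam_ga[cc]
  if (nrow(Xc) < ncol(Xc) + 1L)
    stop("insufficient samples: need at least ", ncol(Xc) + 1L,
         " complete cases, got ", nrow(Xc))
  fit <- lm.fit(Xc, y)
  if (fit$rank < ncol(Xc)) {
    collinear <- colnames(Xc)[is.na(fit$coefficients)]
    stop("rank-deficient design after dropping reference cell type; ",
         "collinear column(s): ", paste(collinear, collapse = ", "))
  }
  out <- data.frame(sample_id = sample_id[cc],
                    eaar = unname(fit$residuals),
                    stringsAsFactors = FALSE)
  attr(out, "design") <- colnames(Xc)
  attr(out, "reference_cell") <- ref
  attr(out, "n_complete") <- nrow(Xc)
  attr(out, "n_dropped") <- n_drop
  class(out) <- c("eaar", "data.frame")
  out
}
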