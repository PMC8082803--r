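#' Lambda path for the elastic net
#'
#' Log-spaced sequence of `n_lambda` penalty values from the smallest lambda
#' that zeroes every coefficient down to `lambda_min_ratio` times it. For
#' ridge (`alpha = 0`) the path anchor of `alpha = 0.001` is used, since the
#' pure-ridge entry point is infinite.
#'
#' @param X Predictor matrix (columns standardized).
#' @param y Response vector.
#' @param alpha Elastic-net mixing parameter in \[0,1\].
#' @param n_lambda Path length.
#' @param lambda_min_ratio Ratio of smallest to largest lambda.
#' @return Decreasing numeric vector of length `n_lambda`.
#' @export
enet_lambda_path <- function(X, y, alpha, n_lambda = 100,
                             lambda_min_ratio = 1e-4) {
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X))
  lmax <- max(abs(crossprod(Xc, y - mean(y)))) / (n * max(alpha, 0.001))
  if (!is.finite(lmax) || lmax <= 0)
    stop("cannot anchor lambda path: X'y is zero or non-finite")
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

#' Fit a gaussian elastic-net coefficient path
#'
#' Coordinate-descent solver for
#' `(1/2n)*RSS + lambda*(alpha*L1 + (1-alpha)/2*L2)` with an unpenalized
#' intercept, warm-started along a decreasing lambda sequence
#' (covariance updates; no internal standardization).
#'
#' @inheritParams enet_lambda_path
#' @param lambda Decreasing penalty sequence; default from
#'   [enet_lambda_path()].
#' @return List with `beta` (p x L matrix), `a0` (intercepts), `nzero`
#'   (non-zero counts per lambda), `lambda`, `alpha`.
#' @export
enet_path <- function(X, y, alpha, lambda = enet_lambda_path(X, y, alpha)) {
  X <- as.matrix(X)
  fit <- .enet_path_cpp(X, y, alpha, lambda)
  rownames(fit$beta) <- colnames(X)
  fit$nzero <- as.integer(fit$nzero)
  fit$a0 <- as.numeric(fit$a0)
  fit$lambda <- lambda
  fit$alpha <- alpha
  fit
}

#' Bootstrapped elastic-net fits over an alpha grid
#'
#' The selection engine: for each of `B` bootstrap resamples (n draws with
#' replacement) and each mixing parameter in `alpha_grid`, a lambda path of
#' `n_lambda` values is fit and scored by `k_folds`-fold cross-validated mean
#' squared error (cvm). Fold assignment is drawn fresh per bootstrap and
#' shared across the alpha grid, so alphas compete on identical folds. Each
#' (alpha, lambda) yields a candidate model whose size `nzero` is the count
#' of non-zero coefficients of the fit on the full bootstrap sample; within
#' each (bootstrap, nzero) group only the minimum-cvm candidate is retained
#' as that bootstrap's best model of that size.
#'
#' `X` and `y` must be z-standardized once, on the full complete-case data
#' set, before calling (coefficients are then on the standardized scale and
#' comparable across bootstraps); resamples are not re-standardized.
#'
#' All randomness derives from `seed`; a fixed seed gives byte-identical
#' output.
#'
#' @param X Numeric matrix of z-standardized predictors (named columns).
#' @param y Z-standardized response (e.g. standardized EAAR).
#' @param B Number of bootstrap resamples (study default 1000; use smaller
#'   values for quick runs).
#' @param alpha_grid Mixing parameters; default 0, 0.1, ..., 1.
#' @param n_lambda Lambda path length per (bootstrap, alpha).
#' @param k_folds Cross-validation folds.
#' @param seed Integer RNG seed.
#' @param lambda_min_ratio Smallest/largest lambda ratio.
#' @return Object of class `enet_boot`: list with `records` (data.frame
#'   `b`, `alpha`, `lambda`, `nzero`, `cvm`; one row per retained best
#'   model), `coef` (matrix of standardized coefficients, rows aligned with
#'   `records`), and the call parameters.
#' @export
fit_bootstrap_enet <- function(X, y, B = 1000,
                               alpha_grid = seq(0, 1, by = 0.1),
                               n_lambda = 100, k_folds = 10, seed = 1,
                               lambda_min_ratio = 1e-4) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) stop("X must have named columns")
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (anyNA(X) || anyNA(y))
    stop("X and y must be complete cases (no missing values)")
  if (sd(y) == 0) stop("y is constant: nothing to select")
  if (n < 5 * k_folds)
    stop("n = ", n, " is below 5 * k_folds = ", 5 * k_folds,
         "; use fewer folds")
  zbad <- which(abs(colMeans(X)) > 1e-6 | abs(apply(X, 2L, sd) - 1) > 1e-6)
  if (length(zbad))
    stop("X columns must be z-standardized (mean 0, SD 1): ",
         paste(colnames(X)[zbad], collapse = ", "))
  if (B < 1) stop("B must be >= 1")

  set.seed(seed)
  rec_list <- vector("list", B)
  coef_list <- vector("list", B)
  nA <- length(alpha_grid)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    foldid <- sample(rep_len(seq_len(k_folds), n))
    Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
    lam_mat <- vapply(alpha_grid, function(a)
      enet_lambda_path(Xb, yb, a, n_lambda, lambda_min_ratio),
      numeric(n_lambda))
    cv <- .enet_cv_grid_cpp(Xb, yb, as.integer(foldid), alpha_grid,
                            lam_mat)
    nz <- as.integer(cv$nzero)
    cvm <- as.numeric(cv$cvm)
    alp <- rep(alpha_grid, each = n_lambda)
    lam <- as.numeric(lam_mat)
    cf <- cv$beta
    o <- order(nz, cvm)               # stable: ties keep grid order
    keep <- o[!duplicated(nz[o])]
    keep <- keep[order(nz[keep])]
    rec_list[[b]] <- data.frame(b = b, alpha = alp[keep],
                                lambda = lam[keep], nzero = nz[keep],
                                cvm = cvm[keep])
    coef_list[[b]] <- cf[, keep, drop = FALSE]
  }
  records <- do.call(rbind, rec_list)
  coefm <- t(do.call(cbind, coef_list))
  colnames(coefm) <- colnames(X)
  structure(list(records = records, coef = coefm, B = B, seed = seed,
                 alpha_grid = alpha_grid, n_lambda = n_lambda,
                 k_folds = k_folds, n = n, var_names = colnames(X)),
            class = "enet_boot")
}

#' @export
print.enet_boot <- function(x, ...) {
  cat(sprintf(
    "<enet_boot> B=%d bootstraps, n=%d, p=%d, %d retained best models\n",
    x$B, x$n, length(x$var_names), nrow(x$records)))
  invisible(x)
}

#' Variable inclusion probabilities and the median-cvm curve
#'
#' Aggregates retained best models over bootstraps: for every model size
#' `nzero`, the median cross-validation error across contributing bootstraps
#' and, per predictor, the VIP — the percentage of contributing bootstraps
#' whose best model of that size has the predictor non-zero. Sizes reached
#' by fewer than `coverage` of the bootstraps are reported but flagged out
#' of the elbow curve (`in_curve = FALSE`).
#'
#' @param fit An `enet_boot` from [fit_bootstrap_enet()].
#' @param coverage Minimum fraction of bootstraps a size must appear in to
#'   enter the elbow curve (default 0.5).
#' @return Data frame of class `vip_table`: `nzero`, `n_boot`, `in_curve`,
#'   `median_cvm`, then one VIP column (percent) per predictor.
#' @export
summarize_vip <- function(fit, coverage = 0.5) {
  stopifnot(inherits(fit, "enet_boot"))
  rec <- fit$records
  if (!nrow(rec)) stop("empty record set")
  sizes <- sort(unique(rec$nzero))
  rows <- lapply(sizes, function(nz) {
    at <- rec$nzero == nz
    vips <- 100 * colMeans(fit$coef[at, , drop = FALSE] != 0)
    c(nzero = nz, n_boot = sum(at), median_cvm = median(rec$cvm[at]), vips)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$in_curve <- out$n_boot >= coverage * fit$B
  out <- out[c("nzero", "n_boot", "in_curve", "median_cvm", fit$var_names)]
  attr(out, "B") <- fit$B
  attr(out, "coverage") <- coverage
  attr(out, "vars") <- fit$var_names
  class(out) <- c("vip_table", "data.frame")
  out
}

#' Choose the model size at the elbow of the median-cvm curve
#'
#' Scales both axes of the (nzero, median_cvm) curve to \[0,1\], draws the
#' chord from the first to the last point, and returns the interior point
#' farthest below it — the point of most decreasing error. The distance is
#' signed: points above the chord mark concavity, not an elbow, so a flat,
#' linear or concave curve has no elbow and falls back to the smallest
#' interior size (maximal parsimony, method `"no_elbow"`). Ties break to
#' the smallest size. Curves with fewer than three points, or with no net
#' decrease, fall back to the size minimizing median cvm
#' (method `"fallback_argmin"`).
#'
#' @param curve A `vip_table` (rows with `in_curve = TRUE` are used) or a
#'   data.frame with columns `nzero` and `median_cvm`.
#' @return Integer chosen size, with attributes `method`
#'   (`"elbow"`, `"no_elbow"`, or `"fallback_argmin"`) and `distances`
#'   (signed, on the normalized scale).
#' @export
select_nzero_elbow <- function(curve) {
  if (inherits(curve, "vip_table"))
    curve <- curve[curve$in_curve, c("nzero", "median_cvm")]
  curve <- as.data.frame(curve)[c("nzero", "median_cvm")]
  curve <- curve[order(curve$nzero), ]
  L <- nrow(curve)
  if (L == 0L) stop("empty curve")
  x <- curve$nzero; y <- curve$median_cvm
  if (L < 3L || all(diff(y) >= 0)) {
    chosen <- x[which.min(y)]
    return(structure(as.integer(chosen), method = "fallback_argmin",
                     distances = rep(0, L)))
  }
  xs <- (x - x[1L]) / (x[L] - x[1L])
  ry <- max(y) - min(y)
  ys <- if (ry > 0) (y - min(y)) / ry else rep(0, L)
  # signed distance below the chord (xs_1,ys_1)-(xs_L,ys_L): the elbow of a
  # decreasing curve is the point of most decreasing error, i.e. the point
  # farthest BELOW the chord; points above it mark concavity, not an elbow
  dx <- xs[L] - xs[1L]; dy <- ys[L] - ys[1L]
  chord_y <- ys[1L] + dy * (xs - xs[1L]) / dx
  d <- (chord_y - ys) / sqrt(1 + (dy / dx)^2)
  d[c(1L, L)] <- -Inf                      # interior points only
  dmax <- max(d)
  if (dmax <= 1e-12) {                     # flat, linear or concave curve:
    chosen <- x[2L]                        # no elbow; maximal parsimony
    method <- "no_elbow"
  } else {
    chosen <- x[which(d == dmax)][1L]      # sorted: first hit = smallest nzero
    method <- "elbow"
  }
  structure(as.integer(chosen), method = method,
            distances = replace(d, c(1L, L), 0))
}

#' Stable variables at a chosen model size
#'
#' A predictor is declared sufficiently stable when its VIP at the chosen
#' size strictly exceeds `100 * threshold` percent of contributing
#' bootstraps (default > 75%).
#'
#' @param vip A `vip_table` from [summarize_vip()].
#' @param chosen_nzero Model size (must be present in `vip`).
#' @param threshold Stability threshold as a fraction (default 0.75).
#' @return Character vector of stable predictor names (possibly empty).
#' @export
select_stable_variables <- function(vip, chosen_nzero, threshold = 0.75) {
  stopifnot(inherits(vip, "vip_table"), threshold > 0, threshold < 1)
  row <- vip[vip$nzero == chosen_nzero, , drop = FALSE]
  if (!nrow(row)) stop("chosen_nzero ", chosen_nzero, " not present in table")
  vars <- attr(vip, "vars")
  v <- unlist(row[1, vars])
  names(v)[v > 100 * threshold]
}

#' Summarize coefficients at the chosen model size
#'
#' For each predictor, the median and 95% confidence interval
#' (2.5th/97.5th percentiles, linear interpolation between order statistics)
#' of its standardized coefficient across the bootstraps in which it was
#' non-zero at the chosen size. The exported prediction vector holds the
#' medians of the stable variables and zero elsewhere.
#'
#' @param fit An `enet_boot`.
#' @param chosen_nzero Chosen model size.
#' @param stable_variables Character vector from
#'   [select_stable_variables()].
#' @param threshold Stability threshold recorded in the result.
#' @return Object of class `vip_selection`: list with `chosen_nzero`,
#'   `stable_variables`, `summary` (data.frame: variable, n_nonzero, vip,
#'   median, ci_lo, ci_hi), `coef_predict` (named vector), `threshold`,
#'   `B`, `seed`.
#' @export
coefficient_summary <- function(fit, chosen_nzero, stable_variables,
                                threshold = 0.75) {
  stopifnot(inherits(fit, "enet_boot"))
  at <- fit$records$nzero == chosen_nzero
  if (!any(at))
    stop("no bootstrap contributed a model of size ", chosen_nzero)
  cf <- fit$coef[at, , drop = FALSE]
  n_contrib <- nrow(cf)
  rows <- lapply(fit$var_names, function(v) {
    vals <- cf[cf[, v] != 0, v]
    if (!length(vals))
      return(data.frame(variable = v, n_nonzero = 0L, vip = 0,
                        median = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_))
    q <- quantile(vals, c(0.025, 0.975), type = 7, names = FALSE)
    data.frame(variable = v, n_nonzero = length(vals),
               vip = 100 * length(vals) / n_contrib,
               median = median(vals), ci_lo = q[1], ci_hi = q[2])
  })
  summary <- do.call(rbind, rows)
  omitted <- summary$variable[summary$n_nonzero == 0L]
  if (length(omitted))
    message("never non-zero at nzero = ", chosen_nzero,
            " (summary omitted): ", paste(omitted, collapse = ", "))
  coef_predict <- stats::setNames(rep(0, length(fit$var_names)),
                                  fit$var_names)
  coef_predict[stable_variables] <-
    summary$median[match(stable_variables, summary$variable)]
  structure(list(chosen_nzero = as.integer(chosen_nzero),
                 stable_variables = stable_variables,
                 summary = summary, coef_predict = coef_predict,
                 n_contributing = n_contrib, threshold = threshold,
                 B = fit$B, seed = fit$seed),
            class = "vip_selection")
}

#' @export
print.vip_selection <- function(x, ...) {
  cat(sprintf("<vip_selection> nzero=%d, %d stable variable(s) (VIP > %g%%, B=%d)\n",
              x$chosen_nzero, length(x$stable_variables),
              100 * x$threshold, x$B))
  if (length(x$stable_variables)) {
    s <- x$summary[x$summary$variable %in% x$stable_variables, ]
    print(s, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' End-to-end VIP selection of acceleration predictors
#'
#' Convenience wrapper: z-standardizes the predictors and the outcome once
#' on the full complete-case data, runs [fit_bootstrap_enet()],
#' [summarize_vip()], [select_nzero_elbow()], [select_stable_variables()]
#' and [coefficient_summary()].
#'
#' @param predictors Data frame or matrix of predictors (one row per
#'   sample).
#' @param outcome Numeric outcome per sample (e.g. EAAR in weeks).
#' @param B,alpha_grid,n_lambda,k_folds,seed Passed to
#'   [fit_bootstrap_enet()].
#' @param threshold Stability threshold (fraction).
#' @param coverage Curve coverage rule, see [summarize_vip()].
#' @return List of class `vip_run`: `fit`, `vip`, `chosen_nzero`,
#'   `selection` (a `vip_selection`).
#' @export
run_vip <- function(predictors, outcome, B = 1000,
                    alpha_grid = seq(0, 1, by = 0.1), n_lambda = 100,
                    k_folds = 10, seed = 1, threshold = 0.75,
                    coverage = 0.5) {
  X <- as.matrix(as.data.frame(predictors))
  cc <- complete.cases(X) & is.finite(outcome)
  X <- X[cc, , drop = FALSE]
  y <- outcome[cc]
  X <- apply(X, 2L, zstandardize)
  y <- zstandardize(y)
  fit <- fit_bootstrap_enet(X, y, B = B, alpha_grid = alpha_grid,
                            n_lambda = n_lambda, k_folds = k_folds,
                            seed = seed)
  vip <- summarize_vip(fit, coverage = coverage)
  chosen <- select_nzero_elbow(vip)
  stable <- select_stable_variables(vip, chosen, threshold)
  sel <- coefficient_summary(fit, chosen, stable, threshold)
  structure(list(fit = fit, vip = vip, chosen_nzero = chosen,
                 selection = sel, n_complete = sum(cc)),
            class = "vip_run")
}

#' @export
print.vip_run <- function(x, ...) {
  cat(sprintf("<vip_run> n=%d complete cases; chosen nzero=%d (%s)\n",
              x$n_complete, as.integer(x$chosen_nzero),
              attr(x$chosen_nzero, "method")))
  print(x$selection)
  invisible(x)
}
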