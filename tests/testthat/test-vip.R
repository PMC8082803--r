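# --- the elastic-net solver against an independent implementation -----------

test_that("coefficient paths agree with glmnet and never have higher objective", {
  skip_if_not_installed("glmnet")
  set.seed(101)
  n <- 150; p <- 9
  X <- apply(matrix(rnorm(n * p), n, p), 2, zstandardize)
  colnames(X) <- paste0("x", 1:p)
  y <- zstandardize(X[, 1] * 0.6 - X[, 4] * 0.3 + rnorm(n))
  obj <- function(b, a0, lam, alpha) {
    r <- y - a0 - X %*% b
    sum(r^2) / (2 * n) + lam * (alpha * sum(abs(b)) +
                                  (1 - alpha) / 2 * sum(b^2))
  }
  for (a in c(0.1, 0.5, 1)) {
    lam <- enet_lambda_path(X, y, a)
    mine <- enet_path(X, y, a, lam)
    g <- glmnet::glmnet(X, y, alpha = a, lambda = lam,
                        standardize = FALSE, thresh = 1e-14)
    expect_lt(max(abs(as.matrix(g$beta) - mine$beta)), 1e-3)
    expect_lt(max(abs(g$a0 - mine$a0)), 1e-3)
    for (k in c(1, 30, 60, 100))
      expect_lte(obj(mine$beta[, k], mine$a0[k], lam[k], a),
                 obj(as.matrix(g$beta)[, k], g$a0[k], lam[k], a) + 1e-6)
  }
})

test_that("ridge retains all coefficients: every alpha=0 record has nzero = p", {
  set.seed(102)
  n <- 60; p <- 4
  X <- apply(matrix(rnorm(n * p), n, p), 2, zstandardize)
  colnames(X) <- paste0("x", 1:p)
  y <- zstandardize(X[, 2] + rnorm(n))
  fit <- fit_bootstrap_enet(X, y, B = 3, alpha_grid = 0, seed = 1)
  expect_true(all(fit$records$nzero == p))
  expect_equal(nrow(fit$records), 3L)   # one size per bootstrap
})

test_that("a lone true predictor enters the lasso path first and wins at nzero = 1", {
  set.seed(103)
  n <- 50; p <- 3
  X <- apply(matrix(rnorm(n * p), n, p), 2, zstandardize)
  colnames(X) <- c("x1", "x2", "x3")
  y <- X[, 1]
  # oracle: scan the whole lasso path; the first non-zero coefficient is x1
  path <- enet_path(X, y, alpha = 1)
  first <- which(path$nzero > 0)[1]
  expect_equal(rownames(path$beta)[path$beta[, first] != 0], "x1")
  fit <- fit_bootstrap_enet(X, y, B = 1, seed = 9)
  rec1 <- which(fit$records$nzero == 1)
  expect_length(rec1, 1L)
  expect_true(fit$coef[rec1, "x1"] != 0)
  expect_equal(sum(fit$coef[rec1, ] != 0), 1L)
})

test_that("bootstrap fits are byte-identical under a fixed seed", {
  set.seed(104)
  n <- 60; p <- 5
  X <- apply(matrix(rnorm(n * p), n, p), 2, zstandardize)
  colnames(X) <- paste0("x", 1:p)
  y <- zstandardize(X[, 1] + rnorm(n))
  f1 <- fit_bootstrap_enet(X, y, B = 4, seed = 77)
  f2 <- fit_bootstrap_enet(X, y, B = 4, seed = 77)
  expect_identical(f1$records, f2$records)
  expect_identical(f1$coef, f2$coef)
  f3 <- fit_bootstrap_enet(X, y, B = 4, seed = 78)
  expect_false(identical(f1$records, f3$records))
})

test_that("permuting predictor columns permutes the outputs correspondingly", {
  set.seed(105)
  n <- 80; p <- 5
  X <- apply(matrix(rnorm(n * p), n, p), 2, zstandardize)
  colnames(X) <- paste0("x", 1:p)
  y <- zstandardize(X[, 1] * 0.5 - X[, 3] * 0.4 + rnorm(n))
  perm <- c(4, 2, 5, 1, 3)
  f1 <- fit_bootstrap_enet(X, y, B = 5, seed = 3)
  f2 <- fit_bootstrap_enet(X[, perm], y, B = 5, seed = 3)
  expect_equal(f1$records$nzero, f2$records$nzero)
  # sweep order differs under permutation, so agreement is to solver
  # tolerance, not bitwise
  expect_equal(f1$records$cvm, f2$records$cvm, tolerance = 1e-7)
  expect_equal(f1$coef[, colnames(f2$coef)], f2$coef, tolerance = 1e-5)
  v1 <- summarize_vip(f1); v2 <- summarize_vip(f2)
  expect_equal(v1[, paste0("x", 1:5)], v2[, paste0("x", 1:5)],
               tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("retained records are the minimum-cvm model of each (bootstrap, nzero) group", {
  set.seed(106)
  n <- 60; p <- 4
  X <- apply(matrix(rnorm(n * p), n, p), 2, zstandardize)
  colnames(X) <- paste0("x", 1:p)
  y <- zstandardize(X[, 1] + rnorm(n))
  seed <- 55; k_folds <- 10
  fit <- fit_bootstrap_enet(X, y, B = 1, k_folds = k_folds, seed = seed)
  # replay the bootstrap's RNG stream and recompute the full grid
  set.seed(seed)
  idx <- sample.int(n, n, replace = TRUE)
  foldid <- sample(rep_len(seq_len(k_folds), n))
  Xb <- X[idx, ]; yb <- y[idx]
  grid <- do.call(rbind, lapply(seq(0, 1, 0.1), function(a) {
    path <- enet_lambda_path(Xb, yb, a)
    cv <- gestaar:::.enet_cv_cpp(Xb, yb, as.integer(foldid), a, path)
    data.frame(nzero = as.integer(cv$nzero), cvm = as.numeric(cv$cvm))
  }))
  for (i in seq_len(nrow(fit$records))) {
    nz <- fit$records$nzero[i]
    expect_equal(fit$records$cvm[i], min(grid$cvm[grid$nzero == nz]),
                 tolerance = 1e-12)
  }
})

# --- aggregation arithmetic --------------------------------------------------

test_that("VIP percentages and the coverage rule follow their definitions", {
  # 10 bootstraps at nzero=1: x1 non-zero in 8 of them -> VIP 80%
  B <- 10
  rec <- data.frame(b = 1:B, alpha = 1, lambda = 0.1, nzero = 1,
                    cvm = seq(1, 2, length.out = B))
  cf <- cbind(x1 = c(rep(0.5, 8), 0, 0), x2 = c(rep(0, 8), 0.4, 0.4))
  # nzero=2 appears in only 4 of 10 bootstraps -> reported, out of curve
  rec2 <- data.frame(b = 1:4, alpha = 0.5, lambda = 0.05, nzero = 2,
                     cvm = rep(0.9, 4))
  cf2 <- cbind(x1 = rep(0.3, 4), x2 = rep(-0.2, 4))
  fit <- fake_enet_boot(rbind(rec, rec2), rbind(cf, cf2), B = B)
  vip <- summarize_vip(fit)
  r1 <- vip[vip$nzero == 1, ]
  expect_equal(r1$x1, 80)
  expect_equal(r1$x2, 20)
  expect_equal(r1$median_cvm, median(rec$cvm))
  expect_true(r1$in_curve)
  expect_false(vip$in_curve[vip$nzero == 2])
  expect_equal(vip$n_boot[vip$nzero == 2], 4)
  expect_error(summarize_vip(fake_enet_boot(rec[0, ], cf[0, , drop = FALSE],
                                            B = 1)), "empty")
})

test_that("the elbow rule picks the hand-computed farthest point from the chord", {
  curve <- data.frame(nzero = 1:5, median_cvm = c(10, 4, 3, 2.8, 2.7))
  ch <- select_nzero_elbow(curve)
  expect_equal(as.integer(ch), 2L)
  expect_equal(attr(ch, "method"), "elbow")
})

test_that("degenerate curves fall back as documented", {
  lin <- data.frame(nzero = 1:4, median_cvm = c(4, 3, 2, 1))
  ch <- select_nzero_elbow(lin)
  expect_equal(as.integer(ch), 2L)            # smallest interior on a line
  expect_equal(attr(ch, "method"), "no_elbow")
  # concave (decreasing but bending the wrong way): no elbow either
  conc <- data.frame(nzero = 0:4, median_cvm = c(4, 3.9, 3.7, 3.2, 1))
  chc <- select_nzero_elbow(conc)
  expect_equal(as.integer(chc), 1L)
  expect_equal(attr(chc, "method"), "no_elbow")
  one <- data.frame(nzero = 3, median_cvm = 1)
  ch1 <- select_nzero_elbow(one)
  expect_equal(as.integer(ch1), 3L)
  expect_equal(attr(ch1, "method"), "fallback_argmin")
  up <- data.frame(nzero = 1:4, median_cvm = c(1, 2, 3, 4))
  chu <- select_nzero_elbow(up)
  expect_equal(as.integer(chu), 1L)           # non-decreasing -> argmin
  expect_equal(attr(chu, "method"), "fallback_argmin")
  expect_error(select_nzero_elbow(lin[0, ]), "empty")
})

test_that("elbow choice agrees with a brute-force distance oracle on random curves", {
  oracle <- function(x, y) {
    # signed height of the chord above each point, scaled to a distance
    L <- length(x)
    xs <- (x - x[1]) / (x[L] - x[1])
    ys <- (y - min(y)) / (max(y) - min(y))
    chord <- ys[1] + (ys[L] - ys[1]) * xs
    d <- (chord - ys) / sqrt(1 + (ys[L] - ys[1])^2)
    d[c(1, L)] <- -Inf
    if (max(d) <= 1e-12) return(x[2])
    x[which(d == max(d))][1]
  }
  set.seed(107)
  checked <- 0
  while (checked < 1000) {
    L <- sample(3:15, 1)
    x <- sort(sample(0:30, L))
    y <- rev(cumsum(rexp(L))) + rnorm(L, 0, 0.3)
    if (all(diff(y) >= 0)) next                 # fallback branch, tested above
    ch <- select_nzero_elbow(data.frame(nzero = x, median_cvm = y))
    expect_identical(as.integer(ch), as.integer(oracle(x, y)))
    checked <- checked + 1
  }
})

test_that("stability calls use a strict threshold on VIP", {
  B <- 100
  rec <- data.frame(b = 1:B, alpha = 1, lambda = 0.1, nzero = 6,
                    cvm = seq_len(B))
  vips <- c(97, 83, 87, 95, 84, 60, 75, 40)   # 75 exactly must NOT pass
  cf <- sapply(vips, function(v) 0.1 * rep(c(1, 0), c(v, B - v)))
  colnames(cf) <- paste0("v", seq_along(vips))
  fit <- fake_enet_boot(rec, cf, B = B)
  vip <- summarize_vip(fit)
  expect_equal(unname(unlist(vip[1, paste0("v", 1:8)])), vips)
  stable <- select_stable_variables(vip, 6)
  expect_setequal(stable, paste0("v", 1:5))
  expect_false("v7" %in% stable)              # VIP exactly 75.0%
  none <- select_stable_variables(vip, 6, threshold = 0.99)
  expect_length(none, 0)
  expect_error(select_stable_variables(vip, 99), "not present")
})

test_that("coefficient summaries use interpolated percentiles of non-zero draws", {
  rec <- data.frame(b = 1:3, alpha = 1, lambda = 0.1, nzero = 1, cvm = 1:3)
  cf <- cbind(x1 = c(0.2, 0.3, 0.4), x2 = c(0, 0, 0))
  fit <- fake_enet_boot(rec, cf, B = 3)
  expect_message(sel <- coefficient_summary(fit, 1, "x1"), "x2")
  s1 <- sel$summary[sel$summary$variable == "x1", ]
  expect_equal(s1$median, 0.3)
  expect_equal(c(s1$ci_lo, s1$ci_hi), c(0.205, 0.395))
  expect_equal(sel$coef_predict, c(x1 = 0.3, x2 = 0))
  # single contributing bootstrap: degenerate CI equal to the value
  fit1 <- fake_enet_boot(rec[1, ], cf[1, , drop = FALSE], B = 1)
  sel1 <- suppressMessages(coefficient_summary(fit1, 1, "x1"))
  s11 <- sel1$summary[1, ]
  expect_equal(unlist(s11[c("median", "ci_lo", "ci_hi")]),
               c(median = 0.2, ci_lo = 0.2, ci_hi = 0.2))
  # identical coefficients: zero-width CI
  cfc <- cbind(x1 = rep(0.25, 3), x2 = rep(0, 3))
  selc <- suppressMessages(coefficient_summary(
    fake_enet_boot(rec, cfc, B = 3), 1, "x1"))
  sc <- selc$summary[1, ]
  expect_equal(sc$ci_hi - sc$ci_lo, 0)
  expect_error(coefficient_summary(fit, 5, "x1"), "no bootstrap")
})

test_that("guards reject unusable inputs", {
  set.seed(108)
  X <- apply(matrix(rnorm(40 * 3), 40, 3), 2, zstandardize)
  colnames(X) <- paste0("x", 1:3)
  y <- zstandardize(rnorm(40))
  expect_error(fit_bootstrap_enet(X, y, B = 2, k_folds = 10, seed = 1),
               "fewer folds")
  expect_error(fit_bootstrap_enet(X, rep(1, 40), B = 2, k_folds = 4,
                                  seed = 1), "constant")
  expect_error(fit_bootstrap_enet(X * 3, y, B = 2, k_folds = 4, seed = 1),
               "standardized")
})
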