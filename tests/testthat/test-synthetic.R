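test_that("predictor generation honours independence, planted correlation and prevalence", {
  vars <- c("a", "b", "c")
  pp <- list(a = list(type = "binary", prevalence = 0.5),
             b = list(type = "continuous", mean = 0, sd = 1),
             c = list(type = "continuous", mean = 10, sd = 2))
  cfg <- sim_config(n = 1000, predictor_params = pp,
                    latent_correlation = diag(3), gamma = NULL)
  X <- generate_predictors(cfg, seed = 301)
  cm <- cor(as.matrix(X))
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.1)

  R <- diag(3); R[2, 3] <- R[3, 2] <- 0.8
  cfg2 <- sim_config(n = 1000, predictor_params = pp,
                     latent_correlation = R)
  X2 <- generate_predictors(cfg2, seed = 302)
  expect_lt(abs(cor(X2$b, X2$c) - 0.8), 0.05)

  pp3 <- list(rare = list(type = "binary", prevalence = 0.04))
  cfg3 <- sim_config(n = 500, predictor_params = pp3,
                     latent_correlation = diag(1))
  X3 <- generate_predictors(cfg3, seed = 303)
  expect_gte(sum(X3$rare), qbinom(0.025, 500, 0.04))
  expect_lte(sum(X3$rare), qbinom(0.975, 500, 0.04))
  # continuous scale mapping
  expect_lt(abs(mean(X2$c) - 10), 0.3)
  expect_lt(abs(sd(X2$c) - 2), 0.2)
})

test_that("a non-PSD latent correlation is rejected with advice", {
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  pp <- list(a = list(type = "continuous", mean = 0, sd = 1),
             b = list(type = "continuous", mean = 0, sd = 1),
             c = list(type = "continuous", mean = 0, sd = 1))
  expect_error(sim_config(predictor_params = pp, latent_correlation = R),
               "positive semi-definite.*nearPD")
})

test_that("the embedded clock recovers planted target ages exactly without noise", {
  cfg <- scenario_cordblood_like(n = 150, sigma_beta = 0)
  coh <- generate_cohort(cfg, seed = 304)
  est <- apply_clock(cfg$clock, coh$betas)
  expect_lt(max(abs(est$dnam_ga_weeks - coh$truth$target)), 1e-8)
})

test_that("the fully deterministic null collapses to chronological age", {
  cfg <- sim_config(n = 60, sigma_a = 0, sigma_beta = 0, delta = 0,
                    gamma = NULL)
  coh <- generate_cohort(cfg, seed = 305)
  est <- apply_clock(cfg$clock, coh$betas)
  expect_equal(est$dnam_ga_weeks, coh$phenotypes$ga_weeks,
               tolerance = 1e-10)
  pe <- cohort_eaar(coh, cfg$clock)
  expect_lt(max(abs(pe$eaar$eaar)), 1e-8)
})

test_that("OLS on the generated data recovers the planted effect vector", {
  cfg <- sim_config(n = 400, gamma = c(birth_weight = 0.3,
                                       maternal_age = 0.25,
                                       maternal_smoking = -0.2))
  coh <- generate_cohort(cfg, seed = 306)
  ph <- as.data.frame(coh$phenotypes)
  vars <- names(cfg$gamma)
  Z <- apply(ph[vars], 2, zstandardize)
  b <- coef(stats::lm((coh$truth$target - coh$truth$ga -
                         coh$truth$confound) ~ Z))[-1]
  expect_lt(max(abs(b - cfg$gamma)), 0.1)
})

test_that("beta clipping stays below 1% at default noise", {
  coh <- generate_cohort(scenario_cordblood_like(n = 1000), seed = 307)
  expect_lt(coh$truth$clip_fraction, 0.01)
  expect_true(all(coh$betas >= 0 & coh$betas <= 1))
})

test_that("generation is byte-identical per seed and distinct across seeds", {
  cfg <- scenario_cordblood_like(n = 80)
  a <- generate_cohort(cfg, seed = 308)
  b <- generate_cohort(cfg, seed = 308)
  expect_identical(unclass(a$betas), unclass(b$betas))
  expect_identical(as.data.frame(a$phenotypes), as.data.frame(b$phenotypes))
  expect_identical(a$truth$accel, b$truth$accel)
  c2 <- generate_cohort(cfg, seed = 309)
  expect_false(identical(unclass(a$betas), unclass(c2$betas)))
})

test_that("generated files round-trip through the readers without loss", {
  cfg <- sim_config(n = 30)
  coh <- generate_cohort(cfg, seed = 310)
  fb <- withr::local_tempfile(fileext = ".csv")
  fp <- withr::local_tempfile(fileext = ".csv")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_beta_matrix(coh$betas, fb)
  write_phenotypes(coh$phenotypes, fp)
  write_clock_table(cfg$clock, fc)
  bb <- read_beta_matrix(fb)
  expect_equal(unclass(bb), unclass(coh$betas), tolerance = 1e-12)
  pp <- read_phenotypes(fp)
  expect_equal(pp$ga_weeks, coh$phenotypes$ga_weeks, tolerance = 1e-12)
  expect_equal(pp$cell_gran, coh$phenotypes$cell_gran, tolerance = 1e-12)
  cc <- read_clock_table(fc)
  expect_equal(cc$weights, cfg$clock$weights)
  expect_equal(cc$intercept, cfg$clock$intercept)
})

test_that("gestational-age draws follow the configured truncated normals", {
  coh <- generate_cohort(sim_config(n = 2000), seed = 311)
  ga <- coh$phenotypes$ga_weeks
  expect_true(all(ga >= 33 & ga <= 43))
  expect_lt(abs(mean(ga) - 40.04), 0.15)
  cvs <- generate_cohort(sim_config(n = 2000, tissue = "cvs"), seed = 312)
  expect_true(all(cvs$phenotypes$ga_weeks >= 10 &
                    cvs$phenotypes$ga_weeks <= 15))
  expect_lt(abs(mean(cvs$phenotypes$ga_weeks) - 12.79), 0.1)
})

test_that("multi-tissue cohorts share individuals and honour the planted coupling", {
  # rho = 1 with shared effects and no beta noise: EAARs nearly identical
  # (residualization against k design columns costs ~k/n of the correlation,
  # so a roomy n is used)
  cfgs <- scenario_crosstissue(n = 1500, sigma_beta = 0)
  mt1 <- generate_multi_tissue(cfgs, rho = 1, seed = 313)
  pe1 <- lapply(names(mt1$tissues), function(tt)
    cohort_eaar(mt1$tissues[[tt]], cfgs[[tt]]$clock))
  expect_identical(mt1$tissues[[1]]$phenotypes$individual_id,
                   mt1$tissues[[2]]$phenotypes$individual_id)
  r1 <- cor(pe1[[1]]$eaar$eaar, pe1[[2]]$eaar$eaar)
  expect_gt(r1, 0.99)
  # rho = 0: near-zero cross-tissue correlation
  mt0 <- generate_multi_tissue(scenario_crosstissue(n = 350), rho = 0,
                               seed = 314)
  cfg0 <- scenario_crosstissue(n = 350)
  pe0 <- lapply(names(mt0$tissues), function(tt)
    cohort_eaar(mt0$tissues[[tt]], cfg0[[tt]]$clock))
  r0 <- cor(pe0[[1]]$eaar$eaar, pe0[[2]]$eaar$eaar)
  expect_lt(abs(r0), 2 / sqrt(350))
  expect_equal(mt0$eaar_cor_implied[1, 2], 0)
  # rho = -1 is a valid coupling for two tissues but not for three
  cfg3 <- scenario_crosstissue(n = 50, tissues = c("cord_blood",
                                                   "placenta_fetal",
                                                   "cvs"))
  expect_error(generate_multi_tissue(cfg3, rho = -1, seed = 1), "not PSD")
})

test_that("multi-tissue truth reports the attenuated observable correlation", {
  cfgs <- scenario_crosstissue(n = 100)
  mt <- generate_multi_tissue(cfgs, rho = 0.5, seed = 315)
  implied <- mt$eaar_cor_implied[1, 2]
  # attenuation from clock noise keeps it just below the planted rho
  expect_lt(implied, 0.5)
  expect_gt(implied, 0.45)
})
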