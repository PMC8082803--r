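#' Truncated-normal and Dirichlet draws
#'
#' `rtrunc_norm` samples by rejection (bounds are a few SD wide here, so
#' acceptance is high); `rdirichlet` normalizes independent gamma draws.
#' @param n Number of draws.
#' @param mean,sd,lower,upper Normal parameters and truncation bounds.
#' @return Numeric vector of length `n`.
#' @keywords internal
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' @rdname rtrunc_norm
#' @param alpha Positive Dirichlet concentration vector.
#' @keywords internal
rdirichlet <- function(n, alpha) {
  stopifnot(all(alpha > 0))
  g <- matrix(rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  g / rowSums(g)
}

#' A toy linear gestational clock for simulation and testing
#'
#' Constructs a clock with `n_cpgs` CpGs whose weights are `+/- 1/(slope *
#' n_cpgs)` with balanced alternating signs and whose intercept is the
#' target mean age. The generator pairs this clock with a rank-one beta
#' construction (direction `v = w / sum(w^2)`, so `|v_j| = slope`): one
#' week of age deviation moves every CpG by `slope` beta units, keeping
#' noise-free betas inside \[0.05, 0.95\] for gestational-scale deviations.
#'
#' @param n_cpgs Even number of CpGs (default 100).
#' @param target_mean Intercept, the age (weeks) at the baseline methylation
#'   profile (default 40, term gestation; use ~12.8 for first-trimester
#'   CVS).
#' @param slope Beta-units of methylation change per week of age (default
#'   0.015).
#' @param name Clock name.
#' @param cpg_prefix Prefix for the generated CpG identifiers.
#' @return A [clock_model()] in weeks.
#' @export
make_toy_clock <- function(n_cpgs = 100, target_mean = 40, slope = 0.015,
                           name = "toy100", cpg_prefix = "cgS") {
  stopifnot(n_cpgs >= 2, n_cpgs %% 2 == 0, slope > 0)
  signs <- rep(c(1, -1), n_cpgs / 2)
  w <- signs / (slope * n_cpgs)
  names(w) <- sprintf("%s%05d", cpg_prefix, seq_len(n_cpgs))
  clock_model(name, target_mean, w, unit = "weeks")
}

.default_predictor_params <- function(include_alcohol = FALSE) {
  p <- list(
    child_sex = list(type = "binary", prevalence = 0.49),
    birth_weight = list(type = "continuous", mean = 3532, sd = 489),
    birth_length = list(type = "continuous", mean = 50.23, sd = 2.20),
    head_circumference = list(type = "continuous", mean = 35.10, sd = 1.52),
    maternal_age = list(type = "continuous", mean = 34.70, sd = 4.81),
    maternal_bmi = list(type = "continuous", mean = 23.94, sd = 4.21),
    maternal_smoking = list(type = "binary", prevalence = 0.04),
    parity = list(type = "binary", prevalence = 0.45),
    delivery_mode = list(type = "binary", prevalence = 0.30),
    induced_labor = list(type = "binary", prevalence = 0.27),
    maternal_diabetes = list(type = "binary", prevalence = 0.22),
    hypertensive_disorder = list(type = "binary", prevalence = 0.06),
    mental_disorders = list(type = "binary", prevalence = 0.11))
  if (include_alcohol)
    p$alcohol_use <- list(type = "binary", prevalence = 0.10)
  p
}

#' Default latent correlation among the simulated predictors
#'
#' Identity except for the blocks seen in real birth cohorts: strongly
#' correlated anthropometrics (birth weight, length, head circumference), a
#' metabolic block (maternal BMI with diabetes and hypertensive disorders)
#' and maternal age with parity.
#'
#' @param vars Predictor names.
#' @return A positive-definite correlation matrix.
#' @export
default_latent_correlation <- function(vars) {
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  set_r <- function(a, b, r) {
    if (all(c(a, b) %in% vars)) R[a, b] <<- R[b, a] <<- r
  }
  set_r("birth_weight", "birth_length", 0.70)
  set_r("birth_weight", "head_circumference", 0.60)
  set_r("birth_length", "head_circumference", 0.50)
  set_r("maternal_bmi", "maternal_diabetes", 0.25)
  set_r("maternal_bmi", "hypertensive_disorder", 0.20)
  set_r("maternal_age", "parity", 0.30)
  R
}

.default_cells <- list(
  cord_blood = c(bcell = 4, cd4t = 8, cd8t = 5, gran = 35, mono = 4,
                 nk = 3, nrbc = 6),
  placenta_fetal = c(trophoblast = 30, stromal = 10, hofbauer = 5,
                     endothelial = 5, nrbc = 3, syncytiotrophoblast = 12),
  placenta_decidual = c(trophoblast = 20, stromal = 18, hofbauer = 5,
                        endothelial = 6, nrbc = 3,
                        syncytiotrophoblast = 13),
  cvs = c(trophoblast = 35, stromal = 12, hofbauer = 4, endothelial = 4,
          nrbc = 2, syncytiotrophoblast = 8))

.default_ga <- list(
  cord_blood = list(mean = 40.04, sd = 1.55, lower = 33, upper = 43),
  placenta_fetal = list(mean = 40.04, sd = 1.55, lower = 33, upper = 43),
  placenta_decidual = list(mean = 39.89, sd = 1.43, lower = 33, upper = 43),
  cvs = list(mean = 12.79, sd = 0.82, lower = 10, upper = 15))

#' Simulation configuration for a synthetic cohort
#'
#' Defines a cohort with the statistical structure the analysis assumes: a
#' truncated-normal gestational-age distribution (term mean 40.04, SD 1.55
#' weeks, truncated to \[33,43\]; CVS mean 12.79, SD 0.82), correlated
#' birth/pregnancy predictors with realistic prevalences and scales, a
#' sparse planted effect vector `gamma` (weeks of acceleration per SD of
#' each predictor), acceleration noise `sigma_a`, a compositional cell-type
#' confound of strength `delta` (weeks per SD of the first cell proportion,
#' entering the target age so that EAAR's cell adjustment is exercised),
#' CpG-level beta noise `sigma_beta`, and an embedded linear clock that the
#' generated betas satisfy exactly in the noise-free limit.
#'
#' @param n Cohort size (default 400).
#' @param tissue One of `"cord_blood"`, `"cvs"`, `"placenta_fetal"`,
#'   `"placenta_decidual"`.
#' @param cohort_id Cohort label written into the sample sheet.
#' @param ga List `mean`, `sd`, `lower`, `upper` (weeks); tissue default.
#' @param predictor_params Named list per predictor: `type` plus
#'   `prevalence` (binary) or `mean`/`sd` (continuous).
#' @param latent_correlation Correlation matrix of the generating latents.
#' @param gamma Named vector of planted effects, weeks per SD; names must
#'   be predictors. Default: all zero.
#' @param sigma_a Acceleration noise SD, weeks (default 0.8).
#' @param delta Cell-type confound strength, weeks per SD of the first
#'   proportion (default 0.5).
#' @param cell_alpha Named positive Dirichlet concentrations; tissue
#'   default.
#' @param sigma_beta Beta-value noise SD (default 0.02).
#' @param clock A [clock_model()]; default [make_toy_clock()] at the
#'   tissue's mean GA.
#' @param include_alcohol Add alcohol use to the predictor set.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 400, tissue = "cord_blood", cohort_id = "SIM",
                       ga = NULL, predictor_params = NULL,
                       latent_correlation = NULL, gamma = NULL,
                       sigma_a = 0.8, delta = 0.5, cell_alpha = NULL,
                       sigma_beta = 0.02, clock = NULL,
                       include_alcohol = FALSE) {
  stopifnot(tissue %in% .tissue_levels, n >= 1, sigma_a >= 0,
            sigma_beta >= 0)
  if (is.null(ga)) ga <- .default_ga[[tissue]]
  if (is.null(predictor_params))
    predictor_params <- .default_predictor_params(include_alcohol)
  vars <- names(predictor_params)
  if (is.null(latent_correlation))
    latent_correlation <- default_latent_correlation(vars)
  stopifnot(identical(dim(latent_correlation), c(length(vars),
                                                 length(vars))))
  ev <- eigen(latent_correlation, symmetric = TRUE, only.values = TRUE)
  if (min(ev$values) < -1e-10)
    stop("latent correlation matrix is not positive semi-definite ",
         "(min eigenvalue ", signif(min(ev$values), 3),
         "); project to the nearest PSD matrix, e.g. Matrix::nearPD()")
  g <- stats::setNames(rep(0, length(vars)), vars)
  if (!is.null(gamma)) {
    bad <- setdiff(names(gamma), vars)
    if (length(bad)) stop("gamma names not in predictor set: ",
                          paste(bad, collapse = ", "))
    g[names(gamma)] <- gamma
  }
  if (is.null(cell_alpha)) cell_alpha <- .default_cells[[tissue]]
  stopifnot(all(cell_alpha > 0), length(cell_alpha) >= 2)
  if (is.null(clock))
    clock <- make_toy_clock(target_mean = ga$mean,
                            name = paste0("toy100_", tissue),
                            cpg_prefix = switch(tissue, cvs = "cgV",
                                                placenta_fetal = "cgP",
                                                placenta_decidual = "cgD",
                                                "cgS"))
  structure(list(n = n, tissue = tissue, cohort_id = cohort_id, ga = ga,
                 predictor_params = predictor_params,
                 latent_correlation = latent_correlation, gamma = g,
                 sigma_a = sigma_a, delta = delta, cell_alpha = cell_alpha,
                 sigma_beta = sigma_beta, clock = clock,
                 include_alcohol = include_alcohol),
            class = "sim_config")
}

#' Generate correlated birth/pregnancy predictors
#'
#' Draws a latent multivariate normal with the configured correlation
#' matrix; binary predictors threshold their latent at the quantile
#' matching the configured prevalence, continuous predictors are affinely
#' mapped to the configured mean and SD.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed (omit when called inside a seeded
#'   generator).
#' @return A data.frame of predictors with attribute `latent` (the latent
#'   draws).
#' @export
generate_predictors <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  pp <- config$predictor_params
  vars <- names(pp)
  n <- config$n
  Z <- matrix(rnorm(n * length(vars)), n) %*%
    chol(config$latent_correlation)
  colnames(Z) <- vars
  X <- as.data.frame(Z)
  for (v in vars) {
    if (pp[[v]]$type == "binary") {
      X[[v]] <- as.numeric(Z[, v] > qnorm(1 - pp[[v]]$prevalence))
    } else {
      X[[v]] <- pp[[v]]$mean + pp[[v]]$sd * Z[, v]
    }
  }
  attr(X, "latent") <- Z
  X
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws gestational ages, predictors, accelerations
#' `a_i = sum_k gamma_k z(X_ik) + eps_i`, Dirichlet cell proportions and a
#' compositional confound, forming the target DNAm age
#' `t_i = GA_i + a_i + delta * z(c_i1)`. Beta values are a rank-one
#' construction around a baseline profile `m_j ~ U(0.2, 0.8)`:
#' `beta_ij = m_j + v_j (t_i - c0 - w.m) + eta_ij` with `v = w / (w.w)`, so
#' the embedded clock recovers `t_i` exactly when `sigma_beta = 0`.
#' Noise-free betas outside \[0.05, 0.95\] are an error (clock scale and
#' age range incompatible); after adding noise, values are clipped to
#' \[0,1\] and the clipped fraction is reported in the truth object.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the draw is byte-identical for a fixed
#'   (config, seed).
#' @return List with `betas` (a [beta_matrix()]), `phenotypes` (a
#'   `phenotype_table`), and `truth` (class `synthetic_truth`: planted
#'   accelerations, confound, target ages, `gamma`, `gamma_std` on the
#'   standardized-EAAR scale, clip fraction, seed).
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n
  ga <- rtrunc_norm(n, config$ga$mean, config$ga$sd, config$ga$lower,
                    config$ga$upper)
  X <- generate_predictors(config)
  parts <- .plant_acceleration(config, X, rnorm(n, 0, config$sigma_a))
  cohort <- .assemble_cohort(config, seed, ga, X, parts$accel)
  cohort
}

# acceleration = planted effects on standardized predictors + noise;
# only predictors carrying a non-zero effect need standardizing
.plant_acceleration <- function(config, X, eps) {
  g <- config$gamma[config$gamma != 0]
  planted <- if (length(g))
    drop(vapply(as.data.frame(X)[names(g)], zstandardize,
                numeric(nrow(X))) %*% g)
  else 0
  list(accel = planted + eps)
}

# shared tail of cohort generation: cells, betas, phenotypes, truth.
# `accel` excludes the cell confound, which is added here.
.assemble_cohort <- function(config, seed, ga, X, accel,
                             individual_id = NULL) {
  n <- config$n
  cells <- rdirichlet(n, config$cell_alpha)
  colnames(cells) <- names(config$cell_alpha)
  confound <- if (config$delta != 0)
    config$delta * zstandardize(cells[, 1]) else rep(0, n)
  target <- ga + accel + confound
  clock <- config$clock
  w <- clock$weights
  J <- length(w)
  m <- runif(J, 0.2, 0.8)
  v <- w / sum(w^2)
  dvec <- target - clock$intercept - sum(w * m)
  b0 <- m + outer(unname(v), dvec)
  if (any(b0 < 0.05 | b0 > 0.95))
    stop("clock scale and target-age range are incompatible: noise-free ",
         "betas leave [0.05, 0.95]; rescale the clock (smaller slope / ",
         "larger weights) or narrow the age range")
  b <- b0 + matrix(rnorm(J * n, 0, config$sigma_beta), J, n)
  clip_fraction <- mean(b < 0 | b > 1)
  b <- pmin(pmax(b, 0), 1)
  if (is.null(individual_id))
    individual_id <- sprintf("ind_%05d", seq_len(n))
  sample_id <- paste0(individual_id, "_", config$tissue)
  betas <- beta_matrix(b, cpg_ids = names(w), sample_ids = sample_id)
  pheno <- data.frame(sample_id = sample_id,
                      individual_id = individual_id,
                      cohort_id = config$cohort_id,
                      tissue = config$tissue, ga_weeks = ga, X,
                      stringsAsFactors = FALSE)
  cellsdf <- as.data.frame(cells)
  names(cellsdf) <- paste0("cell_", names(cellsdf))
  pheno <- cbind(pheno, cellsdf, C1 = rnorm(n), C2 = rnorm(n))
  schema <- data.frame(
    name = names(config$predictor_params),
    type = vapply(config$predictor_params, `[[`, "", "type"),
    stringsAsFactors = FALSE, row.names = NULL)
  pheno <- phenotype_table(pheno, schema = schema)
  cn_var <- sum(w^2) * config$sigma_beta^2   # clock-noise variance, weeks^2
  g <- config$gamma
  sd_eaar <- sqrt(drop(t(g) %*% config$latent_correlation %*% g) +
                    config$sigma_a^2 + cn_var)
  truth <- structure(list(
    sample_id = sample_id, individual_id = individual_id, ga = ga,
    accel = accel, confound = confound, target = target,
    gamma = g, gamma_std = g / sd_eaar, sd_eaar_implied = sd_eaar,
    clock_noise_var = cn_var, clock = clock$name,
    clip_fraction = clip_fraction, seed = seed),
    class = "synthetic_truth")
  list(betas = betas, phenotypes = pheno, truth = truth)
}

#' Generate multi-tissue cohorts with shared individuals
#'
#' One set of individuals sampled in several tissues. Predictors and birth
#' GA are shared; CVS uses its own sampling-time GA. The acceleration noise
#' vector of each individual across tissues is multivariate normal with
#' pairwise correlation `rho`, so `rho` controls how much epigenetic
#' age acceleration corresponds between tissues over and above any shared
#' planted effects. Tissue-specific effect vectors, clocks and cell
#' references are taken from each tissue's config.
#'
#' @param configs Named list of [sim_config()] objects, one per tissue
#'   (>= 2), sharing `n`.
#' @param rho Pairwise cross-tissue correlation of the acceleration noise
#'   (equicorrelation; `|rho| <= 1` and the implied matrix must be PSD).
#' @param seed Integer seed.
#' @return List of class `multi_tissue_cohort`: `tissues` (named list of
#'   per-tissue cohorts as in [generate_cohort()]), `rho`,
#'   `eaar_cor_implied` (matrix of model-implied correlations between
#'   observed per-tissue EAARs, accounting for shared planted effects and
#'   clock noise), `seed`.
#' @export
generate_multi_tissue <- function(configs, rho, seed) {
  stopifnot(length(configs) >= 2, abs(rho) <= 1)
  if (is.null(names(configs)))
    names(configs) <- vapply(configs, `[[`, "", "tissue")
  n <- configs[[1]]$n
  stopifnot(all(vapply(configs, `[[`, 0, "n") == n))
  Tn <- length(configs)
  R <- matrix(rho, Tn, Tn); diag(R) <- 1
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-10)
    stop("equicorrelation matrix with rho = ", rho, " and ", Tn,
         " tissues is not PSD")
  set.seed(seed)
  individual_id <- sprintf("ind_%05d", seq_len(n))
  ga_birth <- rtrunc_norm(n, 40.04, 1.55, 33, 43)
  X <- generate_predictors(configs[[1]])
  # correlated acceleration noise across tissues (scaled per tissue)
  E <- matrix(rnorm(n * Tn), n) %*% chol(R + diag(1e-12, Tn))
  out <- vector("list", Tn)
  names(out) <- names(configs)
  for (ti in seq_len(Tn)) {
    cfg <- configs[[ti]]
    ga_t <- if (cfg$tissue == "cvs")
      rtrunc_norm(n, cfg$ga$mean, cfg$ga$sd, cfg$ga$lower, cfg$ga$upper)
    else ga_birth
    accel <- .plant_acceleration(cfg, X, cfg$sigma_a * E[, ti])$accel
    out[[ti]] <- .assemble_cohort(cfg, seed, ga_t, X, accel,
                                  individual_id = individual_id)
  }
  # model-implied correlation between observed EAARs per tissue pair:
  # cov = gamma_A' R_x gamma_B + rho * sigma_aA * sigma_aB;
  # var_t = gamma_t' R_x gamma_t + sigma_at^2 + clock noise.
  Rx <- configs[[1]]$latent_correlation
  vars_t <- vapply(seq_len(Tn), function(ti) {
    cfg <- configs[[ti]]
    drop(t(cfg$gamma) %*% Rx %*% cfg$gamma) + cfg$sigma_a^2 +
      out[[ti]]$truth$clock_noise_var
  }, 0)
  implied <- diag(Tn)
  for (i in seq_len(Tn - 1)) for (j in (i + 1):Tn) {
    cv <- drop(t(configs[[i]]$gamma) %*% Rx %*% configs[[j]]$gamma) +
      rho * configs[[i]]$sigma_a * configs[[j]]$sigma_a
    implied[i, j] <- implied[j, i] <- cv / sqrt(vars_t[i] * vars_t[j])
  }
  dimnames(implied) <- list(names(configs), names(configs))
  structure(list(tissues = out, rho = rho, eaar_cor_implied = implied,
                 seed = seed),
            class = "multi_tissue_cohort")
}
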