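# Shared fixtures, built in code.

toy_clock3 <- function(unit = "weeks") {
  clock_model("toy3", 30, c(cgA = 10, cgB = -5, cgC = 2), unit = unit)
}

toy_betas32 <- function() {
  beta_matrix(matrix(c(0.5, 0.2, 0.1,
                       0.4, 0.3, 0.6), nrow = 3,
                     dimnames = list(c("cgA", "cgB", "cgC"),
                                     c("s1", "s2"))))
}

# minimal valid phenotype sheet with k samples (cord blood)
toy_phenosheet <- function(k = 10, seed = 1) {
  set.seed(seed)
  schema <- default_predictor_schema()
  df <- data.frame(sample_id = sprintf("s%02d", 1:k),
                   individual_id = sprintf("i%02d", 1:k),
                   cohort_id = "TOY", tissue = "cord_blood",
                   ga_weeks = round(rnorm(k, 40, 1.5), 2))
  for (i in seq_len(nrow(schema))) {
    v <- schema$name[i]
    df[[v]] <- if (schema$type[i] == "binary") rbinom(k, 1, 0.3)
               else round(rnorm(k, 10, 2), 2)
  }
  p <- matrix(rgamma(3 * k, c(5, 3, 2)), k, 3, byrow = TRUE)
  p <- p / rowSums(p)
  df$cell_a <- p[, 1]; df$cell_b <- p[, 2]; df$cell_c <- p[, 3]
  df$C1 <- rnorm(k); df$C2 <- rnorm(k)
  df
}

# construct a pair of vectors with an exact sample Pearson correlation r
vectors_with_cor <- function(n, r, seed = 1) {
  set.seed(seed)
  z1 <- zstandardize(rnorm(n))
  e <- rnorm(n)
  e <- zstandardize(stats::residuals(stats::lm(e ~ z1)))
  list(x = z1, y = r * z1 + sqrt(1 - r^2) * e)
}

# minimal enet_boot object for testing the aggregation arithmetic
fake_enet_boot <- function(records, coef, B, vars = colnames(coef)) {
  structure(list(records = records, coef = coef, B = B, seed = 0,
                 alpha_grid = NA, n_lambda = NA, k_folds = NA,
                 n = NA, var_names = vars),
            class = "enet_boot")
}
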