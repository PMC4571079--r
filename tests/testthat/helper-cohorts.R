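# programmatic fixtures shared across the suite

# one variable separating the classes perfectly (class 0 strictly below 0,
# class 1 strictly above), plus optional noise variables
make_separable_cohort <- function(n = 30, n_noise = 0, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- ifelse(y == 1, runif(n, 1, 2), runif(n, -2, -1))
  X <- cbind(sep = x)
  if (n_noise > 0) {
    X <- cbind(X, matrix(rnorm(n * n_noise), n,
                         dimnames = list(NULL, sprintf("noise%d", 1:n_noise))))
  }
  cohort_table(X, y)
}

# cohort whose phenotype is generated by a planted any-out-of-bounds rule on
# tail thresholds, with a separation margin so recovery is well-posed
make_planted_rule_cohort <- function(n = 150, n_vars = 12, seed = 11,
                                     vars = c(2L, 5L, 7L, 11L),
                                     lower = rep(-2.2, 4),
                                     upper = rep(2.0, 4),
                                     margin = 0.4) {
  spec <- synthetic_spec(n_patients = n, n_vars = n_vars, informative = NULL,
                         rho = 0, prevalence = 0.5,
                         threshold_rule = list(variables = vars,
                                               lower = lower, upper = upper,
                                               margin = margin),
                         seed = seed)
  generate_cohort(spec)
}

# temporary CSV helper
write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
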