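test_that("correlation ranking orders perfect correlates correctly in both modes", {
  set.seed(1)
  y <- rep(c(0L, 1L), 10)
  X <- cbind(pos = as.numeric(y), neg = 1 - y, noise = rnorm(20))
  co <- cohort_table(X, y)
  ranked <- rank_by_correlation(co)
  expect_equal(ranked$variable[1], "pos")
  expect_equal(ranked$correlation[1], 1)
  expect_equal(ranked$variable[3], "neg")
  expect_equal(ranked$correlation[3], -1)

  rabs <- rank_by_correlation(co, mode = "absolute")
  expect_setequal(rabs$variable[1:2], c("pos", "neg"))
  expect_equal(rabs$variable[1:2], c("neg", "pos"))  # |r| tie -> lexicographic
})

test_that("correlation values match the closed-form point-biserial formula", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(0L, 0L, 1L, 1L, 1L)
  co <- cohort_table(cbind(v = x), y)
  # independent oracle: point-biserial r = (m1 - m0)/s * sqrt(n1*n0/(n*(n-1)))
  m1 <- mean(x[y == 1]); m0 <- mean(x[y == 0])
  r_oracle <- (m1 - m0) / sd(x) * sqrt(3 * 2 / (5 * 4))
  ranked <- rank_by_correlation(co)
  expect_equal(ranked$correlation, r_oracle, tolerance = 1e-12)
})

test_that("degenerate inputs to the ranking are rejected", {
  co <- cohort_table(cbind(a = rnorm(10), flat = rep(1, 10)),
                     rep(c(0L, 1L), 5))
  expect_error(rank_by_correlation(co), "flat")
  co2 <- cohort_table(cbind(a = rnorm(10)), rep(1L, 10))
  expect_error(rank_by_correlation(co2), "single class")
})

test_that("the walk attains its analytic supremum on a perfect ranking", {
  # 27 members occupying the top 27 of 112 ranks
  vars <- sprintf("v%03d", 1:112)
  ranked <- structure(
    data.frame(variable = vars, correlation = seq(1, -1, length.out = 112)),
    class = c("ranked_correlation", "data.frame"))
  fcset <- form_fc_set_explicit(vars[1:27])
  w <- random_walk(ranked, fcset)
  expect_equal(w$es, sqrt(27 * 85), tolerance = 1e-9)      # sqrt(2295)
  expect_equal(w$argmax, 27L)
  expect_equal(unname(w$increments[["hit"]]), 1.77430, tolerance = 5e-6)
  expect_equal(unname(w$increments[["miss"]]), -0.56360, tolerance = 5e-6)
  expect_lt(abs(w$running_sum[112]), 1e-9)

  # all members at the bottom: supremum is the final, zero-valued step
  bottom <- form_fc_set_explicit(vars[86:112])
  wb <- random_walk(ranked, bottom)
  expect_equal(wb$es, 0, tolerance = 1e-9)
  expect_equal(wb$argmax, 112L)
})

test_that("walk closure and bounds hold on random instances", {
  set.seed(2)
  for (rep in 1:200) {
    N <- sample(5:150, 1)
    G <- sample(seq_len(N - 1), 1)
    vars <- sprintf("v%04d", seq_len(N))
    ranked <- structure(
      data.frame(variable = sample(vars), correlation = sort(rnorm(N), TRUE)),
      class = c("ranked_correlation", "data.frame"))
    fcset <- form_fc_set_explicit(sample(vars, G))
    w <- random_walk(ranked, fcset)
    expect_lt(abs(w$running_sum[N]), 1e-9)
    expect_gte(w$es, 0)
    expect_lte(w$es, sqrt(G * (N - G)) + 1e-9)
  }
})

test_that("set constructors honour top-down, window and explicit provenance", {
  vil <- data.frame(variable = sprintf("v%03d", 1:112),
                    mean_vi = seq(1, 0, length.out = 112))
  expect_length(form_fc_set(vil, 27), 27)
  expect_equal(unclass(form_fc_set(vil, 3)), c("v001", "v002", "v003"),
               ignore_attr = TRUE)
  w <- form_fc_set_window(vil, 20, 30)
  expect_length(w, 11)
  expect_error(form_fc_set(vil, 113), "range")
  expect_error(form_fc_set_explicit(c("a", "a")), "duplicate")
  expect_error(form_fc_set_explicit("zz", universe = vil$variable), "unknown")
})

test_that("the set-size scan peaks at the planted coordinated set size", {
  g <- generate_cohort(synthetic_spec(
    n_patients = 400, n_vars = 40,
    informative = data.frame(index = 1:10, effect = rep(2, 10)),
    rho = 0, prevalence = 0.5, seed = 5))
  co <- g$cohort
  # importance list with the planted variables on top, by construction
  vil <- data.frame(
    variable = c(g$truth$informative_names,
                 setdiff(co$variables, g$truth$informative_names)),
    stringsAsFactors = FALSE)
  scan <- scan_set_sizes(vil, co, G_range = 3:30)
  expect_equal(attr(scan, "best_G"), 10L)

  single <- scan_set_sizes(vil, co, G_range = 7)
  expect_equal(attr(single, "best_G"), 7L)
})

test_that("phenotype permutation yields small p-values for planted signal sets", {
  g <- generate_cohort(synthetic_spec(
    n_patients = 200, n_vars = 30,
    informative = data.frame(index = 1:5, effect = rep(1.5, 5)),
    rho = 0, prevalence = 0.5, seed = 6))
  fcset <- form_fc_set_explicit(g$truth$informative_names)
  res <- permutation_pvalue(fcset, g$cohort, n_perm = 1000, seed = 7)
  expect_lt(res$p_value, 0.01)
  expect_length(res$es_perm, 1000)
})

test_that("the permutation p-value follows its counting definition at n_perm = 1", {
  co <- generate_null_cohort(30, 8, seed = 8)
  fcset <- form_fc_set_explicit(co$variables[1:3])
  res <- permutation_pvalue(fcset, co, n_perm = 1, seed = 9)
  expect_equal(res$p_value, as.numeric(res$es_perm > res$es))
  smoothed <- permutation_pvalue(fcset, co, n_perm = 1, seed = 9, smooth = TRUE)
  expect_equal(smoothed$p_value, (sum(res$es_perm > res$es) + 1) / 2)
})

test_that("joint row permutation leaves the ranked list invariant", {
  co <- generate_null_cohort(50, 10, seed = 10)
  ranked <- rank_by_correlation(co)
  perm <- sample(50)
  co2 <- cohort_table(co$X[perm, ], co$phenotype[perm], co$patient_ids[perm])
  ranked2 <- rank_by_correlation(co2)
  expect_equal(ranked$variable, ranked2$variable)
  expect_equal(ranked$correlation, ranked2$correlation, tolerance = 1e-12)
})

test_that("absolute-mode walks are invariant to sign flips of the data", {
  g <- generate_cohort(synthetic_spec(
    n_patients = 100, n_vars = 12,
    informative = data.frame(index = c(1, 2), effect = c(1.5, -1.5)),
    rho = 0, prevalence = 0.5, seed = 11))
  co <- g$cohort
  flipped <- cohort_table(-co$X, co$phenotype, co$patient_ids)
  fcset <- form_fc_set_explicit(co$variables[1:4])
  w1 <- random_walk(rank_by_correlation(co, mode = "absolute"), fcset)
  w2 <- random_walk(rank_by_correlation(flipped, mode = "absolute"), fcset)
  expect_equal(w1$running_sum, w2$running_sum, tolerance = 1e-12)
})
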