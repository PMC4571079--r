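test_that("the any-out-of-bounds rule classifies by strict threshold violation", {
  Z <- cbind(v1 = c(-1.2, 0.5), v2 = c(0.0, 0.2))
  tool <- screening_tool(c("v1"), lower = -1.0, upper = 1.0)
  expect_equal(classify(tool, Z), c(1L, 0L))

  vacuous <- screening_tool(c("v1", "v2"), lower = c(-Inf, -Inf),
                            upper = c(Inf, Inf))
  expect_equal(classify(vacuous, Z), c(0L, 0L))

  tight <- screening_tool(c("v1", "v2"), lower = rep(-1e-300, 2),
                          upper = rep(1e-300, 2))
  expect_equal(classify(tight, Z), c(1L, 1L))

  # values exactly at a threshold count as in-bounds
  onedge <- screening_tool("v1", lower = -1.2, upper = 0.5)
  expect_equal(classify(onedge, Z), c(0L, 0L))

  expect_error(classify(screening_tool("v9", -1, 1), Z), "absent")
  expect_error(screening_tool("v1", lower = 0.1, upper = 1), "lower < 0")
})

test_that("adding a member with infinite bounds never changes predictions", {
  set.seed(1)
  Z <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("v", 1:4)))
  for (i in 1:20) {
    k <- sample(1:3, 1)
    vars <- sample(colnames(Z)[1:3], k)
    tool <- screening_tool(vars, lower = -runif(k, 0.5, 2),
                           upper = runif(k, 0.5, 2))
    extended <- screening_tool(c(tool$variables, "v4"),
                               lower = c(tool$lower, -Inf),
                               upper = c(tool$upper, Inf))
    expect_identical(classify(tool, Z), classify(extended, Z))
  }
})

test_that("evaluation reproduces confusion identities and the published counts", {
  y <- c(0L, 1L, 1L, 0L)
  m <- evaluate(y, y)
  expect_equal(m$omr, 0)
  expect_equal(m$tpr, 1)
  m2 <- evaluate(1L - y, y)
  expect_equal(m2$omr, 1)
  expect_equal(m2$tpr, 0)

  # 79 training patients: 27 TP, 11 FN, 37 TN, 4 FP -> OMR 15/79, TPR 27/38
  pred <- c(rep(1L, 27), rep(0L, 11), rep(0L, 37), rep(1L, 4))
  truth <- c(rep(1L, 38), rep(0L, 41))
  m3 <- evaluate(pred, truth)
  expect_equal(m3$tp, 27)
  expect_equal(m3$fn, 11)
  expect_equal(m3$fp, 4)
  expect_equal(m3$omr, 15 / 79)
  expect_equal(100 * m3$omr, 18.98, tolerance = 1e-3)
  expect_equal(m3$tpr, 27 / 38)
  expect_equal(m3$metric1, 31 / 38)
  expect_equal(m3$metric3, m3$metric1 * m3$tpr)
  expect_equal(m3$score, 1 - m3$omr)
  expect_error(evaluate(c(0L, 1L), c(0L, 1L, 1L)), "length")
})

test_that("random tools are reproducible, respect sign constraints and are uniform", {
  co <- generate_null_cohort(100, 3, seed = 2)
  params <- fit_standardization(co)
  set.seed(3); t1 <- random_tool(co$variables, params)
  set.seed(3); t2 <- random_tool(co$variables, params)
  expect_identical(t1, t2)

  set.seed(4)
  for (i in 1:50) {
    tool <- random_tool(co$variables, params)
    expect_true(all(tool$lower < 0), info = "lower bounds negative")
    expect_true(all(tool$upper > 0), info = "upper bounds positive")
  }

  # distributional check: upper threshold uniform on (0, zmax]
  zmax <- (params$max[1] - params$mean[1]) / params$sd[1]
  set.seed(5)
  u <- replicate(10000, random_tool(co$variables[1], params)$upper)
  ks <- suppressWarnings(stats::ks.test(u, "punif", 0, zmax))
  expect_gt(ks$p.value, 0.001)
})

test_that("a one-sided standardized range is widened with a warning", {
  # skewed variable whose standardized minimum could sit above zero is
  # impossible from real data (mean lies inside the range), so emulate with
  # doctored params
  params <- structure(
    data.frame(variable = "v", mean = 0, sd = 1, min = 0.5, max = 2),
    class = c("standardization_params", "data.frame"))
  set.seed(6)
  expect_warning(tool <- random_tool("v", params), "one-sided")
  expect_lt(tool$lower, 0)
})

test_that("subset enumeration counts match closed forms and is lexicographic", {
  en <- enumerate_subsets(27, 3:6)
  expect_identical(en$count, 397215)
  expect_identical(enumerate_subsets(27, 1:27)$count, 134217727)
  expect_identical(enumerate_subsets(5, 5)$count, 1)
  expect_error(enumerate_subsets(5, 6), "sizes")

  en2 <- enumerate_subsets(4, 2)
  got <- list()
  repeat {
    s <- en2$iterator()
    if (is.null(s)) break
    got[[length(got) + 1]] <- s
  }
  expect_equal(got, list(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L),
                         c(2L, 4L), c(3L, 4L)))
  # iterator agrees with the count on a mixed-size enumeration
  en3 <- enumerate_subsets(8, c(1, 3))
  n_seen <- 0
  while (!is.null(en3$iterator())) n_seen <- n_seen + 1
  expect_equal(n_seen, en3$count)
})

test_that("the stochastic search recovers a planted rule and is reproducible", {
  g <- make_planted_rule_cohort(n = 120, n_vars = 6, seed = 7,
                                vars = c(1L, 3L, 5L),
                                lower = rep(-1.6, 3), upper = rep(1.6, 3))
  co <- g$cohort
  res <- search_tools(co, pool = co$variables, sizes = 3, realizations = 800,
                      seed = 8)
  expect_lte(res$best_omr, 0.05)
  res2 <- search_tools(co, pool = co$variables, sizes = 3, realizations = 800,
                       seed = 8)
  expect_identical(res$leaderboard, res2$leaderboard)
  expect_identical(res$best_tools[[1]]$tool, res2$best_tools[[1]]$tool)
})

test_that("search with one variable and one realization yields a single-entry leaderboard", {
  co <- generate_null_cohort(30, 2, seed = 9)
  res <- search_tools(co, pool = co$variables[1], sizes = 1, realizations = 1,
                      seed = 10)
  expect_equal(nrow(res$leaderboard), 1L)
  expect_equal(res$n_subsets, 1L)
})

test_that("best OMR is non-increasing in the number of realizations under one seed", {
  co <- make_planted_rule_cohort(n = 80, n_vars = 5, seed = 11,
                                 vars = c(2L, 4L),
                                 lower = rep(-1.4, 2),
                                 upper = rep(1.4, 2))$cohort
  omrs <- vapply(c(50, 200, 800), function(R) {
    search_tools(co, pool = co$variables, sizes = 2, realizations = R,
                 seed = 12)$best_omr
  }, numeric(1))
  expect_true(all(diff(omrs) <= 1e-12))
})
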