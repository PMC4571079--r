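#' Configuration for the conditional-inference forest
#'
#' @param ntree number of trees (default 1000).
#' @param mtry number of candidate split variables drawn at each node
#'   (default 5; 11 is the other setting commonly exercised).
#' @param alpha significance level for the global-null stop test: a node is
#'   split only if the minimal Bonferroni-adjusted association p-value over
#'   the `mtry` candidates falls below `alpha`.
#' @param min_node minimal child-node size; a node with fewer than
#'   `2 * min_node` members becomes a leaf.
#' @param n_runs number of independently seeded forests averaged into the
#'   mean variable importance list (default 20).
#' @param seed master seed; `NULL` leaves the RNG state untouched.
#' @param bootstrap `"replace"` (size-n bootstrap, default), `"subsample"`
#'   (0.632 n without replacement), or `"none"` (every tree sees the full
#'   sample; no OOB set — useful for single-tree calibration studies).
#' @param split_test `"asymptotic"` normal reference for the split-selection
#'   statistic (default), or `"montecarlo"` for a permutation p-value
#'   (`n_perm_split` draws) that calibrates small nodes better at extra cost.
#' @param n_perm_split Monte-Carlo permutations per candidate when
#'   `split_test = "montecarlo"`.
#' @return a list of class `forest_config`.
#' @export
forest_config <- function(ntree = 1000L, mtry = 5L, alpha = 0.05,
                          min_node = 7L, n_runs = 20L, seed = NULL,
                          bootstrap = c("replace", "subsample", "none"),
                          split_test = c("asymptotic", "montecarlo"),
                          n_perm_split = 499L) {
  bootstrap <- match.arg(bootstrap)
  split_test <- match.arg(split_test)
  stopifnot(ntree >= 1, mtry >= 1, alpha > 0, alpha < 1,
            min_node >= 1, n_runs >= 1, n_perm_split >= 1)
  structure(
    list(ntree = as.integer(ntree), mtry = as.integer(mtry), alpha = alpha,
         min_node = as.integer(min_node), n_runs = as.integer(n_runs),
         seed = seed, bootstrap = bootstrap, split_test = split_test,
         n_perm_split = as.integer(n_perm_split)),
    class = "forest_config"
  )
}

#' Fit a conditional-inference forest
#'
#' An ensemble of trees on independent bootstrap resamples. At each node the
#' association between every candidate variable and the binary phenotype is
#' tested with a standardized permutation-form linear statistic; variable
#' selection continues only when the Bonferroni-adjusted minimal p-value
#' rejects the global null, which separates variable selection from
#' split-point selection and curbs selection bias among correlated
#' predictors. Leaves carry class-1 fractions, not hard votes.
#'
#' @param cohort a [cohort_table()] used as training data.
#' @param config a [forest_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return an object of class `cif_forest`.
#' @export
fit_cif_forest <- function(cohort, config = forest_config(), seed = config$seed) {
  stopifnot(inherits(cohort, "cohort_table"))
  mtry <- min(config$mtry, length(cohort$variables))
  if (!is.null(seed)) set.seed(seed)
  mode <- match(config$bootstrap, c("replace", "subsample", "none")) - 1L
  fit <- cpp_build_forest(cohort$X, cohort$phenotype, config$ntree, mtry,
                          config$alpha, config$min_node, mode,
                          config$split_test == "montecarlo",
                          config$n_perm_split)
  structure(
    list(trees = fit$trees, oob = fit$oob, config = config,
         variables = cohort$variables, n_train = nrow(cohort$X),
         prevalence = mean(cohort$phenotype)),
    class = "cif_forest"
  )
}

#' @export
print.cif_forest <- function(x, ...) {
  cat(sprintf("<cif_forest> %d trees, %d variables, n = %d\n",
              length(x$trees), length(x$variables), x$n_train))
  invisible(x)
}

check_forest_vars <- function(model, cohort) {
  if (!identical(model$variables, cohort$variables)) {
    stop("cohort variables do not match the forest's training variables",
         call. = FALSE)
  }
}

#' Predict class-1 probabilities from a forest
#'
#' @param object a [fit_cif_forest()] model.
#' @param cohort a [cohort_table()] with the training variable set.
#' @param ... unused.
#' @return numeric vector of class-1 probabilities (mean of leaf fractions
#'   over all trees).
#' @export
predict.cif_forest <- function(object, cohort, ...) {
  stopifnot(inherits(cohort, "cohort_table"))
  check_forest_vars(object, cohort)
  as.vector(cpp_predict_forest(object$trees, cohort$X))
}

#' Out-of-bag probability predictions on the training cohort
#'
#' Each patient is predicted only by the trees whose bootstrap sample
#' excluded that patient. Patients that are in-bag for every tree receive
#' the training prevalence, with a warning.
#'
#' @param model a [fit_cif_forest()] model.
#' @param cohort the training [cohort_table()] the model was fitted on.
#' @return numeric vector of OOB class-1 probabilities.
#' @export
predict_oob <- function(model, cohort) {
  stopifnot(inherits(model, "cif_forest"), inherits(cohort, "cohort_table"))
  check_forest_vars(model, cohort)
  agg <- cpp_oob_predict(model$trees, model$oob, cohort$X)
  prob <- ifelse(agg$count > 0, agg$sum / agg$count, model$prevalence)
  if (any(agg$count == 0)) {
    warning(sprintf("%d patient(s) out-of-bag in no tree; using prevalence",
                    sum(agg$count == 0)))
  }
  as.vector(prob)
}

#' Out-of-bag permutation variable importance
#'
#' For each tree and variable: OOB classification accuracy (0.5 probability
#' cut) minus the accuracy after permuting that variable's values among the
#' tree's OOB patients; the importance is the mean over trees. Variables
#' never used in a tree's splits contribute exactly 0 for that tree.
#' Permutation is unconditional.
#'
#' @param model a [fit_cif_forest()] model.
#' @param cohort the training [cohort_table()].
#' @param seed optional seed for the permutations.
#' @return named numeric vector of importances, in cohort variable order.
#' @export
permutation_importance <- function(model, cohort, seed = NULL) {
  stopifnot(inherits(model, "cif_forest"), inherits(cohort, "cohort_table"))
  check_forest_vars(model, cohort)
  if (!is.null(seed)) set.seed(seed)
  imp <- cpp_permutation_importance(model$trees, model$oob,
                                    cohort$X, cohort$phenotype)
  setNames(as.vector(imp), cohort$variables)
}

#' Mean variable importance list over multiple seeded forest runs
#'
#' Forest results are stochastic, so the importance ranking is averaged over
#' `n_runs` independently seeded fits (typically 20), each contributing one
#' OOB permutation-importance vector. The result is sorted by descending
#' mean importance, ties broken lexicographically by variable name.
#'
#' @param cohort a [cohort_table()] used as training data.
#' @param config a [forest_config()]; `config$n_runs` forests are fitted
#'   with seeds derived from `seed`.
#' @param seed master seed (default `config$seed`, falling back to 1).
#' @return an object of class `variable_importance_list`: a data frame with
#'   columns `variable` and `mean_vi`, sorted descending, with the per-run
#'   importance matrix in attribute `runs`.
#' @export
mean_vil <- function(cohort, config = forest_config(), seed = config$seed %||% 1L) {
  stopifnot(inherits(cohort, "cohort_table"))
  p <- length(cohort$variables)
  runs <- matrix(NA_real_, p, config$n_runs,
                 dimnames = list(cohort$variables, NULL))
  for (r in seq_len(config$n_runs)) {
    rs <- derive_seed(seed, "forest_run", r)
    model <- fit_cif_forest(cohort, config, seed = rs)
    runs[, r] <- permutation_importance(model, cohort,
                                        seed = derive_seed(rs, "importance"))
  }
  mean_vi <- rowMeans(runs)
  ord <- order(-mean_vi, names(mean_vi))
  out <- data.frame(variable = names(mean_vi)[ord],
                    mean_vi = unname(mean_vi[ord]),
                    stringsAsFactors = FALSE)
  structure(out, class = c("variable_importance_list", "data.frame"),
            runs = runs, config = config, seed = seed)
}
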