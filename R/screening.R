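#' Construct a threshold screening tool
#'
#' A screening tool is a set of k variables with one negative lower and one
#' positive upper threshold each (2k thresholds, standardized units). A
#' patient is declared a case iff *any* member expression falls strictly
#' above its upper or strictly below its lower threshold; values equal to a
#' threshold count as in-bounds.
#'
#' @param variables character vector of member variable names.
#' @param lower,upper numeric thresholds, one per member; `lower < 0 < upper`
#'   elementwise.
#' @return an object of class `screening_tool`.
#' @export
screening_tool <- function(variables, lower, upper) {
  stopifnot(length(variables) >= 1,
            length(lower) == length(variables),
            length(upper) == length(variables))
  if (any(lower >= 0) || any(upper <= 0)) {
    stop("thresholds must satisfy lower < 0 < upper for every member",
         call. = FALSE)
  }
  structure(
    list(variables = as.character(variables),
         lower = as.numeric(lower), upper = as.numeric(upper)),
    class = "screening_tool"
  )
}

#' @export
print.screening_tool <- function(x, ...) {
  cat("<screening_tool>\n")
  print(data.frame(variable = x$variables, lower = x$lower, upper = x$upper),
        row.names = FALSE)
  invisible(x)
}

#' Classify patients with a screening tool
#'
#' @param tool a [screening_tool()].
#' @param Z a standardized [cohort_table()] (or plain matrix of z-scores
#'   with variable column names).
#' @return integer vector of 0/1 predictions (1 = flagged out of bounds).
#' @export
classify <- function(tool, Z) {
  M <- if (inherits(Z, "cohort_table")) Z$X else as.matrix(Z)
  missing <- setdiff(tool$variables, colnames(M))
  if (length(missing) > 0) {
    stop(sprintf("variable(s) absent from data: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  flagged <- rep(FALSE, nrow(M))
  for (j in seq_along(tool$variables)) {
    z <- M[, tool$variables[j]]
    flagged <- flagged | z > tool$upper[j] | z < tool$lower[j]
  }
  as.integer(flagged)
}

#' Confusion counts and candidate performance metrics
#'
#' Computes the confusion table and the four candidate selection metrics:
#' `metric1` = predicted-positive count / (TP + FN) (documented convention
#' for an ambiguously worded ratio; not used for selection), the true
#' positive rate `tpr` = TP / (TP + FN), `metric3 = metric1 * tpr`, and the
#' overall misclassification rate `omr` = (FP + FN) / n, whose complement
#' `score = 1 - omr` weights both error types equally. Tool selection uses
#' the two-level rule: minimize OMR, break ties by maximal TPR.
#'
#' @param predictions integer 0/1 predictions.
#' @param phenotype integer 0/1 truth of equal length.
#' @return a list of class `tool_metrics` with fields `tp`, `fp`, `tn`,
#'   `fn`, `omr`, `tpr`, `metric1`, `metric3`, `score`.
#' @export
evaluate <- function(predictions, phenotype) {
  if (length(predictions) != length(phenotype)) {
    stop("length mismatch between predictions and phenotype", call. = FALSE)
  }
  stopifnot(all(predictions %in% c(0, 1)), all(phenotype %in% c(0, 1)))
  tp <- sum(predictions == 1 & phenotype == 1)
  fp <- sum(predictions == 1 & phenotype == 0)
  tn <- sum(predictions == 0 & phenotype == 0)
  fn <- sum(predictions == 0 & phenotype == 1)
  n <- length(phenotype)
  npos <- tp + fn
  tpr <- if (npos > 0) tp / npos else NA_real_
  m1 <- if (npos > 0) (tp + fp) / npos else NA_real_
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         omr = (fp + fn) / n, tpr = tpr,
         metric1 = m1, metric3 = m1 * tpr, score = 1 - (fp + fn) / n),
    class = "tool_metrics"
  )
}

std_range <- function(params) {
  data.frame(variable = params$variable,
             zmin = (params$min - params$mean) / params$sd,
             zmax = (params$max - params$mean) / params$sd,
             stringsAsFactors = FALSE)
}

#' Draw a random screening tool
#'
#' For each member variable the upper threshold is drawn uniformly on
#' `(0, zmax]` and the lower uniformly on `[zmin, 0)`, where `zmin`/`zmax`
#' are the standardized training minimum/maximum — a uniform exploration of
#' the observed expression range, anchored at zero so every tool flags
#' "above a positive or below a negative standardized threshold". A
#' variable whose training range is entirely one-sided has the degenerate
#' side widened to a small epsilon, with a warning.
#'
#' @param variables member variable names.
#' @param params [fit_standardization()] result covering the members.
#' @param eps widening constant for one-sided ranges.
#' @return a [screening_tool()]; uses the current RNG state (wrap in
#'   `set.seed()` for reproducibility).
#' @export
random_tool <- function(variables, params, eps = 1e-6) {
  i <- match(variables, params$variable)
  if (anyNA(i)) {
    stop(sprintf("no standardization parameters for: %s",
                 paste(variables[is.na(i)], collapse = ", ")), call. = FALSE)
  }
  zr <- std_range(params)[i, ]
  zmax <- zr$zmax
  zmin <- zr$zmin
  if (any(zmax <= 0) || any(zmin >= 0)) {
    warning("one-sided standardized range; widening to +/- eps")
    zmax <- pmax(zmax, eps)
    zmin <- pmin(zmin, -eps)
  }
  k <- length(variables)
  screening_tool(variables,
                 lower = runif(k) * zmin,
                 upper = runif(k) * zmax)
}

#' Count and enumerate variable subsets
#'
#' Deterministic lexicographic enumeration of all subsets of a pool with
#' sizes in `sizes`; the count is `sum(choose(pool_size, sizes))`. The
#' iterator yields integer index vectors (into the pool) and `NULL` when
#' exhausted, so HPC-scale counts can be verified without materializing the
#' enumeration.
#'
#' @param pool_size number of candidate variables.
#' @param sizes integer vector of subset sizes.
#' @return a list with `count` (double, exact for these magnitudes) and
#'   `iterator` (a closure).
#' @export
enumerate_subsets <- function(pool_size, sizes) {
  sizes <- as.integer(sizes)
  if (any(sizes < 1) || any(sizes > pool_size)) {
    stop("sizes must lie in [1, pool_size]", call. = FALSE)
  }
  count <- sum(choose(pool_size, sizes))
  si <- 0L
  cur <- NULL
  nxt <- function() {
    repeat {
      if (is.null(cur)) {
        si <<- si + 1L
        if (si > length(sizes)) return(NULL)
        cur <<- seq_len(sizes[si])
        return(cur)
      }
      k <- sizes[si]
      # advance to the next k-combination of 1..pool_size in lexicographic order
      j <- k
      while (j >= 1 && cur[j] == pool_size - k + j) j <- j - 1
      if (j < 1) {
        cur <<- NULL
        next
      }
      cur[j] <<- cur[j] + 1L
      if (j < k) cur[(j + 1):k] <<- cur[j] + seq_len(k - j)
      return(cur)
    }
  }
  list(count = count, iterator = nxt)
}

#' Stochastic search for the best screening tool
#'
#' Enumerates variable subsets of the pool and, for each subset, evaluates
#' `realizations` random threshold tools on the standardized training data,
#' keeping the global best under the two-level metric (minimal OMR, ties
#' broken by maximal TPR). All co-optimal tools are retained, since best
#' tools need not be unique. Per-subset seeds derive deterministically from
#' the master seed and the subset's enumeration index, so a distributed or
#' resumed run reproduces the serial result.
#'
#' @param cohort a [cohort_table()] (raw scale) used for training.
#' @param params a [fit_standardization()] result fitted on this cohort (or
#'   `NULL` to fit here).
#' @param pool character vector of candidate variable names.
#' @param sizes subset sizes to try (default 3:6).
#' @param realizations random threshold tools per subset (default 1000).
#' @param seed master seed.
#' @param checkpoint_every optionally write a JSON progress checkpoint every
#'   this many subsets.
#' @param checkpoint_dir directory for checkpoints.
#' @param max_tools cap on the number of co-optimal tools materialized in
#'   `best_tools`; ties beyond the cap are still counted in `n_cooptimal`
#'   (degenerate searches, e.g. tiny patient groups with coarsely quantized
#'   OMR, can tie thousands of tools).
#' @return an object of class `screening_search`: list with `best_tools`
#'   (co-optimal [screening_tool()]s with their metrics, up to `max_tools`),
#'   `best_omr`, `best_tpr`, `n_cooptimal`, and a per-subset `leaderboard`
#'   data frame.
#' @export
search_tools <- function(cohort, params = NULL, pool, sizes = 3:6,
                         realizations = 1000L, seed = 1L,
                         checkpoint_every = NULL, checkpoint_dir = NULL,
                         max_tools = 100L) {
  stopifnot(inherits(cohort, "cohort_table"), length(pool) >= 1)
  if (!all(pool %in% cohort$variables)) {
    stop("pool contains variables absent from the cohort", call. = FALSE)
  }
  if (is.null(params)) params <- fit_standardization(cohort)
  Z <- standardize(cohort, params)$X[, pool, drop = FALSE]
  zr <- std_range(params)
  zr <- zr[match(pool, zr$variable), ]
  zmax <- pmax(zr$zmax, 1e-6)
  zmin <- pmin(zr$zmin, -1e-6)
  y <- cohort$phenotype
  n <- length(y)
  n1 <- sum(y)

  en <- enumerate_subsets(length(pool), sizes)
  best_omr <- Inf
  best_tpr <- -Inf
  best_tools <- list()
  n_cooptimal <- 0L
  lb <- vector("list", 0)
  i <- 0L
  repeat {
    sub <- en$iterator()
    if (is.null(sub)) break
    i <- i + 1L
    k <- length(sub)
    set.seed(derive_seed(seed, "subset", i))
    # draws are consumed realization by realization (2k per tool), so a run
    # with fewer realizations under the same seed explores a prefix of a
    # longer run: the best OMR is non-increasing in `realizations`
    draws <- matrix(runif(2L * k * realizations), nrow = 2L * k)
    L <- sweep(t(draws[seq_len(k), , drop = FALSE]), 2, zmin[sub], "*")
    U <- sweep(t(draws[k + seq_len(k), , drop = FALSE]), 2, zmax[sub], "*")
    ev <- cpp_eval_tools(Z[, sub, drop = FALSE], y, L, U)
    tp <- ev$tp
    pp <- ev$pp
    fp <- pp - tp
    fn <- n1 - tp
    omr <- (fp + fn) / n
    # TPR is undefined when the group has no true cases; the tie-break then
    # carries no information and a fixed 0 keeps the ordering total
    tpr <- if (n1 > 0) tp / n1 else rep(0, realizations)
    bi <- order(omr, -tpr)[1]
    lb[[i]] <- data.frame(subset = i, size = k,
                          variables = paste(pool[sub], collapse = "+"),
                          omr = omr[bi], tpr = tpr[bi])
    improved <- omr[bi] < best_omr - 1e-12 ||
      (abs(omr[bi] - best_omr) <= 1e-12 && tpr[bi] > best_tpr + 1e-12)
    tied <- abs(omr[bi] - best_omr) <= 1e-12 &&
      abs(tpr[bi] - best_tpr) <= 1e-12
    if (improved || tied) {
      hits <- which(abs(omr - omr[bi]) <= 1e-12 & abs(tpr - tpr[bi]) <= 1e-12)
      if (improved) {
        best_omr <- omr[bi]
        best_tpr <- tpr[bi]
        best_tools <- list()
        n_cooptimal <- 0L
      }
      n_cooptimal <- n_cooptimal + length(hits)
      room <- max_tools - length(best_tools)
      for (r in head(hits, room)) {
        m <- structure(
          list(tp = tp[r], fp = fp[r], tn = (n - n1) - fp[r], fn = fn[r],
               omr = omr[r], tpr = if (n1 > 0) tp[r] / n1 else NA_real_,
               metric1 = if (n1 > 0) (tp[r] + fp[r]) / n1 else NA_real_,
               metric3 = if (n1 > 0) (tp[r] + fp[r]) * tp[r] / n1^2
                         else NA_real_,
               score = 1 - omr[r]),
          class = "tool_metrics")
        best_tools[[length(best_tools) + 1]] <- list(
          tool = screening_tool(pool[sub], L[r, ], U[r, ]),
          subset = i, realization = r, metrics = m)
      }
    }
    if (!is.null(checkpoint_every) && i %% checkpoint_every == 0 &&
        !is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(
        list(subsets_done = i, best_omr = best_omr, best_tpr = best_tpr),
        file.path(checkpoint_dir, "checkpoint.json"), auto_unbox = TRUE)
    }
  }
  structure(
    list(best_tools = best_tools, best_omr = best_omr, best_tpr = best_tpr,
         n_cooptimal = n_cooptimal,
         leaderboard = do.call(rbind, lb),
         pool = pool, sizes = sizes, realizations = realizations,
         seed = seed, n_subsets = i),
    class = "screening_search"
  )
}

#' @export
print.screening_search <- function(x, ...) {
  cat(sprintf(
    "<screening_search> %d subsets x %d realizations; best OMR %.4f (TPR %.4f), %d co-optimal tool(s)\n",
    x$n_subsets, x$realizations, x$best_omr, x$best_tpr, x$n_cooptimal))
  invisible(x)
}
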