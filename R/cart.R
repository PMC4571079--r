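#' Fit a Gini-split classification tree
#'
#' Binary recursive partitioning: at each node every (variable, observed
#' value) pair is scanned and the split with the greatest decrease in Gini
#' impurity is accepted; patients with expression strictly below the split
#' value go left, the rest right. Split candidates are the observed data
#' values themselves (not midpoints). Ties in impurity decrease are broken
#' by (variable name, value). Growth stops at `max_depth`, below `min_node`
#' members, or purity. Nodes are addressable as `"level-index"` with the
#' root at `"0-1"` and children of `L-i` at `(L+1)-(2i-1)` and `(L+1)-(2i)`.
#'
#' @param cohort a training [cohort_table()] with both classes present.
#' @param max_depth maximum split depth (default 4).
#' @param min_node minimum node size eligible for splitting (default 5).
#' @return an object of class `cart_tree`: list of node records (`id`,
#'   `level`, `index`, `var`, `value`, `n`, `n1`, `gini`, `children`,
#'   `members`).
#' @export
fit_cart <- function(cohort, max_depth = 4L, min_node = 5L) {
  stopifnot(inherits(cohort, "cohort_table"))
  y <- cohort$phenotype
  if (length(unique(y)) < 2) stop("phenotype has a single class", call. = FALSE)
  X <- cohort$X
  nodes <- list()

  grow <- function(members, level, index) {
    id <- sprintf("%d-%d", level, index)
    n <- length(members)
    n1 <- sum(y[members])
    g <- gini_impurity(n1, n)
    node <- list(id = id, level = level, index = index, var = NA_character_,
                 value = NA_real_, n = n, n1 = n1, gini = g,
                 children = NULL, members = members)
    if (level < max_depth && n >= min_node && n1 > 0 && n1 < n) {
      sp <- best_gini_split(X[members, , drop = FALSE], y[members])
      if (!is.null(sp)) {
        node$var <- sp$var
        node$value <- sp$value
        node$children <- c(sprintf("%d-%d", level + 1, 2 * index - 1),
                           sprintf("%d-%d", level + 1, 2 * index))
        nodes[[id]] <<- node
        left <- members[X[members, sp$var] < sp$value]
        right <- members[X[members, sp$var] >= sp$value]
        grow(left, level + 1L, 2L * index - 1L)
        grow(right, level + 1L, 2L * index)
        return(invisible(NULL))
      }
    }
    nodes[[id]] <<- node
    invisible(NULL)
  }
  grow(seq_along(y), 0L, 1L)
  structure(list(nodes = nodes, variables = cohort$variables,
                 depth = max(vapply(nodes, `[[`, integer(1), "level"))),
            class = "cart_tree")
}

gini_impurity <- function(n1, n) {
  p <- n1 / n
  1 - p^2 - (1 - p)^2
}

# brute-force scan of all (variable, observed value) splits; returns the one
# maximizing the Gini impurity decrease (ties: variable name, then value),
# or NULL when no split produces two non-empty children
best_gini_split <- function(X, y) {
  n <- length(y)
  g0 <- gini_impurity(sum(y), n)
  best <- NULL
  for (v in sort(colnames(X))) {
    x <- X[, v]
    o <- order(x)
    xs <- x[o]
    ys <- y[o]
    cum1 <- cumsum(ys)
    vals <- unique(xs[-1][xs[-1] > xs[-n]])  # candidate cut values (x < value)
    for (val in vals) {
      nl <- sum(xs < val)
      dec <- g0 - (nl / n) * gini_impurity(cum1[nl], nl) -
        ((n - nl) / n) * gini_impurity(cum1[n] - cum1[nl], n - nl)
      if (is.null(best) || dec > best$dec + 1e-12) {
        best <- list(var = v, value = val, dec = dec)
      }
    }
  }
  if (!is.null(best) && best$dec <= 1e-12) best <- NULL
  best
}

#' @export
print.cart_tree <- function(x, ...) {
  cat(sprintf("<cart_tree> %d nodes, depth %d\n", length(x$nodes), x$depth))
  for (nd in x$nodes) {
    ind <- strrep("  ", nd$level)
    if (!is.na(nd$var)) {
      cat(sprintf("%s[%s] n=%d (%d/%d) split %s < %g\n", ind, nd$id, nd$n,
                  nd$n1, nd$n - nd$n1, nd$var, nd$value))
    } else {
      cat(sprintf("%s[%s] n=%d (%d/%d) leaf p=%.3f\n", ind, nd$id, nd$n,
                  nd$n1, nd$n - nd$n1, nd$n1 / nd$n))
    }
  }
  invisible(x)
}

route_to_level <- function(tree, X, level) {
  vapply(seq_len(nrow(X)), function(i) {
    node <- tree$nodes[["0-1"]]
    while (node$level < level && !is.null(node$children)) {
      node <- if (X[i, node$var] < node$value) {
        tree$nodes[[node$children[1]]]
      } else {
        tree$nodes[[node$children[2]]]
      }
    }
    node$id
  }, character(1))
}

#' Assign patients to subgroups at a tree level
#'
#' Routes every patient through the *training* tree's splits down to depth
#' `level`; members of nodes that stopped splitting earlier are carried
#' down unchanged, so the groups always partition the cohort (level 0 is a
#' single group). Validation cohorts are routed with the same
#' training-derived splits, never refitted.
#'
#' @param tree a [fit_cart()] tree.
#' @param cohort a [cohort_table()] sharing the training variables.
#' @param level depth at which to form groups.
#' @return an object of class `level_groups`: list with `level`, `groups`
#'   (named list of patient row indices) and a per-group `counts` data
#'   frame.
#' @export
assign_groups <- function(tree, cohort, level) {
  stopifnot(inherits(tree, "cart_tree"), inherits(cohort, "cohort_table"))
  if (!all(na.omit(vapply(tree$nodes, `[[`, character(1), "var")) %in%
           cohort$variables)) {
    stop("cohort lacks variables used by the tree", call. = FALSE)
  }
  ids <- route_to_level(tree, cohort$X, level)
  groups <- split(seq_along(ids), ids)
  counts <- data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    n1 = vapply(groups, function(m) sum(cohort$phenotype[m]), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  counts$n0 <- counts$n - counts$n1
  structure(list(level = level, groups = groups, counts = counts),
            class = "level_groups")
}

# search within one patient group; falls back to the inherited tool when the
# group is too small or its pool degenerates (constant variables)
group_search <- function(cohort, members, pool, sizes, realizations, seed,
                         fallback = NULL) {
  sub <- subset_cohort(cohort, members)
  usable <- pool[apply(sub$X[, pool, drop = FALSE], 2, sd) > 0]
  if (length(sub$patient_ids) < 2 || length(usable) < min(sizes)) {
    if (is.null(fallback)) stop("degenerate group with no parent tool",
                                call. = FALSE)
    warning("degenerate group; inheriting parent tool")
    return(fallback)
  }
  sub_pool <- cohort_table(sub$X[, usable, drop = FALSE], sub$phenotype,
                           sub$patient_ids)
  params <- fit_standardization(sub_pool)
  sizes_ok <- sizes[sizes <= length(usable)]
  res <- search_tools(sub_pool, params = params, pool = usable,
                      sizes = sizes_ok, realizations = realizations,
                      seed = seed)
  list(tool = res$best_tools[[1]]$tool, params = params,
       omr = res$best_omr, tpr = res$best_tpr, inherited = FALSE,
       n_cooptimal = res$n_cooptimal)
}

#' Per-group screening-tool search with parent-OMR-zero inheritance
#'
#' Runs the stochastic screening search separately within each subgroup at
#' each tree level, standardizing against each group's own training
#' members. A child group whose parent already achieved OMR = 0 inherits
#' the parent's tool instead of searching (the parent's perfect rule cannot
#' be improved on its own members). Pooled level OMR is total misclassified
#' over total patients.
#'
#' @param tree a [fit_cart()] tree.
#' @param train the training [cohort_table()] the tree was fitted on.
#' @param pool candidate variable names for the tools.
#' @param sizes,realizations,seed passed to [search_tools()].
#' @param max_level deepest level to process (default: tree depth).
#' @return an object of class `partition_search`: per-level list of group
#'   results and a `level_omr` data frame (pooled training OMR by level).
#' @export
per_group_search <- function(tree, train, pool, sizes = 3:6,
                             realizations = 1000L, seed = 1L,
                             max_level = tree$depth) {
  stopifnot(inherits(tree, "cart_tree"), inherits(train, "cohort_table"))
  results <- list()  # node id -> group result
  levels <- list()
  omr_rows <- list()
  for (L in 0:max_level) {
    lg <- assign_groups(tree, train, L)
    lev <- list()
    miscl <- 0L
    for (gid in names(lg$groups)) {
      members <- lg$groups[[gid]]
      if (!is.null(results[[gid]])) {
        res <- results[[gid]]  # node already processed (earlier leaf)
      } else {
        node <- tree$nodes[[gid]]
        parent <- parent_id(gid)
        pres <- if (!is.null(parent)) results[[parent]] else NULL
        if (!is.null(pres) && pres$omr == 0) {
          res <- list(tool = pres$tool, params = pres$params, omr = 0,
                      tpr = pres$tpr, inherited = TRUE, n_cooptimal = NA)
          # recorded OMR of an inherited tool is its OMR on this group
          zsub <- standardize_members(train, members, res$params)
          m <- evaluate(classify(res$tool, zsub), train$phenotype[members])
          res$omr <- m$omr
          res$tpr <- m$tpr
        } else {
          res <- group_search(train, members, pool, sizes, realizations,
                              seed = derive_seed(seed, "node", gid),
                              fallback = pres)
          if (!is.null(pres)) {
            # a subgroup search can only refine: keep the parent's tool when
            # the fresh search does not beat it on this group's members
            zsub <- standardize_members(train, members, pres$params)
            pm <- evaluate(classify(pres$tool, zsub),
                           train$phenotype[members])
            ptpr <- if (is.na(pm$tpr)) 0 else pm$tpr
            if (pm$omr < res$omr - 1e-12 ||
                (abs(pm$omr - res$omr) <= 1e-12 && ptpr > res$tpr + 1e-12)) {
              res <- list(tool = pres$tool, params = pres$params,
                          omr = pm$omr, tpr = ptpr, inherited = TRUE,
                          n_cooptimal = NA)
            }
          }
        }
        results[[gid]] <- res
      }
      zsub <- standardize_members(train, members, res$params)
      m <- evaluate(classify(res$tool, zsub), train$phenotype[members])
      miscl <- miscl + m$fp + m$fn
      lev[[gid]] <- c(res, list(group_n = length(members),
                                group_omr = m$omr))
    }
    levels[[as.character(L)]] <- lev
    omr_rows[[L + 1]] <- data.frame(level = L,
                                    omr = miscl / length(train$phenotype))
  }
  structure(list(levels = levels, results = results,
                 level_omr = do.call(rbind, omr_rows), tree = tree,
                 pool = pool, sizes = sizes, realizations = realizations,
                 seed = seed),
            class = "partition_search")
}

parent_id <- function(id) {
  parts <- as.integer(strsplit(id, "-", fixed = TRUE)[[1]])
  if (parts[1] == 0) return(NULL)
  sprintf("%d-%d", parts[1] - 1, ceiling(parts[2] / 2))
}

standardize_members <- function(cohort, members, params) {
  M <- cohort$X[members, params$variable, drop = FALSE]
  sweep(sweep(M, 2, params$mean, "-"), 2, params$sd, "/")
}

#' Level-wise training and validation error of pre-partitioned tools
#'
#' Trains per-group tools at every level of the tree (via
#' [per_group_search()]), then routes the validation cohort through the
#' same training-derived splits, standardizes each validation group with
#' its training group's parameters, and reports pooled OMR by level for
#' both cohorts. The level minimizing validation OMR and whether the two
#' curves cross (an over-fitting diagnostic) are flagged.
#'
#' @param tree a [fit_cart()] tree fitted on `train`.
#' @param train,valid training and validation [cohort_table()]s.
#' @param pool,sizes,realizations,seed passed to [per_group_search()].
#' @param max_level deepest level (default: tree depth).
#' @return a data frame of class `level_curves` with columns `level`,
#'   `train_omr`, `valid_omr`; attributes `best_valid_level`, `crossed`
#'   and the underlying `partition_search`.
#' @export
level_curves <- function(tree, train, valid, pool, sizes = 3:6,
                         realizations = 1000L, seed = 1L,
                         max_level = tree$depth) {
  ps <- per_group_search(tree, train, pool, sizes, realizations, seed,
                         max_level)
  valid_omr <- numeric(max_level + 1)
  for (L in 0:max_level) {
    lg <- assign_groups(tree, valid, L)
    miscl <- 0L
    for (gid in names(lg$groups)) {
      res <- ps$results[[gid]]
      if (is.null(res)) {
        # validation members routed to a region unseen in training at this
        # level cannot occur: groups are training-tree nodes
        stop("validation group without a trained tool: ", gid, call. = FALSE)
      }
      zsub <- standardize_members(valid, lg$groups[[gid]], res$params)
      m <- evaluate(classify(res$tool, zsub),
                    valid$phenotype[lg$groups[[gid]]])
      miscl <- miscl + m$fp + m$fn
    }
    valid_omr[L + 1] <- miscl / length(valid$phenotype)
  }
  out <- data.frame(level = 0:max_level,
                    train_omr = ps$level_omr$omr,
                    valid_omr = valid_omr)
  d <- out$train_omr - out$valid_omr
  structure(out, class = c("level_curves", "data.frame"),
            best_valid_level = out$level[which.min(out$valid_omr)],
            crossed = any(d[-1] * d[-length(d)] < 0),
            partition_search = ps)
}
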