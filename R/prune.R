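# subtree leaf-risk sum and leaf count under `id`, honouring `leafed` marks
subtree_stats <- function(tree, id, leafed) {
  if (tree$is_leaf[id] || leafed[id]) {
    return(c(risk = tree$risk[id], leaves = 1))
  }
  subtree_stats(tree, tree$yes[id], leafed) +
    subtree_stats(tree, tree$no[id], leafed)
}

# ids of internal nodes still expanded
expanded_internal <- function(tree, leafed) {
  which(!tree$is_leaf & !leafed & !is.na(tree$yes))
}

# one weakest-link pass: returns the pruned `leafed` marks, the sequence of
# effective alphas g(t) at which successive collapses occur (non-decreasing),
# and the reachable node count after each collapse
weakest_link <- function(tree, alpha) {
  leafed <- rep(FALSE, nrow(tree))
  alphas <- numeric(0)
  n_nodes <- integer(0)
  reachable <- function() {
    keep <- rep(FALSE, nrow(tree))
    walk <- function(id) {
      keep[id] <<- TRUE
      if (!tree$is_leaf[id] && !leafed[id]) {
        walk(tree$yes[id]); walk(tree$no[id])
      }
    }
    walk(1L)
    keep
  }
  repeat {
    keep <- reachable()
    cand <- expanded_internal(tree, leafed)
    cand <- cand[keep[cand]]
    if (length(cand) == 0) break
    g <- vapply(cand, function(id) {
      st <- subtree_stats(tree, id, leafed)
      (tree$risk[id] - st["risk"]) / (st["leaves"] - 1)
    }, numeric(1))
    gmin <- min(g)
    if (gmin > alpha) break
    leafed[cand[which.min(g)]] <- TRUE
    alphas <- c(alphas, gmin)
    n_nodes <- c(n_nodes, sum(reachable()))
  }
  list(leafed = leafed, alphas = alphas, n_nodes = n_nodes)
}

# drop unreachable rows after collapsing, remapping child ids
compact_tree <- function(tree, leafed) {
  keep <- rep(FALSE, nrow(tree))
  walk <- function(id) {
    keep[id] <<- TRUE
    if (!tree$is_leaf[id] && !leafed[id]) {
      walk(tree$yes[id]); walk(tree$no[id])
    }
  }
  walk(1L)
  new_id <- cumsum(keep)
  out <- tree[keep, , drop = FALSE]
  collapsed <- leafed[keep] & !out$is_leaf
  out$is_leaf[collapsed] <- TRUE
  out$feature[out$is_leaf] <- NA_integer_
  out$threshold[out$is_leaf] <- NA_real_
  out$yes <- ifelse(out$is_leaf, NA_integer_, new_id[out$yes])
  out$no <- ifelse(out$is_leaf, NA_integer_, new_id[out$no])
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Minimal cost-complexity pruning of a single tree
#'
#' Weakest-link pruning: repeatedly collapse the internal node t with the
#' smallest effective alpha `g(t) = (R(t) - R(subtree_t)) / (|leaves_t| - 1)`
#' while `g(t) <= alpha`, where R is the training risk annotated at fit time
#' (weighted squared error of the tree's own boosting targets). The result is
#' the minimal cost-complexity subtree for the given alpha; `alpha = 0` leaves
#' a tree with strictly positive split gains unchanged, `alpha = Inf`
#' collapses it to a single leaf.
#'
#' @param tree a tree table from a fitted `gbt_ensemble` (element of
#'   `$trees`).
#' @param alpha complexity parameter, `>= 0`.
#' @return The pruned tree table; collapsed nodes become leaves carrying the
#'   value the node would have had as a trained leaf.
#' @export
mccp_prune <- function(tree, alpha) {
  stopifnot(is.data.frame(tree), alpha >= 0)
  if (any(is.na(tree$risk))) {
    stop("tree has no risk annotations; fit it with train_detector()",
         call. = FALSE)
  }
  compact_tree(tree, weakest_link(tree, alpha)$leafed)
}

# critical alphas of one tree: the g values of its weakest-link sequence
tree_critical_alphas <- function(tree) weakest_link(tree, Inf)$alphas

# apply one global alpha to every tree of an ensemble
prune_ensemble <- function(ens, alpha) {
  ens$trees <- lapply(ens$trees, mccp_prune, alpha = alpha)
  ens
}

#' Prune an ensemble to a memory budget
#'
#' Sweeps a single global complexity parameter over the ensemble's critical
#' alphas (smallest first) and returns the least-pruned ensemble whose compact
#' three-array representation fits the byte budget (7 bytes per node; e.g.
#' 128 kB for an L1-resident model, 1.5 MB for L2). The returned ensemble
#' carries a `prune_report` with the chosen alpha, byte cost and node count.
#'
#' @param ens a fitted `gbt_ensemble`.
#' @param budget_bytes memory target in bytes (> 0).
#' @param alpha_grid optional increasing vector of alphas to sweep; defaults
#'   to the union of the ensemble's critical alphas.
#' @return The pruned `gbt_ensemble` (alpha 0, unchanged, when the unpruned
#'   model already fits).
#' @examples
#' \donttest{
#' X <- matrix(rnorm(600), 300, 2); y <- as.integer(X[, 1] + X[, 2] > 0)
#' fit <- train_detector(X, y, gbt_hyper(n_trees = 8, max_depth = 4))
#' pruned <- prune_to_budget(fit, 500)
#' pruned$prune_report
#' }
#' @export
prune_to_budget <- function(ens, budget_bytes, alpha_grid = NULL) {
  stopifnot(inherits(ens, "gbt_ensemble"), budget_bytes > 0)
  report <- function(e, alpha) {
    e$prune_report <- list(alpha = alpha, bytes = 7 * ensemble_n_nodes(e),
                           n_nodes = ensemble_n_nodes(e))
    e
  }
  if (7 * ensemble_n_nodes(ens) <= budget_bytes) {
    return(report(ens, 0))
  }
  # per-tree collapse schedules: node count as a step function of alpha
  sched <- lapply(ens$trees, function(tr) {
    wl <- weakest_link(tr, Inf)
    list(alphas = wl$alphas, n_nodes = c(nrow(tr), wl$n_nodes))
  })
  if (is.null(alpha_grid)) {
    alpha_grid <- sort(unique(unlist(lapply(sched, `[[`, "alphas"))))
  }
  if (is.unsorted(alpha_grid, strictly = FALSE)) {
    stop("`alpha_grid` must be increasing", call. = FALSE)
  }
  min_bytes <- 7 * length(ens$trees)  # every tree a single leaf
  if (budget_bytes < min_bytes) {
    stop(sprintf("budget of %d bytes infeasible; minimum achievable is %d bytes",
                 budget_bytes, min_bytes), call. = FALSE)
  }
  nodes_at <- function(alpha) {
    sum(vapply(sched, function(s) {
      s$n_nodes[sum(s$alphas <= alpha) + 1L]
    }, numeric(1)))
  }
  for (alpha in alpha_grid) {
    if (7 * nodes_at(alpha) <= budget_bytes) {
      return(report(prune_ensemble(ens, alpha), alpha))
    }
  }
  report(prune_ensemble(ens, Inf), Inf)
}
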