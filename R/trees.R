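# Internal tree machinery.
#
# Each tree is a data.frame with one row per node:
#   id        1-based row index (root = 1)
#   feature   0-based feature index, NA for leaves
#   threshold split value (go left iff x < threshold; ties go right), NA leaf
#   yes, no   child row ids (NA for leaves)
#   is_leaf   logical
#   value     leaf score contribution; for internal nodes, the value the node
#             would take if collapsed to a leaf (filled by risk annotation)
#   risk      training risk R(t) of the node as a leaf (weighted SSE of the
#             tree's own fitting targets); filled by risk annotation
#   cover     training hessian mass reaching the node

# parse one tree of an xgboost JSON dump into the flat form
parse_dump_tree <- function(node) {
  rows <- list()
  walk <- function(nd) {
    id <- length(rows) + 1L
    rows[[id]] <<- list(id = id, feature = NA_integer_, threshold = NA_real_,
                        yes = NA_integer_, no = NA_integer_,
                        is_leaf = TRUE, value = 0, risk = NA_real_,
                        cover = if (is.null(nd$cover)) NA_real_ else nd$cover)
    if (!is.null(nd$leaf)) {
      rows[[id]]$value <<- nd$leaf
    } else {
      rows[[id]]$is_leaf <<- FALSE
      rows[[id]]$feature <<- as.integer(sub("^f", "", nd$split))
      rows[[id]]$threshold <<- nd$split_condition
      kids <- nd$children
      kid_ids <- vapply(kids, function(k) k$nodeid, numeric(1))
      yes_id <- walk(kids[[which(kid_ids == nd$yes)]])
      no_id <- walk(kids[[which(kid_ids == nd$no)]])
      rows[[id]]$yes <<- yes_id
      rows[[id]]$no <<- no_id
    }
    id
  }
  walk(node)
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

# leaf row id reached by every row of X
tree_route <- function(tree, X) {
  n <- nrow(X)
  node <- rep(1L, n)
  active <- which(!tree$is_leaf[node])
  while (length(active) > 0) {
    nd <- node[active]
    f <- tree$feature[nd] + 1L
    goleft <- X[cbind(active, f)] < tree$threshold[nd]
    node[active] <- ifelse(goleft, tree$yes[nd], tree$no[nd])
    active <- active[!tree$is_leaf[node[active]]]
  }
  node
}

# additive contribution of one tree for every row of X
tree_value <- function(tree, X) tree$value[tree_route(tree, X)]

# annotate risks/collapse values from the tree's own fitting targets:
# targets t_i = -g_i/h_i with weights h_i; R(t) = 1/2 sum h (t - mean_t)^2,
# collapse value = -eta-scaled regularized mean (consistent with xgboost
# leaves, which already include the learning rate).
annotate_tree_risk <- function(tree, X, g, h, learning_rate, lambda) {
  tree$risk <- 0
  tree$cover <- 0
  assign_node <- function(id, rows) {
    sg <- sum(g[rows]); sh <- sum(h[rows]); sg2h <- sum(g[rows]^2 / h[rows])
    tree$risk[id] <<- if (sh > 0) max(0, 0.5 * (sg2h - sg^2 / sh)) else 0
    tree$cover[id] <<- sh
    if (!tree$is_leaf[id]) {
      tree$value[id] <<- -learning_rate * sg / (sh + lambda)
      f <- tree$feature[id] + 1L
      goleft <- X[rows, f] < tree$threshold[id]
      assign_node(tree$yes[id], rows[goleft])
      assign_node(tree$no[id], rows[!goleft])
    }
  }
  assign_node(1L, seq_len(nrow(X)))
  tree
}

# number of nodes over all trees of an ensemble
ensemble_n_nodes <- function(ens) sum(vapply(ens$trees, nrow, numeric(1)))

# raw additive margins: n x n_class matrix (n_class = 1 for binary tasks)
ensemble_margin <- function(ens, X, cast32 = FALSE) {
  K <- ens$n_class
  out <- matrix(ens$base_margin, nrow = nrow(X), ncol = K)
  for (m in seq_along(ens$trees)) {
    tr <- ens$trees[[m]]
    if (cast32) {
      tr$threshold <- cast_f32(tr$threshold)
      tr$value <- cast_f32(tr$value)
    }
    k <- ens$tree_class[m] + 1L
    out[, k] <- out[, k] + tree_value(tr, X)
  }
  out
}

# IEEE-754 single-precision round trip
cast_f32 <- function(x) {
  x <- as.numeric(x)
  na <- is.na(x)
  x[na] <- 0
  y <- readBin(writeBin(x, raw(), size = 4), "numeric", size = 4, n = length(x))
  y[na] <- NA_real_
  y
}
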