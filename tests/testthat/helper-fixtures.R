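# Shared fixtures and independent oracles. Everything is generated in code;
# trained ensembles are cached for the duration of one test run.

toy_recording <- function(n_ch = 4, dur_s = 10, fs = 250, seed = 1,
                          names = c("F7-T7", "T7-P7", "F8-T8", "T8-P8")) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n_ch * dur_s * fs, sd = 20), n_ch),
                fs, names[seq_len(n_ch)], "toy")
}

# linearly separable 2-feature binary problem (with a margin)
toy_xy <- function(n = 300, seed = 3) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n * 2), ncol = 2,
              dimnames = list(NULL, c("f_a", "f_b")))
  score <- X[, 1] + 0.5 * X[, 2]
  X <- X[abs(score) > 0.2, , drop = FALSE][seq_len(n), ]
  list(X = X, y = as.integer(X[, 1] + 0.5 * X[, 2] > 0))
}

.fit_cache <- new.env(parent = emptyenv())

cached_fit <- function(key, maker) {
  if (is.null(.fit_cache[[key]])) .fit_cache[[key]] <- maker()
  .fit_cache[[key]]
}

# a small trained ensemble on a nonlinear 6-feature problem
small_ensemble <- function(n_trees = 20, depth = 3) {
  key <- sprintf("ens_%d_%d", n_trees, depth)
  cached_fit(key, function() {
    set.seed(7)
    X <- matrix(rnorm(400 * 6), 400, 6)
    y <- as.integer(X[, 1] + 0.6 * X[, 2]^2 - 0.5 * X[, 3] > 0.2)
    list(fit = train_detector(X, y, gbt_hyper(n_trees = n_trees,
                                              max_depth = depth)),
         X = X, y = y)
  })
}

# -- independent oracle: naive scalar tree scoring ---------------------------
slow_score <- function(ens, X) {
  walk <- function(tree, x) {
    id <- 1L
    repeat {
      if (tree$is_leaf[id]) return(tree$value[id])
      id <- if (x[tree$feature[id] + 1] < tree$threshold[id]) {
        tree$yes[id]
      } else {
        tree$no[id]
      }
    }
  }
  out <- rep(ens$base_margin, nrow(X))
  for (r in seq_len(nrow(X))) {
    for (tr in ens$trees) out[r] <- out[r] + walk(tr, X[r, ])
  }
  out
}

# -- independent oracle: brute-force minimal cost-complexity -----------------
# enumerate every pruned subtree (every antichain of collapsed internal
# nodes), pick min of R(T) + alpha * |leaves|, smallest tree among minimizers
descendants <- function(tree, id) {
  if (tree$is_leaf[id]) return(integer(0))
  c(tree$yes[id], tree$no[id],
    descendants(tree, tree$yes[id]), descendants(tree, tree$no[id]))
}

brute_force_mccp <- function(tree, alpha) {
  internal <- which(!tree$is_leaf)
  best <- NULL
  n_int <- length(internal)
  for (mask in 0:(2^n_int - 1)) {
    collapsed <- internal[bitwAnd(mask, 2^(seq_len(n_int) - 1)) > 0]
    # canonical: drop members below another member
    top <- collapsed[!vapply(collapsed, function(id) {
      any(vapply(setdiff(collapsed, id),
                 function(a) id %in% descendants(tree, a), logical(1)))
    }, logical(1))]
    # leaves and risk of the pruned tree
    leaf_risk <- 0; n_leaves <- 0
    walk <- function(id) {
      if (tree$is_leaf[id] || id %in% top) {
        leaf_risk <<- leaf_risk + tree$risk[id]
        n_leaves <<- n_leaves + 1
      } else {
        walk(tree$yes[id]); walk(tree$no[id])
      }
    }
    walk(1L)
    cost <- leaf_risk + alpha * n_leaves
    if (is.null(best) || cost < best$cost - 1e-12 ||
        (abs(cost - best$cost) <= 1e-12 && n_leaves < best$n_leaves)) {
      best <- list(cost = cost, n_leaves = n_leaves, top = sort(top))
    }
  }
  best
}

# leaf set of an mccp_prune() result, expressed in the ORIGINAL tree's ids
pruned_leafset <- function(tree, alpha) {
  wl <- eeggate:::weakest_link(tree, alpha)
  keep_leaves <- integer(0)
  walk <- function(id) {
    if (tree$is_leaf[id] || wl$leafed[id]) {
      keep_leaves <<- c(keep_leaves, id)
    } else {
      walk(tree$yes[id]); walk(tree$no[id])
    }
  }
  walk(1L)
  sort(keep_leaves)
}

# hand-buildable tree: supply vectors; value/risk given explicitly
hand_tree <- function(feature, threshold, yes, no, value, risk) {
  data.frame(id = seq_along(value), feature = feature, threshold = threshold,
             yes = yes, no = no, is_leaf = is.na(feature), value = value,
             risk = risk, cover = 1)
}

# direct O(n^2) DFT band-energy oracle
dft_band_energy <- function(x, fs, lo_exclusive) {
  n <- length(x)
  k <- 0:(floor(n / 2))
  freq <- k * fs / n
  p <- vapply(k, function(kk) {
    Mod(sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n)))^2 / n
  }, numeric(1))
  mult <- rep(2, length(k)); mult[1] <- 1
  if (n %% 2 == 0) mult[length(k)] <- 1
  sum((p * mult)[freq > lo_exclusive])
}

# small trained A and S over a shared 6-feature space
cascade_models <- function() {
  cached_fit("cascade_pair", function() {
    set.seed(82)
    n <- 500
    X <- matrix(abs(rnorm(n * 6)), n, 6)
    y_art <- as.integer(X[, 1] + X[, 2] > 2.2)
    y_seiz <- as.integer(X[, 3] + X[, 4] > 2.2)
    hy <- gbt_hyper(n_trees = 10, max_depth = 3)
    list(A = train_detector(X, y_art, hy), S = train_detector(X, y_seiz, hy),
         X = X, y_art = y_art, y_seiz = y_seiz)
  })
}

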