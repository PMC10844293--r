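#' Inverse-frequency ("balanced") class weights
#'
#' Weight of class c is proportional to `1 / frequency(c)`, normalized so the
#' mean per-sample weight is 1. With a 90/10 split the minority/majority
#' weight ratio is 9. The weighted training loss penalizes minority-class
#' misclassifications more heavily — for seizure detection, the mechanism by
#' which rare ictal windows are not swamped by background.
#'
#' @param labels vector of class labels (any atomic type).
#' @return Named numeric vector of per-class weights.
#' @examples
#' balanced_class_weights(c(rep(0, 90), rep(1, 10)))
#' @export
balanced_class_weights <- function(labels) {
  if (length(labels) == 0) stop("`labels` is empty", call. = FALSE)
  tab <- table(labels)
  w <- length(labels) / (length(tab) * as.numeric(tab))
  stats::setNames(w, names(tab))
}

#' Default detector hyperparameters
#'
#' A fixed, configurable hyperparameter set: 72 trees (divisible by both 8 and
#' 9, so the ensemble maps onto 8- or 9-core clusters without padding), depth
#' 6, learning rate 0.1. `weights` is `"balanced"` (inverse class frequency),
#' `"none"`, or a single number giving the positive/negative weight ratio
#' directly (the knob behind the sensitivity/specificity trade-off study).
#'
#' @param n_trees boosting rounds.
#' @param max_depth maximum tree depth.
#' @param learning_rate shrinkage (eta).
#' @param lambda L2 leaf regularization.
#' @param weights class weighting scheme (see above).
#' @param base_score prior positive probability (margin offset).
#' @param seed RNG seed recorded with the model (training itself uses the
#'   exact greedy method and is deterministic).
#' @return A list of class `gbt_hyper`.
#' @export
gbt_hyper <- function(n_trees = 72, max_depth = 6, learning_rate = 0.1,
                      lambda = 1, weights = "balanced", base_score = 0.5,
                      seed = 0) {
  structure(list(n_trees = n_trees, max_depth = max_depth,
                 learning_rate = learning_rate, lambda = lambda,
                 weights = weights, base_score = base_score, seed = seed),
            class = "gbt_hyper")
}

resolve_weights <- function(y, scheme) {
  if (is.numeric(scheme)) {
    w <- ifelse(y == 1, scheme, 1)
  } else if (identical(scheme, "none")) {
    w <- rep(1, length(y))
  } else {
    cw <- balanced_class_weights(y)
    w <- as.numeric(cw[as.character(y)])
  }
  w
}

#' Train a gradient-boosted tree detector
#'
#' Fits a class-weighted XGBoost model (exact greedy splits, single thread —
#' deterministic for a given configuration), then extracts every tree into a
#' package-owned structure annotated with per-node training risks, so the
#' ensemble can be pruned to a memory budget and flattened to the compact
#' embedded format. Binary tasks use the logistic objective; multiclass tasks
#' (artifact type per channel) use softmax.
#'
#' @param X feature tibble from [build_feature_matrix()] (bookkeeping columns
#'   are ignored) or a numeric matrix.
#' @param y label vector: 0/1 for binary, integer codes for multiclass.
#' @param hyper a [gbt_hyper()] configuration.
#' @param task `"binary"` or `"multiclass"`.
#' @return An object of class `gbt_ensemble` with elements `trees` (list of
#'   annotated tree tables), `tree_class`, `learning_rate`, `base_score`,
#'   `base_margin`, `task`, `class_weights`, `feature_names`, `code_map`
#'   (multiclass), `n_class`, `hyper`.
#' @examples
#' X <- matrix(rnorm(400), 200, 2)
#' y <- as.integer(X[, 1] > 0)
#' fit <- train_detector(X, y, gbt_hyper(n_trees = 10, max_depth = 2))
#' mean((predict(fit, X) > 0.5) == y)
#' @export
train_detector <- function(X, y, hyper = gbt_hyper(),
                           task = c("binary", "multiclass")) {
  task <- match.arg(task)
  Xm <- if (is.matrix(X)) X else feature_values(X)
  feature_names <- colnames(Xm)
  colnames(Xm) <- NULL
  if (nrow(Xm) != length(y)) stop("rows of `X` must align with `y`", call. = FALSE)
  y <- as.integer(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) {
    stop("training requires at least two observed classes", call. = FALSE)
  }
  if (task == "binary" && !all(classes %in% c(0L, 1L))) {
    stop("binary task labels must be 0/1", call. = FALSE)
  }
  w <- resolve_weights(y, hyper$weights)
  if (task == "binary") {
    code_map <- c(0L, 1L)
    ylab <- y
    n_class <- 1L
    params <- list(objective = "binary:logistic", base_score = hyper$base_score)
  } else {
    code_map <- classes
    ylab <- match(y, classes) - 1L
    n_class <- length(classes)
    params <- list(objective = "multi:softprob", num_class = n_class)
  }
  params <- c(params, list(
    max_depth = hyper$max_depth, eta = hyper$learning_rate,
    lambda = hyper$lambda, tree_method = "exact", nthread = 1,
    seed = hyper$seed))
  dtrain <- xgboost::xgb.DMatrix(Xm, label = ylab, weight = w)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = hyper$n_trees, verbose = 0)
  dump <- xgboost::xgb.dump(booster, dump_format = "json", with_stats = TRUE)
  nodes <- jsonlite::fromJSON(paste(dump, collapse = "\n"),
                              simplifyVector = FALSE)
  trees <- lapply(nodes, parse_dump_tree)
  ens <- structure(list(
    trees = trees,
    tree_class = rep(seq_len(n_class) - 1L, times = length(trees) / n_class),
    learning_rate = hyper$learning_rate,
    base_score = if (task == "binary") hyper$base_score else 1 / n_class,
    base_margin = if (task == "binary") {
      stats::qlogis(hyper$base_score)
    } else 0,
    task = task, n_class = n_class, code_map = code_map,
    class_weights = stats::setNames(
      vapply(classes, function(cl) mean(w[y == cl]), numeric(1)),
      as.character(classes)),
    feature_names = feature_names, n_features = ncol(Xm), hyper = hyper
  ), class = "gbt_ensemble")
  annotate_ensemble_risk(ens, Xm, ylab, w)
}

# recompute per-iteration gradients/hessians with the package's own traversal
# and annotate every tree's nodes with risks and collapse values
annotate_ensemble_risk <- function(ens, X, y, w) {
  K <- ens$n_class
  n <- nrow(X)
  margin <- matrix(ens$base_margin, n, K)
  lambda <- ens$hyper$lambda
  for (m in seq_along(ens$trees)) {
    k <- ens$tree_class[m] + 1L
    if (K == 1) {
      p <- stats::plogis(margin[, 1])
      g <- w * (p - y)
      h <- pmax(w * p * (1 - p), 1e-16)
    } else {
      mx <- apply(margin, 1, max)
      E <- exp(margin - mx)  # mx recycles down rows (column-major)
      pk <- E[, k] / rowSums(E)
      g <- w * (pk - as.numeric(y == k - 1L))
      h <- pmax(2 * w * pk * (1 - pk), 1e-16)
    }
    ens$trees[[m]] <- annotate_tree_risk(ens$trees[[m]], X, g, h,
                                         ens$learning_rate, lambda)
    margin[, k] <- margin[, k] + tree_value(ens$trees[[m]], X)
  }
  ens
}

#' @export
print.gbt_ensemble <- function(x, ...) {
  cat(sprintf("<gbt_ensemble> %s: %d tree(s), %d nodes, %d feature(s)\n",
              x$task, length(x$trees), ensemble_n_nodes(x), x$n_features))
  invisible(x)
}

#' Predict from a boosted-tree detector
#'
#' @param object a `gbt_ensemble`.
#' @param newdata feature tibble or numeric matrix.
#' @param type `"prob"` (default; positive-class probability for binary,
#'   class-probability matrix for multiclass), `"margin"` (raw additive
#'   score), or `"class"` (0/1 at `threshold`, or the argmax code).
#' @param threshold binary decision threshold on the probability scale
#'   (default 0.5).
#' @param cast32 evaluate with thresholds and leaf values cast to 32-bit
#'   floats (the embedded numeric type).
#' @param ... unused.
#' @return Vector (binary) or matrix (multiclass).
#' @export
predict.gbt_ensemble <- function(object, newdata,
                                 type = c("prob", "margin", "class"),
                                 threshold = 0.5, cast32 = FALSE, ...) {
  type <- match.arg(type)
  Xm <- if (is.matrix(newdata)) newdata else feature_values(newdata)
  if (ncol(Xm) != object$n_features) {
    stop(sprintf("expected %d features, got %d", object$n_features, ncol(Xm)),
         call. = FALSE)
  }
  mg <- ensemble_margin(object, Xm, cast32 = cast32)
  if (object$task == "binary") {
    m <- mg[, 1]
    switch(type,
           margin = m,
           prob = stats::plogis(m),
           class = as.integer(stats::plogis(m) > threshold))
  } else {
    if (type == "margin") return(mg)
    p <- exp(mg - apply(mg, 1, max))
    p <- p / rowSums(p)
    colnames(p) <- as.character(object$code_map)
    if (type == "prob") p else object$code_map[max.col(p, ties.method = "first")]
  }
}

# constant predictor for degenerate single-class channels
constant_model <- function(value, n_features, feature_names = NULL) {
  structure(list(value = value, n_features = n_features,
                 feature_names = feature_names),
            class = "gbt_constant")
}

#' @export
predict.gbt_constant <- function(object, newdata,
                                 type = c("prob", "margin", "class"),
                                 threshold = 0.5, ...) {
  type <- match.arg(type)
  n <- if (is.matrix(newdata)) nrow(newdata) else nrow(newdata)
  if (type == "class") rep(object$value, n)
  else rep(if (object$value == 0) 0 else 1, n)
}

#' @export
print.gbt_constant <- function(x, ...) {
  cat(sprintf("<gbt_constant> always predicts %s\n", x$value))
  invisible(x)
}

#' Fit artifact detectors in the three labeling formats
#'
#' `bc` (window-global binary): one model on the any-channel artifact label.
#' `mc` (per-channel binary): one independent binary model per channel.
#' `mmc` (per-channel multiclass): one model per channel over the observed
#' artifact codes (0 = background plus the artifact types present). Class
#' weighting is applied per model. A channel with a single observed class
#' yields a constant predictor with a warning.
#'
#' @param X feature tibble or matrix.
#' @param labels a window-label list from [label_windows()].
#' @param mode `"bc"`, `"mc"` or `"mmc"`.
#' @param hyper a [gbt_hyper()].
#' @return For `bc` a single `gbt_ensemble`; for `mc`/`mmc` a list of models,
#'   one per channel, of class `gbt_channel_models`.
#' @export
fit_artifact_task <- function(X, labels, mode = c("bc", "mc", "mmc"),
                              hyper = gbt_hyper()) {
  mode <- match.arg(mode)
  if (mode == "bc") {
    return(train_detector(X, labels$bc, hyper, task = "binary"))
  }
  lab <- if (mode == "mc") labels$mc else labels$mmc
  nch <- ncol(lab)
  models <- vector("list", nch)
  Xm <- if (is.matrix(X)) X else feature_values(X)
  for (ch in seq_len(nch)) {
    y <- lab[, ch]
    if (length(unique(y)) < 2) {
      warning(sprintf("channel %d has a single observed class; using a constant predictor",
                      ch))
      models[[ch]] <- constant_model(unique(y), ncol(Xm), colnames(Xm))
    } else {
      models[[ch]] <- train_detector(
        Xm, y, hyper, task = if (mode == "mc") "binary" else "multiclass")
    }
  }
  structure(models, class = "gbt_channel_models", mode = mode)
}

#' @export
print.gbt_channel_models <- function(x, ...) {
  cat(sprintf("<gbt_channel_models> %s: %d channel model(s)\n",
              attr(x, "mode"), length(x)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a boosted ensemble
#'
#' One row per tree: node/leaf counts, depth and training-risk totals.
#'
#' @param x a `gbt_ensemble`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.gbt_ensemble <- function(x, ...) {
  tibble::tibble(
    tree = seq_along(x$trees),
    class = x$tree_class,
    n_nodes = vapply(x$trees, nrow, numeric(1)),
    n_leaves = vapply(x$trees, function(t) sum(t$is_leaf), numeric(1)),
    depth = vapply(x$trees, tree_depth, numeric(1)),
    root_risk = vapply(x$trees, function(t) t$risk[1], numeric(1)),
    leaf_risk = vapply(x$trees, function(t) sum(t$risk[t$is_leaf]), numeric(1))
  )
}

tree_depth <- function(tree) {
  d <- function(id) {
    if (tree$is_leaf[id]) 0L else 1L + max(d(tree$yes[id]), d(tree$no[id]))
  }
  d(1L)
}

#' Summarize a boosted ensemble
#'
#' @param x a `gbt_ensemble`.
#' @param ... unused.
#' @return A one-row tibble: task, tree count, node count, compact byte cost.
#' @export
glance.gbt_ensemble <- function(x, ...) {
  tibble::tibble(
    task = x$task, n_trees = length(x$trees),
    n_nodes = ensemble_n_nodes(x),
    n_features = x$n_features,
    compact_bytes = 7 * ensemble_n_nodes(x),
    learning_rate = x$learning_rate
  )
}
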