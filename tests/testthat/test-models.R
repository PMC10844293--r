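test_that("balanced class weights are inverse-frequency with unit mean", {
  w <- balanced_class_weights(c(rep(0, 50), rep(1, 50)))
  expect_equal(unname(w), c(1, 1))
  w2 <- balanced_class_weights(c(rep(0, 90), rep(1, 10)))
  expect_equal(unname(w2["1"] / w2["0"]), 9)
  y <- c(rep(0, 90), rep(1, 10))
  expect_equal(mean(as.numeric(w2[as.character(y)])), 1)
  expect_error(balanced_class_weights(integer(0)), "empty")
})

test_that("training separates a separable problem and is deterministic", {
  d <- toy_xy()
  fit <- train_detector(d$X, d$y, gbt_hyper(n_trees = 40, max_depth = 4))
  expect_equal(mean(predict(fit, d$X, type = "class") == d$y), 1)
  fit2 <- train_detector(d$X, d$y, gbt_hyper(n_trees = 40, max_depth = 4))
  strip <- function(e) lapply(e$trees, function(t) t[c("feature", "threshold",
                                                       "yes", "no", "value")])
  expect_identical(strip(fit), strip(fit2))
})

test_that("training validates its inputs", {
  d <- toy_xy()
  expect_error(train_detector(d$X, d$y[-1]), "align")
  expect_error(train_detector(d$X, rep(1L, nrow(d$X))), "two observed classes")
  expect_error(predict(small_ensemble()$fit, matrix(0, 2, 3)), "features")
})

test_that("package scoring equals a slow independent re-implementation", {
  e <- small_ensemble(n_trees = 12, depth = 3)
  set.seed(21)
  Xn <- matrix(rnorm(150 * 6), 150, 6)
  expect_equal(predict(e$fit, Xn, type = "margin"), slow_score(e$fit, Xn),
               tolerance = 1e-12)
})

test_that("package scoring matches the training library's predictions", {
  # independent cross-check of the extraction path against xgboost itself
  d <- toy_xy(n = 250, seed = 13)
  hyper <- gbt_hyper(n_trees = 15, max_depth = 4)
  fit <- train_detector(d$X, d$y, hyper)
  w <- balanced_class_weights(d$y)[as.character(d$y)]
  dm <- xgboost::xgb.DMatrix(unname(d$X), label = d$y, weight = as.numeric(w))
  ref <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", base_score = 0.5,
                  max_depth = 4, eta = 0.1, lambda = 1,
                  tree_method = "exact", nthread = 1, seed = 0),
    data = dm, nrounds = 15, verbose = 0)
  expect_equal(predict(fit, d$X), predict(ref, unname(d$X)),
               tolerance = 1e-6)
})

test_that("risk annotations decompose: children risks never exceed parent", {
  e <- small_ensemble(n_trees = 8, depth = 3)
  for (tr in e$fit$trees) {
    for (id in which(!tr$is_leaf)) {
      expect_lte(tr$risk[tr$yes[id]] + tr$risk[tr$no[id]],
                 tr$risk[id] + 1e-8)
    }
  }
})

test_that("artifact task formats produce the documented model cardinality", {
  set.seed(31)
  n <- 240
  X <- matrix(rnorm(n * 8), n, 8)
  mc <- matrix(rbinom(n * 4, 1, 0.25), n, 4)
  mmc <- mc * sample(c(1L, 4L), n * 4, replace = TRUE)
  labels <- list(bc = as.integer(rowSums(mc) > 0), mc = mc, mmc = mmc)
  hy <- gbt_hyper(n_trees = 4, max_depth = 2)
  expect_s3_class(fit_artifact_task(X, labels, "bc", hy), "gbt_ensemble")
  mcm <- fit_artifact_task(X, labels, "mc", hy)
  expect_length(mcm, 4)
  mmcm <- fit_artifact_task(X, labels, "mmc", hy)
  expect_length(mmcm, 4)
  # vocabulary restricted to the observed codes {0, 1, 4}
  expect_setequal(mmcm[[1]]$code_map, sort(unique(mmc[, 1])))
  p <- predict(mmcm[[1]], X, type = "class")
  expect_true(all(p %in% mmcm[[1]]$code_map))
})

test_that("a single-class channel degrades to a constant predictor", {
  set.seed(32)
  X <- matrix(rnorm(100 * 4), 100, 4)
  mc <- cbind(rbinom(100, 1, 0.3), 0L, rbinom(100, 1, 0.3), rbinom(100, 1, 0.3))
  labels <- list(bc = as.integer(rowSums(mc) > 0), mc = mc, mmc = mc)
  expect_warning(
    m <- fit_artifact_task(X, labels, "mc", gbt_hyper(n_trees = 3, max_depth = 2)),
    "constant")
  expect_s3_class(m[[2]], "gbt_constant")
  expect_equal(predict(m[[2]], X, type = "class"), rep(0L, 100))
})

test_that("multiclass training recovers class structure on a toy problem", {
  set.seed(33)
  n <- 300
  y <- sample(c(0L, 2L, 5L), n, replace = TRUE)
  X <- matrix(rnorm(n * 3), n, 3)
  X[, 1] <- X[, 1] + 2.5 * (y == 2)
  X[, 2] <- X[, 2] + 2.5 * (y == 5)
  fit <- train_detector(X, y, gbt_hyper(n_trees = 20, max_depth = 4),
                        task = "multiclass")
  expect_equal(fit$n_class, 3L)
  expect_gt(mean(predict(fit, X, type = "class") == y), 0.9)
  pr <- predict(fit, X, type = "prob")
  expect_equal(rowSums(pr), rep(1, n), tolerance = 1e-9)
})

test_that("tidy and glance summarize ensembles", {
  e <- small_ensemble(n_trees = 8, depth = 3)
  td <- tidy(e$fit)
  expect_equal(nrow(td), 8)
  expect_true(all(td$n_leaves == (td$n_nodes + 1) / 2))  # full binary trees
  gl <- glance(e$fit)
  expect_equal(gl$compact_bytes, 7 * sum(td$n_nodes))
})

test_that("model JSON serialization round trips predictions and risks", {
  e <- small_ensemble(n_trees = 6, depth = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(e$fit, f)
  back <- read_model(f)
  set.seed(41)
  Xn <- matrix(rnorm(80 * 6), 80, 6)
  expect_equal(predict(back, Xn), predict(e$fit, Xn), tolerance = 1e-12)
  expect_equal(back$trees[[1]]$risk, e$fit$trees[[1]]$risk, tolerance = 1e-12)
})
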