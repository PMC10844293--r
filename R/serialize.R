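#' Save / load a boosted ensemble as self-describing JSON
#'
#' The JSON carries every tree's node table (features, thresholds, children,
#' leaf values, risks) plus the ensemble metadata, so the compact flattener
#' and the reference interpreter can consume a stable format independent of
#' the training library.
#'
#' @param ens a `gbt_ensemble` (or `gbt_channel_models` list).
#' @param path output path.
#' @return `write_model()` returns `path` invisibly; `read_model()` the
#'   restored object.
#' @export
write_model <- function(ens, path) {
  to_list <- function(e) {
    if (inherits(e, "gbt_constant")) {
      return(list(kind = "constant", value = e$value,
                  n_features = e$n_features,
                  feature_names = e$feature_names))
    }
    list(
      kind = "ensemble",
      trees = lapply(e$trees, function(tr) as.list(tr)),
      tree_class = e$tree_class, learning_rate = e$learning_rate,
      base_score = e$base_score, base_margin = e$base_margin,
      task = e$task, n_class = e$n_class, code_map = e$code_map,
      class_weights = as.list(e$class_weights),
      feature_names = e$feature_names, n_features = e$n_features
    )
  }
  obj <- if (inherits(ens, "gbt_channel_models")) {
    list(kind = "channel_models", mode = attr(ens, "mode"),
         channels = lapply(ens, to_list))
  } else {
    to_list(ens)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  from_list <- function(o) {
    if (identical(o$kind, "constant")) {
      return(constant_model(o$value, o$n_features, o$feature_names))
    }
    trees <- lapply(o$trees, function(tr) {
      d <- data.frame(
        id = as.integer(tr$id),
        feature = as.integer(replace_null(tr$feature)),
        threshold = as.numeric(replace_null(tr$threshold)),
        yes = as.integer(replace_null(tr$yes)),
        no = as.integer(replace_null(tr$no)),
        is_leaf = as.logical(tr$is_leaf),
        value = as.numeric(tr$value),
        risk = as.numeric(replace_null(tr$risk)),
        cover = as.numeric(replace_null(tr$cover))
      )
      d
    })
    structure(list(
      trees = trees, tree_class = as.integer(o$tree_class),
      learning_rate = o$learning_rate, base_score = o$base_score,
      base_margin = o$base_margin, task = o$task,
      n_class = as.integer(o$n_class), code_map = as.integer(o$code_map),
      class_weights = unlist(o$class_weights),
      feature_names = o$feature_names, n_features = as.integer(o$n_features),
      hyper = NULL
    ), class = "gbt_ensemble")
  }
  if (identical(obj$kind, "channel_models")) {
    structure(lapply(obj$channels, from_list),
              class = "gbt_channel_models", mode = obj$mode)
  } else {
    from_list(obj)
  }
}

replace_null <- function(x) {
  if (is.list(x)) {
    x[vapply(x, is.null, logical(1))] <- NA
    unlist(x)
  } else {
    x
  }
}
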