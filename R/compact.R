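#' Flatten a tree ensemble to the compact three-array format
#'
#' Each tree becomes three parallel arrays in breadth-first node order: the
#' feature array (8-bit; which feature a node compares, with 255 marking a
#' leaf), the index array (16-bit; position of the left/"yes" child — the
#' right child is the next position — with a self-reference marking leaf
#' termination) and the threshold array (32-bit floats; split thresholds for
#' internal nodes, leaf score contributions for leaves). A node therefore
#' costs 1 + 2 + 4 = 7 bytes; per-tree offsets and metadata are kept in a
#' separate header, costed apart from the 7-bytes-per-node figure.
#'
#' @param ens a fitted (optionally pruned) `gbt_ensemble`.
#' @return An object of class `compact_ensemble`: `feature_arr`, `index_arr`,
#'   `threshold_arr` (one concatenated vector each), `tree_offsets` (0-based),
#'   `tree_class`, `n_trees`, `n_features`, `base_margin`, `n_class`, `task`,
#'   `code_map`, `feature_names`.
#' @examples
#' X <- matrix(rnorm(200), 100, 2); y <- as.integer(X[, 1] > 0)
#' ce <- flatten(train_detector(X, y, gbt_hyper(n_trees = 4, max_depth = 2)))
#' memory_bytes(ce)
#' @export
flatten <- function(ens) {
  stopifnot(inherits(ens, "gbt_ensemble"))
  if (ens$n_features > 255) {
    stop(sprintf("feature index overflow: %d features do not fit the 8-bit feature array",
                 ens$n_features), call. = FALSE)
  }
  feat <- list(); idx <- list(); thr <- list()
  offsets <- integer(length(ens$trees))
  pos <- 0L
  for (m in seq_along(ens$trees)) {
    tr <- ens$trees[[m]]
    n <- nrow(tr)
    if (n > 65535) {
      stop(sprintf("node index overflow: tree %d has %d nodes, exceeding the 16-bit index array",
                   m, n), call. = FALSE)
    }
    # breadth-first order
    bfs <- integer(n); bfs[1] <- 1L; head <- 1L; tail <- 1L
    while (head <= tail) {
      id <- bfs[head]
      if (!tr$is_leaf[id]) {
        bfs[tail + 1L] <- tr$yes[id]
        bfs[tail + 2L] <- tr$no[id]
        tail <- tail + 2L
      }
      head <- head + 1L
    }
    newpos <- integer(n); newpos[bfs] <- seq_len(n) - 1L  # 0-based
    f <- integer(n); ix <- integer(n); th <- numeric(n)
    for (j in seq_len(n)) {
      id <- bfs[j]
      if (tr$is_leaf[id]) {
        f[j] <- 255L
        ix[j] <- j - 1L           # self-reference terminates traversal
        th[j] <- tr$value[id]
      } else {
        f[j] <- tr$feature[id]
        ix[j] <- newpos[tr$yes[id]]
        th[j] <- tr$threshold[id]
      }
    }
    feat[[m]] <- f; idx[[m]] <- ix; thr[[m]] <- cast_f32(th)
    offsets[m] <- pos
    pos <- pos + n
  }
  structure(list(
    feature_arr = as.integer(c(integer(0), unlist(feat, use.names = FALSE))),
    index_arr = as.integer(c(integer(0), unlist(idx, use.names = FALSE))),
    threshold_arr = as.numeric(c(numeric(0), unlist(thr, use.names = FALSE))),
    tree_offsets = offsets,
    tree_class = ens$tree_class,
    n_trees = length(ens$trees),
    n_features = ens$n_features,
    base_margin = ens$base_margin,
    n_class = ens$n_class,
    task = ens$task,
    code_map = ens$code_map,
    feature_names = ens$feature_names
  ), class = "compact_ensemble")
}

#' @export
print.compact_ensemble <- function(x, ...) {
  cat(sprintf("<compact_ensemble> %s: %d tree(s), %d nodes, %d bytes (+%d header)\n",
              x$task, x$n_trees, length(x$feature_arr), memory_bytes(x),
              header_bytes(x)))
  invisible(x)
}

#' Memory cost of a compact ensemble
#'
#' `memory_bytes()` is the embedded-model figure: 7 bytes per node (1-byte
#' feature + 2-byte index + 4-byte threshold, packed). Offsets and metadata a
#' deployment would also store are reported separately by `header_bytes()`
#' (4 bytes per tree offset plus a 12-byte fixed header) and excluded from the
#' per-node figure.
#'
#' @param ce a `compact_ensemble`.
#' @return Integer byte count.
#' @examples
#' # a single stump (1 internal node + 2 leaves) costs 21 bytes
#' @export
memory_bytes <- function(ce) {
  stopifnot(inherits(ce, "compact_ensemble"))
  7L * length(ce$feature_arr)
}

#' @rdname memory_bytes
#' @export
header_bytes <- function(ce) {
  stopifnot(inherits(ce, "compact_ensemble"))
  4L * ce$n_trees + 12L
}

#' Reference inference on the compact arrays
#'
#' Walks the three arrays exactly as an embedded interpreter would: start at a
#' tree's offset; while the feature byte is not the leaf sentinel, compare the
#' input's feature against the threshold and move to the index-array child
#' (left when `x < threshold`, the next position otherwise); at a leaf add the
#' threshold-array value to the running score. The result equals the source
#' ensemble's additive margin after 32-bit threshold casting.
#'
#' @param ce a `compact_ensemble`.
#' @param x a single feature vector, or a matrix with one input per row.
#' @return Margin-scale score per input (matrix with `n_class` columns for
#'   multiclass ensembles; an empty ensemble returns the base margin).
#' @export
compact_infer <- function(ce, x) {
  stopifnot(inherits(ce, "compact_ensemble"))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != ce$n_features) {
    stop(sprintf("expected %d features, got %d", ce$n_features, ncol(X)),
         call. = FALSE)
  }
  out <- matrix(ce$base_margin, nrow(X), ce$n_class)
  for (m in seq_len(ce$n_trees)) {
    off <- ce$tree_offsets[m]
    k <- ce$tree_class[m] + 1L
    p <- rep(off + 1L, nrow(X))          # absolute 1-based positions
    active <- which(ce$feature_arr[p] != 255L)
    while (length(active) > 0) {
      pa <- p[active]
      goleft <- X[cbind(active, ce$feature_arr[pa] + 1L)] < ce$threshold_arr[pa]
      p[active] <- off + ce$index_arr[pa] + ifelse(goleft, 1L, 2L)
      active <- active[ce$feature_arr[p[active]] != 255L]
    }
    out[, k] <- out[, k] + ce$threshold_arr[p]
  }
  if (ce$n_class == 1L) out[, 1] else out
}

#' Rebuild a tree ensemble from its compact form
#'
#' Inverse of [flatten()]: reconstructs the tree topology, thresholds and leaf
#' values (now 32-bit-quantized). Training annotations (risks) are not part
#' of the compact format and are absent.
#'
#' @param ce a `compact_ensemble`.
#' @return A `gbt_ensemble` whose predictions match `compact_infer()`.
#' @export
unflatten <- function(ce) {
  stopifnot(inherits(ce, "compact_ensemble"))
  ends <- c(ce$tree_offsets[-1], length(ce$feature_arr))
  trees <- vector("list", ce$n_trees)
  for (m in seq_len(ce$n_trees)) {
    off <- ce$tree_offsets[m]
    n <- ends[m] - off
    rel <- seq_len(n)
    f <- ce$feature_arr[off + rel]
    ix <- ce$index_arr[off + rel]
    th <- ce$threshold_arr[off + rel]
    leaf <- f == 255L
    trees[[m]] <- data.frame(
      id = rel,
      feature = ifelse(leaf, NA_integer_, f),
      threshold = ifelse(leaf, NA_real_, th),
      yes = ifelse(leaf, NA_integer_, ix + 1L),
      no = ifelse(leaf, NA_integer_, ix + 2L),
      is_leaf = leaf,
      value = ifelse(leaf, th, 0),
      risk = NA_real_,
      cover = NA_real_
    )
  }
  structure(list(
    trees = trees, tree_class = ce$tree_class, learning_rate = NA_real_,
    base_score = if (ce$task == "binary") stats::plogis(ce$base_margin)
                 else 1 / ce$n_class,
    base_margin = ce$base_margin, task = ce$task, n_class = ce$n_class,
    code_map = ce$code_map, class_weights = NULL,
    feature_names = ce$feature_names, n_features = ce$n_features,
    hyper = NULL
  ), class = "gbt_ensemble")
}

#' Pad the tree count to a multiple of the core count
#'
#' Parallel embedded inference assigns trees to cores round-robin, so the tree
#' count is padded to a multiple of the core count with zero-leaf stub trees
#' (one all-zero leaf each, for every class in multiclass ensembles).
#' Predictions are unchanged.
#'
#' @param ce a `compact_ensemble`.
#' @param unit the core count (>= 1).
#' @return A `compact_ensemble` with `n_trees %% unit == 0`.
#' @export
pad_tree_count <- function(ce, unit) {
  stopifnot(inherits(ce, "compact_ensemble"), unit >= 1)
  rem <- ce$n_trees %% unit
  if (rem == 0) return(ce)
  n_add <- unit - rem
  pos <- length(ce$feature_arr)
  for (i in seq_len(n_add)) {
    ce$feature_arr <- c(ce$feature_arr, 255L)
    ce$index_arr <- c(ce$index_arr, 0L)
    ce$threshold_arr <- c(ce$threshold_arr, 0)
    ce$tree_offsets <- c(ce$tree_offsets, pos)
    ce$tree_class <- c(ce$tree_class, (i - 1L) %% ce$n_class)
    pos <- pos + 1L
  }
  ce$n_trees <- ce$n_trees + n_add
  ce
}

#' Export / import the compact arrays as a binary blob
#'
#' Writes, per tree, the little-endian concatenation of the three arrays
#' (features as unsigned bytes, indices as unsigned 16-bit, thresholds as
#' 32-bit floats) to `<path>`, with a JSON sidecar `<path>.json` holding
#' offsets and metadata — the layout a C deployment would `mmap`. Bit-exact
#' across platforms.
#'
#' @param ce a `compact_ensemble`.
#' @param path output path for the binary blob.
#' @return `write_compact()` returns `path` invisibly; `read_compact()`
#'   returns the `compact_ensemble`.
#' @export
write_compact <- function(ce, path) {
  stopifnot(inherits(ce, "compact_ensemble"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(ce$feature_arr), con)
  u16 <- ifelse(ce$index_arr > 32767L, ce$index_arr - 65536L, ce$index_arr)
  writeBin(as.integer(u16), con, size = 2, endian = "little")
  writeBin(as.numeric(ce$threshold_arr), con, size = 4, endian = "little")
  meta <- ce[c("tree_offsets", "tree_class", "n_trees", "n_features",
               "base_margin", "n_class", "task", "code_map", "feature_names")]
  meta$n_nodes <- length(ce$feature_arr)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_compact
#' @export
read_compact <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$n_nodes
  con <- file(path, "rb")
  on.exit(close(con))
  feat <- as.integer(readBin(con, "raw", n))
  ix <- readBin(con, "integer", n, size = 2, signed = FALSE, endian = "little")
  th <- readBin(con, "numeric", n, size = 4, endian = "little")
  structure(list(
    feature_arr = feat, index_arr = ix, threshold_arr = th,
    tree_offsets = as.integer(meta$tree_offsets),
    tree_class = as.integer(meta$tree_class),
    n_trees = as.integer(meta$n_trees),
    n_features = as.integer(meta$n_features),
    base_margin = meta$base_margin,
    n_class = as.integer(meta$n_class),
    task = meta$task,
    code_map = as.integer(meta$code_map),
    feature_names = meta$feature_names
  ), class = "compact_ensemble")
}
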