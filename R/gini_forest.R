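# From-scratch decision trees and random forest over the CNN feature
# matrix.
#
# Node candidates follow the randomized scheme of the method: a candidate
# split is a uniformly drawn feature column paired with the feature value
# of a uniformly drawn row currently in the node (the value becomes the
# threshold).  Each node draws ceil(sqrt(n_features)) such candidates and
# keeps the one minimising the child-size-weighted mean Gini impurity;
# candidates_per_node = 1 recovers the fully random single-pick variant,
# and candidates_per_node = "all" evaluates every (row, column) pair
# (used as an exhaustive oracle in tests).  Rows with value <= threshold
# go left.

#' Gini impurity of a class-count distribution
#'
#' \eqn{I_G = 1 - \sum_i p(i)^2} with \eqn{p(i)} the class proportions.
#' Zero for a pure node; at most \eqn{1 - 1/C} (0.5 for two classes).
#'
#' @param counts non-negative integer vector of per-class counts with a
#'   positive total.
#' @return the impurity, a real in `[0, 1 - 1/C]`.
#' @examples
#' gini_impurity(c(3, 1))  # 0.375
#' @export
gini_impurity <- function(counts) {
  if (any(counts < 0)) stop("class counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("empty class distribution")
  p <- counts / total
  1 - sum(p^2)
}

#' Number of split candidates per node: the square-root rule
#'
#' Classification forests conventionally consider about
#' \eqn{\sqrt{\#features}} candidates at each node; this returns the
#' round-up, capped at `n_features` (so 36 features give 6 candidates).
#'
#' @param n_features number of features (>= 1).
#' @return integer candidate count in `[1, n_features]`.
#' @export
max_candidate_features <- function(n_features) {
  if (length(n_features) != 1L || is.na(n_features) || n_features < 1)
    stop("n_features must be a single integer >= 1")
  min(as.integer(ceiling(sqrt(n_features))), as.integer(n_features))
}

#' Bootstrap row indices
#'
#' Draws `n_rows` row indices uniformly with replacement from
#' `1:n_rows`, using the current RNG state (seed with [set.seed()] for
#' reproducibility).
#'
#' @param n_rows number of rows (>= 1).
#' @return integer vector of length `n_rows`.
#' @export
bootstrap_rows <- function(n_rows) {
  if (n_rows < 1L) stop("n_rows must be >= 1")
  sample.int(n_rows, n_rows, replace = TRUE)
}

#' Draw one random (column, threshold) split candidate
#'
#' The column is uniform over the feature columns; the threshold is the
#' drawn column's value at a row drawn uniformly from `node_rows`.
#'
#' @param P numeric feature matrix.
#' @param node_rows non-empty integer vector of row indices at the node.
#' @return list with `feature_col` and `threshold`.
#' @export
draw_split_candidate <- function(P, node_rows) {
  if (!length(node_rows)) stop("node_rows must be non-empty")
  col <- sample.int(ncol(P), 1L)
  row <- node_rows[sample.int(length(node_rows), 1L)]
  list(feature_col = col, threshold = P[row, col])
}

# Child-size-weighted mean Gini of the partition induced by
# (col, thr); Inf when one side is empty.
split_score <- function(P, labels, node_rows, col, thr) {
  left <- P[node_rows, col] <= thr
  nl <- sum(left); nr <- length(node_rows) - nl
  if (nl == 0L || nr == 0L) return(Inf)
  yl <- labels[node_rows[left]]; yr <- labels[node_rows[!left]]
  gl <- gini_impurity(tabulate(yl + 1L, 2L))
  gr <- gini_impurity(tabulate(yr + 1L, 2L))
  (nl * gl + nr * gr) / length(node_rows)
}

#' Forest construction parameters
#'
#' @param n_trees number of trees (default 15, the reference setting).
#' @param candidates_per_node candidates drawn per node; default
#'   `ceiling(sqrt(n_features))` at fit time; `1` gives the fully random
#'   single-candidate variant; `"all"` evaluates every (row, column) pair.
#' @param bootstrap draw a with-replacement bootstrap of the rows for each
#'   tree (default `TRUE`).
#' @param max_depth maximum tree depth (root = depth 0).
#' @param min_samples_leaf nodes with fewer rows are not split further.
#' @param rng_seed seed; each tree uses an independent derived stream.
#' @return a `forest_params` list.
#' @export
forest_params <- function(n_trees = 15L, candidates_per_node = NULL,
                          bootstrap = TRUE, max_depth = 16L,
                          min_samples_leaf = 1L, rng_seed = 1L) {
  if (n_trees < 1L) stop("n_trees must be >= 1")
  structure(list(n_trees = as.integer(n_trees),
                 candidates_per_node = candidates_per_node,
                 bootstrap = isTRUE(bootstrap),
                 max_depth = as.integer(max_depth),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 rng_seed = as.integer(rng_seed)),
            class = "forest_params")
}

resolve_candidates <- function(params, n_features) {
  cpn <- params$candidates_per_node %||% max_candidate_features(n_features)
  if (!identical(cpn, "all")) {
    cpn <- as.integer(cpn)
    if (cpn < 1L) stop("candidates_per_node must be >= 1 or \"all\"")
  }
  cpn
}

#' Best split among randomly drawn candidates
#'
#' Draws `candidates_per_node` candidates via [draw_split_candidate()]
#' (or enumerates every (row, column) pair when
#' `candidates_per_node = "all"`), scores each by child-size-weighted
#' mean Gini, and returns the minimiser.
#'
#' @param P numeric feature matrix.
#' @param labels 0/1 labels aligned with the rows of `P`.
#' @param node_rows integer row indices at the node (impure).
#' @param params a [forest_params()].
#' @return list `(feature_col, threshold, score)`, or `NULL` ("no-split")
#'   when every candidate leaves one child empty.
#' @export
best_split <- function(P, labels, node_rows, params = forest_params()) {
  cpn <- resolve_candidates(params, ncol(P))
  if (identical(cpn, "all")) {
    cand <- expand.grid(row = node_rows, col = seq_len(ncol(P)))
    cols <- cand$col
    thrs <- P[cbind(cand$row, cand$col)]
  } else {
    cols <- integer(cpn); thrs <- numeric(cpn)
    for (i in seq_len(cpn)) {
      d <- draw_split_candidate(P, node_rows)
      cols[i] <- d$feature_col; thrs[i] <- d$threshold
    }
  }
  scores <- vapply(seq_along(cols), function(i)
    split_score(P, labels, node_rows, cols[i], thrs[i]), numeric(1))
  best <- which.min(scores)
  if (!length(best) || !is.finite(scores[best])) return(NULL)
  list(feature_col = cols[best], threshold = thrs[best],
       score = scores[best])
}

leaf_node <- function(counts) {
  # majority class; tie -> negative class (0), the conservative call
  cls <- if (counts[2] > counts[1]) 1L else 0L
  list(type = "leaf", class = cls, counts = as.integer(counts))
}

#' Grow one decision tree on the feature matrix
#'
#' Recursively splits the (optionally bootstrapped) row set until a node
#' is pure (Gini 0), `max_depth` is reached, fewer than
#' `min_samples_leaf` rows remain, or no candidate split separates the
#' rows.  Leaves predict their majority class.
#'
#' @inheritParams best_split
#' @param rows optional integer row multiset to grow on; default is a
#'   bootstrap sample when `params$bootstrap`, else all rows.
#' @return a nested-list tree (`type = "internal"` or `"leaf"`).
#' @export
grow_tree <- function(P, labels, params = forest_params(), rows = NULL) {
  if (length(labels) != nrow(P))
    stop("labels must have one entry per row of P")
  if (is.null(rows))
    rows <- if (params$bootstrap) bootstrap_rows(nrow(P)) else seq_len(nrow(P))
  build <- function(node_rows, depth) {
    counts <- tabulate(labels[node_rows] + 1L, 2L)
    if (gini_impurity(counts) == 0 || depth >= params$max_depth ||
        length(node_rows) < max(2L, params$min_samples_leaf))
      return(leaf_node(counts))
    sp <- best_split(P, labels, node_rows, params)
    if (is.null(sp)) return(leaf_node(counts))
    left <- P[node_rows, sp$feature_col] <= sp$threshold
    list(type = "internal", feature_col = sp$feature_col,
         threshold = sp$threshold,
         left = build(node_rows[left], depth + 1L),
         right = build(node_rows[!left], depth + 1L))
  }
  build(rows, 0L)
}

#' Predict the class of one feature vector with a single tree
#'
#' Walks from the root: value <= threshold goes left, otherwise right.
#'
#' @param tree a tree from [grow_tree()].
#' @param x numeric feature vector of length `n_features`.
#' @param n_features expected length of `x` (checked when supplied).
#' @return predicted class, 0 or 1.
#' @export
predict_tree <- function(tree, x, n_features = NULL) {
  if (!is.null(n_features) && length(x) != n_features)
    stop("feature vector length does not match the model")
  node <- tree
  while (node$type == "internal") {
    node <- if (x[node$feature_col] <= node$threshold) node$left
            else node$right
  }
  node$class
}

#' Fit a random forest on a feature matrix
#'
#' Each tree is grown under an independent RNG stream derived from
#' `params$rng_seed` and the tree index, on its own bootstrap sample when
#' `params$bootstrap`.
#'
#' @param P numeric feature matrix (rows = samples, columns = features).
#' @param labels 0/1 labels aligned with the rows of `P`.
#' @param params a [forest_params()].
#' @return a `cnn_forest` model: list of trees plus metadata.
#' @export
grow_forest <- function(P, labels, params = forest_params()) {
  if (length(labels) != nrow(P))
    stop("labels must have one entry per row of P")
  trees <- lapply(seq_len(params$n_trees), function(t)
    with_seed(derive_seed(params$rng_seed, "tree", t),
              grow_tree(P, labels, params)))
  structure(list(trees = trees, n_features = ncol(P), params = params),
            class = "cnn_forest")
}

#' Majority-vote forest prediction for one feature vector
#'
#' @param model a `cnn_forest`.
#' @param x numeric feature vector of length `model$n_features`.
#' @return list with `class` (majority vote; ties predict 0, the negative
#'   class) and `vote_fraction` (fraction of trees voting positive — the
#'   forest's continuous score, used for AUC).
#' @export
predict_forest <- function(model, x) {
  if (!length(model$trees)) stop("empty forest")
  if (length(x) != model$n_features)
    stop("feature vector length does not match the model")
  votes <- vapply(model$trees, predict_tree, integer(1), x = x)
  frac <- mean(votes == 1L)
  list(class = if (frac > 0.5) 1L else 0L, vote_fraction = frac)
}

#' @export
#' @param object a `cnn_forest`.
#' @param newdata numeric matrix, one feature-vector row per sample.
#' @param ... unused.
#' @rdname predict_forest
predict.cnn_forest <- function(object, newdata, ...) {
  preds <- apply(newdata, 1L, function(x) {
    p <- predict_forest(object, x)
    c(p$class, p$vote_fraction)
  })
  data.frame(class = as.integer(preds[1L, ]), vote_fraction = preds[2L, ])
}

#' @export
print.cnn_forest <- function(x, ...) {
  cat(sprintf("<cnn_forest> %d trees over %d features\n",
              length(x$trees), x$n_features))
  invisible(x)
}

#' Serialize a forest to a human-readable JSON file
#'
#' @param model a `cnn_forest`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
forest_write <- function(model, path) {
  payload <- list(n_features = model$n_features,
                  params = unclass(model$params),
                  trees = model$trees)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a forest written by [forest_write()]
#'
#' @param path path to the JSON file.
#' @return a `cnn_forest` whose predictions are identical to the
#'   original's.
#' @export
forest_read <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  fix_tree <- function(nd) {
    if (nd$type == "leaf")
      list(type = "leaf", class = as.integer(nd$class),
           counts = as.integer(unlist(nd$counts)))
    else
      list(type = "internal", feature_col = as.integer(nd$feature_col),
           threshold = as.numeric(nd$threshold),
           left = fix_tree(nd$left), right = fix_tree(nd$right))
  }
  pp <- payload$params
  params <- forest_params(pp$n_trees,
                          candidates_per_node = pp$candidates_per_node,
                          bootstrap = pp$bootstrap, max_depth = pp$max_depth,
                          min_samples_leaf = pp$min_samples_leaf,
                          rng_seed = pp$rng_seed)
  structure(list(trees = lapply(payload$trees, fix_tree),
                 n_features = as.integer(payload$n_features),
                 params = params),
            class = "cnn_forest")
}
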