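# Built-in CART-style binary decision tree (Gini impurity, axis-aligned
# threshold splits). Kept deliberately small: it is the default weak learner
# for the bagging ensemble, not a general-purpose tree package.

#' Decision-tree weak-learner specification
#'
#' @param max_depth maximum tree depth (`Inf` for unlimited)
#' @param min_split minimum node size eligible for splitting
#' @return a `learner_spec` list with `fit`/`predict` functions
#' @export
tree_learner <- function(max_depth = 5, min_split = 2) {
  structure(list(kind = "tree", max_depth = max_depth, min_split = min_split,
                 fit = function(x, y) fit_tree(x, y, max_depth, min_split),
                 predict = function(model, x) predict_tree(model, x)),
            class = "learner_spec")
}

gini <- function(n1, n0) {
  n <- n1 + n0
  ifelse(n == 0, 0, 1 - (n1 / n)^2 - (n0 / n)^2)
}

# Best threshold split of one feature by weighted Gini. Returns
# c(impurity, threshold) or NULL when the feature is constant.
best_split_feature <- function(x, y) {
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  n <- length(xs)
  distinct <- which(diff(xs) > 0)            # split between xs[i] and xs[i+1]
  if (length(distinct) == 0) return(NULL)
  cum1 <- cumsum(ys)
  n1 <- cum1[n]
  left1 <- cum1[distinct]; leftn <- distinct
  right1 <- n1 - left1; rightn <- n - leftn
  imp <- (leftn * gini(left1, leftn - left1) +
          rightn * gini(right1, rightn - right1)) / n
  b <- which.min(imp)
  thr <- (xs[distinct[b]] + xs[distinct[b] + 1]) / 2
  c(imp[b], thr)
}

# Recursive node builder; nodes stored in a list of rows, children by index.
grow_node <- function(x, y, depth, max_depth, min_split, nodes) {
  n1 <- sum(y == 1L); n0 <- length(y) - n1
  pred <- as.integer(n1 > n0)                # tie -> negative class
  node <- list(leaf = TRUE, pred = pred, n = length(y),
               feature = NA_integer_, threshold = NA_real_,
               left = NA_integer_, right = NA_integer_)
  id <- length(nodes) + 1L
  nodes[[id]] <- node
  if (depth >= max_depth || length(y) < min_split || n1 == 0L || n0 == 0L)
    return(list(id = id, nodes = nodes))
  parent_imp <- gini(n1, n0)
  best <- NULL; best_feat <- NA_integer_
  for (j in seq_len(ncol(x))) {
    s <- best_split_feature(x[, j], y)
    if (!is.null(s) && (is.null(best) || s[1] < best[1] - 1e-12)) {
      best <- s; best_feat <- j             # strict improvement: lowest index wins ties
    }
  }
  if (is.null(best) || best[1] >= parent_imp - 1e-12)
    return(list(id = id, nodes = nodes))
  go_left <- x[, best_feat] <= best[2]
  l <- grow_node(x[go_left, , drop = FALSE], y[go_left], depth + 1,
                 max_depth, min_split, nodes)
  r <- grow_node(x[!go_left, , drop = FALSE], y[!go_left], depth + 1,
                 max_depth, min_split, l$nodes)
  nodes <- r$nodes
  nodes[[id]] <- list(leaf = FALSE, pred = pred, n = length(y),
                      feature = best_feat, threshold = best[2],
                      left = l$id, right = r$id)
  list(id = id, nodes = nodes)
}

fit_tree <- function(x, y, max_depth = 5, min_split = 2) {
  x <- as.matrix(x)
  y <- as.integer(y)
  res <- grow_node(x, y, 0L, max_depth, min_split, list())
  structure(list(nodes = res$nodes, root = res$id, n_features = ncol(x)),
            class = "toxbalance_tree")
}

predict_tree <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$n_features)
    stop_toxbalance("feature dimensionality does not match training",
                    "toxbalance_predict_error")
  vapply(seq_len(nrow(x)), function(i) {
    id <- model$root
    repeat {
      nd <- model$nodes[[id]]
      if (nd$leaf) return(nd$pred)
      id <- if (x[i, nd$feature] <= nd$threshold) nd$left else nd$right
    }
  }, 0L)
}
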