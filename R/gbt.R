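# Gradient-boosted regression trees for binary classification under the
# regularized second-order objective
#   L = sum_i l(yhat_i, y_i) + sum_k [ gamma * T_k + (lambda/2) * ||w_k||^2 ]
# with logistic loss. Exact greedy split search; split gain is
#   1/2 [ GL^2/(HL+lambda) + GR^2/(HR+lambda) - G^2/(H+lambda) ] - gamma
# and the optimal leaf weight is -G/(H+lambda), where G and H are the sums of
# first and second loss derivatives in the node. No R package in the target
# environment provides this learner, so it is implemented here and kept
# deliberately small: no row/column subsampling, fully deterministic given the
# data.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Build one regression tree on gradients g and hessians h. Returns a numeric
# matrix of nodes (preorder), columns: feature index (NA for leaves),
# threshold, child ids, leaf weight, split gain, cover (sum of h).
TREE_COLS <- c("feature", "threshold", "left", "right", "weight", "gain", "cover")

build_tree <- function(X, g, h, max_depth, lambda, gamma, min_child_weight) {
  nodes <- matrix(NA_real_, nrow = 2L^(max_depth + 1L) - 1L, ncol = 7L,
                  dimnames = list(NULL, TREE_COLS))
  n_nodes <- 0L
  new_node <- function(row) {
    n_nodes <<- n_nodes + 1L
    nodes[n_nodes, ] <<- row
    n_nodes
  }
  grow <- function(idx, depth) {
    G <- sum(g[idx]); H <- sum(h[idx])
    if (depth >= max_depth || length(idx) < 2L) {
      return(new_node(c(NA, NA, NA, NA, -G / (H + lambda), NA, H)))
    }
    parent_score <- G * G / (H + lambda)
    best_gain <- 0; best_feature <- NA_integer_; best_threshold <- NA_real_
    for (j in seq_len(ncol(X))) {
      xv <- X[idx, j]
      o <- order(xv, method = "radix")
      xs <- xv[o]
      gs <- cumsum(g[idx][o]); hs <- cumsum(h[idx][o])
      m <- length(xs)
      pos <- which(xs[-m] < xs[-1L])             # splits between distinct values
      if (length(pos) == 0L) next
      GL <- gs[pos]; HL <- hs[pos]
      GR <- G - GL; HR <- H - HL
      ok <- HL >= min_child_weight & HR >= min_child_weight
      if (!any(ok)) next
      gains <- 0.5 * (GL^2 / (HL + lambda) + GR^2 / (HR + lambda) - parent_score) - gamma
      gains[!ok] <- -Inf
      i <- which.max(gains)
      if (gains[i] > best_gain) {
        best_gain <- gains[i]; best_feature <- j
        best_threshold <- (xs[pos[i]] + xs[pos[i] + 1L]) / 2
      }
    }
    if (best_gain <= 0) {
      return(new_node(c(NA, NA, NA, NA, -G / (H + lambda), NA, H)))
    }
    id <- new_node(c(best_feature, best_threshold, NA, NA, NA, best_gain, H))
    go_left <- X[idx, best_feature] < best_threshold
    l_id <- grow(idx[go_left], depth + 1L)
    r_id <- grow(idx[!go_left], depth + 1L)
    nodes[id, "left"] <<- l_id
    nodes[id, "right"] <<- r_id
    id
  }
  grow(seq_len(nrow(X)), 0L)
  nodes[seq_len(n_nodes), , drop = FALSE]
}

predict_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  recur <- function(node, rows) {
    if (length(rows) == 0L) return(invisible())
    if (is.na(tree[node, 1L])) {
      out[rows] <<- tree[node, 5L]
      return(invisible())
    }
    go_left <- X[rows, tree[node, 1L]] < tree[node, 2L]
    recur(tree[node, 3L], rows[go_left])
    recur(tree[node, 4L], rows[!go_left])
  }
  recur(1L, seq_len(nrow(X)))
  out
}

#' Fit a regularized gradient-boosted tree classifier
#'
#' Binary logistic boosting with exact greedy split search under the
#' regularized objective (split penalty `gamma`, L2 leaf-weight penalty
#' `lambda`). The initial margin is the log-odds of the training prevalence.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y 0/1 response vector.
#' @param n_trees number of boosting rounds.
#' @param learning_rate shrinkage applied to each tree's leaf weights.
#' @param max_depth maximum tree depth.
#' @param gamma minimum loss reduction (per-leaf penalty) required to split.
#' @param lambda L2 penalty on leaf weights.
#' @param min_child_weight minimum hessian sum per child.
#' @return object of class `gbt` with the tree list, base margin, and
#'   per-feature split-gain totals.
#' @export
fit_gbt <- function(X, y, n_trees = 200L, learning_rate = 0.1, max_depth = 3L,
                    gamma = 0, lambda = 1, min_child_weight = 1) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (length(y) != nrow(X)) gf_data_error("X and y sizes differ")
  if (length(unique(y)) < 2L) gf_data_error("training set contains a single class")
  if (gamma < 0 || lambda < 0) gf_param_error("penalties must be >= 0")
  p0 <- mean(y)
  base <- log(p0 / (1 - p0))
  margin <- rep(base, nrow(X))
  trees <- vector("list", n_trees)
  gain_by_feature <- numeric(ncol(X))
  for (k in seq_len(n_trees)) {
    p <- sigmoid(margin)
    g <- p - y
    h <- pmax(p * (1 - p), 1e-16)
    tree <- build_tree(X, g, h, max_depth, lambda, gamma, min_child_weight)
    trees[[k]] <- tree
    splits <- !is.na(tree[, "feature"])
    if (any(splits)) {
      gains <- tapply(tree[splits, "gain"], tree[splits, "feature"], sum)
      gain_by_feature[as.integer(names(gains))] <-
        gain_by_feature[as.integer(names(gains))] + gains
    }
    margin <- margin + learning_rate * predict_tree(tree, X)
  }
  structure(list(trees = trees, base = base, learning_rate = learning_rate,
                 feature_names = colnames(X), gain_by_feature = gain_by_feature,
                 params = list(n_trees = n_trees, learning_rate = learning_rate,
                               max_depth = max_depth, gamma = gamma, lambda = lambda,
                               min_child_weight = min_child_weight)),
            class = "gbt")
}

#' Predict probabilities from a fitted booster
#'
#' @param object a [fit_gbt()] model.
#' @param newdata numeric matrix with the model's feature columns.
#' @param ... unused.
#' @return vector of probabilities in (0, 1).
#' @export
predict.gbt <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  margin <- rep(object$base, nrow(newdata))
  for (tree in object$trees) margin <- margin + object$learning_rate * predict_tree(tree, newdata)
  sigmoid(margin)
}
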