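# Shared recursive-partitioning machinery for the classification tree (CTA)
# and the boosted regression trees (GBM).
#
# Both split criteria reduce to the same objective: with per-row targets t
# and weights w, writing S = sum(w t) and W = sum(w) over a node,
#   * weighted Gini (t = y in {0,1}):  sum impurity = 2 [S_tot - sum_leaf S^2/W]
#   * weighted SSE  (t = residual):    sum SSE = sum w t^2 - sum_leaf S^2/W
# so every split maximizes S_L^2/W_L + S_R^2/W_R. Ties are broken toward the
# lowest variable index, then the lowest split value; split points are
# midpoints between consecutive distinct values; a node is split only if the
# objective strictly improves (which also stops pure nodes).

# Xm: numeric matrix; orders: list of full-data sort permutations per column.
best_split <- function(Xm, t, w, mask, orders, min_w) {
  best <- NULL
  best_gain <- -Inf
  for (v in seq_len(ncol(Xm))) {
    o <- orders[[v]]
    o <- o[mask[o]]
    if (length(o) < 2L) next
    x <- Xm[o, v]
    k <- which(diff(x) > 0)
    if (!length(k)) next
    cw <- cumsum(w[o]); cs <- cumsum(w[o] * t[o])
    W <- cw[length(cw)]; S <- cs[length(cs)]
    WL <- cw[k]; SL <- cs[k]; WR <- W - WL; SR <- S - SL
    gain <- SL^2 / WL + SR^2 / WR
    gain[WL < min_w | WR < min_w] <- -Inf
    j <- which.max(gain)
    if (gain[j] > best_gain) {
      best_gain <- gain[j]
      best <- list(var = v, split = (x[k[j]] + x[k[j] + 1L]) / 2,
                   gain = gain[j])
    }
  }
  best
}

# Grow one tree. leaf_value(mask) gives the prediction stored at a leaf;
# returns flat node table (lists of equal-length vectors).
grow_tree <- function(Xm, t, w, max_depth, min_w, leaf_value,
                      orders = lapply(seq_len(ncol(Xm)), function(j)
                        order(Xm[, j]))) {
  var <- integer(0L); split <- numeric(0L)
  left <- integer(0L); right <- integer(0L); pred <- numeric(0L)
  new_node <- function() {
    var[length(var) + 1L] <<- NA_integer_
    split[length(split) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- NA_integer_
    right[length(right) + 1L] <<- NA_integer_
    pred[length(pred) + 1L] <<- NA_real_
    length(var)
  }
  rec <- function(mask, depth) {
    id <- new_node()
    sp <- NULL
    if (depth < max_depth) {
      sp <- best_split(Xm, t, w, mask, orders, min_w)
      if (!is.null(sp)) {
        S <- sum(w[mask] * t[mask]); W <- sum(w[mask])
        if (sp$gain <= S^2 / W + 1e-12) sp <- NULL  # no strict improvement
      }
    }
    if (is.null(sp)) {
      pred[id] <<- leaf_value(mask)
    } else {
      var[id] <<- sp$var
      split[id] <<- sp$split
      go_left <- mask & (Xm[, sp$var] < sp$split)
      left[id] <<- rec(go_left, depth + 1L)
      right[id] <<- rec(mask & !go_left, depth + 1L)
    }
    id
  }
  rec(rep(TRUE, nrow(Xm)), 0L)
  list(var = var, split = split, left = left, right = right, pred = pred)
}

# Vectorized tree prediction: iteratively route rows down the node table.
predict_tree <- function(tree, Xm) {
  node <- rep(1L, nrow(Xm))
  repeat {
    act <- which(!is.na(tree$var[node]))
    if (!length(act)) break
    nd <- node[act]
    x <- Xm[cbind(act, tree$var[nd])]
    node[act] <- ifelse(x < tree$split[nd], tree$left[nd], tree$right[nd])
  }
  tree$pred[node]
}

design_matrix <- function(X, variables) {
  if (!all(variables %in% names(X)))
    stop("missing variables: ",
         paste(setdiff(variables, names(X)), collapse = ", "))
  m <- as.matrix(X[variables])
  storage.mode(m) <- "double"
  m
}

#' Fit a classification tree (CTA)
#'
#' Binary recursive partitioning choosing at each node the (variable, split
#' point) minimizing total weighted Gini impurity; leaves predict the
#' weighted presence fraction. Growth stops at `max_depth`, when a child
#' would fall below `min_node_weight`, or when no split strictly reduces
#' impurity (pure nodes).
#'
#' @param design an `sdm_design`.
#' @param max_depth maximum tree depth (default 5).
#' @param min_node_weight minimum total row weight per leaf (default 1; one
#'   presence row weighs 1).
#' @return an object of class `sdm_cta`.
#' @export
fit_cta <- function(design, max_depth = 5L, min_node_weight = 1) {
  if (max_depth < 0L) stop("`max_depth` must be >= 0")
  Xm <- design_matrix(design$X, design$variables)
  y <- as.numeric(design$y); w <- design$w
  tree <- grow_tree(Xm, y, w, max_depth, min_node_weight,
                    leaf_value = function(mask)
                      sum(w[mask] * y[mask]) / sum(w[mask]))
  structure(list(algorithm = "CTA", variables = design$variables,
                 tree = tree, max_depth = max_depth,
                 min_node_weight = min_node_weight),
            class = c("sdm_cta", "sdm_model"))
}

#' @export
predict.sdm_cta <- function(object, newdata, ...) {
  predict_tree(object$tree, design_matrix(newdata, object$variables))
}

#' Fit a gradient boosted model (GBM) on the logistic deviance
#'
#' Stagewise boosting of shallow regression trees on the negative gradient
#' of the weighted Bernoulli deviance (residual `y - p`), with Newton leaf
#' values `sum(w r) / sum(w p (1-p))` shrunk by `learning_rate`. The initial
#' score is the logit of the weighted prevalence; predictions are the
#' inverse-logit of the summed stage outputs.
#'
#' @param design an `sdm_design`.
#' @param n_trees number of boosting stages (>= 0, default 500).
#' @param learning_rate shrinkage in (0, 1] (default 0.1).
#' @param tree_depth depth of each stage tree (default 2).
#' @param min_node_weight minimum row weight per leaf (default 1).
#' @return an object of class `sdm_gbm`; field `train_deviance` records the
#'   weighted deviance after every stage.
#' @export
fit_gbm <- function(design, n_trees = 500L, learning_rate = 0.1,
                    tree_depth = 2L, min_node_weight = 1) {
  if (n_trees < 0L) stop("`n_trees` must be >= 0")
  if (learning_rate <= 0 || learning_rate > 1)
    stop("`learning_rate` must be in (0, 1]")
  Xm <- design_matrix(design$X, design$variables)
  y <- as.numeric(design$y); w <- design$w
  orders <- lapply(seq_len(ncol(Xm)), function(j) order(Xm[, j]))
  prev <- sum(w * y) / sum(w)
  f0 <- stats::qlogis(min(max(prev, 1e-12), 1 - 1e-12))
  eta <- rep(f0, length(y))
  trees <- vector("list", n_trees)
  dev <- numeric(n_trees)
  for (m in seq_len(n_trees)) {
    p <- stats::plogis(eta)
    r <- y - p
    h <- w * pmax(p * (1 - p), 1e-12)
    tree <- grow_tree(Xm, r, w, tree_depth, min_node_weight, leaf_value =
                        function(mask) 0, orders = orders)
    # Newton leaf values on the grown structure
    leaf <- tree_leaf_of(tree, Xm)
    for (id in which(!is.na(tree$pred))) {
      rows <- leaf == id
      val <- sum(w[rows] * r[rows]) / max(sum(h[rows]), 1e-12)
      tree$pred[id] <- max(min(val, 8), -8)
    }
    eta <- eta + learning_rate * tree$pred[leaf]
    trees[[m]] <- tree
    dev[m] <- bernoulli_deviance(y, stats::plogis(eta), w)
  }
  structure(list(algorithm = "GBM", variables = design$variables,
                 f0 = f0, learning_rate = learning_rate, trees = trees,
                 n_trees = n_trees, tree_depth = tree_depth,
                 train_deviance = dev),
            class = c("sdm_gbm", "sdm_model"))
}

tree_leaf_of <- function(tree, Xm) {
  node <- rep(1L, nrow(Xm))
  repeat {
    act <- which(!is.na(tree$var[node]))
    if (!length(act)) break
    nd <- node[act]
    x <- Xm[cbind(act, tree$var[nd])]
    node[act] <- ifelse(x < tree$split[nd], tree$left[nd], tree$right[nd])
  }
  node
}

bernoulli_deviance <- function(y, p, w) {
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  -2 * sum(w * (y * log(p) + (1 - y) * log(1 - p)))
}

#' @export
predict.sdm_gbm <- function(object, newdata, ...) {
  Xm <- design_matrix(newdata, object$variables)
  eta <- rep(object$f0, nrow(Xm))
  for (tree in object$trees)
    eta <- eta + object$learning_rate * predict_tree(tree, Xm)
  stats::plogis(eta)
}
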