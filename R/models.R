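# The three classifier families. Logistic regression is backed by glmnet
# (penalized GLM solver); k-nearest neighbours and the CART decision tree
# are implemented here because no suitable package is guaranteed in the
# runtime environment. All fits consume a numeric matrix and labels in
# {"binder", "non-binder"} and return objects with a common
# predict_scores() contract: P(binder) in [0, 1].

#' Model family grid definitions
#'
#' Default hyperparameter grids for the three supported families:
#' `logistic_regression` (penalty type l1/l2, regularization strength
#' lambda over 6 logarithmic steps), `k_nearest_neighbors` (odd k from 1 to
#' 25, uniform or inverse-distance vote weighting, Euclidean metric on the
#' selected columns or Tanimoto/Jaccard metric on the full fingerprint
#' block) and `decision_tree` (maximum depth, minimum leaf size, split
#' criterion).
#'
#' @param families character vector naming the families to include.
#' @return named list of `model_family` objects (name + grid of
#'   hyperparameter combinations as a data.frame).
#' @importFrom glmnet glmnet
#' @export
default_model_families <- function(families = c("logistic_regression",
                                                "k_nearest_neighbors",
                                                "decision_tree")) {
  all <- list(
    logistic_regression = expand.grid(
      penalty = c("l1", "l2"),
      lambda = 10^seq(-4, 1, length.out = 6),
      stringsAsFactors = FALSE),
    k_nearest_neighbors = expand.grid(
      k = seq(1L, 25L, by = 2L),
      weights = c("uniform", "distance"),
      metric = c("euclidean", "jaccard"),
      stringsAsFactors = FALSE),
    decision_tree = expand.grid(
      max_depth = c(2L, 4L, 6L, 8L),
      min_leaf = c(1L, 5L, 10L),
      criterion = "gini",
      stringsAsFactors = FALSE))
  bad <- setdiff(families, names(all))
  if (length(bad) > 0) stop("unknown model family: ", paste(bad, collapse = ", "))
  lapply(stats::setNames(families, families), function(f)
    structure(list(name = f, grid = all[[f]]), class = "model_family"))
}

as_binary <- function(labels) {
  bad <- setdiff(unique(labels), CLASS_LEVELS)
  if (length(bad) > 0) stop("unknown label(s): ", paste(bad, collapse = ", "))
  as.integer(labels == "binder")
}

score_to_label <- function(scores, threshold = 0.5) {
  ifelse(scores >= threshold, "binder", "non-binder")
}

# ---- logistic regression (glmnet) ----

fit_logistic <- function(x, y01, penalty = "l2", lambda = 0.01) {
  alpha <- if (penalty == "l1") 1 else 0
  # small-lambda convergence warnings on the path are harmless here
  fit <- suppressWarnings(
    glmnet::glmnet(x, y01, family = "binomial", alpha = alpha,
                   lambda = sort(unique(c(lambda, 10^seq(-4, 1, 0.5))),
                                 decreasing = TRUE),
                   standardize = FALSE))
  list(kind = "logistic_regression", fit = fit, lambda = lambda)
}

predict_logistic <- function(model, x) {
  as.numeric(stats::predict(model$fit, x, s = model$lambda,
                            type = "response"))
}

# ---- k-nearest neighbours ----
# metric "euclidean" works on the (selected, standardized) feature columns;
# "jaccard" is Tanimoto distance on the binary fingerprint block, the
# standard chemical-space neighbourhood

fit_knn <- function(x, y01, k = 5L, weights = "uniform",
                    metric = "euclidean") {
  list(kind = "k_nearest_neighbors", x = x, y01 = y01,
       k = min(as.integer(k), nrow(x)), weights = weights,
       metric = as.character(metric))
}

knn_distance_matrix <- function(xq, xt, metric) {
  if (metric == "jaccard") {
    inter <- tcrossprod(xq, xt)
    uni <- outer(rowSums(xq != 0), rowSums(xt != 0), "+") - inter
    d <- 1 - ifelse(uni == 0, 0, inter / uni)
  } else {
    d <- outer(rowSums(xq^2), rowSums(xt^2), "+") - 2 * tcrossprod(xq, xt)
    d[d < 0] <- 0
    d <- sqrt(d)
  }
  d
}

knn_vote <- function(d, y01, k, weights) {
  apply(d, 1, function(dr) {
    nn <- order(dr)[seq_len(k)]
    if (weights == "distance") {
      w <- 1 / pmax(dr[nn], 1e-12)
      sum(w * y01[nn]) / sum(w)
    } else {
      mean(y01[nn])
    }
  })
}

predict_knn <- function(model, x) {
  d <- knn_distance_matrix(x, model$x, model$metric)
  knn_vote(d, model$y01, model$k, model$weights)
}

# ---- CART decision tree (gini / entropy impurity, axis-aligned splits) ----

impurity <- function(p, criterion) {
  if (criterion == "entropy") {
    q <- c(p, 1 - p); q <- q[q > 0]
    -sum(q * log2(q))
  } else {
    2 * p * (1 - p)
  }
}

best_split <- function(x, y01, min_leaf, criterion) {
  n <- length(y01)
  best <- NULL
  parent <- impurity(mean(y01), criterion)
  for (j in seq_len(ncol(x))) {
    xv <- x[, j]
    o <- order(xv)
    xs <- xv[o]; ys <- y01[o]
    csum <- cumsum(ys)
    total <- csum[n]
    idx <- which(xs[-n] < xs[-1])  # candidate cut points between distinct values
    idx <- idx[idx >= min_leaf & (n - idx) >= min_leaf]
    if (length(idx) == 0) next
    nl <- idx; nr <- n - idx
    pl <- csum[idx] / nl; pr <- (total - csum[idx]) / nr
    gain <- parent - (nl / n) * vapply(pl, impurity, numeric(1), criterion) -
      (nr / n) * vapply(pr, impurity, numeric(1), criterion)
    bi <- which.max(gain)
    if (is.null(best) || gain[bi] > best$gain + 1e-12) {
      best <- list(feature = j, value = (xs[idx[bi]] + xs[idx[bi] + 1]) / 2,
                   gain = gain[bi])
    }
  }
  if (!is.null(best) && best$gain <= 1e-12) best <- NULL
  best
}

grow_tree <- function(x, y01, depth, max_depth, min_leaf, criterion) {
  p <- mean(y01)
  if (depth >= max_depth || length(y01) < 2 * min_leaf || p == 0 || p == 1)
    return(list(leaf = TRUE, p = p, n = length(y01)))
  sp <- best_split(x, y01, min_leaf, criterion)
  if (is.null(sp)) return(list(leaf = TRUE, p = p, n = length(y01)))
  left <- x[, sp$feature] <= sp$value
  list(leaf = FALSE, feature = sp$feature, value = sp$value,
       left = grow_tree(x[left, , drop = FALSE], y01[left], depth + 1,
                        max_depth, min_leaf, criterion),
       right = grow_tree(x[!left, , drop = FALSE], y01[!left], depth + 1,
                         max_depth, min_leaf, criterion))
}

fit_tree <- function(x, y01, max_depth = 4L, min_leaf = 5L, criterion = "gini") {
  list(kind = "decision_tree",
       tree = grow_tree(x, y01, 0L, as.integer(max_depth),
                        as.integer(min_leaf), criterion),
       p = ncol(x))
}

predict_tree_one <- function(node, xrow) {
  while (!node$leaf) {
    node <- if (xrow[node$feature] <= node$value) node$left else node$right
  }
  node$p
}

predict_tree <- function(model, x) {
  apply(x, 1, function(r) predict_tree_one(model$tree, r))
}

# ---- common fit / score dispatch ----

fit_family <- function(family_name, x, y01, hyper) {
  switch(family_name,
         logistic_regression = fit_logistic(x, y01, hyper$penalty, hyper$lambda),
         k_nearest_neighbors = fit_knn(x, y01, hyper$k, hyper$weights,
                                       if (is.null(hyper$metric))
                                         "euclidean" else hyper$metric),
         decision_tree = fit_tree(x, y01, hyper$max_depth, hyper$min_leaf,
                                  hyper$criterion),
         stop("unknown family: ", family_name))
}

predict_scores_raw <- function(model, x) {
  switch(model$kind,
         logistic_regression = predict_logistic(model, x),
         k_nearest_neighbors = predict_knn(model, x),
         decision_tree = predict_tree(model, x),
         stop("unknown model kind"))
}
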