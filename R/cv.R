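# Stratified k-fold cross-validation, grid search over the three model
# families scored by mean CV macro F1, and the trained-model object.
# Preprocessing (descriptor dropping + standardization) and feature
# selection are refit inside every training fold; validation rows never
# contribute to any fitted statistic.

#' Stratified fold assignment
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed RNG seed (private stream; the global RNG state is untouched).
#' @return integer vector of fold ids in `1..k`.
#' @export
make_stratified_folds <- function(labels, k = 5L, seed = 1L) {
  stopifnot(k >= 2)
  n <- length(labels)
  folds <- integer(n)
  rs <- local_rng(seed)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k && length(idx) < 2)
      stop("make_stratified_folds: class '", cl, "' has fewer than 2 members")
    perm <- idx[rs$sample_int(length(idx))]
    folds[perm] <- rep_len(seq_len(k), length(perm))
  }
  folds
}

fingerprint_block_columns <- function(fm) {
  if (!is.null(fm$provenance))
    fm$provenance$column[fm$provenance$block == "fingerprint"]
  else colnames(fm$raw$fingerprints)
}

# per-fold leak-free preprocessing from the raw feature blocks:
# descriptor columns with non-finite values in the fold-training rows are
# dropped, survivors z-scored on fold-training statistics; fingerprint bits
# pass through unscaled
fold_features <- function(fm, train_rows) {
  fps <- fm$raw$fingerprints
  desc <- fm$raw$descriptors
  tr <- desc[train_rows, , drop = FALSE]
  keep <- colnames(desc)[apply(tr, 2, function(v) all(is.finite(v)))]
  tr <- tr[, keep, drop = FALSE]
  mu <- colMeans(tr)
  sdv <- apply(tr, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  dz <- sweep(sweep(desc[, keep, drop = FALSE], 2, mu, "-"), 2, sdv, "/")
  dz[!is.finite(dz)] <- 0
  list(x = cbind(fps, dz), stats = list(keep = keep, mu = mu, sd = sdv))
}

new_cv_result <- function(fold_reports) {
  macro_f1 <- vapply(fold_reports, function(r) r$macro[["f1"]], numeric(1))
  weighted_f1 <- vapply(fold_reports, function(r) r$weighted[["f1"]], numeric(1))
  structure(list(
    per_fold = data.frame(fold = seq_along(fold_reports),
                          macro_f1 = macro_f1, weighted_f1 = weighted_f1),
    fold_reports = fold_reports,
    macro_f1_mean = mean(macro_f1), macro_f1_sd = stats::sd(macro_f1),
    weighted_f1_mean = mean(weighted_f1), weighted_f1_sd = stats::sd(weighted_f1)),
    class = "cv_result")
}

#' @noRd
#' @exportS3Method base::print
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds: macro F1 %.3f +/- %.3f, weighted F1 %.3f +/- %.3f\n",
              nrow(x$per_fold), x$macro_f1_mean, x$macro_f1_sd,
              x$weighted_f1_mean, x$weighted_f1_sd))
  invisible(x)
}

#' Cross-validate one model configuration
#'
#' Runs stratified `k_folds`-fold CV of a single family/hyperparameter
#' configuration on a [build_feature_matrix()] object. Standardization and
#' (optionally) feature selection are refit on each training fold.
#'
#' @param fm a `feature_matrix` over the full training set.
#' @param labels labels aligned with the rows of `fm`.
#' @param family family name (see [default_model_families()]).
#' @param hyper named list/row of hyperparameters for that family.
#' @param k_folds number of folds (default 5).
#' @param seed fold RNG seed.
#' @param select logical: refit the two-stage feature selection inside each
#'   fold (default `FALSE`: use all columns).
#' @return a `cv_result`.
#' @export
cross_validate <- function(fm, labels, family, hyper = NULL, k_folds = 5L,
                           seed = 1L, select = FALSE) {
  if (is.null(hyper))
    hyper <- as.list(default_model_families(family)[[family]]$grid[1, , drop = FALSE])
  folds <- make_stratified_folds(labels, k_folds, seed)
  y01 <- as_binary(labels)
  reports <- lapply(seq_len(k_folds), function(f) {
    tr <- folds != f
    if (length(unique(labels[tr])) < 2)
      stop("cross_validate: training fold ", f, " contains a single class")
    prep <- fold_features(fm, tr)
    cols <- colnames(prep$x)
    if (select) {
      sel <- select_features(prep$x[tr, , drop = FALSE], labels[tr],
                             seed = seed)
      cols <- sel$ids
    }
    if (family == "k_nearest_neighbors" &&
        identical(as.character(hyper$metric), "jaccard"))
      cols <- fingerprint_block_columns(fm)
    fit <- fit_family(family, prep$x[tr, cols, drop = FALSE], y01[tr],
                      as.list(hyper))
    pred <- score_to_label(
      predict_scores_raw(fit, prep$x[!tr, cols, drop = FALSE]))
    classification_report(labels[!tr], pred)
  })
  new_cv_result(reports)
}

# score every grid row of one family on one prepared fold; returns a matrix
# of P(binder) scores, one column per grid row (shared work: one distance
# matrix for all k-NN configs, one glmnet path per penalty for LR)
fold_grid_scores <- function(family, grid, xtr, y01tr, xval,
                             xtr_fp = NULL, xval_fp = NULL) {
  n <- nrow(xval)
  out <- matrix(NA_real_, n, nrow(grid))
  if (family == "logistic_regression") {
    for (pen in unique(grid$penalty)) {
      rows <- which(grid$penalty == pen)
      fit <- fit_logistic(xtr, y01tr, penalty = pen, lambda = 0.01)
      for (r in rows) {
        out[, r] <- as.numeric(stats::predict(fit$fit, xval,
                                              s = grid$lambda[r],
                                              type = "response"))
      }
    }
  } else if (family == "k_nearest_neighbors") {
    metrics <- if (is.null(grid$metric)) "euclidean" else unique(grid$metric)
    for (met in metrics) {
      rows <- if (is.null(grid$metric)) seq_len(nrow(grid)) else
        which(grid$metric == met)
      if (met == "jaccard" && !is.null(xtr_fp)) {
        d <- knn_distance_matrix(xval_fp, xtr_fp, "jaccard")
      } else {
        d <- knn_distance_matrix(xval, xtr, met)
      }
      for (r in rows) {
        out[, r] <- knn_vote(d, y01tr, min(grid$k[r], ncol(d)),
                             as.character(grid$weights[r]))
      }
    }
  } else if (family == "decision_tree") {
    for (r in seq_len(nrow(grid))) {
      fit <- fit_tree(xtr, y01tr, grid$max_depth[r], grid$min_leaf[r],
                      as.character(grid$criterion[r]))
      out[, r] <- predict_tree(fit, xval)
    }
  } else stop("unknown family: ", family)
  out
}

#' Tune, select and train the final classifier
#'
#' Grid search over the given model families scored by mean CV macro F1
#' with in-fold feature selection, followed by a refit of the winning
#' configuration on the full training set (with feature selection refit on
#' the full set). Tie-breaks: higher mean macro F1, then higher mean
#' weighted F1, then fewer selected features, then fixed family order
#' (logistic regression, k-NN, tree).
#'
#' @param fm `feature_matrix` over the training set.
#' @param labels training labels.
#' @param families list from [default_model_families()].
#' @param k_folds CV folds (default 5).
#' @param seed RNG seed controlling folds and selection.
#' @param select run the two-stage feature selection (default `TRUE`).
#' @param threshold decision threshold on P(binder), default 0.5.
#' @return object of class `trained_model` with fields `family`, `hyper`,
#'   `selected_feature_ids`, `transform`, `fit`, `threshold`, `cv` (the
#'   winning configuration's `cv_result`) and `cv_table` (per-family
#'   grid-search summary).
#' @export
tune_and_train <- function(fm, labels, families = default_model_families(),
                           k_folds = 5L, seed = 1L, select = TRUE,
                           threshold = 0.5) {
  stopifnot(length(families) > 0)
  if (length(unique(labels)) < 2) stop("tune_and_train: single-class labels")
  y01 <- as_binary(labels)
  folds <- make_stratified_folds(labels, k_folds, seed)

  # per-fold preparation shared across all families and grid rows
  prep <- lapply(seq_len(k_folds), function(f) {
    tr <- folds != f
    if (length(unique(labels[tr])) < 2)
      stop("tune_and_train: training fold ", f, " contains a single class")
    pf <- fold_features(fm, tr)
    cols <- colnames(pf$x)
    if (select) {
      cols <- select_features(pf$x[tr, , drop = FALSE], labels[tr],
                              seed = seed)$ids
    }
    fp_cols <- fingerprint_block_columns(fm)
    list(xtr = pf$x[tr, cols, drop = FALSE],
         xval = pf$x[!tr, cols, drop = FALSE],
         xtr_fp = pf$x[tr, fp_cols, drop = FALSE],
         xval_fp = pf$x[!tr, fp_cols, drop = FALSE],
         ytr = y01[tr], yval = labels[!tr])
  })

  cv_table <- list()
  best <- NULL
  for (fam_name in names(families)) {
    grid <- families[[fam_name]]$grid
    fold_reports <- vector("list", nrow(grid))
    for (g in seq_len(nrow(grid))) fold_reports[[g]] <- list()
    for (f in seq_len(k_folds)) {
      sc <- fold_grid_scores(fam_name, grid, prep[[f]]$xtr, prep[[f]]$ytr,
                             prep[[f]]$xval, prep[[f]]$xtr_fp,
                             prep[[f]]$xval_fp)
      for (g in seq_len(nrow(grid))) {
        rep_g <- classification_report(prep[[f]]$yval,
                                       score_to_label(sc[, g], threshold))
        fold_reports[[g]][[f]] <- rep_g
      }
    }
    res <- lapply(fold_reports, new_cv_result)
    tab <- cbind(grid,
                 macro_f1_mean = vapply(res, `[[`, numeric(1), "macro_f1_mean"),
                 macro_f1_sd = vapply(res, `[[`, numeric(1), "macro_f1_sd"),
                 weighted_f1_mean = vapply(res, `[[`, numeric(1), "weighted_f1_mean"))
    cv_table[[fam_name]] <- tab
    gi <- order(-tab$macro_f1_mean, -tab$weighted_f1_mean)[1]
    cand <- list(family = fam_name, hyper = as.list(grid[gi, , drop = FALSE]),
                 cv = res[[gi]],
                 macro = tab$macro_f1_mean[gi], weighted = tab$weighted_f1_mean[gi])
    if (is.null(best) ||
        cand$macro > best$macro + 1e-12 ||
        (abs(cand$macro - best$macro) <= 1e-12 &&
         cand$weighted > best$weighted + 1e-12)) {
      best <- cand
    }
  }

  # final refit on the full training set; Tanimoto-metric k-NN operates on
  # the full fingerprint block rather than the selected columns
  jaccard_knn <- best$family == "k_nearest_neighbors" &&
    identical(as.character(best$hyper$metric), "jaccard")
  final_cols <- colnames(fm$x)
  sel_log <- NULL
  if (select && !jaccard_knn) {
    sel <- select_features(fm$x, labels, seed = seed)
    final_cols <- sel$ids
    sel_log <- sel$size_scores
  }
  if (jaccard_knn) final_cols <- fingerprint_block_columns(fm)
  fit <- fit_family(best$family, fm$x[, final_cols, drop = FALSE], y01,
                    best$hyper)
  structure(list(family = best$family, hyper = best$hyper,
                 selected_feature_ids = final_cols,
                 transform = fm$transform, fit = fit,
                 threshold = threshold, cv = best$cv, cv_table = cv_table,
                 selection_log = sel_log, seed = as.integer(seed)),
            class = "trained_model")
}

#' @noRd
#' @exportS3Method base::print
print.trained_model <- function(x, ...) {
  hy <- paste(names(x$hyper), vapply(x$hyper, as.character, character(1)),
              sep = "=", collapse = ", ")
  cat(sprintf("<trained_model> %s (%s); %d features; CV macro F1 %.3f +/- %.3f\n",
              x$family, hy, length(x$selected_feature_ids),
              x$cv$macro_f1_mean, x$cv$macro_f1_sd))
  invisible(x)
}

#' Predict binder labels and scores
#'
#' @param object a `trained_model`.
#' @param newdata either a list of parsed `molecule` objects or a numeric
#'   matrix containing at least the model's selected feature columns.
#' @param ... unused.
#' @return data.frame with `id`, `score` (P(binder)) and `label`.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  if (is.matrix(newdata)) {
    x <- newdata
  } else {
    x <- apply_feature_transform(object$transform, newdata)
  }
  missing_cols <- setdiff(object$selected_feature_ids, colnames(x))
  if (length(missing_cols) > 0)
    stop("predict: missing feature column(s): ",
         paste(missing_cols, collapse = ", "))
  xs <- x[, object$selected_feature_ids, drop = FALSE]
  scores <- predict_scores_raw(object$fit, xs)
  data.frame(id = if (!is.null(rownames(x))) rownames(x) else
    sprintf("row%d", seq_len(nrow(x))),
    score = as.numeric(scores),
    label = score_to_label(scores, object$threshold),
    stringsAsFactors = FALSE)
}

#' Serialize / restore a trained model bundle
#'
#' JSON bundle holding family, hyperparameters, selected features,
#' standardization statistics and fitted parameters. Logistic models store
#' their coefficients; k-NN stores its training matrix; trees store the
#' nested split structure.
#'
#' @param model a `trained_model`.
#' @param path file path (`.json`).
#' @export
save_model_bundle <- function(model, path) {
  fitted <- switch(model$fit$kind,
    logistic_regression = {
      cf <- as.matrix(stats::coef(model$fit$fit, s = model$fit$lambda))
      list(coef = stats::setNames(as.numeric(cf), rownames(cf)),
           lambda = model$fit$lambda)
    },
    k_nearest_neighbors = list(x = model$fit$x, y01 = model$fit$y01,
                               k = model$fit$k, weights = model$fit$weights),
    decision_tree = list(tree = model$fit$tree))
  bundle <- list(format_version = 1L,
                 family = model$family, hyper = model$hyper,
                 selected_feature_ids = model$selected_feature_ids,
                 threshold = model$threshold, seed = model$seed,
                 transform = list(radius = model$transform$cfg$radius,
                                  n_bits = model$transform$cfg$n_bits,
                                  descriptor_keep = model$transform$descriptor_keep,
                                  mu = as.list(model$transform$mu),
                                  sd = as.list(model$transform$sd)),
                 fitted = fitted)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
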