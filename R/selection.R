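# Feature selection: near-zero-variance filtering followed by an
# L1-regularization-path ranking, with the retained-set size chosen by
# cross-validated macro F1. The procedure is a pure function of its inputs,
# so it can be refit inside every CV training fold without leakage.

#' Near-zero-variance column filter
#'
#' Flags columns that are constant or whose modal value accounts for more
#' than `freq_cut` of the rows; such columns carry (almost) no
#' discriminative signal and destabilize distance- and path-based fits.
#'
#' @param x numeric matrix.
#' @param freq_cut maximal tolerated modal-value frequency (default 0.995).
#' @return logical vector, `TRUE` for columns to keep.
#' @export
nzv_keep <- function(x, freq_cut = 0.995) {
  apply(x, 2, function(v) {
    tab <- tabulate(match(v, unique(v)))
    length(tab) > 1 && max(tab) / length(v) <= freq_cut
  })
}

#' Rank features along the lasso regularization path
#'
#' Features are ranked by the order in which they first enter the L1 path of
#' a penalized logistic fit (earlier entry = stronger marginal signal given
#' the already-entered set); features that never enter are dropped.
#'
#' @param x numeric matrix (already near-zero-variance filtered).
#' @param y01 0/1 integer labels.
#' @return character vector of column names, strongest first.
#' @keywords internal
l1_path_ranking <- function(x, y01) {
  fit <- suppressWarnings(
    glmnet::glmnet(x, y01, family = "binomial", alpha = 1,
                   nlambda = 60, standardize = FALSE))
  beta <- fit$beta   # p x nlambda sparse matrix
  entry <- apply(as.matrix(beta) != 0, 1, function(r)
    if (any(r)) which(r)[1] else NA_integer_)
  ord <- order(entry, seq_along(entry), na.last = NA)
  colnames(x)[ord]
}

#' Select features by CV macro F1 over retained-set sizes
#'
#' Two-stage procedure: (1) drop near-zero-variance columns, (2) rank the
#' rest along the lasso path and choose the retained-set size from `sizes`
#' by `k_folds`-fold cross-validated macro F1 of a ridge-logistic probe
#' classifier. Ties prefer the smaller size.
#'
#' @param x numeric feature matrix (training rows only).
#' @param labels labels over `{"binder", "non-binder"}`.
#' @param seed RNG seed for the internal folds.
#' @param sizes candidate retained-set sizes.
#' @param k_folds internal CV folds.
#' @return list with `ids` (ordered selected column names), `size_scores`
#'   (data.frame size/mean macro F1), `n_ranked`, `n_nzv_dropped`.
#' @export
select_features <- function(x, labels, seed = 1L,
                            sizes = c(16L, 32L, 64L, 128L), k_folds = 3L) {
  if (ncol(x) < 2) stop("select_features: need at least 2 features")
  y01 <- as_binary(labels)
  keep <- nzv_keep(x)
  if (!any(keep)) {
    warning("select_features: all features are near-constant; empty selection",
            call. = FALSE)
    return(list(ids = character(0),
                size_scores = data.frame(size = integer(0), macro_f1 = numeric(0)),
                n_ranked = 0L, n_nzv_dropped = ncol(x)))
  }
  xk <- x[, keep, drop = FALSE]
  dup <- duplicated(asplit(xk, 2))  # bit-identical columns carry no new signal
  xk <- xk[, !dup, drop = FALSE]
  ranked <- l1_path_ranking(xk, y01)
  if (length(ranked) == 0) ranked <- colnames(xk)
  sizes <- sort(unique(pmin(as.integer(sizes), length(ranked))))

  if (length(sizes) == 1L) {
    score <- data.frame(size = sizes, macro_f1 = NA_real_)
    return(list(ids = ranked[seq_len(sizes)], size_scores = score,
                n_ranked = length(ranked), n_nzv_dropped = sum(!keep)))
  }

  folds <- make_stratified_folds(labels, k_folds, seed)
  scores <- vapply(sizes, function(m) {
    cols <- ranked[seq_len(m)]
    f1s <- vapply(seq_len(k_folds), function(f) {
      tr <- folds != f; va <- !tr
      fit <- fit_logistic(xk[tr, cols, drop = FALSE], y01[tr],
                          penalty = "l2", lambda = 0.01)
      pred <- score_to_label(predict_logistic(fit, xk[va, cols, drop = FALSE]))
      classification_report(labels[va], pred)$macro[["f1"]]
    }, numeric(1))
    mean(f1s)
  }, numeric(1))
  best <- sizes[which.max(scores)]
  list(ids = ranked[seq_len(best)],
       size_scores = data.frame(size = sizes, macro_f1 = scores),
       n_ranked = length(ranked), n_nzv_dropped = sum(!keep))
}
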