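# Maximum-Tanimoto similarity baseline: a molecule is called a binder when
# its maximum Tanimoto similarity to any training-set binder strictly
# exceeds tau.

#' Baseline classifier configuration
#'
#' @param tau similarity threshold in `[0, 1]`; default 0.5, reflecting
#'   meaningful structural similarity (higher values capture only
#'   near-identical compounds).
#' @param fingerprint a [fingerprint_config()] (default radius 3, 1024 bits).
#' @return a `baseline_config` list.
#' @export
baseline_config <- function(tau = 0.5, fingerprint = fingerprint_config()) {
  stopifnot(tau >= 0, tau <= 1)
  structure(list(tau = tau, fingerprint = fingerprint),
            class = "baseline_config")
}

#' Similarity-baseline prediction for queries
#'
#' Each query is labeled binder iff its maximum Tanimoto similarity over
#' the training-binder fingerprints strictly exceeds `cfg$tau`. An empty
#' training-binder set yields non-binder with similarity 0 (and a warning):
#' a vacuous maximum is treated as no evidence of binding.
#'
#' @param query_fps list of query fingerprints (or a single fingerprint).
#' @param binder_fps list of training-binder fingerprints.
#' @param cfg a [baseline_config()].
#' @return data.frame with `max_similarity` and `label` per query.
#' @export
baseline_predict <- function(query_fps, binder_fps, cfg = baseline_config()) {
  if (inherits(query_fps, "fingerprint")) query_fps <- list(query_fps)
  if (length(binder_fps) == 0) {
    warning("baseline_predict: empty training-binder set; predicting non-binder",
            call. = FALSE)
    return(data.frame(max_similarity = rep(0, length(query_fps)),
                      label = rep("non-binder", length(query_fps)),
                      stringsAsFactors = FALSE))
  }
  sims <- vapply(query_fps, function(q) max(tanimoto_many(q, binder_fps)),
                 numeric(1))
  data.frame(max_similarity = sims,
             label = ifelse(sims > cfg$tau, "binder", "non-binder"),
             stringsAsFactors = FALSE)
}

#' Evaluate the similarity baseline on a labeled test set
#'
#' Fingerprints all molecules with `cfg$fingerprint`, takes the training
#' binders as the reference set, predicts every test record and reports via
#' [classification_report()].
#'
#' @param train_mols,test_mols lists of parsed `molecule` objects.
#' @param train_labels,test_labels labels aligned with the molecule lists.
#' @param cfg a [baseline_config()].
#' @return list with `report` (a `class_report`) and `predictions`
#'   (per-test-record data.frame incl. `max_similarity`).
#' @export
baseline_evaluate <- function(train_mols, train_labels, test_mols,
                              test_labels, cfg = baseline_config()) {
  stopifnot(length(train_mols) == length(train_labels),
            length(test_mols) == length(test_labels))
  binder_fps <- lapply(train_mols[train_labels == "binder"],
                       morgan_fingerprint, cfg = cfg$fingerprint)
  query_fps <- lapply(test_mols, morgan_fingerprint, cfg = cfg$fingerprint)
  pred <- baseline_predict(query_fps, binder_fps, cfg)
  pred$id <- vapply(test_mols, function(m) m$id, character(1))
  list(report = classification_report(test_labels, pred$label),
       predictions = pred[, c("id", "max_similarity", "label")])
}
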