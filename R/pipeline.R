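# End-to-end study orchestration: label -> split -> featurize -> select ->
# tune/train -> test report -> baseline report -> curate -> predict ->
# prospective report, with every artifact and seed written to a run
# manifest. Also the prospective evaluation (measured Ki vs predictions).

#' Run configuration for the end-to-end study
#'
#' @param output_dir directory for artifacts (created if needed).
#' @param synthetic a [synthetic_config()] used to generate the study
#'   dataset and screening library, or `NULL` when `dataset_path` is given.
#' @param dataset_path optional path to a labeled compound table (read via
#'   [read_compound_table()]) replacing the synthetic study dataset.
#' @param library_path optional SMILES library file for curation; when
#'   `NULL` and `synthetic` is set, a synthetic screening library of
#'   `library_size` compounds is generated.
#' @param library_size size of the generated screening library (default 3000).
#' @param labeling a [labeling_config()].
#' @param fingerprint a [fingerprint_config()].
#' @param test_fraction,split_seed stratified-split parameters.
#' @param families model families (see [default_model_families()]).
#' @param k_folds CV folds.
#' @param model_seed seed for folds/selection.
#' @param baseline a [baseline_config()].
#' @param curation a [curation_config()].
#' @param reference_smiles named character vector of the three reference
#'   chemotype SMILES; default: the synthetic parent scaffolds.
#' @return a `run_config` list.
#' @export
run_config <- function(output_dir,
                       synthetic = synthetic_config(),
                       dataset_path = NULL,
                       library_path = NULL,
                       library_size = 3000L,
                       labeling = labeling_config(),
                       fingerprint = fingerprint_config(),
                       test_fraction = 0.14,
                       split_seed = 1L,
                       families = default_model_families(),
                       k_folds = 5L,
                       model_seed = 1L,
                       baseline = baseline_config(),
                       curation = curation_config(),
                       reference_smiles = NULL) {
  if (is.null(synthetic) && is.null(dataset_path))
    stop("run_config: need either a synthetic config or a dataset path")
  for (p in c(dataset_path, library_path)) {
    if (!is.null(p) && !file.exists(p)) stop("run_config: missing input: ", p)
  }
  if (is.null(reference_smiles)) reference_smiles <- default_reference_smiles()
  structure(list(output_dir = output_dir, synthetic = synthetic,
                 dataset_path = dataset_path, library_path = library_path,
                 library_size = as.integer(library_size),
                 labeling = labeling, fingerprint = fingerprint,
                 test_fraction = test_fraction,
                 split_seed = as.integer(split_seed), families = families,
                 k_folds = as.integer(k_folds),
                 model_seed = as.integer(model_seed), baseline = baseline,
                 curation = curation, reference_smiles = reference_smiles),
            class = "run_config")
}

write_report_files <- function(report, stem) {
  writeLines(format_class_report(report), paste0(stem, ".txt"))
  jsonlite::write_json(class_report_as_list(report), paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Execute the full study pipeline
#'
#' Runs every stage on the configured inputs and writes all artifacts
#' (dataset, split manifest, CV tables, classification reports in the
#' standard table layout plus JSON, similarity profiles, prospective
#' selection, predictions, model bundle, and a JSON run manifest) under
#' `cfg$output_dir`. Deterministic: rerunning with the same config
#' reproduces every artifact bit-for-bit.
#'
#' @param cfg a [run_config()].
#' @param verbose print stage progress.
#' @return invisibly, a list with the in-memory results (dataset, split,
#'   model, reports, curation, prospective evaluation, manifest path).
#' @export
run_study <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[synbinder] ", ...)
  stage <- function(name, expr) {
    say(name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  ds <- stage("dataset", {
    if (!is.null(cfg$dataset_path)) {
      read_compound_table(cfg$dataset_path, cfg = cfg$labeling)
    } else {
      make_study_dataset(cfg$synthetic)
    }
  })
  mols <- attr(ds, "molecules")
  write_compound_table(ds, file.path(cfg$output_dir, "dataset.tsv"))

  split <- stage("split", stratified_split(ds$id, ds$label,
                                           cfg$test_fraction, cfg$split_seed))
  write_split_manifest(split, file.path(cfg$output_dir, "split.tsv"))
  tr_idx <- ds$id %in% split$train_ids
  te_idx <- ds$id %in% split$test_ids

  fm <- stage("featurize", build_feature_matrix(mols[tr_idx], cfg$fingerprint))
  write_feature_matrix(fm, file.path(cfg$output_dir, "train_features.tsv"))

  model <- stage("tune_and_train",
                 tune_and_train(fm, ds$label[tr_idx], cfg$families,
                                cfg$k_folds, cfg$model_seed))
  save_model_bundle(model, file.path(cfg$output_dir, "model.json"))
  cv_lines <- unlist(lapply(names(model$cv_table), function(f)
    c(paste0("## ", f),
      utils::capture.output(print(model$cv_table[[f]], row.names = FALSE)))))
  writeLines(cv_lines, file.path(cfg$output_dir, "cv_table.txt"))

  test_pred <- stage("test_report", stats::predict(model, mols[te_idx]))
  test_report <- classification_report(ds$label[te_idx], test_pred$label)
  write_report_files(test_report, file.path(cfg$output_dir, "test_report"))

  base_eval <- stage("baseline",
                     baseline_evaluate(mols[tr_idx], ds$label[tr_idx],
                                       mols[te_idx], ds$label[te_idx],
                                       cfg$baseline))
  write_report_files(base_eval$report,
                     file.path(cfg$output_dir, "baseline_report"))

  refs <- stage("references",
                reference_set(unname(cfg$reference_smiles),
                              names(cfg$reference_smiles), cfg$fingerprint))
  lib <- stage("library", {
    if (!is.null(cfg$library_path)) {
      read_smiles_file(cfg$library_path)
    } else {
      lib_cfg <- cfg$synthetic
      lib_cfg$n_compounds <- cfg$library_size
      lib_cfg$alt_fraction <- max(lib_cfg$alt_fraction, 0.3)
      lib_cfg$seed <- lib_cfg$seed + 65537L
      generate_library(lib_cfg)
    }
  })
  lib_mols <- attr(lib, "molecules")
  profiles <- stage("curate", assign_chemotype(lib_mols, refs,
                                               cfg$curation$alt_cutoff))
  utils::write.table(profiles, file.path(cfg$output_dir, "similarity_profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hist_data <- similarity_histogram(profiles)
  utils::write.table(
    data.frame(bin = rownames(hist_data$counts), hist_data$counts,
               check.names = FALSE),
    file.path(cfg$output_dir, "similarity_histogram.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  prospective <- stage("select_prospective",
                       select_prospective(profiles, cfg$curation))
  utils::write.table(as.data.frame(prospective),
                     file.path(cfg$output_dir, "prospective_selection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  pro_mols <- lib_mols[match(prospective$id, lib$id)]
  pro_pred <- stage("predict_prospective", stats::predict(model, pro_mols))
  utils::write.table(pro_pred, file.path(cfg$output_dir, "prospective_predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # prospective ground truth exists only for synthetic libraries
  pro_eval <- NULL
  if (is.null(cfg$library_path) && !is.null(cfg$synthetic)) {
    lib_cfg <- cfg$synthetic
    lib_cfg$seed <- lib_cfg$seed + 65537L
    measured <- stage("prospective_truth", {
      m <- assign_ground_truth_ki(pro_mols, lib_cfg,
                                  intercept = if (!is.null(attr(ds, "intercept")))
                                    attr(ds, "intercept") else
                                    lib_cfg$intercept_log10Ki)
      m
    })
    pro_eval <- stage("prospective_eval",
                      evaluate_prospective(pro_pred, measured, cfg$labeling))
    write_report_files(pro_eval$report,
                       file.path(cfg$output_dir, "prospective_report"))
    utils::write.table(pro_eval$hits, file.path(cfg$output_dir, "prospective_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("synbinder")),
    seeds = list(synthetic = if (!is.null(cfg$synthetic)) cfg$synthetic$seed,
                 split = cfg$split_seed, model = cfg$model_seed,
                 curation = cfg$curation$seed),
    config = list(test_fraction = cfg$test_fraction,
                  k_folds = cfg$k_folds,
                  binder_threshold_nM = cfg$labeling$binder_threshold_nM,
                  censor_limit_nM = cfg$labeling$censor_limit_nM,
                  tau = cfg$baseline$tau,
                  fingerprint = unclass(cfg$fingerprint),
                  curation = unclass(cfg$curation),
                  library_size = cfg$library_size,
                  synthetic = if (!is.null(cfg$synthetic))
                    unclass(cfg$synthetic)[setdiff(names(cfg$synthetic), "fingerprint")]),
    model = list(family = model$family, hyper = model$hyper,
                 n_features = length(model$selected_feature_ids),
                 cv_macro_f1 = model$cv$macro_f1_mean),
    metrics = list(test_macro_f1 = test_report$macro[["f1"]],
                   test_weighted_f1 = test_report$weighted[["f1"]],
                   baseline_macro_f1 = base_eval$report$macro[["f1"]],
                   prospective_macro_f1 = if (!is.null(pro_eval))
                     pro_eval$report$macro[["f1"]]))
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(dataset = ds, split = split, model = model,
                 test_report = test_report, baseline = base_eval,
                 profiles = profiles, prospective = prospective,
                 prospective_predictions = pro_pred,
                 prospective_eval = pro_eval,
                 manifest_path = file.path(cfg$output_dir, "manifest.json")))
}

#' Evaluate prospective predictions against measured Ki
#'
#' Labels the measured table with [label_from_ki()], matches it to the
#' predictions by id, and reports the classification metrics plus the hit
#' lists: confirmed binders (true positives), false positives with their
#' measured Ki, and the sub-10 nM hits.
#'
#' @param predictions data.frame with `id` and `label` (from
#'   [predict.trained_model()]).
#' @param measured data.frame with `id`, `ki_nM`, `no_binding`.
#' @param cfg a [labeling_config()].
#' @param potent_cutoff_nM cutoff for the "potent hit" sub-list (default 10).
#' @return list with `report` (a `class_report`), `hits` (per-compound
#'   table), `n_predicted_binders`, `n_confirmed`, `n_potent`.
#' @export
evaluate_prospective <- function(predictions, measured,
                                 cfg = labeling_config(),
                                 potent_cutoff_nM = 10) {
  miss <- setdiff(predictions$id, measured$id)
  if (length(miss) > 0)
    stop("evaluate_prospective: no measurement for id(s): ",
         paste(miss, collapse = ", "))
  m <- measured[match(predictions$id, measured$id), ]
  truth <- label_from_ki(m$ki_nM, m$no_binding, cfg)
  report <- classification_report(truth, predictions$label)
  hits <- data.frame(id = predictions$id,
                     predicted = predictions$label,
                     ki_nM = m$ki_nM, no_binding = m$no_binding,
                     measured_label = truth,
                     stringsAsFactors = FALSE)
  hits$outcome <- with(hits, ifelse(
    predicted == "binder" & measured_label == "binder", "true_positive",
    ifelse(predicted == "binder", "false_positive",
           ifelse(measured_label == "binder", "false_negative",
                  "true_negative"))))
  hits$potent <- !hits$no_binding & !is.na(hits$ki_nM) &
    hits$ki_nM < potent_cutoff_nM
  list(report = report, hits = hits,
       n_predicted_binders = sum(hits$predicted == "binder"),
       n_confirmed = sum(hits$outcome == "true_positive"),
       n_potent = sum(hits$potent & hits$predicted == "binder"))
}
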