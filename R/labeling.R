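# Ki-threshold binder labeling with censoring, compound-table IO, and
# stratified train/test splitting with largest-remainder allocation.

#' Labeling configuration
#'
#' @param binder_threshold_nM Ki cutoff (nM) defining the binder class;
#'   default 25. Strictly-below-threshold measurements are binders.
#' @param censor_limit_nM assay censoring limit (nM); default 1000 (1 uM).
#'   "No binding" records mean no displacement curve could be fit below
#'   this limit and are non-binders.
#' @return a `labeling_config` list.
#' @export
labeling_config <- function(binder_threshold_nM = 25, censor_limit_nM = 1000) {
  stopifnot(binder_threshold_nM > 0, censor_limit_nM > 0,
            binder_threshold_nM < censor_limit_nM)
  structure(list(binder_threshold_nM = binder_threshold_nM,
                 censor_limit_nM = censor_limit_nM),
            class = "labeling_config")
}

#' Label a binding measurement as binder / non-binder
#'
#' Binder iff the fitted Ki is strictly below the threshold. Censored
#' ("no binding") measurements and measurements exactly at the threshold
#' are non-binders.
#'
#' @param ki_nM fitted Ki in nM (vectorized; `NA` allowed where censored).
#' @param censored logical, `TRUE` where no curve could be fit below the
#'   censor limit.
#' @param cfg a [labeling_config()].
#' @return character vector of `"binder"` / `"non-binder"`.
#' @export
label_from_ki <- function(ki_nM, censored = FALSE, cfg = labeling_config()) {
  n <- max(length(ki_nM), length(censored))
  ki_nM <- rep_len(ki_nM, n); censored <- rep_len(censored, n)
  bad <- is.na(ki_nM) & !censored
  if (any(bad))
    stop("label_from_ki: record(s) ", paste(which(bad), collapse = ", "),
         " have neither a Ki value nor a censoring flag")
  conflict <- !is.na(ki_nM) & censored & ki_nM <= cfg$censor_limit_nM
  if (any(conflict))
    stop("label_from_ki: censored record(s) with Ki at or below the censor limit")
  ifelse(!censored & ki_nM < cfg$binder_threshold_nM, "binder", "non-binder")
}

#' Read a compound table
#'
#' Delimited text with a header; expected columns `id`, `smiles`, and any of
#' `ki_nM`, `no_binding`, `chemotype`. Lines whose SMILES fail to parse are
#' dropped with a warning reporting the count.
#'
#' @param path file path.
#' @param sep field separator (default tab; `","` for CSV).
#' @param cfg a [labeling_config()] used when `ki_nM`/`no_binding` present.
#' @return data.frame with canonical SMILES, parse bookkeeping and (when
#'   measurements are present) a `label` column; parsed molecules in
#'   attribute `molecules`.
#' @export
read_compound_table <- function(path, sep = "\t", cfg = labeling_config()) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  stopifnot(all(c("id", "smiles") %in% names(df)))
  mols <- canonicalize_all(df$smiles, as.character(df$id))
  ok <- vapply(mols, function(m) isTRUE(m$parse_ok), logical(1))
  if (any(!ok))
    warning(sum(!ok), " compound(s) dropped: unparsable SMILES (",
            paste(df$id[!ok], collapse = ", "), ")", call. = FALSE)
  df <- df[ok, , drop = FALSE]
  mols <- mols[ok]
  df$smiles_canonical <- vapply(mols, function(m) m$smiles_canonical, character(1))
  if ("ki_nM" %in% names(df)) {
    cens <- if ("no_binding" %in% names(df)) as.logical(df$no_binding) else
      rep(FALSE, nrow(df))
    cens[is.na(cens)] <- FALSE
    df$no_binding <- cens
    df$label <- label_from_ki(df$ki_nM, cens, cfg)
  }
  attr(df, "molecules") <- mols
  df
}

#' Write a compound table
#'
#' @param df compound data.frame (as produced by the synthetic generator or
#'   [read_compound_table()]).
#' @param path output path.
#' @param sep field separator.
#' @export
write_compound_table <- function(df, path, sep = "\t") {
  keep <- intersect(c("id", "smiles", "ki_nM", "no_binding", "chemotype",
                      "label", "smiles_canonical"), names(df))
  utils::write.table(df[, keep, drop = FALSE], path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# largest-remainder allocation of `total` across strata with weights w
largest_remainder <- function(w, total) {
  quota <- w / sum(w) * total
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Stratified train/test split
#'
#' Allocates per-class test counts by largest-remainder rounding of the
#' proportional quota, then samples within each class under the given seed.
#'
#' @param ids compound identifiers.
#' @param labels class labels aligned with `ids` (stratification variable).
#' @param test_fraction fraction of records held out; default 0.14
#'   (a 44-of-315 style hold-out).
#' @param seed integer RNG seed; the split is a pure function of
#'   (`ids`, `labels`, `test_fraction`, `seed`).
#' @return object of class `dataset_split`: list with `train_ids`,
#'   `test_ids`, `seed`, `test_fraction`.
#' @export
stratified_split <- function(ids, labels, test_fraction = 0.14, seed = 1L) {
  stopifnot(length(ids) == length(labels), !anyDuplicated(ids),
            test_fraction > 0, test_fraction < 1)
  tab <- table(labels)
  small <- names(tab)[tab < 2]
  if (length(small) > 0)
    stop("stratified_split: class(es) with fewer than 2 members: ",
         paste(small, collapse = ", "))
  total_test <- round(length(ids) * test_fraction)
  classes <- names(tab)
  alloc <- largest_remainder(as.numeric(tab[classes]), total_test)
  names(alloc) <- classes
  test_ids <- character(0)
  rs <- local_rng(seed)
  for (cl in classes) {
    members <- ids[labels == cl]
    pick <- rs$sample(members, alloc[[cl]])
    test_ids <- c(test_ids, pick)
  }
  train_ids <- setdiff(ids, test_ids)
  structure(list(train_ids = train_ids, test_ids = sort(test_ids),
                 seed = as.integer(seed), test_fraction = test_fraction),
            class = "dataset_split")
}

# a private RNG stream that never touches the global .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    s
  })
  run <- function(expr_fun) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, globalenv())
    })
    expr_fun()
  }
  list(
    sample = function(x, size = length(x), replace = FALSE, prob = NULL)
      run(function() if (length(x) == 1 && is.numeric(x)) x else
        sample(x, size, replace, prob)),
    sample_int = function(n, size = n, replace = FALSE)
      run(function() sample.int(n, size, replace)),
    norm = function(n, mean = 0, sd = 1) run(function() stats::rnorm(n, mean, sd)),
    unif = function(n) run(function() stats::runif(n))
  )
}

#' Write / read a split manifest
#'
#' Plain-text manifest: metadata header lines (`# seed`, `# test_fraction`)
#' and one `id<TAB>partition` row per record.
#'
#' @param split a `dataset_split`.
#' @param path file path.
#' @return (read) a `dataset_split`.
#' @export
write_split_manifest <- function(split, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# seed\t%d", split$seed), con)
  writeLines(sprintf("# test_fraction\t%.10g", split$test_fraction), con)
  writeLines(c(paste(split$train_ids, "train", sep = "\t"),
               paste(split$test_ids, "test", sep = "\t")), con)
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  seed <- as.integer(sub("^# seed\t", "", meta[startsWith(meta, "# seed")]))
  frac <- as.numeric(sub("^# test_fraction\t", "",
                         meta[startsWith(meta, "# test_fraction")]))
  parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  structure(list(train_ids = parts[parts[, 2] == "train", 1],
                 test_ids = parts[parts[, 2] == "test", 1],
                 seed = seed, test_fraction = frac),
            class = "dataset_split")
}
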