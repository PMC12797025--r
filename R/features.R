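# Combined featurization: binary fingerprint block + descriptor block, with
# a training-set-fitted transform (descriptor column dropping and z-score
# standardization) that can be applied unchanged to new data. Keeping the
# transform as a first-class object is what makes leak-free cross-validation
# possible downstream.

#' Build a combined fingerprint + descriptor feature matrix
#'
#' Column block 1 holds the fingerprint bits (binary, unscaled), block 2 the
#' surviving descriptors. Descriptor columns with any missing or non-finite
#' value across the fitting rows are dropped (and logged); surviving
#' descriptor columns are z-scored with statistics from the fitting rows.
#' Constant descriptor columns survive with standard deviation treated as 1
#' so they become all-zero rather than NaN (and are then removable by the
#' near-zero-variance filter at modelling time).
#'
#' @param mols list of parsed `molecule` objects (all `parse_ok`).
#' @param cfg a [fingerprint_config()].
#' @return object of class `feature_matrix`: list with `x` (numeric matrix),
#'   `provenance` (data.frame: column, block = "fingerprint"/"descriptor",
#'   source), `transform` (fitted standardization state) and `dropped`
#'   (descriptor drop log).
#' @export
build_feature_matrix <- function(mols, cfg = fingerprint_config()) {
  if (length(mols) == 0) stop("build_feature_matrix: empty compound list")
  bad <- !vapply(mols, function(m) isTRUE(m$parse_ok), logical(1))
  if (any(bad)) stop("build_feature_matrix: ", sum(bad), " unparsed molecule(s)")

  fps <- fingerprint_matrix(mols, cfg)
  desc_full <- descriptor_matrix(mols)
  desc <- desc_full

  drop <- colnames(desc)[apply(desc, 2, function(v) any(!is.finite(v)))]
  keep <- setdiff(colnames(desc), drop)
  desc <- desc[, keep, drop = FALSE]

  mu <- colMeans(desc)
  sdv <- apply(desc, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  desc_z <- sweep(sweep(desc, 2, mu, "-"), 2, sdv, "/")

  x <- cbind(fps, desc_z)
  prov <- data.frame(
    column = colnames(x),
    block = c(rep("fingerprint", ncol(fps)), rep("descriptor", ncol(desc_z))),
    source = c(sprintf("bit_%d", seq_len(ncol(fps)) - 1L), colnames(desc_z)),
    stringsAsFactors = FALSE)
  structure(list(
    x = x,
    provenance = prov,
    transform = list(cfg = cfg, descriptor_keep = keep, mu = mu, sd = sdv),
    dropped = drop,
    raw = list(fingerprints = fps, descriptors = desc_full)),
    class = "feature_matrix")
}

#' Apply a fitted feature transform to new molecules
#'
#' Featurizes `mols` with the fingerprint configuration, descriptor column
#' set and standardization statistics fitted on a training set by
#' [build_feature_matrix()] — no statistics are recomputed.
#'
#' @param transform the `transform` element of a `feature_matrix`.
#' @param mols list of parsed `molecule` objects.
#' @return numeric matrix with the same columns as the fitting matrix.
#' @export
apply_feature_transform <- function(transform, mols) {
  fps <- fingerprint_matrix(mols, transform$cfg)
  desc <- descriptor_matrix(mols)[, transform$descriptor_keep, drop = FALSE]
  desc_z <- sweep(sweep(desc, 2, transform$mu, "-"), 2, transform$sd, "/")
  desc_z[!is.finite(desc_z)] <- 0  # new-data NAs map to the training mean
  cbind(fps, desc_z)
}

#' @noRd
#' @exportS3Method base::print
print.feature_matrix <- function(x, ...) {
  nb <- table(x$provenance$block)
  cat(sprintf("<feature_matrix> %d x %d (%d fingerprint bits, %d descriptors; %d dropped)\n",
              nrow(x$x), ncol(x$x), nb[["fingerprint"]],
              if ("descriptor" %in% names(nb)) nb[["descriptor"]] else 0L,
              length(x$dropped)))
  invisible(x)
}

#' Write a feature matrix and its provenance sidecar
#'
#' @param fm a `feature_matrix`.
#' @param path output path for the tab-delimited matrix; the provenance
#'   sidecar is written next to it as `<path>.columns.tsv`.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(id = rownames(fm$x), fm$x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fm$provenance, paste0(path, ".columns.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
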