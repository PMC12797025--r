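# Plain-text interchange: SMILES line files (SMILES [whitespace] optional id)
# and small JSON artifacts.

#' Read a SMILES line file
#'
#' One record per line: `SMILES[<whitespace>id]`. Empty lines and `#`
#' comments are skipped; unparsable records are dropped with a counted
#' warning.
#'
#' @param path file path.
#' @return data.frame `id`, `smiles`, `smiles_canonical`; parsed molecules
#'   in attribute `molecules`.
#' @export
read_smiles_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("read_smiles_file: no records in ", path)
  parts <- strsplit(lines, "[[:space:]]+")
  smiles <- vapply(parts, `[[`, character(1), 1)
  ids <- vapply(seq_along(parts), function(i)
    if (length(parts[[i]]) > 1) parts[[i]][2] else sprintf("line%d", i),
    character(1))
  mols <- canonicalize_all(smiles, ids)
  ok <- vapply(mols, function(m) isTRUE(m$parse_ok), logical(1))
  if (any(!ok))
    warning(sum(!ok), " record(s) dropped: unparsable SMILES", call. = FALSE)
  df <- data.frame(id = ids[ok], smiles = smiles[ok],
                   smiles_canonical = vapply(mols[ok], function(m)
                     m$smiles_canonical, character(1)),
                   stringsAsFactors = FALSE)
  attr(df, "molecules") <- mols[ok]
  df
}

#' Write a SMILES line file
#'
#' @param df data.frame with `smiles` and `id` columns.
#' @param path output path.
#' @export
write_smiles_file <- function(df, path) {
  writeLines(paste(df$smiles, df$id, sep = "\t"), path)
  invisible(path)
}
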