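# Scaffold-aware library triage against the three reference chemotypes:
# per-compound similarity profiles, per-reference histograms, and the
# diversity-oriented prospective selection (a few top-similarity picks per
# chemotype plus a random sample of low-similarity "alternative" scaffolds).

#' Reference chemotype set
#'
#' Three named reference structures (BV-21-type, M503-type, TZ61-84-type by
#' default) against which library molecules are profiled. Order is
#' significant: exact similarity ties are assigned to the earlier reference.
#'
#' @param smiles character vector of reference SMILES.
#' @param names reference names, same length.
#' @param cfg a [fingerprint_config()].
#' @return a `reference_set`: list of (name, molecule, fingerprint).
#' @export
reference_set <- function(smiles, names, cfg = fingerprint_config()) {
  stopifnot(length(smiles) == length(names), length(smiles) >= 1,
            !anyDuplicated(names))
  refs <- lapply(seq_along(smiles), function(i) {
    mol <- canonicalize(smiles[i], id = names[i])
    if (!mol$parse_ok) stop("reference '", names[i], "' failed to parse")
    list(name = names[i], molecule = mol,
         fingerprint = morgan_fingerprint(mol, cfg))
  })
  structure(list(references = refs, cfg = cfg), class = "reference_set")
}

#' Similarity profile of library molecules against the references
#'
#' For each molecule: Tanimoto similarity to every reference, the nearest
#' reference (ties to the first in reference order) and the alternative
#' flag (all similarities strictly below `alt_cutoff`).
#'
#' @param mols list of parsed `molecule` objects (or a precomputed
#'   fingerprint list).
#' @param refs a [reference_set()].
#' @param alt_cutoff similarity cutoff for the alternative-scaffold flag
#'   (default 0.2).
#' @return data.frame: `id`, one similarity column per reference
#'   (`sim_<name>`), `nearest_reference`, `nearest_score`, `is_alternative`.
#' @export
assign_chemotype <- function(mols, refs, alt_cutoff = 0.2) {
  stopifnot(inherits(refs, "reference_set"))
  fps <- if (length(mols) > 0 && inherits(mols[[1]], "fingerprint")) mols else
    lapply(mols, morgan_fingerprint, cfg = refs$cfg)
  ids <- if (length(mols) > 0 && inherits(mols[[1]], "fingerprint")) {
    nm <- names(mols)
    if (is.null(nm)) sprintf("mol%d", seq_along(mols)) else nm
  } else vapply(mols, function(m) m$id, character(1))
  ref_names <- vapply(refs$references, `[[`, character(1), "name")
  # matrix form: |A&B| via crossproduct of 0/1 matrices
  qm <- do.call(rbind, lapply(fps, as.integer))
  rm_ <- do.call(rbind, lapply(refs$references,
                               function(r) as.integer(r$fingerprint)))
  inter <- tcrossprod(qm, rm_)
  uni <- outer(rowSums(qm), rowSums(rm_), "+") - inter
  sims <- ifelse(uni == 0, 0, inter / uni)
  colnames(sims) <- paste0("sim_", ref_names)
  nearest_idx <- apply(sims, 1, which.max)  # ties -> first reference
  out <- data.frame(id = ids, sims,
                    nearest_reference = ref_names[nearest_idx],
                    nearest_score = sims[cbind(seq_len(nrow(sims)), nearest_idx)],
                    is_alternative = apply(sims < alt_cutoff, 1, all),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-reference histogram of similarity scores
#'
#' Half-open bins `[lo, hi)` of width `bin_width` over `[0, 1]`, final bin
#' closed at 1 so a perfect score is counted once. Optional tagged subsets
#' are returned as overlay tick positions (training/test and prospective
#' overlays in the study figures).
#'
#' @param profiles output of [assign_chemotype()].
#' @param bin_width bin width in `(0, 1]` (default 0.05).
#' @param overlays optional named list of id vectors to emit tick positions
#'   for.
#' @return list with `breaks`, `counts` (bins x references matrix) and
#'   `ticks` (per overlay, per reference score vectors).
#' @export
similarity_histogram <- function(profiles, bin_width = 0.05, overlays = NULL) {
  stopifnot(bin_width > 0, bin_width <= 1)
  sim_cols <- grep("^sim_", names(profiles), value = TRUE)
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  nb <- length(breaks) - 1L
  counts <- vapply(sim_cols, function(cl) {
    idx <- pmin(findInterval(profiles[[cl]], breaks,
                             rightmost.closed = TRUE), nb)
    tabulate(idx, nbins = nb)
  }, integer(nb))
  rownames(counts) <- sprintf("[%.3g,%.3g%s", breaks[-length(breaks)],
                              breaks[-1],
                              c(rep(")", nb - 1L), "]"))
  ticks <- NULL
  if (!is.null(overlays)) {
    ticks <- lapply(overlays, function(ids) {
      sub <- profiles[profiles$id %in% ids, sim_cols, drop = FALSE]
      as.list(sub)
    })
  }
  list(breaks = breaks, counts = counts, ticks = ticks)
}

#' Curation configuration
#'
#' @param n_high number of top-similarity picks (default 14), drawn
#'   round-robin across the reference chemotypes by descending nearest
#'   score.
#' @param n_low number of low-similarity ("alternative") picks (default
#'   16), sampled uniformly from compounds with all reference similarities
#'   below `alt_cutoff`.
#' @param alt_cutoff alternative-scaffold cutoff (default 0.2).
#' @param seed RNG seed for the low-similarity sample.
#' @return a `curation_config` list; prospective set size is
#'   `n_high + n_low` (default 30).
#' @export
curation_config <- function(n_high = 14L, n_low = 16L, alt_cutoff = 0.2,
                            seed = 1L) {
  stopifnot(n_high >= 0, n_low >= 0, n_high + n_low > 0,
            alt_cutoff >= 0, alt_cutoff <= 1)
  structure(list(n_high = as.integer(n_high), n_low = as.integer(n_low),
                 alt_cutoff = alt_cutoff, seed = as.integer(seed)),
            class = "curation_config")
}

#' Select the prospective compound set
#'
#' High-similarity stratum: `n_high` compounds drawn round-robin across the
#' reference chemotypes (each round takes the not-yet-selected compound
#' with the highest nearest score in each chemotype, chemotypes visited in
#' reference order). Low-similarity stratum: `n_low` compounds sampled
#' uniformly (seeded) from those with all reference similarities strictly
#' below `alt_cutoff`. The two strata are disjoint by construction.
#'
#' @param profiles output of [assign_chemotype()] (its `is_alternative`
#'   flag is recomputed against `cfg$alt_cutoff`).
#' @param cfg a [curation_config()].
#' @return object of class `prospective_selection`: data.frame of selected
#'   compounds with `selection` tag (`high_similarity` / `low_similarity`)
#'   joined to their similarity profiles, plus the config as attribute.
#' @export
select_prospective <- function(profiles, cfg = curation_config()) {
  sim_cols <- grep("^sim_", names(profiles), value = TRUE)
  is_alt <- apply(profiles[, sim_cols, drop = FALSE] < cfg$alt_cutoff, 1, all)
  high_pool <- profiles[!is_alt, , drop = FALSE]
  low_pool <- profiles[is_alt, , drop = FALSE]
  if (nrow(high_pool) < cfg$n_high)
    stop("select_prospective: high-similarity stratum shortfall: need ",
         cfg$n_high, ", have ", nrow(high_pool))
  if (nrow(low_pool) < cfg$n_low)
    stop("select_prospective: low-similarity stratum shortfall: need ",
         cfg$n_low, ", have ", nrow(low_pool))

  # round-robin by chemotype, descending nearest score within chemotype
  ref_order <- unique(sub("^sim_", "", sim_cols))
  queues <- lapply(ref_order, function(rn) {
    q <- high_pool[high_pool$nearest_reference == rn, , drop = FALSE]
    q[order(-q$nearest_score, q$id), "id"]
  })
  names(queues) <- ref_order
  high_ids <- character(0)
  while (length(high_ids) < cfg$n_high) {
    advanced <- FALSE
    for (rn in ref_order) {
      if (length(high_ids) >= cfg$n_high) break
      if (length(queues[[rn]]) > 0) {
        high_ids <- c(high_ids, queues[[rn]][1])
        queues[[rn]] <- queues[[rn]][-1]
        advanced <- TRUE
      }
    }
    if (!advanced) break
  }
  if (length(high_ids) < cfg$n_high)
    stop("select_prospective: high-similarity stratum exhausted")

  rs <- local_rng(cfg$seed)
  low_ids <- rs$sample(low_pool$id, cfg$n_low)

  sel <- rbind(
    cbind(profiles[match(high_ids, profiles$id), , drop = FALSE],
          selection = "high_similarity"),
    cbind(profiles[match(low_ids, profiles$id), , drop = FALSE],
          selection = "low_similarity"))
  rownames(sel) <- NULL
  structure(sel, cfg = cfg, class = c("prospective_selection", "data.frame"))
}
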