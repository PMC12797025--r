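# ECFP-style hashed circular (Morgan) fingerprints and Tanimoto similarity.
# The hashing is a stable 31-bit polynomial fold, so fingerprints are
# deterministic across platforms and sessions; identifiers for identical
# circular environments collide by construction (structural hashing of the
# refined invariants), making bits invariant to input atom order.

HASH_MOD <- 2147483647  # 2^31 - 1

# memo cache keyed by (radius, n_bits, input SMILES); bit vectors stored
# packed (128 bytes at 1024 bits), so even large screening runs stay small
.fp_cache <- new.env(parent = emptyenv())
hash_ints <- function(xs) {
  h <- 17
  for (x in xs) h <- (h * 131 + (x + 1)) %% HASH_MOD
  as.integer(h)
}

#' Fingerprint configuration
#'
#' Circular-fingerprint parameters. The package-wide default is radius 3 and
#' 1024 bits, used both for the similarity baseline and for model
#' featurization.
#'
#' @param radius non-negative integer atom-environment radius.
#' @param n_bits positive integer length of the folded bit vector.
#' @return a `fingerprint_config` list.
#' @export
fingerprint_config <- function(radius = 3L, n_bits = 1024L) {
  radius <- as.integer(radius); n_bits <- as.integer(n_bits)
  stopifnot(length(radius) == 1L, radius >= 0L,
            length(n_bits) == 1L, n_bits >= 1L)
  structure(list(radius = radius, n_bits = n_bits),
            class = "fingerprint_config")
}

#' Hashed circular (Morgan/ECFP-style) fingerprint
#'
#' Computes atom-centred circular substructure identifiers up to
#' `cfg$radius`, deduplicates identical environments (same bond set, lowest
#' radius kept), and folds identifiers into `cfg$n_bits` positions.
#'
#' @param mol a `molecule` from [canonicalize()] with `parse_ok = TRUE`.
#' @param cfg a [fingerprint_config()].
#' @return object of class `fingerprint`: integer 0/1 vector of length
#'   `n_bits` with attributes `popcount` and `n_bits`.
#' @export
morgan_fingerprint <- function(mol, cfg = fingerprint_config()) {
  stopifnot(inherits(mol, "molecule"))
  if (!isTRUE(mol$parse_ok)) stop("morgan_fingerprint: molecule failed to parse")
  cache_key <- NULL
  if (cfg$n_bits %% 8L == 0L && !is.na(mol$smiles_input)) {
    cache_key <- paste0(cfg$radius, ":", cfg$n_bits, ":", mol$smiles_input)
    hit <- .fp_cache[[cache_key]]
    if (!is.null(hit)) {
      bits <- as.integer(rawToBits(hit))[seq_len(cfg$n_bits)]
      return(structure(bits, popcount = sum(bits), n_bits = cfg$n_bits,
                       class = "fingerprint"))
    }
  }
  g <- mol$graph
  na <- nrow(g$atoms)
  adj <- adjacency(g)
  bcode <- bond_code_matrix(g)
  inring <- ring_atoms(g)
  a <- g$atoms

  # bond index lookup for environment tracking
  nb <- nrow(g$bonds)
  bond_id <- matrix(0L, na, na)
  if (nb > 0) {
    bond_id[cbind(g$bonds$a1, g$bonds$a2)] <- seq_len(nb)
    bond_id[cbind(g$bonds$a2, g$bonds$a1)] <- seq_len(nb)
  }

  nbr <- lapply(seq_len(na), function(i) adj[[i]])
  nbr_code <- lapply(seq_len(na), function(i) bcode[i, adj[[i]]])
  nbr_bond <- lapply(seq_len(na), function(i) bond_id[i, adj[[i]]])

  ids <- vapply(seq_len(na), function(i) {
    hash_ints(c(length(adj[[i]]), ATOMIC_NUMBER[[a$element[i]]],
                a$charge[i], a$nH[i], as.integer(inring[i]),
                as.integer(a$aromatic[i]), a$isotope[i]))
  }, integer(1))

  all_ids <- ids; all_r <- rep(0L, na); all_key <- rep("", na)
  env <- matrix(FALSE, max(nb, 1L), na)  # bond membership per atom env

  if (cfg$radius > 0L) for (r in seq_len(cfg$radius)) {
    new_ids <- ids
    new_env <- env
    key_r <- character(na)
    for (i in seq_len(na)) {
      nbrs <- nbr[[i]]
      if (length(nbrs) == 0L) next
      o <- order(nbr_code[[i]] * (HASH_MOD + 1) + ids[nbrs])
      new_ids[i] <- hash_ints(c(r, ids[i],
                                rbind(nbr_code[[i]][o], ids[nbrs][o])))
      e <- env[, i]
      e[nbr_bond[[i]]] <- TRUE
      for (j in nbrs) e <- e | env[, j]
      new_env[, i] <- e
      key_r[i] <- paste(which(e), collapse = ",")
    }
    ids <- new_ids; env <- new_env
    all_ids <- c(all_ids, ids)
    all_r <- c(all_r, rep(r, na))
    all_key <- c(all_key, key_r)
  }

  # dedupe identical r>=1 environments (same bond set): keep lowest radius,
  # then lowest id; all radius-0 atom-type identifiers are kept
  keep0 <- all_r == 0L
  o1 <- which(!keep0)[order(all_r[!keep0], all_ids[!keep0])]
  o1 <- o1[!duplicated(all_key[o1]) & nzchar(all_key[o1])]
  sel_ids <- c(all_ids[keep0], all_ids[o1])

  bits <- integer(cfg$n_bits)
  bits[(sel_ids %% cfg$n_bits) + 1L] <- 1L
  if (!is.null(cache_key) && length(ls(.fp_cache)) < 50000L)
    .fp_cache[[cache_key]] <- packBits(as.integer(bits))
  structure(bits, popcount = sum(bits), n_bits = cfg$n_bits,
            class = "fingerprint")
}

#' @noRd
#' @exportS3Method base::print
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %d bits, popcount %d\n",
              attr(x, "n_bits"), attr(x, "popcount")))
  invisible(x)
}

#' Tanimoto similarity of two bit vectors
#'
#' `|a AND b| / |a OR b|`; defined as 0 when both vectors are all-zero.
#'
#' @param a,b fingerprints (or plain 0/1 integer vectors) of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop("tanimoto: fingerprint lengths differ (", length(a), " vs ",
         length(b), ")")
  a <- as.integer(a); b <- as.integer(b)
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0L) return(0)
  inter / uni
}

#' Tanimoto similarities of one query against many fingerprints
#'
#' @param query a fingerprint.
#' @param fps list of fingerprints of the same length.
#' @return numeric vector of similarities.
#' @export
tanimoto_many <- function(query, fps) {
  vapply(fps, function(f) tanimoto(query, f), numeric(1))
}

#' Fingerprint a list of molecules into a 0/1 matrix
#'
#' @param mols list of parsed `molecule` objects.
#' @param cfg a [fingerprint_config()].
#' @return integer matrix, one row per molecule, `n_bits` columns named
#'   `fp0001...`.
#' @export
fingerprint_matrix <- function(mols, cfg = fingerprint_config()) {
  stopifnot(length(mols) > 0)
  m <- t(vapply(mols, function(mm) as.integer(morgan_fingerprint(mm, cfg)),
                integer(cfg$n_bits)))
  colnames(m) <- sprintf("fp%04d", seq_len(cfg$n_bits))
  rownames(m) <- vapply(mols, function(mm) mm$id, character(1))
  m
}
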