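# Canonical atom ranking (iterative neighbourhood refinement with
# deterministic tie promotion) and a DFS SMILES writer shared by the
# canonical and randomized spellings.

canonical_ranks <- function(mol) {
  na <- nrow(mol$atoms)
  if (na == 1L) return(1L)
  adj <- adjacency(mol)
  bond_code <- bond_code_matrix(mol)
  # per-atom bond codes aligned with adj[[i]]
  codes <- lapply(seq_len(na), function(i) bond_code[i, adj[[i]]])
  inring <- ring_atoms(mol)
  a <- mol$atoms
  key0 <- paste(a$element, a$aromatic, a$charge, a$isotope, a$nH,
                vapply(adj, length, integer(1)), inring, sep = "|")
  rank <- match(key0, sort(unique(key0)))

  mult <- 8L * na  # codes <= 4, ranks <= 2*na during tie promotion
  refine <- function(rank) {
    repeat {
      key <- character(na)
      for (i in seq_len(na)) {
        nb <- adj[[i]]
        key[i] <- if (length(nb) == 0L) as.character(rank[i]) else
          paste(rank[i],
                paste(sort(codes[[i]] * mult + rank[nb]), collapse = ","),
                sep = "|")
      }
      # order new labels primarily by old rank so the labeling is monotone
      # across iterations and the loop terminates when the partition is
      # stable (keys embed the old rank, so partitions only ever refine)
      o <- order(rank, key)
      uk <- key[o][!duplicated(key[o])]
      newrank <- match(key, uk)
      if (identical(newrank, rank)) return(rank)
      rank <- newrank
    }
  }
  rank <- refine(rank)
  # promote one atom from the lowest tied class until all ranks distinct;
  # within a refined class atoms are graph-equivalent for chemical graphs,
  # so promoting any member yields the same canonical string
  while (length(unique(rank)) < na) {
    tied <- which(tabulate(rank) > 1)
    cls <- min(tied)
    pick <- which(rank == cls)[1]
    rank <- rank + as.integer(rank > cls | (rank == cls & seq_len(na) != pick))
    rank[pick] <- cls
    rank <- refine(rank)
  }
  rank
}

# bond code lookup (1/2/3 = orders, 4 = aromatic), dense matrix is fine at
# molecule scale
bond_code_matrix <- function(mol) {
  na <- nrow(mol$atoms)
  m <- matrix(0L, na, na)
  b <- mol$bonds
  if (nrow(b) > 0) {
    code <- ifelse(b$aromatic, 4L, b$order)
    m[cbind(b$a1, b$a2)] <- code
    m[cbind(b$a2, b$a1)] <- code
  }
  m
}

atom_token <- function(mol, i) {
  a <- mol$atoms[i, ]
  sym <- if (a$aromatic) tolower(a$element) else a$element
  plain_ok <- a$element %in% ORGANIC_SUBSET && a$charge == 0L &&
    a$isotope == 0L && a$nH == default_h_count(mol, i)
  if (plain_ok) return(sym)
  h <- if (a$nH == 0L) "" else if (a$nH == 1L) "H" else paste0("H", a$nH)
  ch <- if (a$charge == 0L) "" else if (a$charge == 1L) "+" else
    if (a$charge == -1L) "-" else sprintf("%+d", a$charge)
  iso <- if (a$isotope > 0L) as.character(a$isotope) else ""
  paste0("[", iso, sym, h, ch, "]")
}

# what implicit-H count an unbracketed spelling of atom i would imply
default_h_count <- function(mol, i) {
  el <- mol$atoms$element[i]
  if (!(el %in% ORGANIC_SUBSET)) return(-1L)
  b <- mol$bonds
  sel <- b$a1 == i | b$a2 == i
  used <- sum(ifelse(b$aromatic[sel], 1L, b$order[sel])) +
    if (mol$atoms$aromatic[i]) 1L else 0L
  as.integer(max(0, DEFAULT_VALENCE[[el]] - used))
}

bond_token <- function(mol, i, j) {
  b <- mol$bonds
  k <- which((b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i))[1]
  if (b$aromatic[k]) return("")
  ord <- b$order[k]
  if (ord == 2L) return("=")
  if (ord == 3L) return("#")
  # explicit single bond needed between two aromatic atoms (e.g. biphenyl)
  if (mol$atoms$aromatic[i] && mol$atoms$aromatic[j]) return("-")
  ""
}

# DFS spelling; `order_fun(i, candidates)` returns candidates in visit order
write_smiles_graph <- function(mol, start, order_fun) {
  na <- nrow(mol$atoms)
  adj <- adjacency(mol)
  comp <- connected_components(mol)
  pieces <- character(0)
  comp_order <- c(comp[start], setdiff(sort(unique(comp)), comp[start]))

  for (root_comp in comp_order) {
    members <- which(comp == root_comp)
    root <- if (start %in% members) start else members[1]

    # pass 1: tree/back edge classification in deterministic DFS order
    parent <- rep(NA_integer_, na)
    visit_order <- integer(0)
    back_edges <- list()
    seen <- logical(na)
    dfs1 <- function(v) {
      seen[v] <<- TRUE
      visit_order[length(visit_order) + 1L] <<- v
      for (w in order_fun(v, adj[[v]])) {
        if (!seen[w]) {
          parent[w] <<- v
          dfs1(w)
        } else if (!identical(parent[v], w)) {
          key <- paste(min(v, w), max(v, w))
          if (is.null(back_edges[[key]]))
            back_edges[[key]] <<- c(min(v, w), max(v, w))
        }
      }
    }
    dfs1(root)

    # ring-closure digits in order of first-endpoint emission
    pos <- match(seq_len(na), visit_order)
    ring_num <- 0L
    ring_digit <- character(0)
    open_at <- lapply(seq_len(na), function(i) list())
    if (length(back_edges) > 0) {
      eo <- order(vapply(back_edges, function(e) min(pos[e[1]], pos[e[2]]),
                         numeric(1)),
                  vapply(back_edges, function(e) max(pos[e[1]], pos[e[2]]),
                         numeric(1)))
      for (key in names(back_edges)[eo]) {
        e <- back_edges[[key]]
        ring_num <- ring_num + 1L
        dig <- if (ring_num < 10L) as.character(ring_num) else
          sprintf("%%%02d", ring_num)
        first <- if (pos[e[1]] < pos[e[2]]) e[1] else e[2]
        second <- if (pos[e[1]] < pos[e[2]]) e[2] else e[1]
        btok <- bond_token(mol, e[1], e[2])
        open_at[[first]] <- c(open_at[[first]],
                              list(list(d = dig, b = btok, other = second)))
        open_at[[second]] <- c(open_at[[second]],
                               list(list(d = dig, b = btok, other = first)))
      }
    }

    # pass 2: emit
    emit <- function(v) {
      out <- atom_token(mol, v)
      for (rc in open_at[[v]]) out <- paste0(out, rc$b, rc$d)
      kids <- Filter(function(w) identical(parent[w], v),
                     order_fun(v, adj[[v]]))
      if (length(kids) > 0) {
        for (w in kids[-length(kids)]) {
          out <- paste0(out, "(", bond_token(mol, v, w), emit(w), ")")
        }
        w <- kids[length(kids)]
        out <- paste0(out, bond_token(mol, v, w), emit(w))
      }
      out
    }
    pieces <- c(pieces, emit(root))
  }
  paste(pieces, collapse = ".")
}

canonical_smiles <- function(mol) {
  rank <- canonical_ranks(mol)
  start <- which.min(rank)
  write_smiles_graph(mol, start,
                     function(v, cand) cand[order(rank[cand])])
}

# random-but-valid respelling of the same molecule, for invariance tests
random_smiles <- function(mol) {
  na <- nrow(mol$atoms)
  start <- sample.int(na, 1)
  write_smiles_graph(mol, start,
                     function(v, cand) {
                       if (length(cand) <= 1) cand else sample(cand)
                     })
}

#' Parse, normalize and canonicalize a SMILES string
#'
#' Parses `smiles`, keeps the largest covalently connected fragment (salt
#' stripping; no charge neutralization) and emits a canonical SMILES via
#' iterative neighbourhood-refinement atom ranking. Canonicalization is
#' idempotent and invariant to the atom order of the input spelling.
#'
#' @param smiles a single SMILES string.
#' @param id optional identifier carried through the pipeline.
#' @return an object of class `molecule`: list with `id`, `smiles_input`,
#'   `smiles_canonical`, `parse_ok`, and (on success) the internal graph.
#' @examples
#' canonicalize("OCC")$smiles_canonical == canonicalize("CCO")$smiles_canonical
#' canonicalize("C1CC")$parse_ok  # FALSE: unclosed ring
#' @export
canonicalize <- function(smiles, id = NA_character_) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (is.na(smiles) || !nzchar(smiles)) {
    warning("empty SMILES string", call. = FALSE)
    return(structure(list(id = id, smiles_input = smiles,
                          smiles_canonical = NA_character_,
                          parse_ok = FALSE, graph = NULL),
                     class = "molecule"))
  }
  mol <- parse_smiles(smiles)
  if (is.null(mol)) {
    return(structure(list(id = id, smiles_input = smiles,
                          smiles_canonical = NA_character_,
                          parse_ok = FALSE, graph = NULL),
                     class = "molecule"))
  }
  mol <- largest_fragment(mol)
  structure(list(id = id, smiles_input = smiles,
                 smiles_canonical = canonical_smiles(mol),
                 parse_ok = TRUE, graph = mol),
            class = "molecule")
}

#' @noRd
#' @exportS3Method base::print
print.molecule <- function(x, ...) {
  if (x$parse_ok) {
    cat("<molecule>", if (!is.na(x$id)) paste0(x$id, " "), x$smiles_canonical,
        sprintf("(%d heavy atoms)\n", nrow(x$graph$atoms)))
  } else {
    cat("<molecule> parse failure for input:", x$smiles_input, "\n")
  }
  invisible(x)
}

#' Parse a SMILES into a molecule without canonicalizing
#'
#' Cheaper constructor for bulk generation/screening where the canonical
#' string is not needed; `smiles_canonical` is `NA` until requested.
#'
#' @param smiles single SMILES string.
#' @param id optional identifier.
#' @return a `molecule` (possibly with `parse_ok = FALSE`).
#' @export
parse_molecule <- function(smiles, id = NA_character_) {
  mol <- parse_smiles(smiles)
  if (is.null(mol)) {
    return(structure(list(id = id, smiles_input = smiles,
                          smiles_canonical = NA_character_,
                          parse_ok = FALSE, graph = NULL),
                     class = "molecule"))
  }
  structure(list(id = id, smiles_input = smiles,
                 smiles_canonical = NA_character_, parse_ok = TRUE,
                 graph = largest_fragment(mol)),
            class = "molecule")
}

#' Canonicalize a vector of SMILES
#'
#' Vectorized wrapper around [canonicalize()]; unparsable entries are kept
#' with `parse_ok = FALSE` so callers can count and skip them.
#'
#' @param smiles character vector of SMILES.
#' @param ids optional identifiers (recycled against `smiles`).
#' @return list of `molecule` objects.
#' @export
canonicalize_all <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  stopifnot(length(ids) == length(smiles))
  mapply(canonicalize, smiles, ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}
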