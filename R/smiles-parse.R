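# SMILES reading: tokenizer, graph construction, implicit hydrogens,
# fragment handling. Covers the organic subset, bracket atoms with isotope /
# charge / explicit H, aromatic lowercase atoms, ring closures (incl. %nn),
# branches and dot-separated fragments. Stereo marks (@, /, \) are accepted
# and discarded: the pipeline is 2D throughout.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_OK <- c("b", "c", "n", "o", "p", "s", "se", "as")

# default valences used for implicit-H assignment (first value per element)
DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                     F = 1, Cl = 1, Br = 1, I = 1)

ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
                   Cl = 17, Br = 35, I = 53, Se = 34, As = 33, Si = 14,
                   Na = 11, K = 19, Li = 3, Mg = 12, Ca = 20, Zn = 30)

ATOMIC_MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, P = 30.974, S = 32.06, Cl = 35.453, Br = 79.904,
                 I = 126.904, Se = 78.971, As = 74.922, Si = 28.085,
                 Na = 22.99, K = 39.098, Li = 6.94, Mg = 24.305,
                 Ca = 40.078, Zn = 65.38)

new_molgraph <- function(atoms, bonds) {
  structure(list(atoms = atoms, bonds = bonds), class = "molgraph")
}

empty_bonds <- function() {
  data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
             aromatic = logical(0))
}

#' Parse a SMILES string into a molecular graph
#'
#' Low-level parser behind [canonicalize()]. Returns `NULL` (with a warning
#' when `quiet = FALSE`) for strings that are not valid SMILES under the
#' supported grammar.
#'
#' @param smiles single SMILES string.
#' @param quiet suppress the parse-failure warning.
#' @return a `molgraph` (lists of atoms and bonds) or `NULL` on failure.
#' @keywords internal
parse_smiles <- function(smiles, quiet = FALSE) {
  res <- tryCatch(parse_smiles_impl(smiles), error = function(e) e)
  if (inherits(res, "error")) {
    if (!quiet) warning("SMILES parse failed for '", smiles, "': ",
                        conditionMessage(res), call. = FALSE)
    return(NULL)
  }
  res
}

parse_smiles_impl <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (is.na(smiles) || !nzchar(smiles)) stop("empty SMILES")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)

  el <- character(n); arom <- logical(n); chg <- integer(n)
  iso <- integer(n); hexp <- integer(n); bracket <- logical(n)
  b_a1 <- integer(n); b_a2 <- integer(n); b_ord <- integer(n); b_aro <- logical(n)
  n_at <- 0L; n_bd <- 0L

  prev <- NA_integer_       # atom awaiting the next bond
  stack <- integer(0)       # branch stack
  pend <- NA_character_     # pending bond symbol
  rings <- list()           # closure id -> list(atom, sym)

  add_atom <- function(sym, aromatic, charge = 0L, isotope = 0L,
                       h = NA_integer_, brk = FALSE) {
    n_at <<- n_at + 1L
    el[n_at] <<- sym; arom[n_at] <<- aromatic; chg[n_at] <<- charge
    iso[n_at] <<- isotope; hexp[n_at] <<- h; bracket[n_at] <<- brk
    n_at
  }
  add_bond <- function(i, j, sym, a_i, a_j) {
    if (i == j) stop("self bond")
    ord <- switch(if (is.na(sym)) "none" else sym,
                  none = 1L, "-" = 1L, "/" = 1L, "\\" = 1L,
                  "=" = 2L, "#" = 3L, ":" = 1L,
                  stop("bad bond '", sym, "'"))
    aro_b <- (is.na(sym) || sym == ":") && a_i && a_j && !identical(sym, "-")
    if (identical(sym, ":")) aro_b <- TRUE
    n_bd <<- n_bd + 1L
    b_a1[n_bd] <<- i; b_a2[n_bd] <<- j
    b_ord[n_bd] <<- ord; b_aro[n_bd] <<- aro_b
  }
  link <- function(idx) {
    if (!is.na(prev)) add_bond(prev, idx, pend, arom[prev], arom[idx])
    pend <<- NA_character_
    prev <<- idx
  }
  ring_event <- function(id) {
    if (is.na(prev)) stop("ring closure before any atom")
    key <- as.character(id)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, sym = pend)
    } else {
      op <- rings[[key]]
      sym <- if (!is.na(pend)) pend else op$sym
      if (!is.na(pend) && !is.na(op$sym) && pend != op$sym)
        stop("ring bond symbol mismatch")
      add_bond(op$atom, prev, sym, arom[op$atom], arom[prev])
      rings[[key]] <<- NULL
    }
    pend <<- NA_character_
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- parse_bracket_atom(body)
      idx <- add_atom(at$el, at$arom, at$charge, at$isotope, at$h, TRUE)
      link(idx)
      i <- j + 1L
    } else if (two %in% c("Cl", "Br")) {
      idx <- add_atom(two, FALSE)
      link(idx); i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      idx <- add_atom(ch, FALSE)
      link(idx); i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      idx <- add_atom(toupper(ch), TRUE)
      link(idx); i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      if (!is.na(pend)) stop("two bond symbols in a row")
      pend <- ch; i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop("branch with no preceding atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      ring_event(as.integer(ch)); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("bad %nn ring closure")
      ring_event(as.integer(paste0(chars[i + 1L], chars[i + 2L])))
      i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_; pend <- NA_character_; i <- i + 1L
    } else {
      stop("unexpected character '", ch, "'")
    }
  }
  if (length(stack) > 0L) stop("unmatched '('")
  if (length(rings) > 0L) stop("unclosed ring bond")
  if (n_at == 0L) stop("no atoms")
  at_idx <- seq_len(n_at); bd_idx <- seq_len(n_bd)
  b_a1 <- b_a1[bd_idx]; b_a2 <- b_a2[bd_idx]
  if (anyDuplicated(pmin(b_a1, b_a2) * (n_at + 1L) + pmax(b_a1, b_a2)) > 0L)
    stop("duplicate bond")

  atoms <- data.frame(element = el[at_idx], aromatic = arom[at_idx],
                      charge = chg[at_idx], isotope = iso[at_idx],
                      h_explicit = hexp[at_idx], bracket = bracket[at_idx])
  bonds <- data.frame(a1 = b_a1, a2 = b_a2, order = b_ord[bd_idx],
                      aromatic = b_aro[bd_idx])
  mol <- new_molgraph(atoms, bonds)
  mol$atoms$nH <- implicit_hydrogens(mol)
  validate_aromaticity(mol)
  mol
}

parse_bracket_atom <- function(body) {
  m <- regmatches(body, regexec(
    "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?([+-][0-9+-]*)?(:[0-9]+)?$",
    body))[[1]]
  if (length(m) == 0L) stop("bad bracket atom [", body, "]")
  isotope <- if (nzchar(m[2])) as.integer(m[2]) else 0L
  sym <- m[3]
  aromatic <- sym %in% AROMATIC_OK
  el <- if (aromatic) {
    paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  } else sym
  if (!(el %in% names(ATOMIC_NUMBER))) stop("unknown element '", el, "'")
  h <- 0L
  if (!is.na(m[5]) && nzchar(m[5]))
    h <- if (m[5] == "H") 1L else as.integer(substring(m[5], 2))
  charge <- 0L
  if (!is.na(m[6]) && nzchar(m[6])) {
    cs <- m[6]
    if (grepl("^[+-][0-9]+$", cs)) {
      charge <- as.integer(cs)
    } else if (grepl("^\\++$", cs)) {
      charge <- nchar(cs)
    } else if (grepl("^-+$", cs)) {
      charge <- -nchar(cs)
    } else stop("bad charge '", cs, "'")
  }
  list(el = el, arom = aromatic, isotope = isotope, h = h, charge = charge)
}

# implicit H for organic-subset atoms written without brackets; bracket atoms
# carry their explicit H count. Aromatic atoms contribute one valence to the
# delocalized pi system on top of their sigma connections.
implicit_hydrogens <- function(mol) {
  atoms <- mol$atoms; bonds <- mol$bonds
  na <- nrow(atoms)
  bsum <- numeric(na)
  if (nrow(bonds) > 0) {
    ord <- ifelse(bonds$aromatic, 1L, bonds$order)
    for (k in seq_len(nrow(bonds))) {
      bsum[bonds$a1[k]] <- bsum[bonds$a1[k]] + ord[k]
      bsum[bonds$a2[k]] <- bsum[bonds$a2[k]] + ord[k]
    }
  }
  vapply(seq_len(na), function(i) {
    if (atoms$bracket[i]) return(atoms$h_explicit[i])
    dv <- DEFAULT_VALENCE[[atoms$element[i]]]
    used <- bsum[i] + if (atoms$aromatic[i]) 1L else 0L
    as.integer(max(0, dv - used))
  }, integer(1))
}

validate_aromaticity <- function(mol) {
  if (!any(mol$atoms$aromatic)) return(invisible(TRUE))
  deg_aro <- integer(nrow(mol$atoms))
  b <- mol$bonds[mol$bonds$aromatic, , drop = FALSE]
  if (nrow(b) > 0) for (k in seq_len(nrow(b))) {
    deg_aro[b$a1[k]] <- deg_aro[b$a1[k]] + 1L
    deg_aro[b$a2[k]] <- deg_aro[b$a2[k]] + 1L
  }
  if (any(mol$atoms$aromatic & deg_aro < 2L))
    stop("aromatic atom outside an aromatic ring")
  invisible(TRUE)
}

# adjacency as list of integer vectors (neighbour atom indices)
adjacency <- function(mol) {
  na <- nrow(mol$atoms)
  adj <- vector("list", na)
  for (i in seq_len(na)) adj[[i]] <- integer(0)
  b <- mol$bonds
  if (nrow(b) > 0) for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], b$a2[k])
    adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], b$a1[k])
  }
  adj
}

connected_components <- function(mol) {
  na <- nrow(mol$atoms)
  adj <- adjacency(mol)
  comp <- integer(na); cur <- 0L
  for (s in seq_len(na)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- cur
      queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  comp
}

# keep the covalent fragment with the most heavy atoms (ties: first seen)
largest_fragment <- function(mol) {
  comp <- connected_components(mol)
  if (max(comp) == 1L) return(mol)
  sizes <- tabulate(comp)
  keep <- which.max(sizes)
  sel <- which(comp == keep)
  remap <- match(seq_len(nrow(mol$atoms)), sel)
  atoms <- mol$atoms[sel, , drop = FALSE]
  rownames(atoms) <- NULL
  b <- mol$bonds
  bk <- b[b$a1 %in% sel & b$a2 %in% sel, , drop = FALSE]
  bk$a1 <- remap[bk$a1]; bk$a2 <- remap[bk$a2]
  rownames(bk) <- NULL
  new_molgraph(atoms, bk)
}

# bonds that lie on a cycle = non-bridge edges (iterative Tarjan low-link)
ring_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(logical(0))
  na <- nrow(mol$atoms)
  # incidence lists: neighbour atom + bond index
  nadj <- vector("list", na); badj <- vector("list", na)
  for (k in seq_len(nb)) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    nadj[[a]] <- c(nadj[[a]], b); badj[[a]] <- c(badj[[a]], k)
    nadj[[b]] <- c(nadj[[b]], a); badj[[b]] <- c(badj[[b]], k)
  }
  disc <- integer(na); low <- integer(na)
  bridge <- logical(nb); timer <- 0L
  # explicit stacks (vertex, incoming bond, next-neighbour pointer)
  for (root in seq_len(na)) {
    if (disc[root] > 0L) next
    sv <- root; sb <- 0L; sp <- 1L
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    depth <- 1L
    while (depth > 0L) {
      v <- sv[depth]
      ptr <- sp[depth]
      if (ptr <= length(nadj[[v]])) {
        sp[depth] <- ptr + 1L
        w <- nadj[[v]][ptr]; bk <- badj[[v]][ptr]
        if (bk == sb[depth]) next
        if (disc[w] == 0L) {
          timer <- timer + 1L; disc[w] <- low[w] <- timer
          depth <- depth + 1L
          sv[depth] <- w; sb[depth] <- bk; sp[depth] <- 1L
        } else {
          low[v] <- min(low[v], disc[w])
        }
      } else {
        depth <- depth - 1L
        if (depth > 0L) {
          p <- sv[depth]
          low[p] <- min(low[p], low[v])
          if (low[v] > disc[p]) bridge[sb[depth + 1L]] <- TRUE
        }
      }
    }
  }
  !bridge
}

ring_atoms <- function(mol) {
  inring <- logical(nrow(mol$atoms))
  rb <- ring_bonds(mol)
  if (any(rb)) {
    inring[unique(c(mol$bonds$a1[rb], mol$bonds$a2[rb]))] <- TRUE
  }
  inring
}
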