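# A fixed panel of 2D physicochemical and topological descriptors computed
# from the molecular graph (with implicit hydrogens). Bulk counterparts of
# the large Mordred panel: size, composition, H-bonding capacity, ring and
# flexibility counts, and classical connectivity/distance indices. All are
# conformation-free and deterministic; entries that are undefined for a
# given graph (e.g. distance indices of a single atom) are returned NA and
# flagged, never silently zeroed.

DESCRIPTOR_NAMES <- c(
  "MolWt", "HeavyAtomCount", "nC", "nN", "nO", "nS", "nHalogen", "nHetero",
  "nH_total", "FormalCharge", "NumHDonors", "NumHAcceptors",
  "RingBondCount", "RingAtomCount", "nRings", "AromaticAtomCount",
  "AromaticRatio", "NumRotatableBonds", "MaxDegree", "MeanDegree",
  "Chi0", "Chi1", "ZagrebM1", "ZagrebM2", "WienerIndex", "Diameter",
  "Radius", "MeanDistance", "HeteroRatio", "HalogenRatio")

#' Names of the descriptor panel
#'
#' @return character vector of the descriptor names computed by
#'   [compute_descriptors()], in fixed order.
#' @export
descriptor_names <- function() DESCRIPTOR_NAMES

#' Compute the 2D descriptor panel for one molecule
#'
#' @param mol a parsed `molecule` from [canonicalize()].
#' @return named numeric vector over [descriptor_names()]; undefined entries
#'   are `NA` (see the `missing` attribute, a logical mask).
#' @examples
#' d <- compute_descriptors(canonicalize("CCO"))
#' d[["MolWt"]]  # 46.069
#' @export
compute_descriptors <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  if (!isTRUE(mol$parse_ok)) stop("compute_descriptors: molecule failed to parse")
  g <- mol$graph
  a <- g$atoms
  b <- g$bonds
  na <- nrow(a)
  adj <- adjacency(g)
  deg <- vapply(adj, length, integer(1))
  rb <- ring_bonds(g)
  ra <- ring_atoms(g)

  halogens <- c("F", "Cl", "Br", "I")
  nH <- sum(a$nH)
  mw <- sum(ATOMIC_MASS[a$element]) + nH * ATOMIC_MASS[["H"]]

  donors <- sum(a$element %in% c("N", "O") & a$nH > 0)
  acceptors <- sum(a$element %in% c("N", "O"))

  # rotatable: non-ring single bonds between two heavy atoms of degree > 1
  rot <- if (nrow(b) == 0) 0L else
    sum(!rb & b$order == 1L & !b$aromatic & deg[b$a1] > 1L & deg[b$a2] > 1L)

  # cyclomatic number (smallest-set-of-smallest-rings count for connected g)
  ncomp <- length(unique(connected_components(g)))
  nrings <- nrow(b) - na + ncomp

  chi0 <- sum(1 / sqrt(pmax(deg, 1)))
  chi1 <- if (nrow(b) == 0) NA_real_ else
    sum(1 / sqrt(deg[b$a1] * deg[b$a2]))
  zm1 <- sum(deg^2)
  zm2 <- if (nrow(b) == 0) NA_real_ else sum(deg[b$a1] * deg[b$a2])

  if (na > 1 && ncomp == 1) {
    dmat <- graph_distances(adj)
    wiener <- sum(dmat[upper.tri(dmat)])
    ecc <- apply(dmat, 1, max)
    diam <- max(ecc); rad <- min(ecc)
    meand <- mean(dmat[upper.tri(dmat)])
  } else if (na == 1) {
    wiener <- 0; diam <- 0; rad <- 0; meand <- NA_real_
  } else {
    wiener <- NA_real_; diam <- NA_real_; rad <- NA_real_; meand <- NA_real_
  }

  vals <- c(
    MolWt = unname(mw),
    HeavyAtomCount = na,
    nC = sum(a$element == "C"),
    nN = sum(a$element == "N"),
    nO = sum(a$element == "O"),
    nS = sum(a$element == "S"),
    nHalogen = sum(a$element %in% halogens),
    nHetero = sum(!(a$element %in% c("C", "H"))),
    nH_total = nH,
    FormalCharge = sum(a$charge),
    NumHDonors = donors,
    NumHAcceptors = acceptors,
    RingBondCount = sum(rb),
    RingAtomCount = sum(ra),
    nRings = nrings,
    AromaticAtomCount = sum(a$aromatic),
    AromaticRatio = sum(a$aromatic) / na,
    NumRotatableBonds = rot,
    MaxDegree = max(deg),
    MeanDegree = mean(deg),
    Chi0 = chi0,
    Chi1 = chi1,
    ZagrebM1 = zm1,
    ZagrebM2 = zm2,
    WienerIndex = wiener,
    Diameter = diam,
    Radius = rad,
    MeanDistance = meand,
    HeteroRatio = sum(!(a$element %in% c("C", "H"))) / na,
    HalogenRatio = sum(a$element %in% halogens) / na
  )
  vals <- vals[DESCRIPTOR_NAMES]
  structure(vals, missing = is.na(vals))
}

# all-pairs shortest path lengths by repeated BFS (graph is molecule-sized)
graph_distances <- function(adj) {
  na <- length(adj)
  d <- matrix(Inf, na, na)
  for (s in seq_len(na)) {
    dist <- rep(Inf, na); dist[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (dist[w] > dist[v] + 1) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
    d[s, ] <- dist
  }
  d
}

#' Descriptor matrix for a list of molecules
#'
#' @param mols list of parsed `molecule` objects.
#' @return numeric matrix (rows = molecules, columns = descriptor panel),
#'   `NA` where undefined.
#' @export
descriptor_matrix <- function(mols) {
  stopifnot(length(mols) > 0)
  m <- t(vapply(mols, function(mm) as.numeric(compute_descriptors(mm)),
                numeric(length(DESCRIPTOR_NAMES))))
  colnames(m) <- DESCRIPTOR_NAMES
  rownames(m) <- vapply(mols, function(mm) mm$id, character(1))
  m
}
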