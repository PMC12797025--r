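test_that("canonicalization maps equivalent spellings to one form and is idempotent", {
  pairs <- list(c("OCC", "CCO"),
                c("c1ccccc1C", "Cc1ccccc1"),
                c("N#Cc1ccccc1", "c1ccccc1C#N"),
                c("CC(=O)Oc1ccccc1C(=O)O", "OC(=O)c1ccccc1OC(C)=O"))
  for (p in pairs) {
    m1 <- canonicalize(p[1]); m2 <- canonicalize(p[2])
    expect_true(m1$parse_ok && m2$parse_ok)
    expect_identical(m1$smiles_canonical, m2$smiles_canonical)
    expect_identical(canonicalize(m1$smiles_canonical)$smiles_canonical,
                     m1$smiles_canonical)
  }
})

test_that("canonicalization is invariant to randomized respellings", {
  set.seed(7)
  for (s in c("CC(=O)Oc1ccccc1C(=O)O", "c1ccc2ccccc2c1",
              "O=S(=O)(N)c1ccccc1", "c1cc(OC)ccc1-c1nc2cc(C#N)c(N(C)C)cc2s1")) {
    ref <- canonicalize(s)
    for (i in 1:20) {
      spelled <- synbinder:::random_smiles(ref$graph)
      expect_identical(canonicalize(spelled)$smiles_canonical,
                       ref$smiles_canonical,
                       label = paste("respelling", spelled))
    }
  }
})

test_that("unparsable SMILES yield parse_ok = FALSE with a warning, never an error", {
  for (bad in c("C1CC", "C(C", "Cx", "C==C", "[Qq]", "%")) {
    expect_warning(m <- canonicalize(bad))
    expect_false(m$parse_ok)
    expect_true(is.na(m$smiles_canonical))
  }
  expect_warning(m <- canonicalize(""))
  expect_false(m$parse_ok)
})

test_that("salt stripping keeps the largest covalent fragment only", {
  m <- canonicalize("[O-]C(=O)c1ccccc1.[Na+]")
  expect_identical(m$smiles_canonical,
                   canonicalize("[O-]C(=O)c1ccccc1")$smiles_canonical)
  expect_identical(nrow(m$graph$atoms), 9L)
})

test_that("bracket atoms round-trip charge, isotope and explicit hydrogens", {
  for (s in c("[NH4+]", "[13CH4]", "c1cc[nH]c1", "[O-]S(=O)(=O)[O-]")) {
    m <- canonicalize(s)
    expect_true(m$parse_ok)
    expect_identical(canonicalize(m$smiles_canonical)$smiles_canonical,
                     m$smiles_canonical)
  }
  expect_identical(canonicalize("[NH4+]")$graph$atoms$nH, 4L)
  expect_identical(canonicalize("[13CH4]")$graph$atoms$isotope, 13L)
})

test_that("morgan fingerprints match reference-toolkit structure on anchors", {
  # frozen RDKit (2024.09.2) oracle values: popcounts of distinct-environment
  # sets for radius 3 / 1024 bits
  expect_identical(attr(morgan_fingerprint(canonicalize("C")), "popcount"), 1L)
  bz <- morgan_fingerprint(canonicalize("c1ccccc1"))
  ch <- morgan_fingerprint(canonicalize("C1CCCCC1"))
  expect_identical(attr(bz, "popcount"), 4L)  # rdkit: 4
  expect_identical(attr(ch, "popcount"), 4L)  # rdkit: 4
  expect_false(identical(as.integer(bz), as.integer(ch)))
})

test_that("fingerprints are deterministic and spelling-invariant", {
  set.seed(11)
  for (s in c("CC(C)Cc1ccc(cc1)C(C)C(=O)O", "c1cc(F)ccc1-n1cc(-c2ccc(OC)cc2)nn1")) {
    ref <- canonicalize(s)
    fp_ref <- morgan_fingerprint(ref)
    expect_identical(as.integer(morgan_fingerprint(ref)), as.integer(fp_ref))
    for (i in 1:20) {
      m2 <- canonicalize(synbinder:::random_smiles(ref$graph))
      expect_identical(as.integer(morgan_fingerprint(m2)), as.integer(fp_ref))
    }
  }
})

test_that("fingerprint rejects unparsed molecules and honours config", {
  expect_warning(bad <- canonicalize("C1CC"))
  expect_error(morgan_fingerprint(bad), "failed to parse")
  fp <- morgan_fingerprint(canonicalize("CCO"), fingerprint_config(2, 256))
  expect_length(fp, 256L)
  expect_identical(attr(fp, "popcount"), sum(as.integer(fp) == 1L))
})

test_that("tanimoto follows its definition, symmetry and edge rules", {
  a <- fp_from_bits(c(1, 2)); b <- fp_from_bits(c(2, 3))
  expect_equal(tanimoto(a, b), 1 / 3)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(fp_from_bits(1), fp_from_bits(2)), 0)
  expect_equal(tanimoto(fp_from_bits(integer(0)), fp_from_bits(integer(0))), 0)
  expect_error(tanimoto(fp_from_bits(1, 16), fp_from_bits(1, 32)), "length")
  set.seed(3)
  for (i in 1:50) {
    x <- fp_from_bits(sample(64, sample(0:20, 1)), 64)
    y <- fp_from_bits(sample(64, sample(0:20, 1)), 64)
    expect_identical(tanimoto(x, y), tanimoto(y, x))
  }
})

test_that("descriptor panel matches hand-computable anchors and flags NAs", {
  d <- compute_descriptors(canonicalize("CCO"))
  expect_equal(d[["MolWt"]], 2 * 12.011 + 6 * 1.008 + 15.999, tolerance = 1e-9)
  expect_equal(d[["HeavyAtomCount"]], 3)
  expect_equal(d[["NumHDonors"]], 1)
  expect_equal(d[["nRings"]], 0)
  expect_identical(as.numeric(compute_descriptors(canonicalize("CCO"))),
                   as.numeric(d))
  # single atom: distance-based descriptors undefined, flagged missing
  d1 <- compute_descriptors(canonicalize("C"))
  expect_true(is.na(d1[["Chi1"]]))
  expect_true(attr(d1, "missing")[["Chi1"]])
  expect_false(anyNA(d1[c("MolWt", "HeavyAtomCount")]))
  # benzene: aromatic and ring counting
  db <- compute_descriptors(canonicalize("c1ccccc1"))
  expect_equal(db[["AromaticAtomCount"]], 6)
  expect_equal(db[["nRings"]], 1)
  expect_equal(db[["WienerIndex"]], 27)  # closed form for C6 cycle
})

test_that("feature matrix has fingerprint and descriptor blocks with provenance", {
  mols <- canonicalize_all(c("CCO", "CCN", "c1ccccc1", "CC(=O)O", "CCCC",
                             "c1ccncc1", "CCOC", "CC(C)C", "C1CCCC1", "CCS"))
  fm <- build_feature_matrix(mols)
  expect_identical(dim(fm$x), c(10L, 1024L + 30L - length(fm$dropped)))
  expect_identical(fm$provenance$column, colnames(fm$x))
  desc_cols <- fm$provenance$column[fm$provenance$block == "descriptor"]
  mu <- colMeans(fm$x[, desc_cols, drop = FALSE])
  expect_true(all(abs(mu) < 1e-9))
  # descriptor missing for one compound -> its column dropped and logged
  mols1 <- canonicalize_all(c("C", "CCO", "CCN"))  # "C" has NA Chi1 etc.
  fm1 <- build_feature_matrix(mols1)
  expect_true("Chi1" %in% fm1$dropped)
  expect_false("Chi1" %in% fm1$provenance$source)
  # column order deterministic
  fm2 <- build_feature_matrix(mols)
  expect_identical(colnames(fm$x), colnames(fm2$x))
  expect_error(build_feature_matrix(list()), "empty")
})

test_that("a fitted feature transform applies unchanged to new molecules", {
  train <- canonicalize_all(c("CCO", "CCN", "c1ccccc1", "CC(=O)O", "CCCC"))
  fm <- build_feature_matrix(train)
  x_new <- apply_feature_transform(fm$transform, train)
  expect_equal(unname(x_new), unname(fm$x), tolerance = 1e-12)
  other <- canonicalize_all(c("CCCO", "c1ccoc1"))
  x2 <- apply_feature_transform(fm$transform, other)
  expect_identical(colnames(x2), colnames(fm$x))
})
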