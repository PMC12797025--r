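test_that("generated libraries are valid, tagged and deterministic", {
  cfg <- synthetic_config(n_compounds = 120L, alt_fraction = 0.25, seed = 19L)
  lib <- generate_library(cfg)
  expect_identical(nrow(lib), 120L)
  expect_true(all(vapply(attr(lib, "molecules"),
                         function(m) isTRUE(m$parse_ok), logical(1))))
  expect_identical(sum(lib$chemotype == "A"), 30L)
  expect_identical(generate_library(cfg)[, 1:3], lib[, 1:3])
  # different seed, different library
  lib2 <- generate_library(synthetic_config(n_compounds = 120L,
                                            alt_fraction = 0.25, seed = 20L))
  expect_false(identical(lib$smiles, lib2$smiles))
  # infeasible request errors
  expect_error(generate_library(synthetic_config(n_compounds = 60000L,
                                                 alt_fraction = 0)),
               "combinations exist")
})

test_that("same-scaffold pairs are more similar than cross-scaffold pairs", {
  lib <- generate_library(synthetic_config(n_compounds = 120L, seed = 23L))
  mols <- attr(lib, "molecules")
  fps <- lapply(mols, morgan_fingerprint)
  set.seed(1)
  idx <- t(combn(120, 2))
  idx <- idx[sample(nrow(idx), 400), ]
  sims <- apply(idx, 1, function(p) tanimoto(fps[[p[1]]], fps[[p[2]]]))
  same <- lib$chemotype[idx[, 1]] == lib$chemotype[idx[, 2]]
  expect_gt(mean(sims[same]), mean(sims[!same]))
})

test_that("ground-truth Ki follows the latent closed form", {
  cfg <- synthetic_config(noise_sd_log10 = 0, seed = 2L)
  # the parent scaffold itself: similarity 1 by construction
  parent <- canonicalize(unname(default_reference_smiles())[1], id = "parent")
  m <- assign_ground_truth_ki(list(parent), cfg)
  expect_equal(m$similarity, 1)
  expect_equal(m$ki_nM, 10^(3.0 - 2.5), tolerance = 1e-12)  # ~3.16 nM: binder
  expect_identical(label_from_ki(m$ki_nM, m$no_binding), "binder")
  # similarity 0 at zero slope: Ki = 10^intercept = 1000 nM, a non-binder
  cfg0 <- synthetic_config(noise_sd_log10 = 0, slope_per_similarity = 0, seed = 2L)
  m0 <- assign_ground_truth_ki(list(parent), cfg0)
  expect_equal(m0$ki_nM, 1000)
  expect_identical(label_from_ki(m0$ki_nM, m0$no_binding), "non-binder")
  # noise-free Ki is monotone non-increasing in similarity
  lib <- generate_library(synthetic_config(n_compounds = 60L, seed = 3L))
  mm <- assign_ground_truth_ki(attr(lib, "molecules"), cfg)
  ki_eff <- ifelse(mm$no_binding, Inf, mm$ki_nM)
  o <- order(mm$similarity)
  expect_true(all(diff(ki_eff[o]) <= 1e-9))
})

test_that("study datasets reproduce the target shape", {
  ds <- fixture_study()
  expect_identical(nrow(ds), 315L)
  expect_identical(as.integer(table(ds$chemotype)[c("V", "M", "Z")]),
                   c(138L, 121L, 56L))
  bf <- attr(ds, "binder_fraction")
  expect_gte(bf, 0.13); expect_lte(bf, 0.27)
  # censoring conserved: censored records are never binders
  expect_true(all(ds$label[ds$no_binding] == "non-binder"))
  expect_true(all(is.na(ds$ki_nM) == ds$no_binding))
  # same seed reproduces the dataset exactly
  ds2 <- make_study_dataset(synthetic_config(seed = 42L))
  expect_identical(ds, ds2)
})

test_that("the calibrated binder rate holds across seeds and at zero slope", {
  bf <- vapply(101:106, function(s)
    attr(make_study_dataset(synthetic_config(n_compounds = 150L, seed = s)),
         "binder_fraction"), numeric(1))
  expect_true(all(abs(bf - 0.20) <= 0.07))
  ds0 <- make_study_dataset(synthetic_config(n_compounds = 150L, seed = 107L,
                                             slope_per_similarity = 0))
  expect_gte(attr(ds0, "binder_fraction"), 0.1)  # labels exist without signal
  # and the labels carry no structural signal: similarity does not separate
  sims_b <- ds0$similarity[ds0$label == "binder"]
  sims_n <- ds0$similarity[ds0$label == "non-binder"]
  expect_gt(t.test(sims_b, sims_n)$p.value, 0.001)
})

test_that("study tables round-trip through the pipeline text format", {
  ds <- make_study_dataset(synthetic_config(n_compounds = 60L, seed = 31L))
  path <- tempfile(fileext = ".tsv")
  write_compound_table(ds, path)
  back <- read_compound_table(path)
  expect_identical(back$id, ds$id)
  expect_identical(back$label, ds$label)
  expect_equal(back$ki_nM, ds$ki_nM, tolerance = 1e-6)
})
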