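# profiles are plain data.frames, so selection logic is tested on
# constructed tables; chemotype assignment is tested on real molecules
make_profiles <- function(n, seed = 1, alt_frac = 0.25) {
  set.seed(seed)
  n_alt <- round(n * alt_frac)
  sims <- rbind(
    matrix(runif(3 * (n - n_alt), 0.05, 1), n - n_alt, 3),
    matrix(runif(3 * n_alt, 0, 0.19), n_alt, 3))
  dimnames(sims) <- list(NULL, c("sim_R1", "sim_R2", "sim_R3"))
  nearest <- apply(sims, 1, which.max)
  data.frame(id = sprintf("q%04d", seq_len(n)), sims,
             nearest_reference = c("R1", "R2", "R3")[nearest],
             nearest_score = sims[cbind(seq_len(n), nearest)],
             is_alternative = apply(sims < 0.2, 1, all),
             stringsAsFactors = FALSE, check.names = FALSE)
}

test_that("chemotype assignment finds the nearest reference with first-wins ties", {
  refs <- reference_set(c("c1ccccc1", "C1CCCCC1", "CCO"),
                        c("aryl", "cyclo", "alcohol"))
  mols <- canonicalize_all(c("c1ccccc1", "C1CCCCC1", "CCCO"))
  prof <- assign_chemotype(mols, refs)
  expect_identical(prof$nearest_reference[1], "aryl")
  expect_equal(prof$nearest_score[1], 1)
  expect_identical(prof$nearest_reference[2], "cyclo")
  # exact tie: a molecule equidistant from two identical references
  refs2 <- reference_set(c("CCO", "CCO"), c("first", "second"))
  p2 <- assign_chemotype(canonicalize_all("CCO"), refs2)
  expect_identical(p2$nearest_reference, "first")
  # alternative flag: all three scores below the cutoff
  p3 <- data.frame(sim_a = 0.15, sim_b = 0.12, sim_c = 0.08)
  expect_true(all(as.numeric(p3) < 0.2))
  prof_alt <- assign_chemotype(canonicalize_all("OCC(O)CO"), refs)
  expect_identical(prof_alt$is_alternative,
                   unname(apply(prof_alt[, grep("^sim_", names(prof_alt))] < 0.2,
                                1, all)))
})

test_that("similarity histograms conserve counts with the stated edge rule", {
  prof <- make_profiles(100)
  h <- similarity_histogram(prof, bin_width = 0.1)
  expect_true(all(colSums(h$counts) == 100))
  # all-zero scores land in the first bin
  p0 <- make_profiles(10)
  p0[, c("sim_R1", "sim_R2", "sim_R3")] <- 0
  h0 <- similarity_histogram(p0, 0.1)
  expect_true(all(h0$counts[1, ] == 10))
  expect_true(all(h0$counts[-1, ] == 0))
  # a perfect score is counted once, in the final (closed) bin
  p1 <- make_profiles(5)
  p1$sim_R1[1] <- 1.0
  h1 <- similarity_histogram(p1, 0.25)
  expect_identical(sum(h1$counts[, "sim_R1"]), 5L)
  expect_gte(h1$counts[nrow(h1$counts), "sim_R1"], 1L)
  # overlay ticks returned per tagged subset
  h2 <- similarity_histogram(prof, 0.1, overlays = list(train = prof$id[1:10]))
  expect_length(h2$ticks$train$sim_R1, 10L)
})

test_that("prospective selection fills both strata exactly and reproducibly", {
  prof <- make_profiles(800, seed = 3)
  cfg <- curation_config(n_high = 14, n_low = 16, seed = 21)
  sel <- select_prospective(prof, cfg)
  expect_identical(nrow(sel), 30L)
  expect_identical(anyDuplicated(sel$id), 0L)
  expect_identical(sum(sel$selection == "low_similarity"), 16L)
  low <- sel[sel$selection == "low_similarity", ]
  expect_true(all(low$sim_R1 < 0.2 & low$sim_R2 < 0.2 & low$sim_R3 < 0.2))
  expect_identical(select_prospective(prof, cfg), sel)
  # round-robin optimality: every high pick outranks unselected compounds
  # of its own chemotype
  high <- sel[sel$selection == "high_similarity", ]
  rest <- prof[!(prof$id %in% sel$id) & !prof$is_alternative, ]
  for (ref in unique(high$nearest_reference)) {
    hmin <- min(high$nearest_score[high$nearest_reference == ref])
    rmax <- max(c(-Inf, rest$nearest_score[rest$nearest_reference == ref]))
    expect_gte(hmin, rmax)
  }
})

test_that("selection reports shortfalls by stratum", {
  prof <- make_profiles(50, seed = 5)
  prof[, c("sim_R1", "sim_R2", "sim_R3")] <-
    pmax(prof$sim_R1, 0.5)  # no alternatives at all
  prof$is_alternative <- FALSE
  expect_error(select_prospective(prof, curation_config(n_high = 5, n_low = 3)),
               "low-similarity stratum")
  prof2 <- make_profiles(10, seed = 6)
  expect_error(select_prospective(prof2, curation_config(n_high = 40, n_low = 0)),
               "high-similarity stratum")
})
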