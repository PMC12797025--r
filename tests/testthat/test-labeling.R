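test_that("Ki labeling follows the 25 nM rule with strict threshold and censoring", {
  cfg <- labeling_config()
  expect_identical(label_from_ki(5, FALSE, cfg), "binder")
  expect_identical(label_from_ki(100, FALSE, cfg), "non-binder")
  expect_identical(label_from_ki(NA, TRUE, cfg), "non-binder")
  expect_identical(label_from_ki(25, FALSE, cfg), "non-binder")  # boundary
  expect_identical(label_from_ki(c(1, 24.9, 25.1, NA), c(FALSE, FALSE, FALSE, TRUE)),
                   c("binder", "binder", "non-binder", "non-binder"))
  expect_error(label_from_ki(NA, FALSE, cfg), "neither")
  expect_error(label_from_ki(500, TRUE, cfg), "censor limit")
  expect_error(labeling_config(binder_threshold_nM = 2000), "binder_threshold")
})

test_that("labeling is monotone in Ki", {
  set.seed(5)
  ki <- sort(runif(200, 0.1, 2000))
  lab <- label_from_ki(ki, FALSE)
  # once non-binder, never binder again at higher Ki
  expect_true(all(diff(lab == "binder") <= 0))
})

test_that("stratified split reproduces the study allocation: 44 test, 9 binders", {
  labels <- rep(c("binder", "non-binder"), c(64, 251))
  ids <- sprintf("c%03d", seq_along(labels))
  sp <- stratified_split(ids, labels, test_fraction = 44 / 315, seed = 1L)
  expect_length(sp$test_ids, 44L)
  expect_identical(sum(labels[match(sp$test_ids, ids)] == "binder"), 9L)
  # 100 records, 20 binders, fraction 0.2 -> 20 test with 4 binders
  l2 <- rep(c("binder", "non-binder"), c(20, 80))
  i2 <- sprintf("x%03d", 1:100)
  sp2 <- stratified_split(i2, l2, 0.2, seed = 3L)
  expect_length(sp2$test_ids, 20L)
  expect_identical(sum(l2[match(sp2$test_ids, i2)] == "binder"), 4L)
})

test_that("splits are deterministic, partition the ids, and stay proportional", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(50:400, 1)
    nb <- sample(5:(n %/% 3), 1)
    labels <- sample(rep(c("binder", "non-binder"), c(nb, n - nb)))
    ids <- sprintf("m%04d", seq_len(n))
    frac <- runif(1, 0.1, 0.4)
    sp <- stratified_split(ids, labels, frac, seed = i)
    expect_identical(stratified_split(ids, labels, frac, seed = i), sp)
    expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
    expect_setequal(c(sp$train_ids, sp$test_ids), ids)
    bf_test <- mean(labels[match(sp$test_ids, ids)] == "binder")
    expect_lte(abs(bf_test - nb / n), 1 / length(sp$test_ids) + 1e-12)
  }
  expect_error(stratified_split(c("a", "b", "c"), c("binder", "non-binder", "non-binder"),
                                0.3, 1), "fewer than 2")
})

test_that("split manifests round-trip through disk", {
  labels <- rep(c("binder", "non-binder"), c(10, 40))
  ids <- sprintf("c%02d", 1:50)
  sp <- stratified_split(ids, labels, 0.2, seed = 17L)
  path <- tempfile(fileext = ".tsv")
  write_split_manifest(sp, path)
  sp2 <- read_split_manifest(path)
  expect_identical(sort(sp2$train_ids), sort(sp$train_ids))
  expect_identical(sort(sp2$test_ids), sort(sp$test_ids))
  expect_identical(sp2$seed, sp$seed)
  expect_equal(sp2$test_fraction, sp$test_fraction)
})

test_that("compound tables round-trip and drop unparsable rows with a count", {
  df <- data.frame(id = c("a", "b", "c", "d"),
                   smiles = c("CCO", "C1CC", "c1ccccc1", "CC(=O)O"),
                   ki_nM = c(5, 10, NA, 400),
                   no_binding = c(FALSE, FALSE, TRUE, FALSE))
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  w <- capture_warnings(tab <- read_compound_table(path))
  expect_true(any(grepl("1 compound", w)))
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$label, c("binder", "non-binder", "non-binder"))
  expect_length(attr(tab, "molecules"), 3L)
})
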