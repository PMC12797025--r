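# Model selection on constructed numeric feature matrices. A fake
# feature_matrix wrapper lets the CV machinery run on arbitrary matrices:
# the "descriptor" block is empty so per-fold standardization is a no-op on
# the binary features.
fake_fm <- function(x) {
  structure(list(
    x = x,
    provenance = data.frame(column = colnames(x), block = "fingerprint",
                            source = colnames(x)),
    transform = NULL, dropped = character(0),
    raw = list(fingerprints = x,
               descriptors = matrix(numeric(0), nrow(x), 0))),
    class = "feature_matrix")
}

make_separable <- function(n = 80, p = 12, seed = 1) {
  set.seed(seed)
  y <- rep(c("binder", "non-binder"), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  x[, 1] <- ifelse(y == "binder", 3, -3) + rnorm(n, 0, 0.1)
  colnames(x) <- sprintf("f%02d", seq_len(p))
  rownames(x) <- sprintf("r%03d", seq_len(n))
  list(x = x, y = y)
}

test_that("cross-validation separates linearly separable data for every family", {
  d <- make_separable()
  fm <- fake_fm(d$x)
  for (fam in c("logistic_regression", "k_nearest_neighbors", "decision_tree")) {
    cv <- cross_validate(fm, d$y, fam, k_folds = 5, seed = 2)
    expect_gt(cv$macro_f1_mean, 0.95, label = fam)
    expect_true(all(cv$per_fold$macro_f1 >= 0) && all(cv$per_fold$macro_f1 <= 1))
    expect_equal(cv$macro_f1_mean, mean(cv$per_fold$macro_f1))
  }
})

test_that("cross-validation is deterministic and near-chance on permuted labels", {
  d <- make_separable(n = 60)
  fm <- fake_fm(d$x)
  cv1 <- cross_validate(fm, d$y, "logistic_regression", k_folds = 5, seed = 9)
  cv2 <- cross_validate(fm, d$y, "logistic_regression", k_folds = 5, seed = 9)
  expect_identical(cv1, cv2)
  # Monte-Carlo null: labels independent of features
  set.seed(31)
  nulls <- vapply(1:20, function(i) {
    y <- sample(rep(c("binder", "non-binder"), 30))
    x <- matrix(rnorm(60 * 10), 60, 10,
                dimnames = list(NULL, sprintf("f%02d", 1:10)))
    cross_validate(fake_fm(x), y, "logistic_regression", k_folds = 5,
                   seed = i)$macro_f1_mean
  }, numeric(1))
  expect_lt(abs(mean(nulls) - 0.5), 0.1)
})

test_that("fold preprocessing statistics come from training rows only", {
  set.seed(4)
  x <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  mols_desc <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("d1", "d2")))
  fm <- structure(list(x = cbind(x, mols_desc),
                       raw = list(fingerprints = x, descriptors = mols_desc)),
                  class = "feature_matrix")
  tr <- rep(c(TRUE, FALSE), c(30, 10))
  prep1 <- synbinder:::fold_features(fm, tr)
  # perturb validation-row descriptors: fitted statistics must not move
  fm2 <- fm
  fm2$raw$descriptors[!tr, ] <- fm2$raw$descriptors[!tr, ] + 100
  prep2 <- synbinder:::fold_features(fm2, tr)
  expect_identical(prep1$stats, prep2$stats)
  expect_identical(prep1$x[tr, ], prep2$x[tr, ])
})

test_that("feature selection finds a planted predictive column among noise", {
  set.seed(6)
  n <- 90
  y <- rep(c("binder", "non-binder"), length.out = n)
  x <- matrix(rnorm(n * 101), n, 101,
              dimnames = list(NULL, c("signal", sprintf("noise%03d", 1:100))))
  x[, "signal"] <- ifelse(y == "binder", 2, -2) + rnorm(n, 0, 0.3)
  sel <- select_features(x, y, seed = 3)
  expect_true("signal" %in% sel$ids)
  expect_identical(sel$ids[1], "signal")  # strongest signal enters first
})

test_that("feature selection drops duplicates and refuses all-constant input", {
  set.seed(8)
  n <- 60
  y <- rep(c("binder", "non-binder"), length.out = n)
  sig <- ifelse(y == "binder", 1.5, -1.5) + rnorm(n, 0, 0.4)
  x <- cbind(s1 = sig, s2 = sig, n1 = rnorm(n), n2 = rnorm(n))
  sel <- select_features(x, y, seed = 1)
  expect_lte(sum(c("s1", "s2") %in% sel$ids), 1L)  # at most one duplicate kept
  xc <- matrix(1, n, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_warning(sel0 <- select_features(xc, y), "near-constant")
  expect_length(sel0$ids, 0L)
})

test_that("tune_and_train prefers logistic regression on linear-logit ground truth", {
  wins <- 0L
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 120; p <- 15
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%02d", 1:p)))
    beta <- c(2.5, -2, 1.5, rep(0, p - 3))
    pr <- plogis(x %*% beta)
    y <- ifelse(runif(n) < pr, "binder", "non-binder")
    if (length(unique(y)) < 2) next
    model <- tune_and_train(fake_fm(x), y, k_folds = 5, seed = s, select = FALSE)
    if (model$family == "logistic_regression") wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})

test_that("tuning is deterministic and works with a single-configuration grid", {
  d <- make_separable(n = 70, seed = 5)
  fm <- fake_fm(d$x)
  fams <- default_model_families("logistic_regression")
  fams$logistic_regression$grid <-
    fams$logistic_regression$grid[3, , drop = FALSE]
  m1 <- tune_and_train(fm, d$y, fams, k_folds = 5, seed = 4, select = FALSE)
  m2 <- tune_and_train(fm, d$y, fams, k_folds = 5, seed = 4, select = FALSE)
  expect_identical(m1$hyper, m2$hyper)
  expect_identical(m1$selected_feature_ids, m2$selected_feature_ids)
  expect_identical(predict(m1, d$x), predict(m2, d$x))
  expect_error(tune_and_train(fm, rep("binder", 70)), "single-class")
})

test_that("prediction recovers training labels, is row-order invariant, and validates columns", {
  d <- make_separable(n = 50, seed = 11)
  model <- tune_and_train(fake_fm(d$x), d$y,
                          default_model_families("k_nearest_neighbors"),
                          k_folds = 5, seed = 2, select = FALSE)
  pred <- predict(model, d$x)
  expect_identical(pred$label, d$y)  # includes a 1-NN-style exact match case
  perm <- sample(nrow(d$x))
  pred_perm <- predict(model, d$x[perm, ])
  expect_equal(pred_perm$score, pred$score[perm])
  expect_error(predict(model, d$x[, 1:3]), "missing feature")
})

test_that("model bundles serialize to portable JSON", {
  d <- make_separable(n = 40, seed = 13)
  model <- tune_and_train(fake_fm(d$x), d$y,
                          default_model_families("logistic_regression"),
                          k_folds = 4, seed = 1, select = FALSE)
  path <- tempfile(fileext = ".json")
  # transform is NULL for matrix-backed fits; bundle the fitted parts only
  model$transform <- list(cfg = fingerprint_config(),
                          descriptor_keep = character(0),
                          mu = numeric(0), sd = numeric(0))
  save_model_bundle(model, path)
  bundle <- jsonlite::read_json(path)
  expect_identical(bundle$family, "logistic_regression")
  expect_true(all(c("hyper", "selected_feature_ids", "fitted") %in% names(bundle)))
})
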