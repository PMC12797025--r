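test_that("published binder row reproduces: F1(0.47, 0.89) rounds to 0.62", {
  expect_identical(round(f1_score(0.47, 0.89), 2), 0.62)
})

test_that("prospective confusion counts reproduce the printed aggregate metrics", {
  # TP=7 FP=6 FN=2 TN=15 over 30 predictions
  y_true <- rep(c("binder", "binder", "non-binder", "non-binder"),
                c(7, 2, 6, 15))
  y_pred <- rep(c("binder", "non-binder", "binder", "non-binder"),
                c(7, 2, 6, 15))
  r <- classification_report(y_true, y_pred)
  expect_identical(round(r$per_class$f1[r$per_class$class == "non-binder"], 2), 0.79)
  expect_identical(round(r$macro[["f1"]], 2), 0.71)
  expect_identical(round(r$weighted[["f1"]], 2), 0.74)
})

test_that("perfect and degenerate predictions behave per definition", {
  y <- rep(c("binder", "non-binder"), c(4, 8))
  perfect <- classification_report(y, y)
  expect_equal(perfect$accuracy, 1)
  expect_equal(unname(perfect$macro), c(1, 1, 1))
  expect_false(perfect$zero_division)
  # nothing predicted positive: precision defined as 0 and flagged
  allneg <- classification_report(y, rep("non-binder", 12))
  expect_equal(allneg$per_class$precision[allneg$per_class$class == "binder"], 0)
  expect_true(allneg$zero_division)
  expect_equal(allneg$macro[["f1"]],
               mean(c(0, f1_score(8 / 12, 1))))
  expect_error(classification_report(character(0), character(0)), "empty")
  expect_error(classification_report(c("binder"), c("active")), "unknown")
  expect_error(classification_report(c("binder"), c("binder", "binder")),
               "length")
})

test_that("report agrees exactly with the confusion-matrix oracle on random labels", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(2:60, 1)
    y_true <- sample(c("binder", "non-binder"), n, replace = TRUE)
    y_pred <- sample(c("binder", "non-binder"), n, replace = TRUE)
    r <- classification_report(y_true, y_pred)
    o <- report_oracle(y_true, y_pred)
    expect_identical(r$accuracy, o$accuracy)
    expect_identical(r$macro[["f1"]], o$macro_f1)
    expect_identical(r$weighted[["f1"]], o$weighted_f1)
    expect_identical(r$per_class$precision[r$per_class$class == "binder"],
                     o$per_class$binder[["precision"]])
  }
})

test_that("macro F1 is invariant under class relabeling; weighted follows support", {
  swap <- function(x) ifelse(x == "binder", "non-binder", "binder")
  set.seed(21)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    y_true <- sample(c("binder", "non-binder"), n, replace = TRUE)
    y_pred <- sample(c("binder", "non-binder"), n, replace = TRUE)
    a <- classification_report(y_true, y_pred)
    b <- classification_report(swap(y_true), swap(y_pred))
    expect_equal(a$macro[["f1"]], b$macro[["f1"]])
    expect_equal(a$accuracy, b$accuracy)
    o <- report_oracle(swap(y_true), swap(y_pred))
    expect_equal(b$weighted[["f1"]], o$weighted_f1)
  }
})

test_that("the text report uses the standard table layout", {
  y <- rep(c("binder", "non-binder"), c(3, 9))
  p <- rep(c("binder", "non-binder", "binder", "non-binder"), c(2, 1, 1, 8))
  lines <- format_class_report(classification_report(y, p))
  expect_match(lines[1], "Precision\\s+Recall\\s+F1")
  expect_match(lines[2], "^Non-binder")
  expect_match(lines[3], "^Binder")
  expect_match(lines[4], "^Accuracy")
  expect_match(lines[5], "^Macro")
  expect_match(lines[6], "^Weighted")
})
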