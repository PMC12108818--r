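# One-vs-rest classification metrics.

test_that("the published test confusion matrix reproduces the published
           per-class and average metrics", {
  cm <- matrix(c(90, 0, 0,  0, 45, 4,  0, 2, 40), 3, 3, byrow = TRUE,
               dimnames = list(true = c("Normal", "ODE", "PPE"),
                               pred = c("Normal", "ODE", "PPE")))
  mt <- classification_metrics(cm)
  norm <- mt$per_class[1, ]
  expect_equal(unlist(norm[c("accuracy", "precision", "recall",
                             "specificity")]), rep(1, 4),
               ignore_attr = TRUE)
  ode <- mt$per_class[2, ]
  expect_equal(round(unlist(ode[c("accuracy", "precision", "recall",
                                  "specificity")]), 4),
               c(0.9669, 0.9574, 0.9184, 0.9848), ignore_attr = TRUE)
  ppe <- mt$per_class[3, ]
  expect_equal(round(unlist(ppe[c("accuracy", "precision", "recall",
                                  "specificity")]), 4),
               c(0.9669, 0.9091, 0.9524, 0.9712), ignore_attr = TRUE)
  # the table's average row follows the rounded-then-averaged convention
  expect_equal(round(unname(mt$macro_printed), 4),
               c(0.9779, 0.9555, 0.9569, 0.9853))
  # the exact macro agrees except in the final specificity digit
  expect_equal(round(unname(mt$macro[1:3]), 4), c(0.9779, 0.9555, 0.9569))
  expect_lt(abs(mt$macro[["specificity"]] - 0.9853), 1e-4)
  # pooled accuracy is the trace ratio, distinct from the macro headline
  expect_equal(mt$pooled_accuracy, 175 / 181)
})

test_that("hand-computed binary case and degenerate cases", {
  # [[8,2],[1,9]] row-major
  bin <- classification_metrics(matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE))
  c0 <- bin$per_class[1, ]
  expect_equal(c0$accuracy, 0.85)
  expect_equal(c0$precision, 8 / 9)
  expect_equal(c0$recall, 0.8)
  expect_equal(c0$specificity, 0.9)
  # perfect diagonal: everything 1
  expect_true(all(unlist(classification_metrics(diag(c(5, 3, 2)))$macro) == 1))
  expect_error(classification_metrics(matrix(0, 3, 3)), "empty")
  # a never-predicted class yields an undefined precision, flagged
  cm <- matrix(c(3, 0, 0,  2, 0, 0,  0, 0, 4), 3, 3, byrow = TRUE)
  mt <- classification_metrics(cm)
  expect_true(is.na(mt$per_class$precision[2]))
  expect_true("class1" %in% mt$undefined)
  # zero-support class excluded from the macro
  cm2 <- matrix(c(3, 1, 0,  0, 0, 0,  0, 0, 4), 3, 3, byrow = TRUE)
  mt2 <- classification_metrics(cm2)
  expect_equal(mt2$excluded_from_macro, "class1")
  expect_false(is.na(mt2$macro[["accuracy"]]))
})

test_that("metrics agree with an independent loop-based implementation
           on random confusion matrices", {
  set.seed(41)
  for (k in 1:100) {
    K <- sample(2:5, 1)
    n <- sample(20:100, 1)
    y_true <- sample(0:(K - 1), n, replace = TRUE)
    y_pred <- sample(0:(K - 1), n, replace = TRUE)
    cm <- confusion_matrix(y_true, y_pred, classes = paste0("c", 1:K))
    mt <- classification_metrics(cm)
    ref <- brute_ovr_metrics(y_true, y_pred, K)
    got <- as.matrix(mt$per_class[c("accuracy", "precision", "recall",
                                    "specificity")])
    expect_equal(unname(got), unname(ref), tolerance = 1e-9)
  }
})

test_that("macro one-vs-rest accuracy dominates pooled accuracy for
           K > 2 with off-diagonal mass", {
  set.seed(42)
  for (k in 1:25) {
    K <- sample(3:5, 1)
    cm <- matrix(sample(0:20, K * K, replace = TRUE), K, K)
    diag(cm) <- diag(cm) + 5
    if (sum(cm) - sum(diag(cm)) == 0) next
    mt <- classification_metrics(cm)
    expect_gte(mt$macro[["accuracy"]], mt$pooled_accuracy)
  }
})

test_that("confusion matrices validate inputs and count correctly", {
  cm <- confusion_matrix(c(0, 1, 2, 2), c(0, 1, 2, 2))
  expect_equal(unname(diag(unclass(cm))), c(1L, 1L, 2L))
  expect_equal(unname(rowSums(unclass(cm))), c(1L, 1L, 2L))
  expect_equal(unname(diag(unclass(
    confusion_matrix(c(0, 1), c(1, 0), classes = c("a", "b"))))), c(0L, 0L))
  expect_error(confusion_matrix(c(0, 3), c(0, 1)), "range")
  expect_error(confusion_matrix(0:2, 0:1), "length")
  # factor/character labels map through the class set
  cmf <- confusion_matrix(c("ODE", "PPE"), c("ODE", "ODE"))
  expect_equal(unclass(cmf)["PPE", "ODE"], 1L)
  # tidy/glance surfaces
  mt <- classification_metrics(cm)
  td <- tidy(mt)
  expect_equal(nrow(td), 4)
  expect_equal(td$class[4], "macro")
  expect_equal(glance(mt)$pooled_accuracy, 1)
})
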