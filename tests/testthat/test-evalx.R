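test_that("confusion counts are exact", {
  t1 <- rep(c("crystal", "other"), c(3, 7))
  expect_equal(unclass(confusion(t1, t1))[c("tp", "fp", "tn", "fn")],
               list(tp = 3, fp = 0, tn = 7, fn = 0))
  allc <- confusion(rep("other", 10), rep("crystal", 10))
  expect_equal(c(allc$tp, allc$fp, allc$tn, allc$fn), c(0, 10, 0, 0))
  expect_error(confusion(t1, t1[1:3]), class = "dropvision_error_shape")
  expect_error(confusion(c("crystal", "maybe"), c("other", "other")),
               class = "dropvision_error_unknown_label")
})

test_that("metrics follow their formulas on a worked example", {
  truth <- rep(c("crystal", "other"), c(10, 100))
  pred <- c(rep("crystal", 9), "other",            # 9 TP, 1 FN
            rep("crystal", 10), rep("other", 90))  # 10 FP, 90 TN
  mr <- cls_metrics(confusion(truth, pred))
  expect_equal(mr$recall, 0.9)
  expect_equal(mr$specificity, 0.9)
  expect_equal(mr$balanced_accuracy, 0.9)
  expect_equal(mr$precision, 9 / 19)
  expect_equal(mr$accuracy, 99 / 110)
})

test_that("a constant predictor exposes the accuracy trap", {
  truth <- rep(c("crystal", "other"), c(5, 95))
  mr <- cls_metrics(confusion(truth, rep("other", 100)))
  expect_equal(mr$accuracy, 0.95)
  expect_equal(mr$balanced_accuracy, 0.5)
  expect_equal(mr$recall, 0)
  expect_equal(mr$f1, 0)   # TP = 0 with misses: zero, not undefined
})

test_that("degenerate divisions are undefined, never zero", {
  mr <- cls_metrics(confusion(rep("other", 5), rep("other", 5)))
  expect_true(is.na(mr$recall))            # no positives at all
  expect_true(is.na(mr$precision))
  expect_true(is.na(mr$balanced_accuracy))
  expect_true(is.na(mr$f1))                # TP = FP = FN = 0
})

test_that("balanced accuracy equals accuracy on balanced sets and is scale-free", {
  set.seed(8)
  truth <- rep(c("crystal", "other"), each = 40)
  pred <- sample(c("crystal", "other"), 80, replace = TRUE)
  mr <- cls_metrics(confusion(truth, pred))
  expect_equal(mr$balanced_accuracy, mr$accuracy)
  # scaling both classes by a common factor leaves balanced accuracy unchanged
  mr3 <- cls_metrics(confusion(rep(truth, 3), rep(pred, 3)))
  expect_equal(mr3$balanced_accuracy, mr$balanced_accuracy)
})

test_that("metrics agree with a per-element tally oracle on random matrices", {
  set.seed(123)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    truth <- sample(c("crystal", "other"), n, replace = TRUE)
    pred <- sample(c("crystal", "other"), n, replace = TRUE)
    mr <- cls_metrics(confusion(truth, pred))
    # formula-free oracle: count element by element
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (j in seq_len(n)) {
      if (truth[j] == "crystal" && pred[j] == "crystal") tp <- tp + 1
      else if (truth[j] == "other" && pred[j] == "crystal") fp <- fp + 1
      else if (truth[j] == "other" && pred[j] == "other") tn <- tn + 1
      else fn <- fn + 1
    }
    if (tp + fn > 0) expect_equal(mr$recall, tp / (tp + fn))
    if (tp + fp > 0) expect_equal(mr$precision, tp / (tp + fp))
    expect_equal(mr$accuracy, (tp + tn) / n)
    if (tp + fn > 0 && tn + fp > 0) {
      expect_equal(mr$balanced_accuracy,
                   (tp / (tp + fn) + tn / (tn + fp)) / 2)
    }
  }
})

test_that("per-type recall matches a filtered recomputation", {
  m <- make_manifest(12, modalities = "visible")
  m$binary_label <- rep(c("crystal", "other"), c(9, 3))
  m$crystal_type <- c(rep("microcrystals", 4), rep("needles_clusters", 3),
                      rep("single_crystal", 2), rep(NA, 3))
  pred <- c("crystal", "crystal", "crystal", "other",   # micro 3/4
            "crystal", "crystal", "crystal",            # needles 3/3
            "other", "other",                           # single 0/2
            "other", "other", "other")
  tab <- recall_by_type(m, pred)
  expect_equal(tab$recall[tab$crystal_type == "microcrystals"], 0.75)
  expect_equal(tab$recall[tab$crystal_type == "needles_clusters"], 1)
  expect_equal(tab$recall[tab$crystal_type == "single_crystal"], 0)
  # independent oracle: filter then recall, per type
  for (ty in tab$crystal_type) {
    sel <- !is.na(m$crystal_type) & m$crystal_type == ty
    expect_equal(tab$recall[tab$crystal_type == ty],
                 mean(pred[sel] == "crystal"))
  }
  # unknown types are quarantined with a warning
  m$crystal_type[1] <- "dendrite"
  expect_warning(tab2 <- recall_by_type(m, pred),
                 class = "dropvision_warning_quarantine")
  expect_equal(nrow(attr(tab2, "quarantine")), 1)
})
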