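test_that("precision/recall/F1 follow their defining ratios", {
  expect_equal(unlist(precision_recall_f1(5, 0, 0)), c(precision = 1, recall = 1, f1 = 1))
  expect_equal(suppressWarnings(unlist(precision_recall_f1(0, 0, 0))),
               c(precision = 0, recall = 0, f1 = 0))
  expect_warning(precision_recall_f1(0, 0, 0), "0/0")
  expect_equal(unlist(precision_recall_f1(3, 1, 1)),
               c(precision = 0.75, recall = 0.75, f1 = 0.75))
  expect_error(precision_recall_f1(-1, 0, 0), "non-negative")
})

test_that("accuracy is the success fraction on the percent scale", {
  expect_equal(accuracy_percent(100, 100), 100)
  expect_equal(accuracy_percent(0, 100), 0)
  expect_equal(accuracy_percent(30, 100), 30)  # 100-trials-per-letter protocol
  expect_error(accuracy_percent(1, 0), "positive")
})

test_that("report handles perfect and degenerate predictions", {
  r <- classification_report(c("A", "B", "A", "C"), c("A", "B", "A", "C"))
  expect_equal(r$accuracy, 1)
  expect_true(all(r$per_class$f1 == 1))
  wrong <- suppressWarnings(classification_report(rep("A", 4), rep("B", 4),
                                                  classes = c("A", "B")))
  expect_equal(wrong$per_class$precision[1], 0)
  expect_equal(wrong$per_class$recall[1], 0)
  expect_equal(wrong$accuracy, 0)
  expect_error(classification_report("A", c("A", "B")), "equal length")
})

test_that("report matches a brute-force confusion enumeration on random labels", {
  classes <- c("a", "b", "c", "d", "e")
  set.seed(77)
  for (rep in 1:25) {
    truth <- sample(classes, 200, replace = TRUE, prob = runif(5))
    pred <- sample(classes, 200, replace = TRUE)
    got <- suppressWarnings(classification_report(truth, pred, classes))
    want <- report_oracle(truth, pred, classes)
    expect_equal(got$per_class$precision, want$per_class$precision)
    expect_equal(got$per_class$recall, want$per_class$recall)
    expect_equal(got$per_class$f1, want$per_class$f1)
    expect_equal(got$per_class$support, unname(want$per_class$support))
    expect_equal(got$accuracy, want$accuracy)
    # standard identities: weighted recall equals overall accuracy;
    # F1 between min and max of precision and recall
    expect_equal(got$weighted[["recall"]], got$accuracy)
    expect_true(all(got$per_class$f1 >=
                      pmin(got$per_class$precision, got$per_class$recall) - 1e-12))
    expect_true(all(got$per_class$f1 <=
                      pmax(got$per_class$precision, got$per_class$recall) + 1e-12))
  }
})

test_that("report generation is pure and CSV export mirrors the table", {
  truth <- c("A", "A", "B", "B", "C")
  pred <- c("A", "B", "B", "B", "C")
  r1 <- classification_report(truth, pred)
  r2 <- classification_report(truth, pred)
  expect_identical(r1, r2)
  path <- file.path(tempdir(), "report.csv")
  write_report_csv(r1, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), 3 + 3)  # per-class rows + accuracy/macro/weighted
  expect_equal(tab$support[1:3], r1$per_class$support)
  out <- capture.output(print(r1))
  expect_true(any(grepl("Precision", out)))
  expect_true(any(grepl("Macro", out)))
})
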