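# Brute-force metric oracle: recompute every quantity by direct counting
# over the (y_true, y_pred) pairs, independently of the package's
# marginalization code.
oracle_metrics <- function(y_true, y_pred, K = 4) {
  n <- length(y_true)
  out <- lapply(seq_len(K) - 1L, function(c) {
    TP <- sum(y_true == c & y_pred == c)
    FP <- sum(y_true != c & y_pred == c)
    FN <- sum(y_true == c & y_pred != c)
    TN <- sum(y_true != c & y_pred != c)
    pre <- if (TP + FP == 0) 0 else TP / (TP + FP)
    sen <- if (TP + FN == 0) 0 else TP / (TP + FN)
    list(Acc = (TP + TN) / n, Pre = pre, Sen = sen,
         Spe = if (TN + FP == 0) 0 else TN / (TN + FP),
         F1 = if (pre + sen == 0) 0 else 2 * pre * sen / (pre + sen))
  })
  list(per_class = out, overall = mean(y_true == y_pred))
}

test_that("confusion matrices count exactly", {
  cm <- confusion_matrix(c(0, 0, 1), c(0, 1, 1))
  expected <- matrix(0L, 4, 4, dimnames = list(true = c("N","P","S1","S2"),
                                               pred = c("N","P","S1","S2")))
  expected[1, 1] <- 1L; expected[1, 2] <- 1L; expected[2, 2] <- 1L
  expect_identical(unclass(cm), expected)

  perfect <- confusion_matrix(0:3, 0:3)
  expect_identical(unname(diag(perfect)), rep(1L, 4))
  expect_identical(sum(perfect) - sum(diag(perfect)), 0L)

  expect_identical(sum(confusion_matrix(integer(0), integer(0))), 0L)
  expect_error(confusion_matrix(c(0, 4), c(0, 1)), "out of range")
})

test_that("the hand-computed one-vs-rest example reproduces exactly", {
  # TP=50, TN=40, FP=5, FN=5 for class N against the rest
  y_true <- c(rep(0, 55), rep(1, 45))
  y_pred <- c(rep(0, 50), rep(1, 5), rep(0, 5), rep(1, 40))
  rep_ <- metrics_report(confusion_matrix(y_true, y_pred))
  n_row <- rep_$per_class[rep_$per_class$class == "N", ]
  expect_equal(n_row$Acc, (50 + 40) / 100)
  expect_equal(n_row$Pre, 50 / 55)
  expect_equal(n_row$Sen, 50 / 55)
  expect_equal(n_row$Spe, 40 / 45)
  expect_equal(n_row$F1,
               2 * (50 / 55) * (50 / 55) / ((50 / 55) + (50 / 55)))
})

test_that("metrics match the brute-force oracle on 100 random label vectors", {
  withr::with_seed(77, {
    for (i in 1:100) {
      n <- sample(5:60, 1)
      y_true <- sample(0:3, n, replace = TRUE)
      y_pred <- sample(0:3, n, replace = TRUE)
      rep_ <- metrics_report(confusion_matrix(y_true, y_pred))
      orc <- oracle_metrics(y_true, y_pred)
      for (c in 1:4) {
        for (m in c("Acc", "Pre", "Sen", "Spe", "F1"))
          expect_equal(rep_$per_class[[m]][c], orc$per_class[[c]][[m]],
                       tolerance = 1e-12)
      }
      expect_equal(rep_$overall_accuracy, orc$overall, tolerance = 1e-12)
    }
  })
})

test_that("perfect predictions give 1.0 everywhere; empty matrices error", {
  y <- rep(0:3, times = c(10, 7, 5, 3))
  rep_ <- metrics_report(confusion_matrix(y, y))
  expect_true(all(as.matrix(rep_$per_class[, c("Acc", "Pre", "Sen", "Spe", "F1")]) == 1))
  expect_identical(rep_$overall_accuracy, 1)
  expect_error(metrics_report(confusion_matrix(integer(0), integer(0))), "empty")
})

test_that("harmonic-mean bound and accuracy identities hold on random draws", {
  withr::with_seed(99, {
    for (i in 1:25) {
      n <- sample(20:80, 1)
      y_true <- sample(0:3, n, replace = TRUE)
      y_pred <- ifelse(runif(n) < 0.6, y_true, sample(0:3, n, replace = TRUE))
      rep_ <- metrics_report(confusion_matrix(y_true, y_pred))
      per <- rep_$per_class
      pos <- per$Pre > 0 & per$Sen > 0
      expect_true(all(per$F1[pos] >= pmin(per$Pre, per$Sen)[pos] - 1e-12))
      expect_true(all(per$F1[pos] <= pmax(per$Pre, per$Sen)[pos] + 1e-12))
      # overall accuracy equals the count-weighted per-class sensitivity mean
      wts <- as.vector(table(factor(y_true, levels = 0:3)))
      expect_equal(rep_$overall_accuracy,
                   sum(per$Sen * wts) / sum(wts), tolerance = 1e-12)
    }
  })
})

test_that("zero-denominator classes report 0 and are flagged", {
  # class S2 never predicted and never true beyond...: TP=0, FP=0 for S2
  y_true <- c(0, 0, 1, 1, 3)
  y_pred <- c(0, 0, 1, 1, 1)
  rep_ <- metrics_report(confusion_matrix(y_true, y_pred))
  s2 <- rep_$per_class[rep_$per_class$class == "S2", ]
  expect_identical(s2$Pre, 0)
  expect_true("S2" %in% rep_$zero_denominator)
  # S1 never occurs at all: flagged too, with Sen = 0 by convention
  expect_true("S1" %in% rep_$zero_denominator)
})

test_that("metric reports round-trip through JSON and format as a table", {
  y_true <- c(0, 1, 2, 3, 0, 1)
  y_pred <- c(0, 1, 2, 2, 0, 0)
  rep_ <- metrics_report(confusion_matrix(y_true, y_pred))
  f <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(rep_, f)
  back <- read_metrics_report(f)
  expect_equal(back$per_class, rep_$per_class, ignore_attr = TRUE)
  expect_equal(back$overall_accuracy, rep_$overall_accuracy)
  expect_identical(unclass(back$confusion), unclass(rep_$confusion))
  txt <- format_metrics_table(rep_)
  expect_match(txt, "Overall accuracy")
  expect_match(txt, "S1")
})
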