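test_that("alignment matches hypersphere geometry", {
  u <- matrix(c(1, 0, 0), 1)
  v <- matrix(c(0, 1, 0), 1)
  expect_equal(alignment(u, u), 0)
  expect_equal(alignment(u, v), 2)            # ||x - y||^2 = 2 - 2 cos(pi/2)
  expect_equal(alignment(u, -u), 4)           # antipodal
  expect_error(alignment(u[0, , drop = FALSE], v[0, , drop = FALSE]), "empty")
})

test_that("uniformity matches enumerated pair expectations", {
  u <- matrix(c(1, 0), 1)
  expect_equal(uniformity(rbind(u, u, u)), 0)
  # two antipodal points: 4 ordered pairs, distances (0, 4, 4, 0)
  expect_equal(uniformity(rbind(u, -u)), log((2 + 2 * exp(-8)) / 4),
               tolerance = 1e-10)
  # spread points score strictly lower than collapsed ones
  sphere <- normalize_rows(matrix(rnorm(40), 10))
  expect_lt(uniformity(sphere), uniformity(rbind(u, u, u)))
  expect_error(uniformity(u), "at least 2")
})

test_that("vectorized alignment/uniformity equal an explicit double loop", {
  set.seed(9)
  x <- normalize_rows(matrix(rnorm(32 * 6), 32))
  y <- normalize_rows(matrix(rnorm(32 * 6), 32))
  al_loop <- mean(vapply(1:32, function(i) sum((x[i, ] - y[i, ])^2), numeric(1)))
  expect_equal(alignment(x, y), al_loop, tolerance = 1e-6)
  acc <- 0
  for (i in 1:32) for (j in 1:32) acc <- acc + exp(-2 * sum((x[i, ] - x[j, ])^2))
  expect_equal(uniformity(x), log(acc / 32^2), tolerance = 1e-6)
  # both invariant under a common rotation
  q <- qr.Q(qr(matrix(rnorm(36), 6)))
  expect_equal(alignment(x %*% q, y %*% q), alignment(x, y), tolerance = 1e-9)
  expect_equal(uniformity(x %*% q), uniformity(x), tolerance = 1e-9)
})

test_that("confusion tallies count one-vs-rest outcomes", {
  truth <- c(1, 1, 1, 1, 0, 0)
  pred <- c(1, 1, 1, 0, 1, 0)
  t1 <- confusion_tally(pred, truth, 2L)
  expect_equal(t1$tp[t1$class == 1], 3L)
  expect_equal(t1$fp[t1$class == 1], 1L)
  expect_equal(t1$fn[t1$class == 1], 1L)
  expect_true(all(t1$tp + t1$fp + t1$fn + t1$tn == 6L))
  # perfect predictions
  t2 <- confusion_tally(0:4, 0:4, 5L)
  expect_true(all(t2$fp == 0L) && all(t2$fn == 0L))
  # constant predictor: class-0 fp = count of all other classes
  t3 <- confusion_tally(rep(0L, 5), 0:4, 5L)
  expect_equal(t3$fp[t3$class == 0], 4L)
  expect_error(confusion_tally(c(0, 1), c(0, 1, 1)), "mismatch")
})

test_that("precision/recall/F1 match hand-computed values", {
  tally <- data.frame(class = 0:1, tp = c(0L, 8L), fp = c(0L, 2L),
                      fn = c(0L, 4L), tn = c(14L, 0L))
  suppressWarnings(prf <- precision_recall_f1(tally, "binary"))
  expect_equal(unname(prf["precision"]), 80)
  expect_equal(unname(prf["recall"]), 100 * 8 / 12, tolerance = 1e-9)
  expect_equal(unname(prf["f1"]), 100 * 2 * 0.8 * (2 / 3) / (0.8 + 2 / 3),
               tolerance = 1e-9)
  perfect <- confusion_tally(c(0, 1, 1), c(0, 1, 1), 2L)
  expect_equal(unname(precision_recall_f1(perfect, "binary")), c(100, 100, 100))
  # macro average is the unweighted mean of per-class one-vs-rest values
  pred <- c(0, 0, 1, 1, 1, 0)
  truth <- c(0, 1, 1, 1, 0, 0)
  macro <- precision_recall_f1(confusion_tally(pred, truth, 2L), "macro")
  per_class <- vapply(0:1, function(k) {
    tl <- confusion_tally(as.integer(pred == k), as.integer(truth == k), 2L)
    precision_recall_f1(tl, "binary")
  }, numeric(3))
  expect_equal(macro, rowMeans(per_class), tolerance = 1e-9)
  # zero-denominator classes contribute 0 with a warning
  expect_warning(precision_recall_f1(confusion_tally(c(0, 0), c(0, 1), 2L), "macro"),
                 "zero denominator")
})

test_that("accuracy is the percent of exact matches", {
  expect_equal(accuracy(0:4, 0:4), 100)
  expect_equal(accuracy(c(1, 1, 0, 0), c(1, 0, 1, 0)), 50)
  expect_equal(accuracy(c(0, 1, 2, 3, 0), c(0, 1, 2, 3, 4)), 80)
  expect_error(accuracy(integer(0), integer(0)), "no samples")
})

test_that("rank-based AUC matches pair counting, ties and transforms", {
  expect_equal(auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 75)
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 100)
  expect_equal(auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 50)
  # invariance under strictly monotone score transforms
  set.seed(3)
  s <- runif(40)
  y <- rbinom(40, 1, 0.5)
  base <- auc(s, y)
  expect_equal(auc(exp(s), y), base)
  expect_equal(auc(3 * s - 7, y), base)
  skip_if_not_installed("pROC")
  ref <- 100 * as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<", levels = c(0, 1))))
  expect_equal(base, ref, tolerance = 1e-9)
})

test_that("macro AUC averages one-vs-rest values and skips absent classes", {
  set.seed(4)
  scores <- matrix(runif(30), 10, 3)
  truth <- c(0, 0, 1, 1, 1, 2, 2, 0, 1, 2)
  per <- vapply(0:2, function(k) auc(scores[, k + 1], as.integer(truth == k)),
                numeric(1))
  expect_equal(auc(scores, truth, "macro_ovr"), mean(per), tolerance = 1e-9)
  expect_warning(auc(scores, rep(c(0, 1), 5), "macro_ovr"), "absent")
})

test_that("classification report composes the individual metrics", {
  set.seed(12)
  truth <- rbinom(30, 1, 0.5)
  scores <- ifelse(truth == 1, runif(30, 0.4, 1), runif(30, 0, 0.6))
  pred <- as.integer(scores > 0.5)
  rep1 <- classification_report(scores, pred, truth, "binary")
  expect_equal(rep1$accuracy, accuracy(pred, truth))
  expect_equal(rep1$auc, auc(scores, truth))
  tl <- confusion_tally(pred, truth, 2L)
  expect_equal(rep1$precision,
               unname(precision_recall_f1(tl, "binary")["precision"]))
  expect_equal(rep1$mode, "binary")
  # perfect binary classifier scores 100 on all five metrics
  perf <- classification_report(truth, truth, truth, "binary")
  expect_equal(c(perf$accuracy, perf$precision, perf$recall, perf$f1, perf$auc),
               rep(100, 5))
  # majority-class predictor on balanced data: accuracy 50
  bal <- rep(c(0L, 1L), 10)
  suppressWarnings(rep2 <- classification_report(rep(0.5, 20), rep(0L, 20), bal,
                                                 "binary"))
  expect_equal(rep2$accuracy, 50)
  # serialization round trip keeps the five metrics
  f <- tempfile(fileext = ".json")
  write_report_json(rep1, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$accuracy, rep1$accuracy)
  expect_equal(back$auc, rep1$auc)
  expect_equal(back$mode, "binary")
})

test_that("binary accuracy equals (TP+TN)/total from the tally", {
  set.seed(21)
  for (rep in 1:5) {
    truth <- rbinom(25, 1, 0.4)
    pred <- rbinom(25, 1, 0.5)
    tl <- confusion_tally(pred, truth, 2L)
    r <- tl[tl$class == 1, ]
    expect_equal(accuracy(pred, truth), 100 * (r$tp + r$tn) / 25)
  }
})
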