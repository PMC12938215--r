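test_that("confusion counting matches a brute-force tally", {
  expect_equal(diag(confusionCounts(stationLevels(), stationLevels())),
               setNames(rep(1L, 8), stationLevels()))
  cm <- confusionCounts("4L", "4R")
  expect_equal(cm["4L", "4R"], 1L)
  expect_equal(sum(cm), 1L)
  set.seed(51)
  tr <- sample(stationLevels(), 200, TRUE)
  pr <- sample(stationLevels(), 200, TRUE)
  cm <- confusionCounts(tr, pr)
  brute <- matrix(0L, 8, 8, dimnames = dimnames(cm))
  for (i in 1:200) brute[tr[i], pr[i]] <- brute[tr[i], pr[i]] + 1L
  expect_equal(cm, brute)
  expect_error(confusionCounts(c("4L", "XX"), c("4L", "4L")), "unknown")
  expect_error(confusionCounts(c("4L"), c("4L", "4R")), "length")
})

test_that("per-class metrics match brute-force TP/FP/FN enumeration", {
  # perfect predictions: everything 100
  cm <- confusionCounts(rep(stationLevels(), 3), rep(stationLevels(), 3))
  pc <- perClassMetrics(cm)
  expect_true(all(pc$precision == 100 & pc$sensitivity == 100 & pc$f1 == 100))
  # random matrix vs enumeration
  set.seed(52)
  cm <- matrix(rpois(64, 4), 8, 8,
               dimnames = list(true = stationLevels(),
                               predicted = stationLevels()))
  pc <- perClassMetrics(cm)
  for (k in 1:8) {
    tp <- cm[k, k]; fp <- sum(cm[, k]) - tp; fn <- sum(cm[k, ]) - tp
    expect_equal(pc$precision[k], 100 * tp / (tp + fp))
    expect_equal(pc$sensitivity[k], 100 * tp / (tp + fn))
    expect_equal(pc$f1[k],
                 2 * pc$precision[k] * pc$sensitivity[k] /
                   (pc$precision[k] + pc$sensitivity[k]))
    expect_equal(pc$support[k], sum(cm[k, ]))
  }
  # absent and never-predicted class: flagged zeros
  cm0 <- cm; cm0[3, ] <- 0L; cm0[, 3] <- 0L
  pc0 <- perClassMetrics(cm0)
  expect_equal(pc0$precision[3], 0)
  expect_equal(pc0$sensitivity[3], 0)
  expect_true(pc0$flagged[3])
})

test_that("per-class metrics agree with an independent library implementation", {
  skip_if_not_installed("caret")
  set.seed(53)
  tr <- factor(sample(stationLevels(), 300, TRUE), stationLevels())
  pr <- factor(ifelse(runif(300) < 0.55, as.character(tr),
                      sample(stationLevels(), 300, TRUE)), stationLevels())
  pc <- perClassMetrics(confusionCounts(as.character(tr), as.character(pr)))
  ref <- caret::confusionMatrix(pr, tr)$byClass
  expect_equal(pc$precision / 100, unname(ref[, "Precision"]),
               tolerance = 1e-10)
  expect_equal(pc$sensitivity / 100, unname(ref[, "Sensitivity"]),
               tolerance = 1e-10)
})

test_that("macro averaging is the unweighted mean", {
  pc <- data.frame(station = stationLevels(),
                   precision = c(77.6, 75.6, 76.6, 52.1, 50.7, 85.8, 36.2, 47.8),
                   sensitivity = c(81.6, 72.7, 38.8, 69.9, 36.4, 59.9, 60.9, 52.1),
                   f1 = c(79.5, 74.1, 51.5, 59.7, 42.4, 70.5, 45.4, 49.9),
                   support = rep(1L, 8))
  mac <- macroAverage(pc)
  expect_equal(round(mac[["precision"]], 1), 62.8)
  expect_equal(round(mac[["f1"]], 1), 59.1)
  same <- pc; same$precision <- 42; same$sensitivity <- 42; same$f1 <- 42
  expect_equal(unname(macroAverage(same)), rep(42, 3))
})

test_that("weighted averaging uses supports and collapses to macro when equal", {
  pc <- data.frame(station = stationLevels(),
                   precision = c(77.6, 75.6, 76.6, 52.1, 50.7, 85.8, 36.2, 47.8),
                   sensitivity = c(81.6, 72.7, 38.8, 69.9, 36.4, 59.9, 60.9, 52.1),
                   f1 = c(79.5, 74.1, 51.5, 59.7, 42.4, 70.5, 45.4, 49.9),
                   support = c(598L, 490L, 379L, 386L, 99L, 506L, 276L, 397L))
  w <- weightedAverage(pc)
  expect_equal(round(w[["precision"]], 1), 67.1)
  expect_equal(round(w[["sensitivity"]], 1), 63.1)
  eq <- pc; eq$support <- rep(10L, 8)
  expect_equal(weightedAverage(eq), macroAverage(eq), tolerance = 1e-12)
  none <- pc; none$support <- rep(0L, 8)
  expect_error(weightedAverage(none), "positive")
})

test_that("weighted sensitivity equals accuracy for every confusion matrix", {
  set.seed(54)
  for (i in 1:20) {
    cm <- matrix(rpois(64, 3), 8, 8,
                 dimnames = list(true = stationLevels(),
                                 predicted = stationLevels()))
    cm[cbind(1:8, 1:8)] <- cm[cbind(1:8, 1:8)] + 1L # all supports > 0
    pc <- perClassMetrics(cm)
    expect_equal(weightedAverage(pc)[["sensitivity"]],
                 100 * sum(diag(cm)) / sum(cm), tolerance = 1e-10)
  }
})

test_that("macro and weighted aggregates are invariant to class order", {
  set.seed(55)
  tr <- sample(stationLevels(), 150, TRUE)
  pr <- sample(stationLevels(), 150, TRUE)
  a1 <- aggregateMetrics(tr, pr, stationLevels())
  perm <- sample(stationLevels())
  a2 <- aggregateMetrics(tr, pr, perm)
  expect_equal(a1$macro, a2$macro, tolerance = 1e-10)
  expect_equal(a1$weighted, a2$weighted, tolerance = 1e-10)
  expect_equal(a1$accuracy, a2$accuracy)
  # per-class rows are permuted accordingly
  expect_equal(a2$perClass$precision[match(stationLevels(), a2$perClass$station)],
               a1$perClass$precision, tolerance = 1e-10)
})

test_that("stratified metrics partition images and error on pending items", {
  set.seed(56)
  n <- 120
  preds <- data.frame(image_id = sprintf("i%03d", 1:n),
                      true_station = sample(stationLevels(), n, TRUE),
                      predicted_station = sample(stationLevels(), n, TRUE))
  cons <- data.frame(image_id = preds$image_id,
                     final_label = sample(annotationLabels(), n, TRUE,
                                          prob = c(0.7, 0.1, 0.1, 0.1)),
                     agreement_level = "complete")
  sm <- stratifyMetrics(preds, cons)
  expect_equal(sum(vapply(sm, function(x) x[["support"]], numeric(1))), n)
  # single category: stratum equals global macro metrics over present classes
  cons1 <- cons; cons1$final_label <- "artifact"
  sm1 <- stratifyMetrics(preds, cons1)
  glob <- aggregateMetrics(preds$true_station, preds$predicted_station)
  present <- glob$perClass[glob$perClass$support > 0, ]
  expect_equal(sm1$artifact[["accuracy"]], glob$accuracy, tolerance = 1e-10)
  expect_equal(sm1$artifact[["f1"]], mean(present$f1), tolerance = 1e-10)
  # pending consensus: error naming the item
  consP <- cons; consP$final_label[3] <- NA
  expect_error(stratifyMetrics(preds, consP), "pending")
  expect_error(stratifyMetrics(preds, cons[-1, ]), "no consensus")
})

test_that("report-time rounding is half away from zero at one decimal", {
  df <- data.frame(precision = c(63.45, 10.04), sensitivity = c(0.05, 99.95),
                   f1 = c(50, 50), support = c(1L, 1L))
  out <- formatMetrics(df)
  expect_equal(out$precision, c(63.5, 10.0))
  expect_equal(out$sensitivity, c(0.1, 100.0))
})
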