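# The reference screening outcome used throughout: 412 healthy images of
# which 391 were called healthy, and 139 glaucomatous of which 48 were
# called glaucoma.
referenceOutcome <- function() {
  labels <- rep(c("healthy", "glaucoma"), c(412, 139))
  preds <- c(rep("healthy", 391), rep("glaucoma", 21),
             rep("glaucoma", 48), rep("healthy", 91))
  list(labels = labels, preds = preds)
}

test_that("confusion counts tally the screening outcome correctly", {
  ro <- referenceOutcome()
  cc <- confusionCounts(ro$labels, ro$preds)
  expect_identical(truePositives(cc, "healthy"), 391L)
  expect_identical(falsePositives(cc, "healthy"), 91L)
  expect_identical(falseNegatives(cc, "healthy"), 21L)
  expect_identical(truePositives(cc, "glaucoma"), 48L)
  expect_identical(trueNegatives(cc, "glaucoma"), 391L)
  expect_identical(falsePositives(cc, "glaucoma"), 21L)
  expect_error(confusionCounts(c("a", "b"), "a"), "equal length")
  expect_error(confusionCounts(character(0), character(0)), "empty")
})

test_that("precision, recall, F1 and specificity match hand values", {
  ro <- referenceOutcome()
  cc <- confusionCounts(ro$labels, ro$preds)
  expect_equal(classPrecision(cc, "healthy"), 100 * 391 / 482,
               tolerance = 1e-12)
  expect_equal(classRecall(cc, "healthy"), 100 * 391 / 412,
               tolerance = 1e-12)
  expect_equal(classPrecision(cc, "glaucoma"), 100 * 48 / 69,
               tolerance = 1e-12)
  expect_equal(classRecall(cc, "glaucoma"), 100 * 48 / 139,
               tolerance = 1e-12)
  # specificity of the positive class equals the recall of the other class
  expect_equal(classSpecificity(cc, "glaucoma"), classRecall(cc, "healthy"))
  expect_equal(f1Score(100, 100), 1)
  p <- 37.5
  expect_equal(f1Score(p, p), p / 100)  # harmonic-mean identity
  expect_identical(f1Score(0, 0), 0)    # documented convention
})

test_that("undefined metrics raise instead of silently returning zero", {
  cc <- confusionCounts(c("healthy", "healthy"), c("healthy", "healthy"),
                        classes = c("healthy", "glaucoma"))
  expect_error(classPrecision(cc, "glaucoma"), "undefined")
  expect_error(classRecall(cc, "glaucoma"), "undefined")
  # zero-valued but defined cases return 0
  cc2 <- confusionCounts(c("healthy", "glaucoma"), c("glaucoma", "healthy"))
  expect_identical(classPrecision(cc2, "healthy"), 0)
})

test_that("binary complementarity holds on random outcomes", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    labels <- sample(c("healthy", "glaucoma"), n, replace = TRUE)
    preds <- sample(c("healthy", "glaucoma"), n, replace = TRUE)
    cc <- confusionCounts(labels, preds)
    expect_identical(truePositives(cc, "healthy"),
                     trueNegatives(cc, "glaucoma"))
    expect_identical(falsePositives(cc, "healthy"),
                     falseNegatives(cc, "glaucoma"))
    # and all four metrics agree with a brute-force recount
    tp <- sum(labels == "healthy" & preds == "healthy")
    fp <- sum(labels != "healthy" & preds == "healthy")
    fn <- sum(labels == "healthy" & preds != "healthy")
    if (tp + fp > 0) {
      expect_equal(classPrecision(cc, "healthy"), 100 * tp / (tp + fp))
    }
    if (tp + fn > 0) {
      expect_equal(classRecall(cc, "healthy"), 100 * tp / (tp + fn))
    }
  }
})

test_that("the classification report reproduces the reference table", {
  ro <- referenceOutcome()
  rep <- classificationReport(ro$labels, ro$preds)
  h <- rep$per_class[rep$per_class$class == "healthy", ]
  g <- rep$per_class[rep$per_class$class == "glaucoma", ]
  expect_equal(round(h$precision, 2), 81.12)
  expect_equal(round(h$recall, 2), 94.90)
  expect_equal(h$f1, 0.8747, tolerance = 1e-4)
  expect_identical(h$support, 412)
  expect_equal(round(g$precision, 2), 69.57)
  expect_equal(round(g$recall, 2), 34.53)
  expect_equal(g$f1, 0.4615, tolerance = 1e-4)
  expect_equal(round(rep$total$precision, 2), 78.21)
  expect_equal(round(rep$total$accuracy, 2), 79.67)
  expect_equal(rep$total$f1, 0.7705, tolerance = 1e-4)
  expect_identical(rep$total$support, 551)
})

test_that("report handles small hand-checked cases", {
  rep <- classificationReport(c("healthy", "healthy", "glaucoma"),
                              c("healthy", "glaucoma", "glaucoma"))
  expect_equal(rep$total$accuracy, 200 / 3, tolerance = 1e-9)
  h <- rep$per_class[rep$per_class$class == "healthy", ]
  expect_equal(h$precision, 100)
  expect_equal(h$recall, 50)
  allgood <- classificationReport(rep(c("healthy", "glaucoma"), 5),
                                  rep(c("healthy", "glaucoma"), 5))
  expect_true(all(allgood$per_class$precision == 100))
  expect_equal(allgood$total$f1, 1)
})

test_that("trapezoidal AUC equals brute-force pair concordance", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.7),
                      c("glaucoma", "glaucoma", "healthy"))$auc, 1)
  expect_equal(rocAuc(c(0.9, 0.6, 0.7),
                      c("glaucoma", "glaucoma", "healthy"))$auc, 0.5)
  set.seed(13)
  for (i in 1:40) {
    n <- sample(5:200, 1)
    labels <- c("glaucoma", "healthy",
                sample(c("healthy", "glaucoma"), n, replace = TRUE))
    scores <- round(runif(n + 2), sample(1:3, 1))  # coarse => ties
    expect_equal(rocAuc(scores, labels)$auc,
                 concordanceAuc(scores, labels), tolerance = 1e-12)
  }
  expect_error(rocAuc(runif(5), rep("healthy", 5)), "both classes")
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(99)
  labels <- sample(c("healthy", "glaucoma"), 150, replace = TRUE)
  scores <- runif(150) + 0.4 * (labels == "glaucoma")
  ours <- rocAuc(scores, labels)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("healthy", "glaucoma"),
    direction = "<")))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("uninformative scores give AUC near one half", {
  set.seed(4)
  labels <- sample(c("healthy", "glaucoma"), 1000, replace = TRUE)
  expect_equal(rocAuc(runif(1000), labels)$auc, 0.5, tolerance = 0.05)
})

test_that("sensitivity at fixed specificity reads the step function", {
  perfect <- rocAuc(c(0.9, 0.8, 0.1, 0.2),
                    c("glaucoma", "glaucoma", "healthy", "healthy"))
  expect_equal(sensitivityAtSpecificity(perfect, 85), 100)
  expect_equal(sensitivityAtSpecificity(perfect, 100), 100)
  # a useless one-threshold classifier: nothing reaches 85% specificity
  # except the all-negative corner with zero sensitivity
  flat <- rocAuc(c(0.5, 0.5), c("glaucoma", "healthy"))
  expect_equal(sensitivityAtSpecificity(flat, 85), 0)
  # hand-built curve: pos scores {0.9, 0.7, 0.4}, neg {0.8, 0.2}
  curve <- rocAuc(c(0.9, 0.7, 0.4, 0.8, 0.2),
                  c("glaucoma", "glaucoma", "glaucoma",
                    "healthy", "healthy"))
  expect_equal(sensitivityAtSpecificity(curve, 60), 100 / 3,
               tolerance = 1e-9)
  expect_equal(sensitivityAtSpecificity(curve, 50), 100)
  expect_error(sensitivityAtSpecificity(curve, 0), "target")
  expect_error(sensitivityAtSpecificity(curve, 150), "target")
})

test_that("k-fold splits are balanced, exhaustive and reproducible", {
  ids <- sprintf("im%03d", 1:650)
  s <- kfoldSplit(ids, 10, seed = 3)
  expect_true(all(table(s$assignment) == 65))
  expect_identical(sort(names(s$assignment)), sort(ids))
  s2 <- kfoldSplit(ids, 10, seed = 3)
  expect_identical(s$assignment, s2$assignment)
  small <- kfoldSplit(letters[1:7], 3, seed = 1)
  expect_identical(sort(as.integer(table(small$assignment)),
                        decreasing = TRUE), c(3L, 2L, 2L))
  expect_error(kfoldSplit(letters[1:3], 5), "k must lie")
  # stratified splits keep class counts within one per fold
  labs <- rep(c("healthy", "glaucoma"), c(30, 10))
  st <- kfoldSplit(sprintf("s%02d", 1:40), 5, seed = 2, stratify = labs)
  perFold <- table(st$assignment, labs)
  expect_true(all(perFold[, "glaucoma"] == 2))
  expect_true(all(perFold[, "healthy"] == 6))
})
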