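# small labelled dataset builder: maps across sessions, one feature set
miniDataset <- function(nParticipants = 3, nSessions = 2, nMaps = 2,
                        spec = memSpec(256L, 32L, 4L), set = "set64_128") {
  maps <- list()
  for (p in seq_len(nParticipants)) for (s in seq_len(nSessions))
    for (i in seq_len(nMaps))
      maps[[length(maps) + 1L]] <- randomMap(spec, sprintf("P%d", p),
                                             sprintf("S%d", s), i)
  buildFeatures(maps, featureSetSpec(set, spec))
}

test_that("LOSO folds partition by participant-session without leakage", {
  set.seed(1)
  d <- miniDataset()
  folds <- losoSplit(d)
  expect_length(folds, 6L)   # 3 participants x 2 sessions
  for (f in folds) {
    trainKeys <- unique(paste(f$train$participant, f$train$session))
    testKeys <- unique(paste(f$test$participant, f$test$session))
    expect_length(testKeys, 1L)
    expect_false(testKeys %in% trainKeys)
    expect_identical(nrow(f$train) + nrow(f$test), nrow(d))
    # complete sessions keep the folds class-balanced
    expect_true(all(table(f$test$element) == 2L))
    expect_true(all(table(f$train$element) == 10L))
  }
  oneSession <- d[paste(d$participant, d$session) == "P1 S1", ]
  attr(oneSession, "fsSpec") <- attr(d, "fsSpec")
  expect_error(losoSplit(oneSession), "at least two")
})

test_that("knn recovers exact matches and nearest neighbours", {
  sym <- symbolicMap(memSpec(256L, 32L, 4L))
  train <- buildFeatures(sym, featureSetSpec("set32_64", sym@spec))
  # identical test point, k = 1 -> its own class
  expect_identical(knnClassify(train, train, 1L), train$element)
  # 1-D toy: 0.2 is nearer 0.1 (class 1) than 0.9 (class 2)
  toy <- data.frame(participant = "P", session = "S", stimulus = 1L,
                    element = c(1L, 2L), range_ms = "", apen64 = c(0.1, 0.9))
  test <- toy[1, ]; test$apen64 <- 0.2
  expect_identical(knnClassify(toy, test, 1L), 1L)
  expect_error(knnClassify(toy, test, 3L), "nrow")
})

test_that("knn matches an exhaustive distance-sort oracle", {
  set.seed(77)
  d <- miniDataset(nParticipants = 2, nSessions = 2, nMaps = 2,
                   set = "set32_64_128")
  key <- paste(d$participant, d$session)
  train <- d[key != "P1 S1", ]; test <- d[key == "P1 S1", ]
  fc <- c("apen32", "apen64", "apen128")
  for (k in c(1L, 7L)) {
    got <- knnClassify(train, test, k)
    oracle <- vapply(seq_len(nrow(test)), function(i) {
      dist <- sqrt(rowSums((as.matrix(train[, fc]) -
                            matrix(as.numeric(test[i, fc]),
                                   nrow(train), 3, byrow = TRUE))^2))
      nb <- order(dist, train$element)[seq_len(k)]
      votes <- table(train$element[nb])
      top <- as.integer(names(votes)[votes == max(votes)])
      if (length(top) > 1L) {
        sums <- tapply(dist[nb], train$element[nb], sum)[as.character(top)]
        top <- top[sums == min(sums)]
      }
      min(top)
    }, integer(1))
    expect_identical(got, oracle)
  }
})

test_that("knn predictions are invariant to training-row order", {
  skip_if_not_installed("class")
  set.seed(15)
  d <- miniDataset(nParticipants = 2, nSessions = 2)
  key <- paste(d$participant, d$session)
  train <- d[key != "P1 S1", ]; test <- d[key == "P1 S1", ]
  base <- knnClassify(train, test, 5L)
  perm <- train[sample(nrow(train)), ]
  expect_identical(knnClassify(perm, test, 5L), base)
  # at k = 1 no vote can tie and distances are continuous: class::knn
  # must agree exactly
  ref <- as.integer(as.character(class::knn(
    train[, c("apen64", "apen128")], test[, c("apen64", "apen128")],
    factor(train$element), k = 1)))
  expect_identical(knnClassify(train, test, 1L), ref)
})

test_that("classification metrics match a counting oracle", {
  perfect <- evaluateClassification(1:4, 1:4, nClasses = 4)
  expect_identical(perfect$accuracy, 1)
  expect_true(all(perfect$perClass == 1))
  expect_true(all(perfect$confusion == diag(4)))

  # two-class tally with known confusion counts:
  # TP = 83, FN = 17, TN = 921, FP = 79 for class 1
  truth <- rep(c(1L, 2L), c(100L, 1000L))
  pred <- c(rep(1L, 83), rep(2L, 17), rep(1L, 79), rep(2L, 921))
  ev <- evaluateClassification(pred, truth, nClasses = 2,
                               designatedClass = 1L)
  expect_equal(ev$sensitivity, 0.83)
  expect_equal(ev$specificity, 0.921)
  expect_equal(ev$accuracy, (83 + 921) / 1100)

  set.seed(6)
  truth <- sample(1:3, 60, replace = TRUE)
  pred <- sample(1:3, 60, replace = TRUE)
  ev <- evaluateClassification(pred, truth, nClasses = 3)
  for (a in 1:3) for (b in 1:3)
    expect_identical(ev$confusion[a, b], sum(truth == a & pred == b))
  expect_equal(ev$perClass,
               vapply(1:3, function(cl) mean(pred[truth == cl] == cl),
                      numeric(1)))
  expect_equal(rowSums(ev$confusion),
               vapply(1:3, function(cl) sum(truth == cl), integer(1)),
               ignore_attr = TRUE)
  expect_error(evaluateClassification(1:3, 1:4), "equal length")
})

test_that("runLOSO aggregates folds over the k grid into an EvalReport", {
  set.seed(23)
  d <- miniDataset(nParticipants = 3, nSessions = 2, nMaps = 2)
  rep <- runLOSO(d, kGrid = c(3L, 7L))
  expect_s4_class(rep, "EvalReport")
  expect_identical(rep@nFolds, 6L)
  # finest size 64 on a 256-sample map -> 4 classes
  expect_identical(dim(rep@perSegment), c(4L, 2L))
  expect_true(all(rep@overall >= 0 & rep@overall <= 1))
  # balanced classes: mean per-segment accuracy reproduces overall accuracy
  expect_equal(colMeans(rep@perSegment), rep@overall,
               ignore_attr = TRUE, tolerance = 1e-12)
  # confusion rows sum to per-class test counts pooled over folds
  expect_true(all(rowSums(rep@confusion[[1]]) == nrow(d) / 4L))
  files <- writeEvalReport(rep, file.path(withr::local_tempdir(), "eval"))
  expect_true(all(file.exists(files)))
})
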