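#' Leave-one-participant-session-out folds
#'
#' One cross-validation fold per participant-session: all elements of
#' that session's maps form the test set, every other session's elements
#' the training set.  A session never contributes to both sides of its
#' fold, and because every complete session carries the same balanced
#' class layout, the folds are class-balanced.
#'
#' @param dataset a \code{FeatureDataset} from \code{\link{buildFeatures}}
#'   covering at least two participant-sessions.
#' @return list of folds, each a list \code{(session, train, test)} with
#'   \code{train}/\code{test} row subsets of \code{dataset}.
#' @export
losoSplit <- function(dataset) {
  key <- paste(dataset$participant, dataset$session, sep = ":")
  sessions <- unique(key)
  if (length(sessions) < 2L)
    stop("leave-one-session-out needs at least two participant-sessions")
  lapply(sessions, function(s)
    list(session = s,
         train = dataset[key != s, , drop = FALSE],
         test = dataset[key == s, , drop = FALSE]))
}

#' Deterministic k-nearest-neighbour classification
#'
#' Plain Euclidean knn over the feature columns: every test row is
#' assigned the majority class among its \code{k} nearest training rows.
#' All ties are resolved deterministically: neighbour selection at the
#' distance cutoff prefers lower class label, then earlier training row;
#' a tied vote goes to the class with the smaller summed neighbour
#' distance, then to the lower class label.  The features are entropies
#' on a common scale, so no feature normalization is applied.
#'
#' @param train,test \code{FeatureDataset}s with identical feature
#'   columns.
#' @param k number of neighbours, \code{1 <= k <= nrow(train)}.
#' @return integer vector of predicted class labels, one per test row.
#' @export
knnClassify <- function(train, test, k) {
  fc <- featureColumns(train)
  if (!length(fc) || !identical(fc, featureColumns(test)))
    stop("train and test must share the same feature columns")
  k <- as.integer(k)
  if (k < 1L || k > nrow(train))
    stop("'k' must lie in 1..nrow(train) (= ", nrow(train), ")")
  tr <- as.matrix(train[, fc, drop = FALSE])
  te <- as.matrix(test[, fc, drop = FALSE])
  cls <- as.integer(train$element)
  unname(apply(te, 1L, function(p) {
    d <- sqrt(colSums((t(tr) - p)^2))
    ord <- order(d, cls, seq_along(d))
    nb <- ord[seq_len(k)]
    votes <- tapply(rep(1L, k), cls[nb], sum)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      sums <- tapply(d[nb], cls[nb], sum)[top]
      top <- top[sums == min(sums)]
    }
    min(as.integer(top))
  }))
}

#' Classification metrics
#'
#' Tallies predictions against truth: overall accuracy, per-class
#' accuracy, and the confusion matrix (rows = truth, columns =
#' prediction, over all labels \code{1..nClasses}).  For a designated
#' class, one-vs-rest sensitivity \code{TP/(TP+FN)} and specificity
#' \code{TN/(TN+FP)}.
#'
#' @param predictions,truth aligned integer label vectors.
#' @param nClasses number of classes (labels are \code{1..nClasses}).
#' @param designatedClass class for sensitivity/specificity; default the
#'   best-classified class.
#' @return list with \code{accuracy}, \code{perClass}, \code{confusion},
#'   \code{bestClass}, \code{designatedClass}, \code{sensitivity},
#'   \code{specificity}.
#' @examples
#' evaluateClassification(c(1, 2, 2), c(1, 2, 1), nClasses = 2)
#' @export
evaluateClassification <- function(predictions, truth,
                                   nClasses = max(truth),
                                   designatedClass = NULL) {
  predictions <- as.integer(predictions)
  truth <- as.integer(truth)
  if (length(predictions) != length(truth))
    stop("'predictions' and 'truth' must have equal length")
  lev <- seq_len(nClasses)
  cm <- table(factor(truth, lev), factor(predictions, lev))
  cm <- matrix(as.integer(cm), nClasses, nClasses,
               dimnames = list(truth = lev, predicted = lev))
  n <- rowSums(cm)
  perClass <- ifelse(n > 0, diag(cm) / n, NA_real_)
  best <- which.max(perClass)
  if (is.null(designatedClass)) designatedClass <- best
  tp <- cm[designatedClass, designatedClass]
  fn <- sum(cm[designatedClass, ]) - tp
  fp <- sum(cm[, designatedClass]) - tp
  tn <- sum(cm) - tp - fn - fp
  list(accuracy = mean(predictions == truth),
       perClass = as.numeric(perClass),
       confusion = cm,
       bestClass = as.integer(best),
       designatedClass = as.integer(designatedClass),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp))
}

#' Leave-one-session-out knn evaluation of a feature set
#'
#' The full detection protocol for one feature set: split the dataset by
#' participant-session (\code{\link{losoSplit}}), classify every fold's
#' test elements with \code{\link{knnClassify}} for each \code{k} of the
#' grid, and aggregate.  Per-segment accuracy is the mean over folds of
#' the within-fold per-class accuracy (folds are class-balanced, so this
#' equals pooled per-class accuracy); the confusion matrix is pooled
#' over folds; sensitivity/specificity are reported for the designated
#' class, by default the best segment at each k.
#'
#' @param dataset a \code{FeatureDataset}.
#' @param kGrid integer vector of neighbourhood sizes (default the
#'   canonical grid 3, 7, 15, 31, 63, 127, 255); values exceeding the
#'   training-set size are an error.
#' @param designatedClass optional fixed class for
#'   sensitivity/specificity.
#' @return an \linkS4class{EvalReport}.
#' @export
runLOSO <- function(dataset, kGrid = c(3L, 7L, 15L, 31L, 63L, 127L, 255L),
                    designatedClass = NULL) {
  fsSpec <- attr(dataset, "fsSpec")
  stopifnot(inherits(fsSpec, "FeatureSetSpec"))
  kGrid <- as.integer(kGrid)
  folds <- losoSplit(dataset)
  ncl <- fsSpec$nElements
  nk <- length(kGrid)
  overall <- sens <- spec <- numeric(nk)
  best <- desig <- integer(nk)
  perSeg <- matrix(0, ncl, nk)
  confs <- vector("list", nk)
  X <- fsSpec$finest
  ranges <- sprintf("%d-%d", (seq_len(ncl) - 1L) * X, seq_len(ncl) * X)
  for (j in seq_len(nk)) {
    preds <- lapply(folds, function(f)
      knnClassify(f$train, f$test, kGrid[j]))
    pc <- vapply(seq_along(folds), function(i)
      evaluateClassification(preds[[i]], folds[[i]]$test$element,
                             ncl)$perClass,
      numeric(ncl))
    perSeg[, j] <- rowMeans(matrix(pc, nrow = ncl), na.rm = TRUE)
    pooled <- evaluateClassification(unlist(preds),
                                     unlist(lapply(folds,
                                                   function(f) f$test$element)),
                                     ncl, designatedClass = designatedClass)
    overall[j] <- pooled$accuracy
    best[j] <- which.max(perSeg[, j])
    if (is.null(designatedClass)) {
      pooled <- evaluateClassification(
        unlist(preds),
        unlist(lapply(folds, function(f) f$test$element)),
        ncl, designatedClass = best[j])
    }
    desig[j] <- pooled$designatedClass
    sens[j] <- pooled$sensitivity
    spec[j] <- pooled$specificity
    confs[[j]] <- pooled$confusion
  }
  kn <- paste0("k", kGrid)
  names(overall) <- names(sens) <- names(spec) <- names(best) <- kn
  dimnames(perSeg) <- list(ranges, kn)
  names(confs) <- kn
  new("EvalReport", featureSet = fsSpec$name, kGrid = kGrid,
      classRanges = ranges, overall = overall, perSegment = perSeg,
      confusion = confs, bestSegment = best, sensitivity = sens,
      specificity = spec, designatedClass = desig,
      nFolds = length(folds))
}

#' Write an evaluation report to disk
#'
#' Writes \code{<stem>_overall.csv} (one row, columns k3..k255),
#' \code{<stem>_per_segment.csv} (rows = segment time ranges, columns =
#' k), one confusion-matrix CSV per k, and \code{<stem>.json} with all
#' metrics.
#'
#' @param report an \linkS4class{EvalReport}.
#' @param stem output path without extension.
#' @return invisibly, the files written.
#' @export
writeEvalReport <- function(report, stem) {
  stopifnot(is(report, "EvalReport"))
  f1 <- paste0(stem, "_overall.csv")
  f2 <- paste0(stem, "_per_segment.csv")
  utils::write.csv(as.data.frame(t(report@overall)), f1, row.names = FALSE)
  utils::write.csv(data.frame(segment = report@classRanges,
                              report@perSegment, check.names = FALSE),
                   f2, row.names = FALSE)
  fc <- vapply(seq_along(report@kGrid), function(j) {
    f <- sprintf("%s_confusion_k%d.csv", stem, report@kGrid[j])
    cm <- report@confusion[[j]]
    dimnames(cm) <- list(report@classRanges, report@classRanges)
    utils::write.csv(cm, f)
    f
  }, character(1))
  fj <- paste0(stem, ".json")
  jsonlite::write_json(
    list(feature_set = report@featureSet, k = report@kGrid,
         n_folds = report@nFolds, overall = as.list(report@overall),
         per_segment = as.data.frame(report@perSegment),
         best_segment = as.list(report@bestSegment),
         sensitivity = as.list(report@sensitivity),
         specificity = as.list(report@specificity)),
    fj, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2, fc, fj))
}
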