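#' Classification metrics from confusion counts
#'
#' Sensitivity `SE = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`, their
#' geometric mean `GM = sqrt(SE * SP)` (the preferred summary under class
#' imbalance) and accuracy `ACC = (TP+TN)/(TP+FN+TN+FP)`.
#'
#' @param tp,fn,tn,fp Non-negative confusion counts.  Both classes must be
#'   represented (`tp + fn > 0` and `tn + fp > 0`).
#' @return An object of class `"pri_metrics"`: list with `se`, `sp`, `gm`,
#'   `acc` and the counts.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  tp <- unname(tp); fn <- unname(fn); tn <- unname(tn); fp <- unname(fp)
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (tp + fn == 0) stop("SE undefined: no positive samples (tp + fn = 0)")
  if (tn + fp == 0) stop("SP undefined: no negative samples (tn + fp = 0)")
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  structure(list(se = se, sp = sp, gm = sqrt(se * sp),
                 acc = (tp + tn) / (tp + fn + tn + fp),
                 counts = counts),
            class = "pri_metrics")
}

#' @export
print.pri_metrics <- function(x, digits = 4, ...) {
  vals <- c(SE = x$se, SP = x$sp, GM = x$gm, ACC = x$acc)
  if (!is.null(x$auc)) vals <- c(vals, AUC = x$auc)
  print(round(vals, digits))
  invisible(x)
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin so every fold preserves the class ratio as closely as
# integer counts allow.
stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (cls in levels(y)) {
    idx <- which(y == cls)
    if (length(idx) < folds)
      stop("class '", cls, "' has ", length(idx),
           " samples; at least ", folds, " required for ", folds, "-fold CV")
    assign[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

train_classifier <- function(x, y, classifier) {
  switch(classifier,
    rf = ranger::ranger(x = x, y = y, num.trees = 500, probability = TRUE,
                        num.threads = 1),
    svm = e1071::svm(x, y, kernel = "radial", cost = 1,
                     gamma = 1 / ncol(x), probability = TRUE),
    nb = {
      fit <- e1071::naiveBayes(x, y)
      # guard against zero within-class variance (degenerate Gaussian)
      fit$tables <- lapply(fit$tables, function(tab) {
        tab[, 2] <- pmax(tab[, 2], 1e-3)
        tab
      })
      fit
    },
    stop("unknown classifier: ", classifier))
}

# Returns list(label = factor predictions, score = P(positive))
predict_classifier <- function(fit, x, classifier) {
  switch(classifier,
    rf = {
      p <- stats::predict(fit, data = x, num.threads = 1)$predictions[, "positive"]
      list(label = factor(ifelse(p > 0.5, "positive", "negative"),
                          levels = c("negative", "positive")),
           score = p)
    },
    svm = {
      pred <- stats::predict(fit, x, probability = TRUE)
      list(label = pred,
           score = attr(pred, "probabilities")[, "positive"])
    },
    nb = list(label = stats::predict(fit, x),
              score = stats::predict(fit, x, type = "raw")[, "positive"]))
}

roc_auc <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c("negative", "positive"), direction = "<", quiet = TRUE)))
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Folds are stratified to preserve the positive:negative ratio.  The
#' confusion counts are pooled over all out-of-fold predictions
#' (micro-averaging — stable for small datasets), and the AUC is computed
#' from the pooled out-of-fold scores.
#'
#' @param dataset A `pri_dataset`.
#' @param classifier `"svm"` (RBF kernel, cost 1, gamma 1/dimension),
#'   `"rf"` (random forest, 500 trees, via ranger) or `"nb"` (Gaussian
#'   naive Bayes).
#' @param folds Number of folds (default 10); each class needs at least
#'   `folds` samples.  `folds = n` gives leave-one-out (unstratified by
#'   necessity).
#' @param seed Random seed controlling fold assignment and classifier
#'   randomness; a fixed seed reproduces the report exactly.
#' @return A `"pri_metrics"` object with the additional elements `auc`,
#'   `classifier`, `folds`, and the pooled out-of-fold `scores` and
#'   `predictions`.
#' @export
cross_validate <- function(dataset, classifier = c("rf", "svm", "nb"),
                           folds = 10, seed = NULL) {
  classifier <- match.arg(classifier)
  x <- dataset$features
  y <- dataset$labels
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  if (folds > length(y))
    stop("folds exceeds the number of samples")
  # folds = n is leave-one-out: one sample per fold, no stratification
  fold_of <- if (folds == length(y)) seq_along(y)
             else stratified_folds(y, folds)
  pred_label <- factor(rep(NA_character_, length(y)), levels = levels(y))
  pred_score <- numeric(length(y))
  for (f in seq_len(folds)) {
    test <- fold_of == f
    fit <- train_classifier(x[!test, , drop = FALSE], y[!test], classifier)
    out <- predict_classifier(fit, x[test, , drop = FALSE], classifier)
    pred_label[test] <- out$label
    pred_score[test] <- out$score
  }
  m <- confusion_metrics(
    tp = sum(y == "positive" & pred_label == "positive"),
    fn = sum(y == "positive" & pred_label == "negative"),
    tn = sum(y == "negative" & pred_label == "negative"),
    fp = sum(y == "negative" & pred_label == "positive"))
  m$auc <- roc_auc(y, pred_score)
  m$classifier <- classifier
  m$folds <- folds
  m$scores <- pred_score
  m$predictions <- pred_label
  m
}

#' Improvement ratio of reliable over random negatives
#'
#' The signed percent change of a performance measure when reliable
#' negatives replace random negatives:
#' `IR = (reliable - random) / random * 100`.
#'
#' @param reliable,random Metric values (scalars or equal-length vectors)
#'   obtained with reliable and random negative sets; `random` must be
#'   non-zero.
#' @return Percentages (positive when the reliable negatives help).
#' @export
improvement_ratio <- function(reliable, random) {
  if (any(random == 0))
    stop("IR undefined: baseline (random) metric is 0")
  (reliable - random) / random * 100
}

#' Improvement-ratio table for two metric reports
#'
#' @param reliable,random `"pri_metrics"` objects from the same dataset
#'   evaluated with reliable and random negative sets.
#' @return Named numeric vector of IR percentages for SE, SP, GM, ACC (and
#'   AUC when both reports carry one).
#' @export
improvement_table <- function(reliable, random) {
  keys <- c(se = "SE", sp = "SP", gm = "GM", acc = "ACC")
  if (!is.null(reliable$auc) && !is.null(random$auc)) keys["auc"] <- "AUC"
  vals <- vapply(names(keys), function(k)
    improvement_ratio(reliable[[k]], random[[k]]), numeric(1))
  stats::setNames(vals, keys)
}
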