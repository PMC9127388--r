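#' Gini impurity of a class distribution
#'
#' `1 - sum(p_i^2)` over the class proportions at a node; 0 for a pure
#' node, maximal (0.5 for two classes) at the uniform split.
#'
#' @param proportions numeric vector in [0, 1] summing to 1 (within
#'   1e-9).
#' @return unitless impurity.
#' @examples
#' giniImpurity(c(0.5, 0.5))  # 0.5
#' giniImpurity(c(0.8, 0.2))  # 0.32
#' @export
giniImpurity <- function(proportions) {
  if (any(proportions < 0) || any(proportions > 1))
    stop("proportions must lie in [0, 1]")
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must sum to 1")
  1 - sum(proportions^2)
}

#' Random-forest tuning configuration
#'
#' @param mtry,ntree fixed values or `"auto"` to tune.
#' @param mtryGrid candidate mtry values (default 1..n_factors at fit
#'   time).
#' @param ntreeSchedule increasing tree counts scanned for OOB-error
#'   stabilization.
#' @param tuneNtreeFixed forest size used while tuning mtry.
#' @param eliminationDropFraction fraction of factors dropped per
#'   backward-elimination round (least Gini importance first).
#' @param seRuleMultiplier multiplier of the OOB-error standard error in
#'   the smallest-model selection rule (1.0 = the 1-SE rule).
#' @param positive class treated as positive in the reported metrics
#'   (default `"0"`, non-narrowing).
#' @param seed integer seed threaded through all stochastic steps.
#' @return validated list (class `"rfConfig"`).
#' @export
rfConfig <- function(mtry = "auto", ntree = "auto", mtryGrid = NULL,
                     ntreeSchedule = seq(500L, 5000L, by = 500L),
                     tuneNtreeFixed = 1000L,
                     eliminationDropFraction = 0.2,
                     seRuleMultiplier = 1.0,
                     positive = "0", seed = 1L) {
  stopifnot(eliminationDropFraction > 0, eliminationDropFraction < 1,
            seRuleMultiplier >= 0, all(diff(ntreeSchedule) > 0))
  structure(list(mtry = mtry, ntree = ntree, mtryGrid = mtryGrid,
                 ntreeSchedule = as.integer(ntreeSchedule),
                 tuneNtreeFixed = as.integer(tuneNtreeFixed),
                 eliminationDropFraction = eliminationDropFraction,
                 seRuleMultiplier = seRuleMultiplier,
                 positive = as.character(positive), seed = as.integer(seed)),
            class = "rfConfig")
}

checkLabels <- function(labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("both classes must be present")
  labels
}

oobErrorOf <- function(forest) unname(forest$err.rate[forest$ntree, "OOB"])

#' Tune mtry by out-of-bag error
#'
#' Fits one forest per candidate mtry at a fixed tree count and returns
#' the candidate minimizing the OOB misclassification error (ties go to
#' the smallest mtry). OOB predictions use only trees whose bootstrap
#' excluded the sample.
#'
#' @param x predictor data.frame / matrix.
#' @param labels binary class labels.
#' @param config an [rfConfig()].
#' @return list: `mtry` (chosen), `oob` (named error per candidate, as
#'   a fraction).
#' @export
tuneMtry <- function(x, labels, config = rfConfig()) {
  labels <- checkLabels(labels)
  grid <- config$mtryGrid
  if (is.null(grid)) grid <- seq_len(ncol(x))
  grid <- grid[grid >= 1 & grid <= ncol(x)]
  oob <- vapply(grid, function(m) {
    set.seed(config$seed)
    oobErrorOf(randomForest::randomForest(x, labels, mtry = m,
                                          ntree = config$tuneNtreeFixed))
  }, numeric(1))
  names(oob) <- grid
  list(mtry = grid[which.min(oob)], oob = oob)
}

#' Choose ntree at OOB-error stabilization
#'
#' Reads the cumulative OOB-error trace of a single forest grown to the
#' largest scheduled size and returns the smallest schedule entry from
#' which the trace stays flat: every subsequent step-to-step change is
#' below `tolPts` percentage points (the minimum forest size keeping
#' the OOB error at its stable value).
#'
#' @inheritParams tuneMtry
#' @param mtry the (tuned) mtry to use.
#' @param tolPts stabilization tolerance in percentage points.
#' @return list: `ntree` (chosen), `trace` (OOB error fraction at each
#'   schedule entry), `stabilized` (logical).
#' @export
tuneNtree <- function(x, labels, mtry, config = rfConfig(), tolPts = 0.5) {
  labels <- checkLabels(labels)
  sched <- config$ntreeSchedule
  set.seed(config$seed)
  fit <- randomForest::randomForest(x, labels, mtry = mtry,
                                    ntree = max(sched))
  trace <- fit$err.rate[sched, "OOB"]
  names(trace) <- sched
  if (length(sched) > 1L) {
    flat <- abs(diff(trace)) < tolPts / 100
    stableFrom <- Position(isFALSE, rev(flat))  # last unstable step
    k <- if (is.na(stableFrom) || is.null(stableFrom)) 1L
         else length(sched) - stableFrom + 1L
    if (k < length(sched))
      return(list(ntree = sched[k], trace = trace, stabilized = TRUE))
  }
  warning("OOB error did not stabilize within the ntree schedule; ",
          "using the largest entry")
  list(ntree = sched[length(sched)], trace = trace, stabilized = FALSE)
}

#' Backward factor elimination by Gini importance
#'
#' varSelRF-style selection: fit a forest on all factors, record the
#' OOB error and its binomial standard error, drop the least important
#' `eliminationDropFraction` of factors by mean decrease in Gini index,
#' and refit until two factors remain. The chosen set is the smallest
#' whose OOB error is within `seRuleMultiplier` standard errors of the
#' minimum observed OOB error. The full initial Gini ranking is returned
#' for cross-checking against the selection.
#'
#' @inheritParams tuneMtry
#' @param mtry forest mtry during elimination (capped at the surviving
#'   factor count).
#' @param ntree forest size per elimination step.
#' @return list: `selected` (factor names, by decreasing importance),
#'   `ranking` (named full-model Gini importance, decreasing),
#'   `history` (data.frame of set size and OOB error per step).
#' @export
selectFactors <- function(x, labels, mtry = NULL, ntree = 1000L,
                          config = rfConfig()) {
  labels <- checkLabels(labels)
  x <- as.data.frame(x)
  if (ncol(x) < 1L) stop("no factors supplied")
  if (ncol(x) == 1L)
    return(list(selected = names(x), ranking = stats::setNames(NA_real_, names(x)),
                history = data.frame(size = 1L, oob = NA_real_)))
  n <- length(labels)
  current <- names(x)
  sets <- list(); oobs <- numeric(); imps <- list()
  repeat {
    m <- if (is.null(mtry)) max(1L, floor(sqrt(length(current))))
         else min(mtry, length(current))
    set.seed(config$seed)
    fit <- randomForest::randomForest(x[current], labels, mtry = m,
                                      ntree = ntree, importance = FALSE)
    imp <- sort(randomForest::importance(fit, type = 2)[, 1], decreasing = TRUE)
    sets[[length(sets) + 1L]] <- names(imp)
    oobs <- c(oobs, oobErrorOf(fit))
    imps[[length(imps) + 1L]] <- imp
    if (length(current) <= 2L) break
    nDrop <- max(1L, floor(config$eliminationDropFraction * length(current)))
    current <- names(imp)[seq_len(length(imp) - nDrop)]
  }
  se <- sqrt(oobs * (1 - oobs) / n)
  best <- which.min(oobs)
  thresh <- oobs[best] + config$seRuleMultiplier * se[best]
  sizes <- lengths(sets)
  admissible <- which(oobs <= thresh)
  pick <- admissible[which.min(sizes[admissible])]
  list(selected = sets[[pick]],
       ranking = imps[[1L]],
       history = data.frame(size = sizes, oob = oobs, se = se))
}

#' Confusion counts from truth/prediction vectors
#'
#' @param truth,predicted class vectors (coerced to character).
#' @param positive class treated as positive.
#' @return A [ConfusionCounts-class].
#' @export
confusionCounts <- function(truth, predicted, positive = "0") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  keep <- !is.na(truth) & !is.na(predicted)
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) without a prediction (e.g. no ",
            "out-of-bag votes) excluded from the confusion matrix")
    truth <- truth[keep]; predicted <- predicted[keep]
  }
  pos <- as.character(positive)
  new("ConfusionCounts",
      tp = sum(truth == pos & predicted == pos),
      fn = sum(truth == pos & predicted != pos),
      fp = sum(truth != pos & predicted == pos),
      tn = sum(truth != pos & predicted != pos),
      positive = pos)
}

#' Classification metric suite from a confusion matrix
#'
#' Overall accuracy `(TP+TN)/(TP+FN+FP+TN)`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(FP+TN)`, positive prediction value `TP/(TP+FP)` and
#' negative prediction value `TN/(FN+TN)`, each as a percentage, plus
#' the complementary overall error and per-class error rates. Ratios
#' with a zero denominator are reported as `NA` (undefined), never as 0.
#' Values are exact; round only at display.
#'
#' @param confusion a [ConfusionCounts-class] (or the result of
#'   [confusionCounts()]).
#' @return named numeric (percent): `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `oob_error`, `error_positive_class`,
#'   `error_negative_class`.
#' @examples
#' cm <- new("ConfusionCounts", tp = 138, fn = 22, fp = 28, tn = 117,
#'           positive = "0")
#' round(classificationMetrics(cm), 2)
#' @export
classificationMetrics <- function(confusion) {
  stopifnot(is(confusion, "ConfusionCounts"))
  tp <- confusion@tp; fn <- confusion@fn; fp <- confusion@fp; tn <- confusion@tn
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  acc <- rate(tp + tn, tp + fn + fp + tn)
  c(accuracy = acc,
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, fp + tn),
    ppv = rate(tp, tp + fp),
    npv = rate(tn, fn + tn),
    oob_error = 100 - acc,
    error_positive_class = rate(fn, tp + fn),
    error_negative_class = rate(fp, fp + tn))
}

#' Train the tuned, factor-selected progression classifier
#'
#' End-to-end random-forest stage: tune mtry on the full factor set by
#' OOB error, choose ntree at OOB stabilization, run backward
#' elimination to the selected factor subset, and fit the final forest,
#' reporting its OOB confusion matrix and metric suite.
#'
#' @param table cohort feature data.frame (see
#'   [computeCohortFeatures()]).
#' @param config an [rfConfig()].
#' @param factors candidate factor columns (default [featureNames()]).
#' @return An [RFResult-class].
#' @export
trainProgressionModel <- function(table, config = rfConfig(),
                                  factors = featureNames()) {
  x <- as.data.frame(table[factors])
  labels <- checkLabels(table$label)
  mtry <- config$mtry
  if (identical(mtry, "auto")) mtry <- tuneMtry(x, labels, config)$mtry
  ntree <- config$ntree
  if (identical(ntree, "auto")) ntree <- tuneNtree(x, labels, mtry, config)$ntree
  sel <- selectFactors(x, labels, mtry = mtry, ntree = min(ntree, 1000L),
                       config = config)
  set.seed(config$seed)
  fit <- randomForest::randomForest(x[sel$selected], labels,
                                    mtry = min(mtry, length(sel$selected)),
                                    ntree = ntree)
  cm <- confusionCounts(labels, fit$predicted, config$positive)
  met <- classificationMetrics(cm)
  new("RFResult", mtry = as.numeric(min(mtry, length(sel$selected))),
      ntree = as.numeric(ntree), oobError = 100 * oobErrorOf(fit),
      importance = sel$ranking, selected = sel$selected, confusion = cm,
      metrics = met[c("accuracy", "sensitivity", "specificity", "ppv", "npv")],
      forest = fit)
}
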