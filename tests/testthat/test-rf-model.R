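test_that("Gini impurity follows 1 - sum(p^2) with its bounds", {
  expect_equal(giniImpurity(c(0.5, 0.5)), 0.5)
  expect_equal(giniImpurity(c(1, 0)), 0)
  expect_equal(giniImpurity(c(0.8, 0.2)), 0.32)
  expect_error(giniImpurity(c(0.5, 0.4)), "sum to 1")
  expect_error(giniImpurity(c(1.2, -0.2)), "\\[0, 1\\]")
  set.seed(1)
  for (k in 1:50) {
    p1 <- runif(1)
    g <- giniImpurity(c(p1, 1 - p1))
    expect_gte(g, 0); expect_lte(g, 0.5)
  }
})

test_that("the metric suite reproduces known confusion matrices exactly", {
  perfect <- new("ConfusionCounts", tp = 10, fn = 0, fp = 0, tn = 10,
                 positive = "0")
  expect_true(all(classificationMetrics(perfect)[1:5] == 100))
  even <- new("ConfusionCounts", tp = 5, fn = 5, fp = 5, tn = 5,
              positive = "0")
  expect_true(all(classificationMetrics(even)[1:5] == 50))
  # zero denominators are undefined, not zero
  noPos <- new("ConfusionCounts", tp = 0, fn = 0, fp = 3, tn = 7,
               positive = "1")
  m <- classificationMetrics(noPos)
  expect_true(is.na(m["sensitivity"]))
  expect_false(is.na(m["specificity"]))
})

test_that("accuracy decomposes over per-class rates on random matrices", {
  set.seed(2)
  for (k in 1:25) {
    cm <- new("ConfusionCounts", tp = sample(0:50, 1), fn = sample(1:50, 1),
              fp = sample(1:50, 1), tn = sample(0:50, 1), positive = "0")
    m <- classificationMetrics(cm)
    P <- cm@tp + cm@fn; N <- cm@fp + cm@tn
    expect_equal(m[["accuracy"]],
                 (m[["sensitivity"]] * P + m[["specificity"]] * N) / (P + N),
                 tolerance = 1e-12)
    expect_equal(m[["oob_error"]], 100 - m[["accuracy"]], tolerance = 1e-12)
  }
})

test_that("confusion counts respect the positive-class parameter", {
  truth <- c(0, 0, 1, 1, 1)
  pred <- c(0, 1, 1, 1, 0)
  cm0 <- confusionCounts(truth, pred, positive = "0")
  expect_equal(c(cm0@tp, cm0@fn, cm0@fp, cm0@tn), c(1, 1, 1, 2))
  cm1 <- confusionCounts(truth, pred, positive = "1")
  expect_equal(c(cm1@tp, cm1@fn, cm1@fp, cm1@tn), c(2, 1, 1, 1))
})

make_cohort_xy <- function(n = 300, pInf = 2, pNoise = 17, seed = 1,
                           beta = 2.5) {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * (pInf + pNoise)), n))
  names(x) <- paste0(c(rep("inf", pInf), rep("noise", pNoise)),
                     seq_len(pInf + pNoise))
  eta <- beta * rowSums(x[seq_len(pInf)])
  y <- factor(as.integer(runif(n) < plogis(eta)))
  list(x = x, y = y)
}

test_that("mtry tuning breaks ties toward the smallest candidate", {
  set.seed(3)
  n <- 120
  x <- data.frame(sep = rep(c(-2, 2), each = n / 2) + rnorm(n, 0, 0.1),
                  n1 = rnorm(n), n2 = rnorm(n))
  y <- factor(rep(c(0, 1), each = n / 2))
  tuned <- tuneMtry(x, y, rfConfig(tuneNtreeFixed = 300, seed = 3))
  expect_true(all(tuned$oob < 0.02))
  expect_equal(tuned$mtry, 1L)
})

test_that("pure-noise OOB error sits at chance and signal beats permutation", {
  d <- make_cohort_xy(n = 300, pInf = 0, pNoise = 19, seed = 4, beta = 0)
  set.seed(4)
  y <- factor(rep(0:1, 150))
  f <- randomForest::randomForest(d$x, y, mtry = 4, ntree = 500)
  oobNoise <- f$err.rate[500, "OOB"]
  expect_lt(abs(oobNoise - 0.5), 0.06)

  s <- make_cohort_xy(n = 300, pInf = 2, pNoise = 17, seed = 5)
  set.seed(5)
  fSig <- randomForest::randomForest(s$x, s$y, mtry = 4, ntree = 500)
  set.seed(5)
  fPerm <- randomForest::randomForest(s$x, sample(s$y), mtry = 4, ntree = 500)
  expect_lt(fSig$err.rate[500, "OOB"], fPerm$err.rate[500, "OOB"])
  expect_lt(abs(fPerm$err.rate[500, "OOB"] - 0.5), 0.08)
})

test_that("ntree selection returns the first entry of a flat OOB trace", {
  set.seed(6)
  n <- 150
  x <- data.frame(sep = rep(c(-3, 3), each = n / 2), n1 = rnorm(n))
  y <- factor(rep(c(0, 1), each = n / 2))
  cfg <- rfConfig(ntreeSchedule = c(100L, 200L, 300L, 400L), seed = 6)
  tn <- tuneNtree(x, y, mtry = 1, cfg)
  expect_equal(tn$ntree, 100L)
  expect_true(tn$stabilized)
  expect_length(tn$trace, 4L)
})

test_that("backward elimination keeps planted informative factors", {
  d <- make_cohort_xy(n = 300, seed = 7)
  sel <- selectFactors(d$x, d$y, mtry = 4, ntree = 500,
                       config = rfConfig(seed = 7))
  expect_true(all(c("inf1", "inf2") %in% sel$selected))
  expect_true(all(sel$selected %in% names(d$x)))
  # ordered by decreasing importance within the final ranking
  imp <- sel$ranking[sel$selected]
  expect_length(sel$ranking, 19L)
  expect_gt(min(sel$history$size), 1L)
  # single factor passes through
  one <- selectFactors(d$x["inf1"], d$y, config = rfConfig(seed = 7))
  expect_identical(one$selected, "inf1")
})

test_that("the trained progression model reports a coherent result object", {
  pairs <- generateCohort(cohortConfig(nPatients = 4L,
                                       slicesPerPatient = c(30L, 30L),
                                       totalSlices = NULL, seed = 9))
  feats <- computeCohortFeatures(pairs, surrogate = TRUE)
  rf <- trainProgressionModel(feats, rfConfig(mtry = 4, ntree = 500, seed = 9))
  expect_s4_class(rf, "RFResult")
  cm <- rf@confusion
  expect_equal(cm@tp + cm@fn + cm@fp + cm@tn, nrow(feats))
  expect_equal(unname(rf@metrics["accuracy"]),
               unname(classificationMetrics(cm)["accuracy"]))
  expect_equal(unname(rf@oobError), 100 - unname(rf@metrics["accuracy"]),
               tolerance = 1e-9)
  expect_true(all(rf@selected %in% featureNames()))
})
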