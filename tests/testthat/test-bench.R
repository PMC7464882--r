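test_that("yield labeling applies the DBH cutoff with high at the boundary", {
  pop <- tiny_population(n = 4, seed = 3)
  pop$dbh_cm <- c(4.06, 5.43, 4.3, 1.71)
  y <- label_yield(pop, cutoff = 4.3)
  expect_equal(as.character(y), c("low", "high", "high", "low"))
  pop$dbh_cm[1] <- NA
  expect_error(label_yield(pop), "missing DBH")
})

test_that("confusion quadrants cross observed yield with diagnosed balance", {
  y <- c(rep("high", 3), rep("low", 2))
  b <- c(rep("balanced", 3), rep("imbalanced", 2))
  q <- confusion_quadrants(y, b)
  expect_equal(unname(q[c("TN", "FN", "FP", "TP")]), c(3L, 0L, 0L, 2L))

  q2 <- confusion_quadrants(y, rep("balanced", 5))
  expect_equal(unname(q2["FP"] + q2["TP"]), 0L)

  # order invariance
  set.seed(42)
  y3 <- sample(c("low", "high"), 30, replace = TRUE)
  b3 <- sample(c("balanced", "imbalanced"), 30, replace = TRUE)
  perm <- sample(30)
  expect_equal(confusion_quadrants(y3, b3),
               confusion_quadrants(y3[perm], b3[perm]))
  expect_error(confusion_quadrants(y3, b3[1:10]), "length mismatch")
})

test_that("classification accuracy reproduces the published identities", {
  # confusion counts published for the survey's naive Bayes and neural nets
  expect_equal(round(classification_accuracy(
    c(TN = 614, FN = 318, FP = 212, TP = 717)), 3), 0.715)
  expect_equal(round(classification_accuracy(
    c(TN = 548, FN = 271, FP = 278, TP = 764)), 3), 0.705)
  expect_equal(classification_accuracy(c(TN = 1, FN = 0, FP = 0, TP = 0)), 1)
  expect_error(classification_accuracy(c(TN = 0, FN = 0, FP = 0, TP = 0)),
               "empty confusion matrix")

  # identity: CA from quadrants equals raw agreement accuracy
  set.seed(7)
  for (rep in 1:100) {
    n <- sample(5:50, 1)
    y <- sample(c("low", "high"), n, replace = TRUE)
    b <- sample(c("balanced", "imbalanced"), n, replace = TRUE)
    agree <- mean((y == "high") == (b == "balanced"))
    expect_equal(classification_accuracy(confusion_quadrants(y, b)), agree)
  }
})

test_that("rank-based AUC matches exhaustive pair counting", {
  expect_equal(auc_score(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.2)), 0.75)
  expect_equal(auc_score(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc_score(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_error(auc_score(c(1, 1, 1), c(0.1, 0.2, 0.3)), "single-class")

  # brute-force oracle: concordant pairs + half ties, all n <= 30 cases
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(4:30, 1)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- round(stats::runif(n), 1)  # coarse grid to force ties
    pos <- which(y); neg <- which(!y)
    conc <- 0
    for (i in pos) for (j in neg) {
      conc <- conc + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    }
    expect_equal(auc_score(y, s), conc / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }

  # factor labels: the "high" level is the positive class
  expect_equal(auc_score(factor(c("low", "high")), c(0.2, 0.9)), 1)
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 60
    y <- sample(c(0, 1), n, replace = TRUE, prob = c(0.4, 0.6))
    s <- round(stats::rnorm(n, mean = y), 1)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, levels = c(0, 1),
                                          direction = "<", quiet = TRUE)))
    expect_equal(auc_score(y, s), ref, tolerance = 1e-12)
  }
})

test_that("the naive Bayes engine runs under the same seeded protocol", {
  pop <- suppressMessages(make_benchmark_population("nutrients+factors",
                                                    n = 300, seed = 12))
  feats <- cndiag:::expression_features(pop, "clr", include_factors = FALSE)
  dat <- cbind(yield = label_yield(pop), feats)
  b <- cross_validate(dat, names(feats), runs = 2, seed = 3,
                      engine = "naive_bayes")
  expect_length(b$auc, 2)
  expect_true(all(b$auc >= 0 & b$auc <= 1))
  b2 <- cross_validate(dat, names(feats), runs = 2, seed = 3,
                       engine = "naive_bayes")
  expect_identical(b$auc, b2$auc)
  expect_error(cross_validate(dat, names(feats), runs = 1, seed = 1,
                              engine = "mystery"), "unknown engine")
})

test_that("AUC informativeness bands follow the 0.7/0.9 thresholds", {
  expect_equal(classify_informative(0.63), "uninformative")
  expect_equal(classify_informative(0.78), "informative")
  expect_equal(classify_informative(0.7), "informative")
  expect_equal(classify_informative(0.9), "informative")
  expect_equal(classify_informative(0.95), "highly-informative")
  expect_error(classify_informative(1.2), "lie in")
})

test_that("Monte-Carlo holdout cross-validation is seeded and reproducible", {
  pop <- suppressMessages(make_benchmark_population("nutrients+factors",
                                                    n = 300, seed = 5))
  yield <- label_yield(pop)
  feats <- cndiag:::expression_features(pop, "clr", include_factors = TRUE)
  dat <- cbind(yield = yield, feats)
  b1 <- cross_validate(dat, names(feats), runs = 3, seed = 77, num_trees = 100)
  b2 <- cross_validate(dat, names(feats), runs = 3, seed = 77, num_trees = 100)
  expect_identical(b1$auc, b2$auc)
  expect_identical(b1$ca, b2$ca)
  expect_length(b1$auc, 3)
  expect_equal(b1$run_seeds, 77 + 1:3)
  expect_equal(sum(b1$quadrants), 3 * 30)
  expect_error(cross_validate(dat, names(feats), runs = 2), "seed is required")
})

test_that("expression benchmark pairs folds across feature expressions", {
  pop <- suppressMessages(make_benchmark_population("nutrients-only",
                                                    n = 300, seed = 9))
  res <- expression_bench(pop, expressions = c("raw", "clr", "ilr", "pwlr"),
                          runs = 2, seed = 11, num_trees = 100)
  expect_equal(nrow(res$summary), 4)
  expect_equal(res$summary$expression, c("raw", "clr", "ilr", "pwlr"))
  # same folds: identical run seeds across expressions
  expect_identical(res$raw$run_seeds, res$pwlr$run_seeds)
  # feature counts per expression
  expect_length(cndiag:::expression_features(pop, "pwlr"), 66)
  expect_length(cndiag:::expression_features(pop, "clr"), 12)
  expect_length(cndiag:::expression_features(pop, "ilr"), 11)
  expect_length(cndiag:::expression_features(pop, "raw"), 11)
})

test_that("raw and clr expressions carry the same information on a noiseless rule", {
  pop <- suppressMessages(make_benchmark_population("nutrients-only",
                                                    n = 400, seed = 15))
  # noiseless rule: yield determined by one clr coordinate alone
  cl <- specimen_clr(pop)
  pop$dbh_cm <- ifelse(cl[, "N"] > stats::median(cl[, "N"]), 6, 2)
  res <- expression_bench(pop, expressions = c("raw", "clr"),
                          runs = 5, seed = 19, num_trees = 200)
  expect_gt(min(res$summary$auc), 0.9)
  expect_lt(abs(res$summary$auc[1] - res$summary$auc[2]), 0.05)
})

test_that("feature ablation flags the sole signal feature", {
  set.seed(123)
  n <- 400
  signal <- stats::rnorm(n)
  dat <- data.frame(
    yield = factor(ifelse(signal + stats::rnorm(n, 0, 0.4) > 0,
                          "high", "low"), levels = c("low", "high")),
    signal = signal,
    dup = signal,               # exact duplicate: removal must be harmless
    noise = stats::rnorm(n))
  ab <- feature_ablation(dat, c("signal", "dup", "noise"),
                         runs = 3, seed = 55, num_trees = 150)
  expect_equal(nrow(ab), 3)
  expect_lt(abs(ab$delta_auc[ab$feature == "dup"]), 0.05)
  expect_lt(abs(ab$delta_auc[ab$feature == "signal"]), 0.05)
  # removing both copies of the signal is catastrophic; removing noise is not
  ab2 <- feature_ablation(dat[, c("yield", "signal", "noise")],
                          c("signal", "noise"),
                          runs = 3, seed = 55, num_trees = 150)
  expect_lt(ab2$delta_auc[ab2$feature == "signal"], -0.2)
  expect_gt(ab2$delta_auc[ab2$feature == "noise"], -0.1)
})

test_that("the chi-squared balance criterion flags distant compositions", {
  pop <- tiny_population(n = 200, seed = 61)
  bal <- chi2_balance(pop, fx$norms, alpha = 0.05)
  expect_true(all(bal %in% c("balanced", "imbalanced")))
  # the population is drawn at the norms, so most specimens are balanced
  expect_gt(mean(bal == "balanced"), 0.5)
  # a grossly perturbed specimen is imbalanced
  bad <- pop[1, , drop = FALSE]
  bad$mn_mg_kg <- bad$mn_mg_kg * 40
  expect_equal(chi2_balance(bad, fx$norms), "imbalanced")
})
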