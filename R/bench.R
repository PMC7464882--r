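#' Label specimens as low or high yielding
#'
#' Partitions the population at a critical DBH (default 4.3 cm, an
#' economically viable yield target). A specimen exactly at the cutoff is
#' labeled `high` (recorded convention).
#'
#' @param specimens Canonical specimen data frame.
#' @param cutoff Critical DBH in cm (default 4.3).
#' @return Factor of labels (`low`/`high`) aligned with the rows.
#' @export
label_yield <- function(specimens, cutoff = 4.3) {
  dbh <- specimens$dbh_cm
  if (is.null(dbh) || any(is.na(dbh))) stop("missing DBH")
  factor(ifelse(dbh >= cutoff, "high", "low"), levels = c("low", "high"))
}

#' Confusion quadrants from yield and nutrient-balance classes
#'
#' Crosses the observed yield class with the diagnosed (or predicted)
#' nutrient-balance class into the four diagnostic quadrants:
#' * TN (true negative): high yield, balanced — negative response to
#'   fertilization; these specimens supply the reference norms;
#' * FN (false negative): low yield despite balance — some other factor
#'   limits yield;
#' * FP (false positive): high yield despite imbalance — luxury consumption
#'   or contamination;
#' * TP (true positive): low yield and imbalance — expected to respond to
#'   fertilization.
#'
#' @param yield Factor/character of `low`/`high` observed yield classes.
#' @param balance Factor/character of `balanced`/`imbalanced` diagnoses.
#' @return Object of class `confusion_quadrants`: named integer vector
#'   `c(TN, FN, FP, TP)`.
#' @export
confusion_quadrants <- function(yield, balance) {
  if (length(yield) != length(balance)) stop("length mismatch")
  yield <- as.character(yield); balance <- as.character(balance)
  stopifnot(all(yield %in% c("low", "high")),
            all(balance %in% c("balanced", "imbalanced")))
  q <- c(TN = sum(yield == "high" & balance == "balanced"),
         FN = sum(yield == "low" & balance == "balanced"),
         FP = sum(yield == "high" & balance == "imbalanced"),
         TP = sum(yield == "low" & balance == "imbalanced"))
  structure(as.integer(q), names = names(q), class = "confusion_quadrants")
}

#' Classification accuracy from confusion quadrants
#'
#' \eqn{CA = (TN + TP) / (TN + FN + FP + TP)}: the fraction of specimens
#' whose diagnosed balance agrees with their observed yield class.
#'
#' @param q A `confusion_quadrants` vector or any named vector with
#'   `TN, FN, FP, TP`.
#' @return CA as a fraction in `[0, 1]`.
#' @export
classification_accuracy <- function(q) {
  need <- c("TN", "FN", "FP", "TP")
  if (!all(need %in% names(q))) stop("need named counts TN, FN, FP, TP")
  tot <- sum(q[need])
  if (tot == 0) stop("empty confusion matrix")
  unname((q["TN"] + q["TP"]) / tot)
}

#' Rank-based AUC (Mann-Whitney with midrank ties)
#'
#' Area under the ROC curve computed as the Mann-Whitney U statistic on
#' score ranks, using midranks for ties: the probability that a random
#' positive scores above a random negative, counting ties as one half.
#'
#' @param labels Binary labels: logical, 0/1, or a factor whose `"high"`
#'   (or last) level is the positive class.
#' @param scores Numeric scores, larger meaning more likely positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("length mismatch")
  if (is.factor(labels) || is.character(labels)) {
    lv <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
    pos_level <- if ("high" %in% lv) "high" else lv[length(lv)]
    pos <- labels == pos_level
  } else {
    pos <- as.logical(labels)
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("single-class input: need both classes")
  r <- rank(scores)  # midranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Interpret an AUC value
#'
#' @param auc AUC in `[0, 1]`.
#' @return `"uninformative"` below 0.7, `"informative"` in `[0.7, 0.9]`,
#'   `"highly-informative"` above 0.9.
#' @export
classify_informative <- function(auc) {
  if (auc < 0 || auc > 1) stop("AUC must lie in [0, 1]")
  if (auc < 0.7) "uninformative"
  else if (auc <= 0.9) "informative"
  else "highly-informative"
}

# fit the configured classifier and return P(high) on newdata
fit_and_score <- function(train, test, features, engine, seed, num_trees) {
  fml <- stats::as.formula(paste("yield ~",
                                 paste(sprintf("`%s`", features),
                                       collapse = " + ")))
  if (engine == "ranger") {
    fit <- ranger::ranger(fml, data = train, probability = TRUE,
                          num.trees = num_trees, seed = seed,
                          num.threads = 1,
                          respect.unordered.factors = "order")
    stats::predict(fit, data = test, num.threads = 1)$predictions[, "high"]
  } else if (engine == "naive_bayes") {
    if (!requireNamespace("e1071", quietly = TRUE)) {
      stop("engine 'naive_bayes' requires the e1071 package")
    }
    fit <- e1071::naiveBayes(fml, data = train)
    stats::predict(fit, newdata = test, type = "raw")[, "high"]
  } else {
    stop("unknown engine: ", engine)
  }
}

#' Monte-Carlo holdout cross-validation of a yield classifier
#'
#' For each run, a seeded random fraction of the data is held out and scored
#' by a model trained on the remainder; AUC and classification accuracy are
#' averaged over runs (default 10 runs of 10% holdout). Predicted balance is
#' taken as the predicted yield class (predicted high = balanced), so the
#' confusion quadrants come from the model's confusion matrix. Run seeds are
#' recorded for exact replay; if a holdout happens to miss one class it is
#' resampled with a logged retry.
#'
#' @param data Data frame containing a `yield` factor (`low`/`high`) and the
#'   feature columns.
#' @param features Character vector of feature column names.
#' @param runs Number of Monte-Carlo runs (default 10).
#' @param holdout Holdout fraction (default 0.1).
#' @param seed Integer seed governing all randomness.
#' @param engine `"ranger"` (random forest, default) or `"naive_bayes"`.
#' @param num_trees Trees per forest (default 500).
#' @param expression Label stored on the result.
#' @return Object of class `bench_result`: list with `expression`,
#'   `mean_auc`, `mean_ca`, per-run `auc`/`ca`, summed `quadrants`, and
#'   `run_seeds`.
#' @export
cross_validate <- function(data, features, runs = 10, holdout = 0.1,
                           seed, engine = "ranger", num_trees = 500,
                           expression = "features") {
  if (missing(seed)) stop("seed is required for cross-validation")
  stopifnot(is.factor(data$yield), all(features %in% names(data)))
  n <- nrow(data)
  run_seeds <- seed + seq_len(runs)
  auc <- ca <- numeric(runs)
  quad <- c(TN = 0L, FN = 0L, FP = 0L, TP = 0L)
  for (i in seq_len(runs)) {
    rs <- run_seeds[i]
    repeat {
      set.seed(rs)
      test_idx <- sample.int(n, size = max(2, round(holdout * n)))
      test <- data[test_idx, , drop = FALSE]
      train <- data[-test_idx, , drop = FALSE]
      if (nlevels(droplevels(test$yield)) == 2 &&
          nlevels(droplevels(train$yield)) == 2) break
      message("holdout missed a class; resampling run ", i)
      rs <- rs + 7919L
    }
    p_high <- fit_and_score(train, test, features, engine,
                            seed = run_seeds[i], num_trees = num_trees)
    auc[i] <- auc_score(test$yield, p_high)
    balance <- ifelse(p_high >= 0.5, "balanced", "imbalanced")
    q <- confusion_quadrants(test$yield, balance)
    ca[i] <- classification_accuracy(q)
    quad <- quad + q
  }
  structure(list(expression = expression, engine = engine,
                 mean_auc = mean(auc), mean_ca = mean(ca),
                 auc = auc, ca = ca, quadrants = quad,
                 runs = runs, holdout = holdout, run_seeds = run_seeds),
            class = "bench_result")
}

#' @export
print.bench_result <- function(x, ...) {
  cat(sprintf("<bench_result> %s (%s): mean AUC %.3f (%s), mean CA %.3f over %d runs\n",
              x$expression, x$engine, x$mean_auc,
              classify_informative(x$mean_auc), x$mean_ca, x$runs))
  invisible(x)
}

# build the feature data frame for one nutrient expression
expression_features <- function(specimens, expression, kappa = 1000,
                                include_factors = FALSE,
                                sbp = build_default_sbp()) {
  comp <- specimen_compositions(specimens, kappa = kappa)
  feats <- switch(expression,
    raw  = as.data.frame(specimens[, nutrient_columns()]),
    clr  = as.data.frame(clr_transform(comp)),
    ilr  = as.data.frame(ilr_transform(comp, sbp)),
    pwlr = as.data.frame(pwlr_features(comp)),
    stop("unknown expression: ", expression))
  if (expression == "clr") names(feats) <- paste0("clr_", composition_parts())
  if (expression == "ilr") names(feats) <- sprintf("ilr_%02d", 1:11)
  if (include_factors) {
    feats$clone <- factor(specimens$clone)
    feats$soil_type <- factor(specimens$soil_type)
    feats$location <- factor(specimens$location)
    feats$age_yr <- specimens$age_yr
  }
  rownames(feats) <- NULL
  feats
}

#' Benchmark nutrient expressions under a shared protocol
#'
#' Runs the same Monte-Carlo holdout protocol on several feature expressions
#' of the tissue composition — raw concentrations (11 features), pairwise
#' log ratios (66), clr (12), ilr balances (11) — with identical fold seeds,
#' so results are paired across expressions.
#'
#' @param specimens Canonical specimen data frame.
#' @param expressions Subset of `c("raw", "pwlr", "clr", "ilr")`.
#' @param include_factors Also include clone, soil type, location and age as
#'   features (default FALSE).
#' @param cutoff Critical DBH for [label_yield()].
#' @param ... Passed to [cross_validate()] (`runs`, `holdout`, `seed`,
#'   `engine`, `num_trees`).
#' @return List of [cross_validate()] results, one per expression, plus a
#'   `summary` data frame (expression, AUC, CA, TN, FN, FP, TP).
#' @export
expression_bench <- function(specimens,
                             expressions = c("raw", "pwlr", "clr", "ilr"),
                             include_factors = FALSE, cutoff = 4.3, ...) {
  yield <- label_yield(specimens, cutoff = cutoff)
  results <- lapply(expressions, function(ex) {
    feats <- expression_features(specimens, ex,
                                 include_factors = include_factors)
    dat <- cbind(yield = yield, feats)
    cross_validate(dat, features = names(feats), expression = ex, ...)
  })
  names(results) <- expressions
  summary <- do.call(rbind, lapply(results, function(r) {
    data.frame(expression = r$expression, auc = r$mean_auc, ca = r$mean_ca,
               TN = r$quadrants["TN"], FN = r$quadrants["FN"],
               FP = r$quadrants["FP"], TP = r$quadrants["TP"],
               row.names = NULL)
  }))
  c(results, list(summary = summary))
}

#' Leave-one-feature-out ablation
#'
#' Re-runs the cross-validation with each feature removed in turn (same fold
#' seeds as the full model) and reports the change in mean AUC. A strongly
#' negative delta marks a feature the model depends on; a delta near zero a
#' redundant one.
#'
#' @param data Data frame with `yield` factor and feature columns.
#' @param features Feature column names.
#' @param ... Passed to [cross_validate()].
#' @return Data frame with one row per feature: `feature`,
#'   `mean_auc_without`, `delta_auc` (without minus full).
#' @export
feature_ablation <- function(data, features, ...) {
  if (length(features) < 2) stop("need at least 2 features to ablate")
  full <- cross_validate(data, features, expression = "full", ...)
  rows <- lapply(features, function(f) {
    r <- cross_validate(data, setdiff(features, f),
                        expression = paste0("without_", f), ...)
    data.frame(feature = f, mean_auc_without = r$mean_auc,
               delta_auc = r$mean_auc - full$mean_auc, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_auc") <- full$mean_auc
  out
}

#' Chi-squared balance criterion (alternative to model-predicted balance)
#'
#' Diagnoses each specimen as `balanced` when its global CND imbalance
#' \eqn{r^2 = \sum I_i^2} stays below the chi-squared critical value with 11
#' degrees of freedom, `imbalanced` otherwise. This is the compositional
#' alternative to using a classifier's predicted yield class as the balance
#' criterion; the classifier route is the default elsewhere.
#'
#' @param specimens Canonical specimen data frame.
#' @param norms [reference_norms()].
#' @param alpha Upper-tail probability for the critical value (default
#'   0.05).
#' @param kappa Closure constant.
#' @return Character vector of `balanced`/`imbalanced`.
#' @export
chi2_balance <- function(specimens, norms, alpha = 0.05, kappa = 1000) {
  cl <- specimen_clr(specimens, kappa = kappa)
  idx <- sweep(sweep(cl, 2, norms$mean), 2, norms$sd, `/`)
  r2 <- rowSums(idx^2)
  crit <- stats::qchisq(1 - alpha, df = 11)
  unname(ifelse(r2 <= crit, "balanced", "imbalanced"))
}
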