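# Replicated rare-event classification of HAAD vs non-HAAD days.
#
# The experiment: label October-December days by the HAAD detector, train a
# classifier (logistic regression with linearised covariates, or
# componentwise gradient boosting) on a random 70% of days, score the held
# 30%, flag the top-k scored days where k is the number of observed HAADs
# in the test set, and average the 2x2 confusion counts over replicates.

#' Classifier specification for HAAD prediction
#'
#' @param variant `"logistic"` (linear logistic regression) or
#'   `"boosting"` (componentwise gradient boosting; linear base learners
#'   for most covariates, smoothing splines for precipitation and the
#'   rolling temperature/humidity means, and a shallow tree over the
#'   thunderstorm and pollen variables to allow their interactions).
#' @param covariates covariate columns used as (linear) predictors.
#' @param smooth_terms boosting covariates given smoothing-spline base
#'   learners.
#' @param tree_terms boosting covariate group given the tree base learner.
#' @param mstop boosting iterations.
#' @param nu boosting learning rate.
#' @param tree_maxdepth boosting tree depth.
#' @param threshold_rule how many test days to flag: `"test_count"` flags
#'   as many days as the test set holds observed HAADs (the default);
#'   `"train_frequency"` flags `round(train prevalence * test size)` days.
#' @return object of class `"classifier_spec"`.
#' @export
classifier_spec <- function(variant = c("logistic", "boosting"),
                            covariates = c("seasonal", "working_day",
                                           "RH_rl", "RH_dv", "TM_rl",
                                           "TM_dv", "PR", "NS", "EW",
                                           "GR", "NG", "GR_lg", "NG_lg",
                                           "TS"),
                            smooth_terms = c("PR", "TM_rl", "RH_rl"),
                            tree_terms = c("TS", "GR", "NG", "GR_lg",
                                           "NG_lg"),
                            mstop = 100, nu = 0.1, tree_maxdepth = 2,
                            threshold_rule = c("test_count",
                                               "train_frequency")) {
  structure(list(variant = match.arg(variant), covariates = covariates,
                 smooth_terms = smooth_terms, tree_terms = tree_terms,
                 mstop = mstop, nu = nu, tree_maxdepth = tree_maxdepth,
                 threshold_rule = match.arg(threshold_rule)),
            class = "classifier_spec")
}

#' Binary HAAD labels for the pollen-season days
#'
#' @param series the [admission_series()] the detector ran on.
#' @param haad_dates `Date` vector of detected HAADs (from
#'   [detect_haads()] on the full series).
#' @return data.frame with columns `date` and `label` (0/1), restricted
#'   to October-December days of the series.
#' @export
make_labels <- function(series, haad_dates) {
  stopifnot(is.data.frame(series), "date" %in% names(series))
  keep <- month_num(series$date) >= 10L
  data.frame(date = series$date[keep],
             label = as.integer(series$date[keep] %in% haad_dates))
}

#' Assemble the classification frame
#'
#' Joins labels with the linearised covariates, the precomputed seasonal
#' effect (evaluated from a fitted [fit_seasonal_cycle()] cycle) and the
#' working-day indicator (Monday-Friday and not in `holidays`).
#'
#' @param labels output of [make_labels()].
#' @param covariates covariate series with the derived columns.
#' @param cycle a fitted `"seasonal_cycle"` supplying the fixed seasonal
#'   covariate.
#' @param holidays optional `Date` vector of public holidays.
#' @return data.frame of complete rows: `date`, `label`, `seasonal`,
#'   `working_day` and the engineered covariates.
#' @export
build_class_frame <- function(labels, covariates, cycle,
                              holidays = as.Date(character(0))) {
  stopifnot(inherits(cycle, "seasonal_cycle"))
  d <- merge(labels, as.data.frame(covariates), by = "date")
  d$seasonal <- predict(cycle, day_of_year_cyclic(d$date))
  wk <- weekday_factor(d$date)
  d$working_day <- as.integer(!wk %in% c("Sa", "Su") &
                                !d$date %in% holidays)
  d$TS <- as.numeric(d$TS)
  keep <- c("date", "label", "seasonal", "working_day", "RH_rl", "RH_dv",
            "TM_rl", "TM_dv", "PR", "NS", "EW", "GR", "NG", "GR_lg",
            "NG_lg", "TS")
  keep <- intersect(keep, names(d))
  d <- d[, keep]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Random day-level train/test split with a minimum of test HAADs
#'
#' Samples a uniform random split of the labelled days (70% train by
#' default) and re-draws until the test set contains at least
#' `min_test_haads` positive labels (and, so that a classifier can be
#' trained at all, the training set keeps at least `min_train_haads`).
#'
#' @param frame labelled data.frame (column `label`).
#' @param train_fraction fraction of days assigned to training.
#' @param min_test_haads minimum positives required in the test set.
#' @param min_train_haads minimum positives left in the training set.
#' @param seed optional integer seed for the draw.
#' @param max_tries resampling attempts before giving up.
#' @return list with data.frames `train` and `test`.
#' @export
split_train_test <- function(frame, train_fraction = 0.7,
                             min_test_haads = 2L, min_train_haads = 0L,
                             seed = NULL, max_tries = 1000L) {
  stopifnot("label" %in% names(frame))
  n <- nrow(frame)
  if (sum(frame$label) < min_test_haads + min_train_haads)
    stopf("infeasible split: fewer than %d positive labels in total",
          min_test_haads + min_train_haads)
  if (!is.null(seed)) set.seed(seed)
  n_test <- round((1 - train_fraction) * n)
  for (t in seq_len(max_tries)) {
    idx_test <- sample.int(n, n_test)
    k <- sum(frame$label[idx_test])
    if (k >= min_test_haads && sum(frame$label) - k >= min_train_haads)
      return(list(train = frame[-idx_test, , drop = FALSE],
                  test = frame[idx_test, , drop = FALSE]))
  }
  stopf("no acceptable split found in %d attempts", max_tries)
}

#' Fit a HAAD classifier
#'
#' @param train training frame (columns `label` and the spec covariates).
#' @param spec a [classifier_spec()].
#' @return object of class `"haad_classifier"`; `predict(.., newdata)`
#'   returns HAAD probabilities.
#' @export
fit_classifier <- function(train, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (length(unique(train$label)) < 2)
    stopf("degenerate fit: training set contains a single class")
  covs <- intersect(spec$covariates, names(train))
  if (spec$variant == "logistic") {
    form <- as.formula(paste("label ~", paste(covs, collapse = " + ")))
    model <- suppressWarnings(
      stats::glm(form, data = train, family = stats::binomial()))
  } else {
    lin <- setdiff(covs, c(spec$smooth_terms, spec$tree_terms))
    model <- boost_logit(train[covs], train$label,
                         linear_terms = lin,
                         smooth_terms = intersect(spec$smooth_terms, covs),
                         tree_terms = intersect(spec$tree_terms, covs),
                         mstop = spec$mstop, nu = spec$nu,
                         tree_maxdepth = spec$tree_maxdepth)
  }
  structure(list(model = model, spec = spec, covariates = covs),
            class = "haad_classifier")
}

#' @export
predict.haad_classifier <- function(object, newdata, ...) {
  if (object$spec$variant == "logistic")
    as.numeric(suppressWarnings(
      predict(object$model, newdata = newdata, type = "response")))
  else
    as.numeric(predict(object$model, newdata = newdata[object$covariates]))
}

#' Flag the top-k scored days
#'
#' Exactly `k` days are flagged: those with the highest scores, ties
#' broken by earlier date (stable order when no dates are given).
#'
#' @param scores numeric scores.
#' @param k number of days to flag (`0 <= k <= length(scores)`).
#' @param dates optional `Date` vector for tie-breaking.
#' @return logical vector with exactly `k` `TRUE` entries.
#' @export
discretise_topk <- function(scores, k, dates = NULL) {
  n <- length(scores)
  if (k > n || k < 0) stopf("'k' must lie in 0..length(scores)")
  out <- rep(FALSE, n)
  if (k == 0) return(out)
  ord <- if (is.null(dates)) order(-scores) else order(-scores, dates)
  out[ord[seq_len(k)]] <- TRUE
  out
}

#' Replicated train/test evaluation of a HAAD classifier
#'
#' Repeats the split / fit / score / top-k cycle `n_replicates` times and
#' averages the resulting 2x2 confusion counts. Within each replicate the
#' number of flagged test days `k` follows the spec's threshold rule
#' (test-set HAAD count by default), so `hits + false_alarms = k` and
#' `hits + misses = test positives` hold exactly per replicate.
#'
#' @param frame labelled classification frame from [build_class_frame()].
#' @param spec a [classifier_spec()].
#' @param n_replicates number of random splits (default 100).
#' @param seed integer seed controlling the whole experiment.
#' @param train_fraction,min_test_haads passed to [split_train_test()].
#' @return object of class `"haad_evaluation"`: `replicates` (per-replicate
#'   counts), `mean_table` (averaged 2x2 confusion matrix, observed by
#'   predicted) and `tpr` (ratio of mean hits to mean observed positives).
#' @export
evaluate_replicates <- function(frame, spec = classifier_spec(),
                                n_replicates = 100L, seed = 1L,
                                train_fraction = 0.7, min_test_haads = 2L) {
  set.seed(seed)
  rep_seeds <- sample.int(1e8, n_replicates)
  res <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    sp <- tryCatch(
      split_train_test(frame, train_fraction, min_test_haads,
                       min_train_haads = 1L, seed = rep_seeds[r]),
      error = function(e) stopf("replicate %d: %s", r, conditionMessage(e)))
    cls <- tryCatch(fit_classifier(sp$train, spec),
                    error = function(e)
                      stopf("replicate %d: %s", r, conditionMessage(e)))
    scores <- predict(cls, sp$test)
    k <- switch(spec$threshold_rule,
                test_count = sum(sp$test$label),
                train_frequency = round(mean(sp$train$label) *
                                          nrow(sp$test)))
    pred <- discretise_topk(scores, k, sp$test$date)
    obs <- sp$test$label == 1
    res[[r]] <- data.frame(replicate = r, k = k,
                           n_test = nrow(sp$test),
                           hits = sum(pred & obs),
                           misses = sum(!pred & obs),
                           false_alarms = sum(pred & !obs),
                           correct_neg = sum(!pred & !obs))
  }
  reps <- do.call(rbind, res)
  mt <- matrix(c(mean(reps$correct_neg), mean(reps$false_alarms),
                 mean(reps$misses), mean(reps$hits)),
               nrow = 2, byrow = TRUE,
               dimnames = list(observed = c("not HAAD", "HAAD"),
                               predicted = c("not HAAD", "HAAD")))
  structure(list(replicates = reps, mean_table = mt,
                 tpr = mean(reps$hits) /
                   (mean(reps$hits) + mean(reps$misses))),
            class = "haad_evaluation")
}

#' @export
print.haad_evaluation <- function(x, ...) {
  cat("Replicated HAAD classification (", nrow(x$replicates),
      " splits)\n", sep = "")
  print(round(x$mean_table, 2))
  cat(sprintf("true-positive rate: %.1f%%\n", 100 * x$tpr))
  invisible(x)
}
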