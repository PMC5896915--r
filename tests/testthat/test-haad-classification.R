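# Shared classification frame: labels from injected spikes on a simulation
# with frequent triggers, covariates linearised, seasonal effect fixed.
class_frame <- local({
  env <- new.env()
  function() {
    if (is.null(env$fr)) {
      cfg <- generator_config(n_years = 6, spike_multiplier = 4,
                              spike_prob = 1, spike_grlg_q = 0.5,
                              spike_rh_q = 0.3)
      sim <- simulate_study(cfg, seed = 77)
      cyc <- fit_seasonal_cycle(sim$admissions)
      labels <- make_labels(sim$admissions, detect_haads(sim$admissions))
      env$fr <- build_class_frame(labels, sim$covariates, cyc)
    }
    env$fr
  }
})

test_that("labels are restricted to October-December days", {
  sim <- shared_sim()
  feb_haad <- as.Date("2002-02-10")
  nov_haad <- as.Date("2002-11-10")
  lab <- make_labels(sim$admissions, c(feb_haad, nov_haad))
  expect_true(all(format(lab$date, "%m") %in% c("10", "11", "12")))
  expect_equal(sum(lab$label), 1)
  expect_equal(lab$date[lab$label == 1], nov_haad)
  lab0 <- make_labels(sim$admissions, as.Date(character(0)))
  expect_true(all(lab0$label == 0))
})

test_that("train/test splits respect sizes and the minimum-HAAD constraint", {
  fr <- data.frame(date = seq(as.Date("2001-10-01"), by = "day",
                              length.out = 100),
                   label = c(rep(1, 5), rep(0, 95)), x = rnorm(100))
  sp <- split_train_test(fr, seed = 1)
  expect_equal(nrow(sp$test), 30)
  expect_equal(nrow(sp$train), 70)
  expect_gte(sum(sp$test$label), 2)
  # with exactly two positives both must land in the test set
  fr2 <- fr
  fr2$label <- c(rep(1, 2), rep(0, 98))
  for (s in 1:5) {
    sp2 <- split_train_test(fr2, seed = s)
    expect_equal(sum(sp2$test$label), 2)
  }
  fr3 <- fr
  fr3$label <- 0
  expect_error(split_train_test(fr3), "infeasible")
})

test_that("test membership is near-uniform at the target fraction", {
  fr <- data.frame(date = seq(as.Date("2001-10-01"), by = "day",
                              length.out = 200),
                   label = c(rep(1, 8), rep(0, 192)))
  hits <- numeric(200)
  for (s in 1:100) {
    sp <- split_train_test(fr, seed = s)
    hits <- hits + as.integer(fr$date %in% sp$test$date)
  }
  freq <- hits[9:200] / 100   # negatives: unconstrained by resampling
  expect_lt(abs(mean(freq) - 0.3), 3 * sqrt(0.3 * 0.7 / (100 * 192)) + 0.01)
})

test_that("top-k discretisation flags exactly k days with date tie-breaks", {
  scores <- c(0.9, 0.5, 0.5, 0.1)
  dates <- as.Date("2001-10-01") + 0:3
  expect_equal(discretise_topk(scores, 0, dates), rep(FALSE, 4))
  expect_equal(discretise_topk(scores, 4, dates), rep(TRUE, 4))
  expect_equal(discretise_topk(scores, 2, dates), c(TRUE, TRUE, FALSE, FALSE))
  # reversing the dates sends the later tied score into the selection
  expect_equal(discretise_topk(scores, 2, rev(dates)),
               c(TRUE, FALSE, TRUE, FALSE))
  expect_error(discretise_topk(scores, 5, dates), "0..length")
})

test_that("classifiers require two classes and produce probabilities", {
  fr <- class_frame()
  expect_gte(sum(fr$label), 3)
  one_class <- fr[fr$label == 0, ]
  expect_error(fit_classifier(one_class), "single class")
  cls <- fit_classifier(fr, classifier_spec("logistic"))
  p <- predict(cls, fr)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("a separable feature is learned perfectly by both variants", {
  set.seed(4)
  n <- 300
  fr <- data.frame(date = seq(as.Date("2001-10-01"), by = "day",
                              length.out = n),
                   label = rbinom(n, 1, 0.1))
  fr$seasonal <- fr$label * 2 + rnorm(n, sd = 0.01)
  fr$working_day <- rbinom(n, 1, 0.7)
  for (v in c("RH_rl", "TM_rl", "PR", "GR_lg", "TS")) fr[[v]] <- rnorm(n)
  for (variant in c("logistic", "boosting")) {
    cls <- fit_classifier(fr, classifier_spec(variant, mstop = 60))
    acc <- mean((predict(cls, fr) > 0.5) == fr$label)
    expect_gte(acc, 0.99)
  }
})

test_that("boosting with zero iterations scores every day identically", {
  fr <- class_frame()
  cls <- fit_classifier(fr, classifier_spec("boosting", mstop = 0))
  p <- predict(cls, fr)
  expect_equal(length(unique(p)), 1)
  expect_equal(unique(p), mean(fr$label), tolerance = 1e-8)
})

test_that("replicated evaluation keeps its bookkeeping identities", {
  fr <- class_frame()
  ev <- evaluate_replicates(fr, classifier_spec("logistic"),
                            n_replicates = 20, seed = 3)
  r <- ev$replicates
  expect_true(all(r$hits + r$false_alarms == r$k))
  expect_true(all(r$hits + r$misses >= 2))   # the split constraint
  expect_true(all(r$hits + r$misses + r$false_alarms + r$correct_neg ==
                    r$n_test))
  # averaged observed row sums equal the mean test composition
  expect_equal(sum(ev$mean_table["HAAD", ]), mean(r$hits + r$misses))
  # full determinism given the seed
  ev2 <- evaluate_replicates(fr, classifier_spec("logistic"),
                             n_replicates = 20, seed = 3)
  expect_identical(ev$replicates, ev2$replicates)
})

test_that("weak probabilistic spike triggers give a low true-positive rate", {
  # spikes only probabilistically linked to covariates: prediction is hard
  cfg <- generator_config(n_years = 6, spike_multiplier = 4,
                          spike_prob = 0.3, spike_grlg_q = 0.5,
                          spike_rh_q = 0.3)
  sim <- simulate_study(cfg, seed = 55)
  cyc <- fit_seasonal_cycle(sim$admissions)
  labels <- make_labels(sim$admissions, detect_haads(sim$admissions))
  fr <- build_class_frame(labels, sim$covariates, cyc)
  ev <- evaluate_replicates(fr, classifier_spec("logistic"),
                            n_replicates = 40, seed = 9)
  expect_lt(ev$tpr, 0.5)
})
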