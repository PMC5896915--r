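# Componentwise gradient boosting for binary outcomes.
#
# A small functional gradient-descent booster for the logistic loss: each
# iteration fits every candidate base learner to the current negative
# gradient (y - p) and keeps the single best one (least squares), so the
# ensemble performs implicit variable selection. Base learners: simple
# linear regressions per covariate, low-df smoothing splines for covariates
# expected to act non-linearly, and a shallow regression tree over a
# designated covariate group (allowing interactions within that group).

fit_base_linear <- function(x, r) {
  vx <- var(x)
  b <- if (is.finite(vx) && vx > 0) stats::cov(x, r) / vx else 0
  a <- mean(r) - b * mean(x)
  list(type = "linear", a = a, b = b)
}

fit_base_smooth <- function(x, r, df = 4) {
  if (length(unique(x)) < df + 2) return(fit_base_linear(x, r))
  # near-flat residuals make the target df unattainable; smooth.spline then
  # warns and falls back to maximal smoothing, which is fine for a base
  # learner, so the warning is muffled
  sp <- try(suppressWarnings(smooth.spline(x, r, df = df)), silent = TRUE)
  if (inherits(sp, "try-error")) return(fit_base_linear(x, r))
  list(type = "smooth", model = sp)
}

fit_base_tree <- function(X, r, maxdepth = 2) {
  d <- cbind(data.frame(.r = r), X)
  list(type = "tree",
       model = rpart::rpart(.r ~ ., data = d, method = "anova",
                            control = rpart::rpart.control(
                              maxdepth = maxdepth, cp = 0, minbucket = 8,
                              xval = 0)))
}

predict_base <- function(learner, var, X) {
  switch(learner$type,
         linear = learner$a + learner$b * X[[var]],
         smooth = predict(learner$model, X[[var]])$y,
         tree = predict(learner$model, newdata = X))
}

#' Componentwise gradient boosting for a binary outcome
#'
#' @param X data.frame of covariates.
#' @param y 0/1 response.
#' @param linear_terms covariates fitted with linear base learners.
#' @param smooth_terms covariates fitted with smoothing-spline base
#'   learners (df 4).
#' @param tree_terms covariate group fitted jointly with a shallow
#'   regression-tree base learner (interactions allowed within the group).
#' @param mstop number of boosting iterations (0 gives the constant
#'   log-odds of the training prevalence).
#' @param nu learning rate.
#' @param tree_maxdepth depth of the tree base learner.
#' @return object of class `"boost_logit"` with a `predict` method
#'   returning probabilities.
#' @export
boost_logit <- function(X, y, linear_terms, smooth_terms = character(0),
                        tree_terms = character(0), mstop = 100, nu = 0.1,
                        tree_maxdepth = 2) {
  stopifnot(all(y %in% 0:1))
  p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
  f0 <- log(p0 / (1 - p0))
  f <- rep(f0, length(y))
  steps <- vector("list", mstop)
  use_tree <- length(tree_terms) > 0
  if (mstop > 0) for (m in seq_len(mstop)) {
    r <- y - stats::plogis(f)
    best <- NULL
    best_sse <- Inf
    for (v in linear_terms) {
      cand <- fit_base_linear(X[[v]], r)
      sse <- sum((r - predict_base(cand, v, X))^2)
      if (sse < best_sse) { best <- list(learner = cand, var = v); best_sse <- sse }
    }
    for (v in smooth_terms) {
      cand <- fit_base_smooth(X[[v]], r)
      sse <- sum((r - predict_base(cand, v, X))^2)
      if (sse < best_sse) { best <- list(learner = cand, var = v); best_sse <- sse }
    }
    if (use_tree) {
      cand <- fit_base_tree(X[tree_terms], r, tree_maxdepth)
      sse <- sum((r - predict_base(cand, NULL, X[tree_terms]))^2)
      if (sse < best_sse) { best <- list(learner = cand, var = NA); best_sse <- sse }
    }
    f <- f + nu * predict_base(best$learner, best$var, X)
    steps[[m]] <- best
  }
  structure(list(f0 = f0, nu = nu, steps = steps, tree_terms = tree_terms),
            class = "boost_logit")
}

#' @export
predict.boost_logit <- function(object, newdata, type = c("response", "link"),
                                ...) {
  type <- match.arg(type)
  f <- rep(object$f0, nrow(newdata))
  for (st in object$steps) {
    X <- if (identical(st$learner$type, "tree"))
      newdata[object$tree_terms] else newdata
    f <- f + object$nu * predict_base(st$learner, st$var, X)
  }
  if (type == "link") f else stats::plogis(f)
}
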