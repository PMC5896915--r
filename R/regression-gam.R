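# Additive regression models for daily admission rates.
#
# Eight model specifications share a common structure: a cyclic day-of-year
# smooth, penalised cubic regression smooths of the engineered weather and
# pollen covariates (shrinkage variants, so GCV can drop a term by driving
# its EDF to zero), a weekday factor with Sunday reference and a
# thunderstorm indicator with "no thunderstorm" reference. Pollen terms are
# only available in the October-December specifications.

MET_TERMS <- c("RH_rl", "RH_dv", "TM_rl", "TM_dv", "PR", "NS", "EW")
POLLEN_DAILY <- c("GR", "NG")
POLLEN_LAGGED <- c("GR_lg", "NG_lg")
AQ_TERMS <- c("O3", "PM25")

#' Regression model specification (models 1-8)
#'
#' Returns the term roster of one of the eight admission-rate model
#' specifications. All models include the cyclic seasonal smooth, the
#' weekday factor and the thunderstorm indicator in addition to the listed
#' smooths.
#'
#' \describe{
#'   \item{1}{full year; weather smooths only.}
#'   \item{2}{October-December; weather + daily pollen smooths.}
#'   \item{3}{October-December; weather + daily and 3-day-lagged pollen.}
#'   \item{4}{model 3 plus thunderstorm-by-pollen interactions.}
#'   \item{5}{full year; weather + air-quality smooths.}
#'   \item{6}{model 2 plus air-quality smooths.}
#'   \item{7}{model 3 plus air-quality smooths.}
#'   \item{8}{model 4 plus air-quality smooths.}
#' }
#'
#' @param id model id, 1-8.
#' @param stepwise reserved flag for explicit stepwise term selection;
#'   only shrinkage-based implicit selection is implemented, so this must
#'   remain `FALSE`.
#' @return an object of class `"model_spec"`.
#' @export
model_spec <- function(id, stepwise = FALSE) {
  id <- as.integer(id)
  if (!id %in% 1:8) stopf("model id must be 1..8")
  if (isTRUE(stepwise))
    stopf("explicit stepwise selection is not implemented; see ?model_spec")
  smooths <- switch(id,
    MET_TERMS,                                        # 1
    c(MET_TERMS, POLLEN_DAILY),                       # 2
    c(MET_TERMS, POLLEN_DAILY, POLLEN_LAGGED),        # 3
    c(MET_TERMS, POLLEN_DAILY, POLLEN_LAGGED),        # 4
    c(MET_TERMS, AQ_TERMS),                           # 5
    c(MET_TERMS, POLLEN_DAILY, AQ_TERMS),             # 6
    c(MET_TERMS, POLLEN_DAILY, POLLEN_LAGGED, AQ_TERMS),  # 7
    c(MET_TERMS, POLLEN_DAILY, POLLEN_LAGGED, AQ_TERMS))  # 8
  structure(list(id = id,
                 period = if (id %in% c(1L, 5L)) "full_year" else "oct_dec",
                 smooths = smooths,
                 interactions = id %in% c(4L, 8L),
                 stepwise = FALSE),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model %d (%s): S(DOY) + %s + weekday + TS%s\n", x$id,
              if (x$period == "full_year") "full year" else "Oct-Dec",
              paste0("s(", x$smooths, ")", collapse = " + "),
              if (x$interactions) " + TS:pollen" else ""))
  invisible(x)
}

interaction_terms <- function(spec) {
  if (!spec$interactions) return(character(0))
  paste0("TS_x_", intersect(c(POLLEN_DAILY, POLLEN_LAGGED), spec$smooths))
}

#' Build the model frame for a regression specification
#'
#' Merges admissions and covariates by date, restricts to the
#' specification's period, adds the cyclic day-of-year coordinate, the
#' weekday factor (reference Sunday) and the thunderstorm indicator
#' (reference "no thunderstorm", coded 0/1), constructs any
#' indicator-by-covariate interaction columns, and keeps rows complete in
#' every required column.
#'
#' @param covariates a covariate series (see [derive_covariates()]).
#' @param admissions an [admission_series()].
#' @param spec a [model_spec()].
#' @return data.frame with attribute `"spec"`.
#' @export
build_design <- function(covariates, admissions, spec) {
  stopifnot(inherits(spec, "model_spec"))
  missing_cols <- setdiff(c(spec$smooths, "TS"), names(covariates))
  if (length(missing_cols))
    stopf("covariates lack required term column(s): %s",
          paste(missing_cols, collapse = ", "))
  d <- merge(as.data.frame(admissions)[c("date", "rate")],
             as.data.frame(covariates), by = "date")
  if (spec$period == "oct_dec") d <- d[month_num(d$date) >= 10L, ]
  d$doy <- day_of_year_cyclic(d$date)
  d$WK <- weekday_factor(d$date)
  d$TS <- as.numeric(d$TS)
  for (v in interaction_terms(spec))
    d[[v]] <- d$TS * d[[sub("^TS_x_", "", v)]]
  keep <- c("date", "rate", "doy", "WK", "TS", spec$smooths,
            interaction_terms(spec))
  d <- d[, keep]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "spec") <- spec
  d
}

# error on exactly collinear numeric columns before handing to the fitter
check_collinear <- function(frame, vars) {
  num <- vars[vapply(frame[vars], is.numeric, logical(1))]
  if (length(num) < 2) return(invisible())
  cc <- suppressWarnings(stats::cor(frame[num]))
  cc[!is.finite(cc)] <- 0
  bad <- which(abs(cc) > 1 - 1e-10 & upper.tri(cc), arr.ind = TRUE)
  if (nrow(bad))
    stopf("rank deficiency: collinear terms %s",
          paste(sprintf("%s ~ %s", num[bad[, 1]], num[bad[, 2]]),
                collapse = ", "))
}

#' Fit an additive admission-rate model
#'
#' Fits the Gaussian additive model of a [model_spec()] with
#' [mgcv::gam()]: a cyclic cubic smooth of day-of-year and penalised cubic
#' regression smooths of every continuous term, plus the parametric
#' weekday, thunderstorm and interaction terms. Implicit term selection
#' uses the double-penalty construction (`select = TRUE`: the penalty null
#' space of each smooth gets its own smoothing parameter), so GCV can
#' shrink an uninformative term's EDF to zero while leaving the linear
#' component of a genuinely informative term unshrunk.
#'
#' @param frame a model frame from [build_design()].
#' @param spec the matching [model_spec()]; defaults to the frame's.
#' @param family model family (Gaussian identity on rates by default; a
#'   count family may be supplied, in which case the response is still the
#'   rate unless you refit on counts yourself).
#' @param k_smooth basis dimension per 1-D smooth (default 10).
#' @param k_doy basis dimension of the cyclic seasonal smooth (default 30).
#' @param method smoothness-selection criterion passed to [mgcv::gam()]
#'   (default GCV).
#' @param gamma degrees-of-freedom charge multiplier in the selection
#'   criterion. The default `NULL` uses `log(n)/2`, a BIC-type charge that
#'   makes the implicit dropping of uninformative terms reliable; plain
#'   GCV (`gamma = 1`) retains spurious low-amplitude wiggles in null
#'   terms in a substantial fraction of fits (see the methods vignette).
#' @param select use the double-penalty construction for implicit term
#'   selection (default `TRUE`).
#' @param bs basis for the 1-D smooths (default `"cr"`; `"cs"` gives the
#'   single-penalty shrinkage variant).
#' @return object of class `"asthma_fit"` wrapping the `gam` fit.
#' @export
fit_admissions_model <- function(frame, spec = attr(frame, "spec"),
                                 family = stats::gaussian(),
                                 k_smooth = 10, k_doy = 30,
                                 method = "GCV.Cp", gamma = NULL,
                                 select = TRUE, bs = "cr") {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(gamma)) gamma <- log(nrow(frame)) / 2
  vars <- c(spec$smooths, interaction_terms(spec), "TS")
  check_collinear(frame, vars)
  rhs <- c(sprintf("s(doy, bs = 'cc', k = %d)", k_doy),
           sprintf("s(%s, bs = '%s', k = %d)", spec$smooths, bs, k_smooth),
           "WK", "TS", interaction_terms(spec))
  form <- as.formula(paste("rate ~", paste(rhs, collapse = " + ")))
  fit <- mgcv::gam(form, data = frame, knots = list(doy = c(0, 365.25)),
                   family = family, method = method, gamma = gamma,
                   select = select)
  structure(list(gam = fit, spec = spec, frame = frame),
            class = "asthma_fit")
}

#' Implied linear slope of a smooth term with standard error
#'
#' Secant slope of the fitted smooth between two covariate values
#' (quartiles by default), with the delta-method standard error from the
#' coefficient covariance. For a term that is truly linear this estimates
#' its slope.
#'
#' @param fit an `"asthma_fit"`.
#' @param term covariate name of the smooth.
#' @param probs two probabilities defining the secant (default quartiles).
#' @return list with `slope` and `se`.
#' @export
smooth_slope <- function(fit, term, probs = c(0.25, 0.75)) {
  stopifnot(inherits(fit, "asthma_fit"), term %in% fit$spec$smooths)
  q <- quantile(fit$frame[[term]], probs, na.rm = TRUE)
  nd <- fit$frame[c(1, 1), , drop = FALSE]
  nd[[term]] <- as.numeric(q)
  X <- predict(fit$gam, nd, type = "lpmatrix")
  cvec <- (X[2, ] - X[1, ]) / diff(as.numeric(q))
  cvec[!grepl(sprintf("s\\(%s\\)", term), names(coef(fit$gam)))] <- 0
  list(slope = sum(cvec * coef(fit$gam)),
       se = sqrt(drop(t(cvec) %*% vcov(fit$gam) %*% cvec)))
}

#' Per-term statistics of a fitted admission model
#'
#' @param fit an `"asthma_fit"`.
#' @return data.frame with one row per model term: `term`, `type`
#'   (`"linear"` or `"smooth"`), `estimate` (parametric terms only),
#'   `se`, `edf` (smooth terms only), `statistic` (t or F), `p_value`,
#'   and `dropped` (`TRUE` when a smooth was shrunk to EDF below 0.05).
#' @export
term_stats <- function(fit) {
  stopifnot(inherits(fit, "asthma_fit"))
  sm <- summary(fit$gam)
  pt <- sm$p.table
  lin <- data.frame(term = rownames(pt), type = "linear",
                    estimate = pt[, 1], se = pt[, 2], edf = NA_real_,
                    statistic = pt[, 3], p_value = pt[, 4],
                    row.names = NULL)
  st <- sm$s.table
  smo <- data.frame(term = rownames(st), type = "smooth",
                    estimate = NA_real_, se = NA_real_, edf = st[, "edf"],
                    statistic = st[, "F"], p_value = st[, "p-value"],
                    row.names = NULL)
  out <- rbind(lin, smo)
  out$dropped <- !is.na(out$edf) & out$edf < 0.05
  out
}

#' @export
print.asthma_fit <- function(x, ...) {
  cat(sprintf("Additive admission-rate model %d (%s), n = %d\n",
              x$spec$id,
              if (x$spec$period == "full_year") "full year" else "Oct-Dec",
              nrow(x$frame)))
  cat(sprintf("  GCV score %.5g; deviance explained %.1f%%\n",
              x$gam$gcv.ubre, 100 * summary(x$gam)$dev.expl))
  invisible(x)
}

#' Effective degrees of freedom of one smooth term
#'
#' @param fit an `"asthma_fit"`.
#' @param var covariate name of the smooth (e.g. `"EW"` for `s(EW)`).
#' @return the term's EDF; 0 means the term was dropped by shrinkage.
#' @export
edf_of <- function(fit, var) {
  st <- summary(fit$gam)$s.table
  row <- paste0("s(", var, ")")
  if (!row %in% rownames(st)) stopf("no smooth term for '%s'", var)
  unname(st[row, "edf"])
}

#' Population-scaled effect size of a model term
#'
#' Expresses a term's contribution as additional daily admissions in a
#' reference population: for a continuous linear term, coefficient times
#' the 0.95 quantile of the covariate (computed on the fitted model frame)
#' times `population/1e5`; for a binary or categorical term, coefficient
#' times `population/1e5`; for a smooth term, the fitted smooth evaluated
#' at the covariate's 0.95 quantile times `population/1e5`. The default
#' population of 4 million gives the conventional factor of 40. The
#' confidence interval propagates only the uncertainty of the regression
#' coefficient (or of the smooth at the evaluation point).
#'
#' @param fit an `"asthma_fit"` (or, for linear terms, any object with
#'   `coef` and `vcov` methods plus a `frame` element).
#' @param term term name: a parametric coefficient name (e.g. `"TS"`,
#'   `"WKMo"`) or a covariate with a smooth (e.g. `"PR"`).
#' @param population reference population (default 4e6).
#' @param level confidence level (default 0.95).
#' @return list with `term`, `effect`, `lower`, `upper`, `q95` (the
#'   quantile used, `NA` for binary/categorical terms) and `dropped`.
#' @export
effect_size <- function(fit, term, population = 4e6, level = 0.95) {
  stopifnot(inherits(fit, "asthma_fit"))
  fac <- population / 1e5
  zc <- qnorm(1 - (1 - level) / 2)
  sm_terms <- fit$spec$smooths
  if (term %in% sm_terms) {
    edf <- edf_of(fit, term)
    q95 <- unname(quantile(fit$frame[[term]], 0.95, na.rm = TRUE))
    if (edf < 0.05)
      return(list(term = term, effect = 0, lower = 0, upper = 0,
                  q95 = q95, dropped = TRUE))
    nd <- fit$frame[1, , drop = FALSE]
    nd[[term]] <- q95
    p <- predict(fit$gam, newdata = nd, type = "terms", se.fit = TRUE)
    col <- paste0("s(", term, ")")
    val <- p$fit[1, col]
    sev <- p$se.fit[1, col]
    return(list(term = term, effect = unname(val * fac),
                lower = unname((val - zc * sev) * fac),
                upper = unname((val + zc * sev) * fac),
                q95 = q95, dropped = FALSE))
  }
  cf <- coef(fit$gam)
  if (!term %in% names(cf))
    stopf("term '%s' not present in the fit", term)
  b <- cf[[term]]
  sev <- sqrt(vcov(fit$gam)[term, term])
  # continuous parametric terms scale by their 0.95 quantile; indicator
  # and factor-level terms use the coefficient directly
  base <- sub("^TS_x_", "", term)
  is_binary <- term == "TS" || grepl("^WK", term)
  q95 <- NA_real_
  mult <- 1
  if (!is_binary) {
    # indicator-by-covariate interactions are scaled by the q95 of the
    # underlying covariate, not of the mostly-zero interaction column
    src <- if (grepl("^TS_x_", term)) base else term
    if (src %in% names(fit$frame)) {
      q95 <- unname(quantile(fit$frame[[src]], 0.95, na.rm = TRUE))
      mult <- q95
    }
  }
  list(term = term, effect = unname(b * mult * fac),
       lower = unname((b - zc * sev) * mult * fac),
       upper = unname((b + zc * sev) * mult * fac),
       q95 = q95, dropped = FALSE)
}

#' Predict admission rates from a fitted model
#'
#' Evaluates the fitted linear predictor on new covariate data (built with
#' the same rules as [build_design()], but without requiring observed
#' admissions). A warning is issued when any continuous covariate lies
#' outside its training range (extrapolation).
#'
#' @param fit an `"asthma_fit"`.
#' @param covariates covariate series covering the prediction dates; may
#'   be the training frame itself.
#' @return data.frame with columns `date` and `predicted` (rate per
#'   100,000).
#' @export
predict_rates <- function(fit, covariates) {
  stopifnot(inherits(fit, "asthma_fit"))
  spec <- fit$spec
  d <- as.data.frame(covariates)
  if (!"doy" %in% names(d)) d$doy <- day_of_year_cyclic(d$date)
  if (!"WK" %in% names(d)) d$WK <- weekday_factor(d$date)
  d$TS <- as.numeric(d$TS)
  for (v in interaction_terms(spec))
    if (!v %in% names(d)) d[[v]] <- d$TS * d[[sub("^TS_x_", "", v)]]
  need <- c("doy", "TS", spec$smooths, interaction_terms(spec))
  keep <- stats::complete.cases(d[, need])
  d <- d[keep, , drop = FALSE]
  for (v in spec$smooths) {
    rng <- range(fit$frame[[v]], na.rm = TRUE)
    if (any(d[[v]] < rng[1] | d[[v]] > rng[2])) {
      warning(sprintf("covariate '%s' outside training range; extrapolating",
                      v), call. = FALSE)
      break
    }
  }
  data.frame(date = d$date,
             predicted = as.numeric(predict(fit$gam, newdata = d)))
}

#' Variance explained, raw and deseasonalised
#'
#' Squared correlation between fitted and observed rates, and the plain
#' correlation between the two series after subtracting the seasonal mean
#' (the fitted model's own seasonal term by default, or a supplied
#' [fit_seasonal_cycle()] cycle) from both.
#'
#' @param fit an `"asthma_fit"`.
#' @param cycle optional `"seasonal_cycle"`; when `NULL` the model's own
#'   `s(doy)` term plus intercept is used as the seasonal mean.
#' @return list with `r_squared` and `deseasonalised_correlation`.
#' @export
variance_explained <- function(fit, cycle = NULL) {
  stopifnot(inherits(fit, "asthma_fit"))
  obs <- fit$frame$rate
  pred <- fitted(fit$gam)
  if (is.null(cycle)) {
    seas <- predict(fit$gam, type = "terms")[, "s(doy)"] +
      coef(fit$gam)[1]
  } else {
    seas <- cycle$mean_level +
      predict(cycle, day_of_year_cyclic(fit$frame$date))
  }
  r2 <- stats::cor(obs, pred)^2
  des <- stats::cor(obs - seas, pred - seas)
  list(r_squared = unname(r2),
       deseasonalised_correlation = unname(des))
}
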