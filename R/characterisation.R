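# Descriptive and inferential characterisation of HAADs.

#' Over-representation of a condition among HAADs
#'
#' Compares the proportion of days satisfying a boolean condition among
#' HAADs against the proportion among all days, with the chi-squared test
#' for equality of proportions (no continuity correction by default; with
#' as few as 16 HAADs the correction matters, so the choice is surfaced in
#' the output).
#'
#' @param haad_dates `Date` vector of HAADs.
#' @param days `Date` vector of all days in the comparison set.
#' @param condition logical vector parallel to `days`.
#' @param name condition label carried into the output.
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return list with `condition`, `prop_haad`, `prop_all`, `n_haad`,
#'   `n_all`, `statistic`, `p_value`, `correction`.
#' @export
condition_overrepresentation <- function(haad_dates, days, condition,
                                         name = "condition",
                                         correct = FALSE) {
  stopifnot(inherits(haad_dates, "Date"), inherits(days, "Date"),
            length(days) == length(condition))
  if (length(haad_dates) < 1) stopf("at least one HAAD is required")
  if (mean(is.na(condition)) > 0.10)
    warning("condition undefined on more than 10% of days", call. = FALSE)
  ok <- !is.na(condition)
  days <- days[ok]; condition <- condition[ok]
  is_haad <- days %in% haad_dates
  x1 <- sum(condition[is_haad]); n1 <- sum(is_haad)
  x2 <- sum(condition); n2 <- length(days)
  if (n1 == 0) stopf("no HAAD dates found among the supplied days")
  p1 <- x1 / n1; p2 <- x2 / n2
  if ((x1 == 0 && x2 == 0) || (x1 == n1 && x2 == n2)) {
    stat <- 0; pv <- 1  # degenerate: identical proportions, zero variance
  } else {
    ht <- suppressWarnings(prop.test(c(x1, x2), c(n1, n2),
                                     correct = correct))
    stat <- unname(ht$statistic); pv <- ht$p.value
  }
  list(condition = name, prop_haad = p1, prop_all = p2,
       n_haad = n1, n_all = n2, statistic = stat, p_value = pv,
       correction = correct)
}

#' Calendar structure of a set of HAAD records
#'
#' Partitions HAADs into the October-December allergy season, February
#' (the return-to-school period) and all other months, and tallies
#' weekdays overall and within each period.
#'
#' @param haads data.frame with a `date` column (e.g. [load_haad_table()]),
#'   possibly empty.
#' @return list with `period` (named counts `oct_dec`, `feb`, `other`),
#'   `weekday` (counts Su..Sa) and `weekday_by_period` (3 x 7 matrix).
#' @export
haad_calendar_summary <- function(haads) {
  stopifnot(is.data.frame(haads), "date" %in% names(haads))
  wk_levels <- c("Su", "Mo", "Tu", "We", "Th", "Fr", "Sa")
  if (nrow(haads) == 0) {
    z <- setNames(rep(0L, 7), wk_levels)
    return(list(period = c(oct_dec = 0L, feb = 0L, other = 0L),
                weekday = z,
                weekday_by_period = matrix(0L, 3, 7,
                  dimnames = list(c("oct_dec", "feb", "other"),
                                  wk_levels))))
  }
  m <- month_num(haads$date)
  per <- ifelse(m >= 10L, "oct_dec", ifelse(m == 2L, "feb", "other"))
  per <- factor(per, levels = c("oct_dec", "feb", "other"))
  wk <- weekday_factor(haads$date)
  list(period = c(oct_dec = sum(per == "oct_dec"),
                  feb = sum(per == "feb"),
                  other = sum(per == "other")),
       weekday = table(wk),
       weekday_by_period = table(per, wk))
}

#' Binomial sex-ratio test per age group
#'
#' Exact two-sided binomial test of whether the fraction of male patients
#' differs from 0.5, within each age group.
#'
#' @param counts data.frame with columns `age_group`, `male`, `female`
#'   (non-negative counts).
#' @return data.frame with `age_group`, `male`, `female`, `prop_male` and
#'   `p_value` (`NA` for empty groups).
#' @export
sex_ratio_test <- function(counts) {
  stopifnot(all(c("age_group", "male", "female") %in% names(counts)))
  if (any(counts$male < 0 | counts$female < 0))
    stopf("counts must be non-negative")
  n <- counts$male + counts$female
  pv <- rep(NA_real_, nrow(counts))
  for (i in seq_len(nrow(counts)))
    if (n[i] > 0)
      pv[i] <- binom.test(counts$male[i], n[i], p = 0.5)$p.value
  data.frame(age_group = counts$age_group, male = counts$male,
             female = counts$female,
             prop_male = ifelse(n > 0, counts$male / n, NA_real_),
             p_value = pv)
}

# midpoint of a five-year age bin label ("0-4" -> 2, "85+" -> 87.5)
age_bin_midpoint <- function(label) {
  out <- rep(NA_real_, length(label))
  rng <- grepl("^[0-9]+-[0-9]+$", label)
  plus <- grepl("^[0-9]+\\+$", label)
  if (any(!(rng | plus))) stopf("unknown age bin label(s): %s",
                                paste(unique(label[!(rng | plus)]),
                                      collapse = ", "))
  out[rng] <- vapply(strsplit(label[rng], "-"),
                     function(x) mean(as.numeric(x)), numeric(1))
  out[plus] <- as.numeric(sub("\\+$", "", label[plus])) + 2.5
  out
}

#' Age-sex distribution of admissions
#'
#' Cell proportions over age-group x sex (summing to 1 over the whole
#' subset) and mean age per sex, using five-year bin midpoints (the open
#' `85+` bin counts as 87.5).
#'
#' @param admissions data.frame of admission records with columns
#'   `age_group` (labels `"0-4"`, ..., `"80-84"`, `"85+"`) and `sex`.
#' @return list with `proportions` (data.frame `age_group`, `sex`,
#'   `prop`) and `mean_age` (named per sex).
#' @export
age_sex_distribution <- function(admissions) {
  stopifnot(all(c("age_group", "sex") %in% names(admissions)),
            nrow(admissions) > 0)
  mid <- age_bin_midpoint(admissions$age_group)
  tab <- as.data.frame(table(age_group = admissions$age_group,
                             sex = admissions$sex),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  tab$prop <- tab$count / nrow(admissions)
  mean_age <- tapply(mid, admissions$sex, mean)
  list(proportions = tab[, c("age_group", "sex", "prop")],
       mean_age = mean_age)
}

#' Mean admission rate by weekday and month
#'
#' @param series an [admission_series()] covering at least one full year.
#' @return 7 x 12 matrix of mean rates (weekdays Su..Sa by months
#'   Jan..Dec).
#' @export
weekday_month_means <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("date", "rate") %in% names(series)))
  if (as.numeric(diff(range(series$date))) < 364)
    stopf("at least one full year of data is required")
  wk <- weekday_factor(series$date)
  mo <- factor(month_num(series$date), levels = 1:12, labels = month.abb)
  tapply(series$rate, list(wk, mo), mean, na.rm = TRUE)
}
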