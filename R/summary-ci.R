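#' Exact Poisson confidence interval for a count
#'
#' Two-sided exact (Garwood, chi-square inversion) interval for a Poisson
#' mean given an observed count: lower `qchisq(alpha/2, 2k)/2` (0 when the
#' count is 0), upper `qchisq(1 - alpha/2, 2k + 2)/2`. The exact method,
#' rather than the normal approximation, is used because it reproduces
#' published category-count intervals exactly after rounding.
#'
#' @param count nonnegative integer count.
#' @param level confidence level (default 0.95).
#' @return named vector `c(lower =, upper =)`, full precision (round for
#'   table display).
#' @export
#' @examples
#' round(poisson_count_ci(13521))  # 13294, 13751
poisson_count_ci <- function(count, level = 0.95) {
  if (length(count) != 1L || is.na(count) || count < 0 ||
      count != round(count)) {
    stop("count must be a single nonnegative integer")
  }
  alpha <- 1 - level
  lower <- if (count == 0) 0 else stats::qchisq(alpha / 2, 2 * count) / 2
  upper <- stats::qchisq(1 - alpha / 2, 2 * (count + 1)) / 2
  c(lower = lower, upper = upper)
}

#' Normal-theory confidence interval for a sample mean
#'
#' `mean +/- z * sd / sqrt(n)` with the standard-normal quantile
#' (1.959964 at 95%).
#'
#' @param values numeric sample of at least 2 values.
#' @param level confidence level.
#' @return named vector `c(mean =, lower =, upper =)`.
#' @export
normal_mean_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  half <- stats::qnorm(1 - (1 - level) / 2) * stats::sd(values) /
    sqrt(length(values))
  c(mean = m, lower = m - half, upper = m + half)
}

#' Descriptive cohort summary (baseline-characteristics table)
#'
#' Summarises a baseline data.frame into labelled rows: numeric columns as
#' means with normal-theory intervals, logical/factor/character columns as
#' category counts with exact Poisson intervals. Percentages are reported
#' per category over non-missing rows and are not forced to close to 100%.
#'
#' @param data data.frame of patient-level baseline variables.
#' @param level confidence level.
#' @return data.frame with columns `label`, `statistic`, `ci_low`,
#'   `ci_high`, `method`.
#' @export
cohort_summary <- function(data, level = 0.95) {
  rows <- list()
  for (nm in names(data)) {
    x <- data[[nm]]
    if (is.numeric(x) && !is.integer(x)) {
      ci <- normal_mean_ci(x, level)
      rows[[length(rows) + 1L]] <- data.frame(
        label = nm, statistic = ci[["mean"]], ci_low = ci[["lower"]],
        ci_high = ci[["upper"]], method = "normal-mean",
        stringsAsFactors = FALSE)
    } else {
      x <- as.factor(x)
      for (lv in levels(x)) {
        k <- sum(x == lv, na.rm = TRUE)
        ci <- poisson_count_ci(k, level)
        rows[[length(rows) + 1L]] <- data.frame(
          label = paste0(nm, ":", lv), statistic = k,
          ci_low = ci[["lower"]], ci_high = ci[["upper"]],
          method = "poisson-count", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  stopifnot(all(out$ci_low <= out$statistic + 1e-9),
            all(out$statistic <= out$ci_high + 1e-9))
  out
}

#' Simple baseline-characteristics generator
#'
#' Emits a plausible patient-level baseline table for the synthetic
#' cohort: age drawn from a normal law per starting arm, sex and a few
#' comorbidity flags as Bernoulli draws. Intended only to exercise the
#' descriptive summary; no attempt is made to model the joint covariate
#' distribution of a real registry.
#'
#' @param n_patients number of patients.
#' @param arm starting arm label attached to every row.
#' @param age_mean,age_sd normal parameters for age (years).
#' @param p_male,p_diabetes,p_hypertension Bernoulli probabilities.
#' @param seed integer seed.
#' @return data.frame with columns `arm`, `age`, `sex`, `diabetes`,
#'   `hypertension`.
#' @export
generate_baseline <- function(n_patients, arm = "OMT", age_mean = 62.9,
                              age_sd = 11, p_male = 0.69,
                              p_diabetes = 0.43, p_hypertension = 0.74,
                              seed = 1L) {
  with_seed(seed, data.frame(
    arm = arm,
    age = stats::rnorm(n_patients, age_mean, age_sd),
    sex = ifelse(stats::runif(n_patients) < p_male, "male", "female"),
    diabetes = stats::runif(n_patients) < p_diabetes,
    hypertension = stats::runif(n_patients) < p_hypertension,
    stringsAsFactors = FALSE
  ))
}
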