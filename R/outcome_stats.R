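# Correlation and regression of regional WMSA volumes against developmental
# outcome scores: Pearson r, simple linear regression, and one-at-a-time
# bivariate covariate adjustment.  Two-sided p < 0.05, no multiplicity
# correction (by design: associations are screened one at a time).

check_xy <- function(x, y, min_n = 3) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite (remove missing values first)")
  if (length(x) < min_n) stop(sprintf("need at least %d observations", min_n))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("x and y must both have non-zero variance")
  invisible(TRUE)
}

#' Pearson correlation with a two-sided p-value
#'
#' @param x,y numeric vectors of equal length (>= 3), non-constant.
#' @return list with `r`, `p_value` (t distribution, n-2 df) and `n`.
#' @export
pearson_r <- function(x, y) {
  check_xy(x, y)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Simple linear regression Y = a + bX
#'
#' @param x predictor, `y` response; both numeric, length >= 3, non-constant.
#' @param y response vector.
#' @return An object of class `RegressionResult`: `intercept` (a), `slope`
#'   (b), `r`, `r_squared`, `p_value` (two-sided, slope != 0), `n`, and
#'   `perfect_agreement` (`TRUE` when b = 1 and a = 0 within numerical
#'   tolerance).
#' @export
simple_linreg <- function(x, y) {
  check_xy(x, y)
  fit <- stats::lm(y ~ x)
  # exact lines are legitimate inputs (r = +/-1 cases); silence lm's
  # "essentially perfect fit" advisory
  sm <- suppressWarnings(summary(fit))
  b <- unname(stats::coef(fit)[2])
  a <- unname(stats::coef(fit)[1])
  r <- unname(stats::cor(x, y))
  p <- sm$coefficients[2, 4]
  scale <- max(abs(y), 1)
  structure(list(intercept = a, slope = b, r = r,
                 r_squared = sm$r.squared, p_value = p, n = length(x),
                 perfect_agreement = isTRUE(abs(b - 1) < 1e-8 &&
                                            abs(a) < 1e-8 * scale)),
            class = "RegressionResult")
}

#' @export
print.RegressionResult <- function(x, ...) {
  cat(sprintf("Y = %.4g + %.4g X   (r = %.4f, R^2 = %.4f, p = %.3g, n = %d)%s\n",
              x$intercept, x$slope, x$r, x$r_squared, x$p_value, x$n,
              if (x$perfect_agreement) "  [perfect agreement]" else ""))
  invisible(x)
}

#' Bivariate covariate-adjusted regression
#'
#' Fits `y ~ x + covariate` by least squares and reports the adjusted slope
#' of `x` together with the covariate's two-sided p-value — the
#' one-at-a-time influence screen for sex, gestational age and postmenstrual
#' age.  A constant covariate adds no information and falls back to the
#' simple regression; collinear predictors are an error.
#'
#' @param x predictor of interest.
#' @param y response.
#' @param covariate numeric covariate (encode sex as 0/1).
#' @return list with `slope_x`, `slope_x_p`, `covariate_slope`,
#'   `covariate_p`, `n`.
#' @export
bivariate_adjusted <- function(x, y, covariate) {
  check_xy(x, y, min_n = 4)
  if (length(covariate) != length(x)) stop("covariate length mismatch")
  if (any(!is.finite(covariate))) stop("covariate must be finite")
  if (stats::sd(covariate) == 0) {
    fit <- simple_linreg(x, y)
    return(list(slope_x = fit$slope, slope_x_p = fit$p_value,
                covariate_slope = NA_real_, covariate_p = NA_real_,
                n = length(x)))
  }
  X <- cbind(1, x, covariate)
  if (qr(X)$rank < 3L)
    stop("covariate is collinear with the predictor")
  fit <- stats::lm(y ~ x + covariate)
  sm <- summary(fit)$coefficients
  list(slope_x = unname(sm["x", 1]), slope_x_p = unname(sm["x", 4]),
       covariate_slope = unname(sm["covariate", 1]),
       covariate_p = unname(sm["covariate", 4]),
       n = length(x))
}

#' Simulate an outcome table (regional WMSA volumes vs developmental scores)
#'
#' Generates a cohort table shaped like the study export: regional WMSA
#' volumes (log-normal across subjects), standardized language and cognitive
#' composite scores generated as linear functions of volume plus Gaussian
#' noise, and the three screened covariates.  Defaults give score SDs and
#' means in the standardized-scale ballpark (mean ~ 90-95, SD ~ 14-17) with
#' a negative volume-score relationship.
#'
#' @param n cohort size.
#' @param slope_language,slope_cognitive score change per cm^3 of entire-WM
#'   WMSA volume (negative: larger lesion load, lower scores).
#' @param mean_volume_cm3,sd_log volume scale (log-normal parameters).
#' @param noise_sd residual score SD.
#' @param seed integer seed.
#' @return data.frame with columns `subject`, `entire_wm_mm3`,
#'   `periventricular_mm3`, `centrum_semiovale_mm3`, `language`,
#'   `cognitive`, `sex` (0/1), `ga_weeks`, `pma_weeks`.
#' @export
simulate_outcome_table <- function(n = 38,
                                   slope_language = -1.5,
                                   slope_cognitive = -1.8,
                                   mean_volume_cm3 = 8, sd_log = 0.6,
                                   noise_sd = 10, seed = 1L) {
  with_seed(seed, {
    vol <- stats::rlnorm(n, meanlog = log(mean_volume_cm3) - sd_log^2 / 2,
                         sdlog = sd_log)
    pv_frac <- stats::rbeta(n, 8, 4)            # most load is periventricular
    cs_frac <- (1 - pv_frac) * stats::rbeta(n, 6, 6)
    language <- 105 + slope_language * vol + stats::rnorm(n, sd = noise_sd)
    cognitive <- 102 + slope_cognitive * vol + stats::rnorm(n, sd = noise_sd)
    data.frame(
      subject = sprintf("S%03d", seq_len(n)),
      entire_wm_mm3 = vol * 1000,
      periventricular_mm3 = vol * pv_frac * 1000,
      centrum_semiovale_mm3 = vol * cs_frac * 1000,
      language = language,
      cognitive = cognitive,
      sex = stats::rbinom(n, 1, 0.5),
      ga_weeks = stats::rnorm(n, 25.5, 1.6),
      pma_weeks = stats::rnorm(n, 38.7, 2.3))
  })
}

#' Region-by-score correlation/regression report
#'
#' Runs [pearson_r()] and [simple_linreg()] for every volume column against
#' every score column, plus [bivariate_adjusted()] for each covariate, one
#' at a time.
#'
#' @param df outcome data frame (see [simulate_outcome_table()] for the
#'   expected shape).
#' @param volume_cols,score_cols,covariate_cols column names.
#' @return data.frame: one row per region x score (x covariate) combination
#'   with `r`, `r_squared`, `intercept`, `slope`, `p_value`, and for
#'   covariate rows the adjusted slope and covariate p.
#' @export
outcome_report <- function(df,
                           volume_cols = c("entire_wm_mm3",
                                           "periventricular_mm3",
                                           "centrum_semiovale_mm3"),
                           score_cols = c("language", "cognitive"),
                           covariate_cols = c("sex", "ga_weeks", "pma_weeks")) {
  missing_cols <- setdiff(c(volume_cols, score_cols, covariate_cols), names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("missing columns: %s", paste(missing_cols, collapse = ", ")))
  rows <- list()
  for (vc in volume_cols) for (sc in score_cols) {
    x <- df[[vc]]; y <- df[[sc]]
    pr <- pearson_r(x, y)
    lr <- simple_linreg(x, y)
    rows[[length(rows) + 1L]] <- data.frame(
      region = vc, score = sc, covariate = NA_character_,
      n = lr$n, r = pr$r, r_squared = lr$r_squared,
      intercept = lr$intercept, slope = lr$slope, p_value = lr$p_value,
      adjusted_slope = NA_real_, covariate_p = NA_real_)
    for (cv in covariate_cols) {
      ba <- bivariate_adjusted(x, y, df[[cv]])
      rows[[length(rows) + 1L]] <- data.frame(
        region = vc, score = sc, covariate = cv,
        n = ba$n, r = NA_real_, r_squared = NA_real_,
        intercept = NA_real_, slope = NA_real_, p_value = ba$slope_x_p,
        adjusted_slope = ba$slope_x, covariate_p = ba$covariate_p)
    }
  }
  do.call(rbind, rows)
}
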