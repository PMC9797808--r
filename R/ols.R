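#' Ordinary least-squares fit with Table-style output
#'
#' Fits `outcome ~ predictors` by OLS (intercept always included) and
#' collects the quantities reported in the study tables: unstandardized
#' coefficients, their standard errors, t statistics, two-sided p values,
#' confidence intervals at `ci_level` (99% by default) and the adjusted R
#' squared `1 - (1 - R^2)(n - 1)/(n - p - 1)`.
#'
#' @param data Data frame containing the variables.
#' @param outcome Name of the response column.
#' @param predictors Character vector of predictor columns (may be empty
#'   for an intercept-only model).
#' @param ci_level Two-sided confidence level for the coefficient
#'   intervals, default 0.99.
#' @return An object of class `ols_fit`; see [tidy.ols_fit()] and
#'   [glance.ols_fit()].
#' @details Requires `n > p + 1` complete rows and a full-rank design;
#'   rank-deficient designs raise an error naming the collinear columns.
#'   Predictors enter in raw (unstandardized) units.
#' @export
ols_fit <- function(data, outcome, predictors = character(), ci_level = 0.99) {
  stopifnot(is.character(outcome), length(outcome) == 1,
            ci_level > 0, ci_level < 1)
  cols <- c(outcome, predictors)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "sysseg_validation_error")
  }
  df <- as.data.frame(data)[cols]
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  p <- length(predictors)
  if (n <= p + 1) {
    abort(paste0("Need n > p + 1 complete rows; n = ", n, ", p = ", p, "."),
          class = "sysseg_validation_error")
  }
  fml <- if (p == 0) {
    stats::reformulate("1", response = outcome)
  } else {
    stats::reformulate(sprintf("`%s`", predictors), response = outcome)
  }
  fit <- lm(fml, data = df)
  aliased <- is.na(coef(fit))
  if (any(aliased)) {
    abort(paste0("Rank-deficient design; collinear column(s): ",
                 paste(gsub("`", "", names(coef(fit))[aliased]),
                       collapse = ", ")),
          class = "sysseg_validation_error")
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  ci <- confint(fit, level = ci_level)
  coefs <- tibble::tibble(
    term = gsub("`", "", rownames(ct)),
    estimate = unname(ct[, "Estimate"]),
    std_error = unname(ct[, "Std. Error"]),
    statistic = unname(ct[, "t value"]),
    p_value = unname(ct[, "Pr(>|t|)"]),
    conf_low = unname(ci[, 1]),
    conf_high = unname(ci[, 2])
  )
  structure(
    list(outcome = outcome, predictors = predictors, coefficients = coefs,
         r_squared = if (p == 0) 0 else sm$r.squared,
         adj_r_squared = if (p == 0) 0 else sm$adj.r.squared,
         sigma = sm$sigma, n = n, df_residual = fit$df.residual,
         ci_level = ci_level, fit = fit),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("<ols_fit> ", x$outcome, " ~ ",
      if (length(x$predictors)) paste(x$predictors, collapse = " + ") else "1",
      "\n  n = ", x$n, ", adj R^2 = ", signif(x$adj_r_squared, 4),
      ", ", round(100 * x$ci_level), "% CIs\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Coefficient table of an OLS fit
#'
#' @param x An `ols_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`, `conf_low`, `conf_high`.
#' @exportS3Method generics::tidy
tidy.ols_fit <- function(x, ...) x$coefficients

#' One-row model summary of an OLS fit
#'
#' @param x An `ols_fit`.
#' @param ... Unused.
#' @return Tibble with `r_squared`, `adj_r_squared`, `sigma`, `n`,
#'   `df_residual`.
#' @exportS3Method generics::glance
glance.ols_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
                 sigma = x$sigma, n = x$n, df_residual = x$df_residual)
}

#' Coefficient plot with confidence intervals
#'
#' @param object An `ols_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ols_fit <- function(object, ...) {
  df <- dplyr::filter(tidy(object), .data$term != "(Intercept)")
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate,
                                   stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::labs(x = "Unstandardized coefficient", y = NULL,
                  title = paste0("Outcome: ", object$outcome),
                  subtitle = paste0(round(100 * object$ci_level),
                                    "% confidence intervals")) +
    ggplot2::theme_bw()
}
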