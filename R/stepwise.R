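#' Forward stepwise OLS with an alpha-to-enter rule
#'
#' Iteratively adds, among the remaining candidates, the predictor whose
#' addition to the current model yields the smallest partial-t p value,
#' provided that p value is below `alpha_enter`; stops when no candidate
#' qualifies. The retained model is refit once and reported with
#' unstandardized coefficients and `ci_level` confidence intervals; a
#' per-step trace records the entered variable, its t and p at entry, and
#' the cumulative adjusted R squared.
#'
#' @param data Data frame (complete cases on outcome + candidates are used).
#' @param outcome Response column name.
#' @param candidates Character vector of candidate predictor columns.
#'   Ties in entry p values are broken by candidate list order.
#' @param alpha_enter Significance level a candidate must beat to enter
#'   (default 0.05).
#' @param ci_level Confidence level for the final coefficient intervals
#'   (default 0.99).
#' @param removal Also drop already-entered variables whose p value rises
#'   above `alpha_remove` after a new entry? Off by default (forward-only).
#' @param alpha_remove Alpha-to-remove used when `removal = TRUE`.
#' @return An object of class `stepwise_fit` with elements `retained`
#'   (variable names in entry order), `trace` (tibble: `step`, `action`,
#'   `variable`, `adj_r_squared`, `statistic`, `p_value`), and `final`
#'   (the refit [ols_fit()]; intercept-only when nothing qualifies).
#' @export
forward_stepwise <- function(data, outcome, candidates,
                             alpha_enter = 0.05, ci_level = 0.99,
                             removal = FALSE, alpha_remove = 0.10) {
  stopifnot(length(candidates) >= 1, alpha_enter > 0, alpha_enter < 1)
  cols <- c(outcome, candidates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "sysseg_validation_error")
  }
  df <- as.data.frame(data)[cols]
  df <- df[complete.cases(df), , drop = FALSE]

  retained <- character()
  remaining <- candidates
  trace <- list()
  step <- 0L
  partial_p <- function(current, cand) {
    # a candidate collinear with the current model cannot qualify
    f <- tryCatch(ols_fit(df, outcome, c(current, cand), ci_level = ci_level),
                  sysseg_validation_error = function(e) NULL)
    if (is.null(f)) return(c(stat = NA_real_, p = Inf, adj = NA_real_))
    i <- match(cand, f$coefficients$term)
    c(stat = unname(f$coefficients$statistic[i]),
      p = unname(f$coefficients$p_value[i]), adj = f$adj_r_squared)
  }
  repeat {
    if (length(remaining) == 0) break
    stats_mat <- vapply(remaining, function(cand) partial_p(retained, cand),
                        numeric(3))
    if (!any(is.finite(stats_mat["p", ]))) break
    best <- which.min(stats_mat["p", ])
    if (stats_mat["p", best] >= alpha_enter) break
    step <- step + 1L
    entered <- remaining[best]
    retained <- c(retained, entered)
    remaining <- setdiff(remaining, entered)
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = step, action = "enter", variable = entered,
      adj_r_squared = stats_mat["adj", best],
      statistic = stats_mat["stat", best], p_value = stats_mat["p", best]
    )
    if (removal && length(retained) > 1) {
      repeat {
        f <- ols_fit(df, outcome, retained, ci_level = ci_level)
        tab <- dplyr::filter(f$coefficients, .data$term != "(Intercept)")
        worst <- which.max(tab$p_value)
        if (tab$p_value[worst] <= alpha_remove) break
        drop_var <- tab$term[worst]
        retained <- setdiff(retained, drop_var)
        remaining <- c(remaining, drop_var)
        step <- step + 1L
        f2 <- ols_fit(df, outcome, retained, ci_level = ci_level)
        trace[[length(trace) + 1]] <- tibble::tibble(
          step = step, action = "remove", variable = drop_var,
          adj_r_squared = f2$adj_r_squared,
          statistic = tab$statistic[worst], p_value = tab$p_value[worst]
        )
      }
    }
  }
  final <- ols_fit(df, outcome, retained, ci_level = ci_level)
  structure(
    list(outcome = outcome, candidates = candidates, retained = retained,
         alpha_enter = alpha_enter, removal = removal,
         trace = if (length(trace)) dplyr::bind_rows(trace) else
           tibble::tibble(step = integer(), action = character(),
                          variable = character(), adj_r_squared = numeric(),
                          statistic = numeric(), p_value = numeric()),
         final = final),
    class = "stepwise_fit"
  )
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("<stepwise_fit> outcome: ", x$outcome, "\n  retained (",
      length(x$retained), "/", length(x$candidates), "): ",
      if (length(x$retained)) paste(x$retained, collapse = ", ") else
        "none (intercept-only)", "\n", sep = "")
  print(x$trace)
  invisible(x)
}

#' Coefficient table of the retained stepwise model
#'
#' @param x A `stepwise_fit`.
#' @param ... Unused.
#' @return Tibble in the same shape as [tidy.ols_fit()].
#' @exportS3Method generics::tidy
tidy.stepwise_fit <- function(x, ...) tidy(x$final)

#' One-row summary of the retained stepwise model
#'
#' @param x A `stepwise_fit`.
#' @param ... Unused.
#' @return Tibble with fit statistics plus `n_retained` and `n_candidates`.
#' @exportS3Method generics::glance
glance.stepwise_fit <- function(x, ...) {
  dplyr::mutate(glance(x$final), n_retained = length(x$retained),
                n_candidates = length(x$candidates))
}

#' Step-trace plot of adjusted R squared against entered variables
#'
#' @param object A `stepwise_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.stepwise_fit <- function(object, ...) {
  tr <- object$trace
  if (nrow(tr) == 0) {
    abort("Nothing was retained; no trace to plot.")
  }
  tr$label <- paste0(tr$step, ". ", tr$variable)
  ggplot2::ggplot(tr, ggplot2::aes(.data$step, .data$adj_r_squared)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$action), size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.8,
                       size = 3) +
    ggplot2::labs(x = "Step", y = "Adjusted R squared",
                  title = paste0("Stepwise trace: ", object$outcome)) +
    ggplot2::theme_bw()
}

#' Reversed-outcome model: depression/anxiety/stress as the dependent
#'
#' Refits the stepwise regression with the DASS total as the outcome and
#' the RNT composite, sex, age, emotional stability, cognitive complaints
#' and the network segregation terms as candidates — used to check whether
#' segregation relates to depression once RNT is available as a predictor.
#'
#' @param data Cohort table containing `dass` and the candidate columns.
#' @param outcome Outcome column, default `"dass"`.
#' @param candidates Candidate predictors.
#' @param ... Passed to [forward_stepwise()].
#' @return A `stepwise_fit`.
#' @export
reversed_model <- function(data, outcome = "dass",
                           candidates = c("rnt", "sex", "age",
                                          "emotional_stability",
                                          "cognitive_complaints",
                                          "sys_asn", "sys_ddmn", "sys_vdmn",
                                          "sys_lecn", "sys_recn"),
                           ...) {
  forward_stepwise(data, outcome, candidates, ...)
}

#' Two-sample t test (pooled by default)
#'
#' Student's pooled-variance two-sided t test comparing a score between two
#' groups (e.g. RNT between female and male participants); a Welch variant
#' is available via `welch = TRUE`.
#'
#' @param group_a,group_b Numeric vectors, each with >= 2 values and
#'   positive variance.
#' @param welch Use the Welch (unequal-variance) statistic instead?
#' @return Tibble with `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
two_sample_ttest <- function(group_a, group_b, welch = FALSE) {
  for (g in list(a = group_a, b = group_b)) {
    if (length(g) < 2 || anyNA(g) || var(g) == 0) {
      abort("Each group needs >= 2 complete values with positive variance.",
            class = "sysseg_validation_error")
    }
  }
  ht <- t.test(group_a, group_b, var.equal = !welch)
  tibble::tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_a = mean(group_a),
                 mean_b = mean(group_b))
}
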