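# container for a single fitted analysis: estimate, CI, NI verdict

new_analysis_result <- function(outcome, term, estimate, se, df, ci_level,
                                ni_margin = NULL, population = "ITT",
                                n_used, scale = c("difference", "odds"),
                                coefficients = NULL, extra = list()) {
  scale <- match.arg(scale)
  alpha <- 1 - ci_level
  q <- if (is.finite(df)) qt(1 - alpha / 2, df) else qnorm(1 - alpha / 2)
  half <- q * se
  ci <- c(estimate - half, estimate + half)
  ni_verdict <- if (is.null(ni_margin)) NA else ci[2] < ni_margin
  res <- list(outcome = outcome, term = term, estimate = estimate,
              se = se, df = df, ci_lower = ci[1], ci_upper = ci[2],
              ci_level = ci_level, ni_margin = ni_margin,
              ni_verdict = ni_verdict, population = population,
              n_used = n_used, scale = scale,
              coefficients = coefficients, imputation_meta = NULL)
  res[names(extra)] <- extra
  structure(res, class = "analysis_result")
}

#' @export
print.analysis_result <- function(x, ...) {
  cat(sprintf("%s (%s population, n = %d)\n", x$outcome, x$population,
              x$n_used))
  if (x$scale == "odds") {
    cat(sprintf("  odds ratio [%s]: %.3f  (%.0f%% CI %.3f to %.3f)\n",
                x$term, exp(x$estimate), 100 * x$ci_level,
                exp(x$ci_lower), exp(x$ci_upper)))
  } else {
    cat(sprintf("  estimate [%s]: %.3f  (%.0f%% CI %.3f to %.3f)\n",
                x$term, x$estimate, 100 * x$ci_level, x$ci_lower,
                x$ci_upper))
  }
  if (!is.null(x$ni_margin) && !is.na(x$ni_verdict))
    cat(sprintf("  non-inferiority (margin %.3g): %s\n", x$ni_margin,
                if (x$ni_verdict) "shown (upper CI bound < margin)"
                else "not shown"))
  if (!is.null(x$imputation_meta))
    cat(sprintf("  pooled over b = %d imputations (between-var %.4g, within-var %.4g)\n",
                x$imputation_meta$b, x$imputation_meta$between_var,
                x$imputation_meta$within_var))
  invisible(x)
}

#' Confidence interval of an analysis result
#' @param object an `analysis_result`.
#' @param parm ignored (single-parameter results).
#' @param level ignored; the level is fixed when the result is created.
#' @param ... ignored.
#' @return Length-2 numeric vector `c(lower, upper)`.
#' @export
confint.analysis_result <- function(object, parm, level, ...) {
  c(object$ci_lower, object$ci_upper)
}
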