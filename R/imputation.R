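#' Multiple-imputation configuration
#'
#' Settings for chained-equations imputation of the trial dataset. The
#' number of completed datasets `b` is never below 10; with `b = "auto"`
#' it is `max(10, ceiling(100 * f))` where `f` is the missingness
#' fraction of the primary outcome (day-3 pain). The imputation model
#' always contains the full analysis model — primary outcome, baseline
#' pain, age, biological sex and treatment — plus the remaining diary
#' days as auxiliary predictors (the data are longitudinal, and the
#' neighboring days are the strongest predictors of a missing day).
#'
#' @param b number of imputed datasets (integer >= 10) or `"auto"`.
#' @param iterations chained-equation cycles per dataset (default 20).
#' @param pmm_k donors for predictive mean matching (default 5).
#' @param variables columns entering the imputation model; the default
#'   covers the analysis-model variables and the daily pain diary.
#' @param seed integer RNG seed (required at [impute_trial()] time).
#' @return An object of class `imputation_config`.
#' @export
imputation_config <- function(b = "auto", iterations = 20, pmm_k = 5,
                              variables = c(paste0("pain_d", 0:6),
                                            "age", "sex"),
                              seed = NULL) {
  if (!identical(b, "auto")) {
    b <- assert_count(b, "b", lower = 2)
    if (b < 10)
      stop("`b` must be at least 10 imputations", call. = FALSE)
  }
  iterations <- assert_count(iterations, "iterations", lower = 1)
  pmm_k <- assert_count(pmm_k, "pmm_k", lower = 1)
  if (!all(c("pain_d3", "pain_d0", "age", "sex") %in% variables))
    stop("the imputation model must include all analysis-model variables",
         call. = FALSE)
  if (!is.null(seed)) seed <- assert_count(seed, "seed")
  structure(list(b = b, iterations = iterations, pmm_k = pmm_k,
                 variables = variables, seed = seed),
            class = "imputation_config")
}

# predictive mean matching: draw regression parameters from their
# approximate posterior, predict observed and missing units, and donate
# an observed value from the k nearest predictions
pmm_draw <- function(y_obs, X_obs, X_mis, k) {
  qrx <- qr(X_obs)
  keep <- qrx$pivot[seq_len(qrx$rank)]
  Xo <- X_obs[, keep, drop = FALSE]
  Xm <- X_mis[, keep, drop = FALSE]
  fit <- lm.fit(Xo, y_obs)
  beta <- fit$coefficients
  res <- fit$residuals
  dfres <- max(1L, length(y_obs) - length(beta))
  s2_draw <- sum(res^2) / rchisq(1, dfres)
  xtxi <- chol2inv(chol(crossprod(Xo) +
                          diag(1e-8, ncol(Xo))))
  beta_draw <- beta + drop(chol(s2_draw * xtxi + diag(1e-12, ncol(Xo))) %*%
                             rnorm(ncol(Xo)))
  pred_obs <- drop(Xo %*% beta)
  pred_mis <- drop(Xm %*% beta_draw)
  vapply(pred_mis, function(p) {
    d <- abs(pred_obs - p)
    donors <- order(d)[seq_len(min(k, length(d)))]
    y_obs[donors[sample.int(length(donors), 1)]]
  }, numeric(1))
}

# logistic imputation with an approximate posterior draw of the
# coefficients; falls back to the observed marginal frequency if the
# fit degenerates (e.g. separation in a small stratum)
logreg_draw <- function(y_obs, X_obs, X_mis) {
  p_mis <- tryCatch({
    fit <- suppressWarnings(glm.fit(X_obs, y_obs, family = binomial()))
    beta <- fit$coefficients
    if (anyNA(beta) || any(abs(beta) > 15)) stop("degenerate")
    w <- fit$weights
    xtwxi <- chol2inv(chol(crossprod(X_obs * sqrt(w)) +
                             diag(1e-8, ncol(X_obs))))
    beta_draw <- beta + drop(chol(xtwxi + diag(1e-12, ncol(X_obs))) %*%
                               rnorm(ncol(X_obs)))
    plogis(drop(X_mis %*% beta_draw))
  }, error = function(e) rep(mean(y_obs), nrow(X_mis)))
  as.integer(runif(length(p_mis)) < p_mis)
}

#' Chained-equations multiple imputation of a trial dataset
#'
#' Imputes missing diary and covariate values by chained equations:
#' each incomplete variable is regressed in turn on all others in the
#' imputation model (plus the treatment indicator), cycling
#' `iterations` times per dataset. Integer NRS pain variables are
#' imputed by predictive mean matching (so imputed values stay on the
#' observed 0-10 grid); biological sex by a posterior-draw logistic
#' model. A non-binary gender label is treated as unknown biological sex
#' and imputed like any missing value — its uncertainty thereby
#' propagates into the pooled analysis.
#'
#' @param ds a `trial_dataset`.
#' @param cfg an [imputation_config()]; its `seed` (or the `seed`
#'   argument) must be set.
#' @param seed overrides `cfg$seed`.
#' @return An object of class `imputed_trial`: a list with `datasets`
#'   (list of `b` completed data frames, where the `sex` column holds
#'   the completed biological sex), `b`, `config`, `seed`, and `traces`
#'   (per-dataset iteration means of each imputed variable, for
#'   convergence monitoring).
#' @export
impute_trial <- function(ds, cfg = imputation_config(), seed = NULL) {
  stopifnot(inherits(cfg, "imputation_config"))
  if (is.null(seed)) seed <- cfg$seed
  if (is.null(seed)) stop("a seed is required", call. = FALSE)

  vars <- cfg$variables
  missing_cols <- setdiff(vars, names(ds))
  if (length(missing_cols))
    stop("columns not in dataset: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  # numeric working matrix; sex becomes 0/1 (male = 1), nonbinary -> NA
  work <- data.frame(treatment = treatment_indicator(ds))
  for (v in vars) {
    work[[v]] <- if (v == "sex")
      ifelse(ds$sex == "nonbinary", NA_real_,
             as.numeric(ds$sex == "male"))
    else as.numeric(ds[[v]])
  }
  all_missing <- vars[vapply(vars, function(v) all(is.na(work[[v]])),
                             logical(1))]
  if (length(all_missing))
    stop("variable(s) 100% missing: ",
         paste(all_missing, collapse = ", "), call. = FALSE)

  frac_primary <- mean(is.na(work$pain_d3))
  b <- if (identical(cfg$b, "auto"))
    max(10L, as.integer(ceiling(100 * frac_primary))) else cfg$b

  incomplete <- vars[vapply(vars, function(v) anyNA(work[[v]]),
                            logical(1))]

  finish <- function(w) {
    out <- ds
    for (v in incomplete) {
      if (v == "sex") {
        out$sex <- ifelse(w$sex == 1, "male", "female")
      } else {
        out[[v]] <- if (grepl("^pain_d", v)) as.integer(w[[v]]) else w[[v]]
      }
    }
    out
  }

  if (!length(incomplete)) {
    datasets <- replicate(b, {out <- ds; out}, simplify = FALSE)
    return(structure(list(datasets = datasets, b = b, config = cfg,
                          seed = seed, frac_missing_primary = frac_primary,
                          traces = NULL),
                     class = "imputed_trial"))
  }

  mis_idx <- lapply(incomplete, function(v) which(is.na(work[[v]])))
  names(mis_idx) <- incomplete

  datasets <- vector("list", b)
  traces <- vector("list", b)
  for (m in seq_len(b)) {
    res_m <- with_seed_if(substream_seed(seed, m), {
      w <- work
      # initialize by random draws from the observed margins
      for (v in incomplete) {
        obs <- w[[v]][!is.na(w[[v]])]
        w[[v]][mis_idx[[v]]] <- sample(obs, length(mis_idx[[v]]),
                                       replace = TRUE)
      }
      tr <- matrix(NA_real_, cfg$iterations, length(incomplete),
                   dimnames = list(NULL, incomplete))
      for (it in seq_len(cfg$iterations)) {
        for (v in incomplete) {
          idx <- mis_idx[[v]]
          preds <- setdiff(names(w), v)
          X <- cbind(1, as.matrix(w[preds]))
          obs_rows <- setdiff(seq_len(nrow(w)), idx)
          if (v == "sex") {
            w[[v]][idx] <- logreg_draw(w[[v]][obs_rows],
                                       X[obs_rows, , drop = FALSE],
                                       X[idx, , drop = FALSE])
          } else {
            w[[v]][idx] <- pmm_draw(w[[v]][obs_rows],
                                    X[obs_rows, , drop = FALSE],
                                    X[idx, , drop = FALSE], cfg$pmm_k)
          }
          tr[it, v] <- mean(w[[v]][idx])
        }
      }
      list(data = finish(w), trace = tr)
    })
    datasets[[m]] <- res_m$data
    traces[[m]] <- res_m$trace
  }
  structure(list(datasets = datasets, b = b, config = cfg, seed = seed,
                 frac_missing_primary = frac_primary, traces = traces),
            class = "imputed_trial")
}

#' @export
print.imputed_trial <- function(x, ...) {
  cat(sprintf("Chained-equations imputation: b = %d datasets, %d iterations\n",
              x$b, x$config$iterations))
  cat(sprintf("  missingness on primary outcome: %.1f%%\n",
              100 * x$frac_missing_primary))
  invisible(x)
}

#' Pool analysis results across imputed datasets (Rubin's rules)
#'
#' Combines `b` identically specified `analysis_result`s: the pooled
#' estimate is the mean of the estimates; the total variance is the mean
#' within-imputation variance plus `(1 + 1/b)` times the between
#' variance; degrees of freedom use the Barnard-Rubin small-sample
#' adjustment. The pooled confidence interval and non-inferiority
#' verdict are recomputed from the pooled quantities.
#'
#' @param results list of `analysis_result`s from the same model fitted
#'   on each imputed dataset.
#' @return A pooled `analysis_result` with `imputation_meta` filled in.
#' @export
#' @examples
#' # two hand-made results: estimates 1 and 2, within-variances 0.5 each
#' # pool to estimate 1.5 with total variance 0.5 + 1.5 * 0.5 = 1.25
pool_results <- function(results) {
  if (length(results) < 2L)
    stop("pooling needs at least 2 results", call. = FALSE)
  if (!all(vapply(results, inherits, logical(1), "analysis_result")))
    stop("all elements must be analysis_result objects", call. = FALSE)
  outc <- unique(vapply(results, `[[`, character(1), "outcome"))
  term <- unique(vapply(results, `[[`, character(1), "term"))
  if (length(outc) != 1L || length(term) != 1L)
    stop("heterogeneous model specifications cannot be pooled",
         call. = FALSE)
  b <- length(results)
  est <- vapply(results, `[[`, numeric(1), "estimate")
  wvar <- vapply(results, function(r) r$se^2, numeric(1))
  qbar <- mean(est)
  ubar <- mean(wvar)
  bvar <- if (b > 1) sum((est - qbar)^2) / (b - 1) else 0
  tvar <- ubar + (1 + 1 / b) * bvar

  df_com <- min(vapply(results, `[[`, numeric(1), "df"))
  if (bvar == 0 || tvar == 0) {
    df <- df_com
  } else {
    r <- (1 + 1 / b) * bvar / ubar
    lambda <- (1 + 1 / b) * bvar / tvar
    df_old <- (b - 1) / lambda^2
    df <- if (is.finite(df_com)) {
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
      df_old * df_obs / (df_old + df_obs)
    } else df_old
  }

  tmpl <- results[[1]]
  out <- new_analysis_result(
    outcome = tmpl$outcome, term = tmpl$term, estimate = qbar,
    se = sqrt(tvar), df = df, ci_level = tmpl$ci_level,
    ni_margin = tmpl$ni_margin, population = tmpl$population,
    n_used = tmpl$n_used, scale = tmpl$scale)
  out$imputation_meta <- list(b = b, within_var = ubar,
                              between_var = bvar, total_var = tvar,
                              df = df)
  out
}

#' Primary ANCOVA on imputed data, pooled
#'
#' Convenience wrapper: fits [primary_ancova()] on every completed
#' dataset of an `imputed_trial` and pools with [pool_results()].
#'
#' @param imp an `imputed_trial` from [impute_trial()].
#' @param ... passed to [primary_ancova()].
#' @return A pooled `analysis_result`.
#' @export
pooled_ancova <- function(imp, ...) {
  stopifnot(inherits(imp, "imputed_trial"))
  pool_results(lapply(imp$datasets, primary_ancova, ...))
}
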