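#' Planning assumptions for the non-inferiority design
#'
#' Bundles every quantity entering the sample-size calculation for the
#' one-sided two-sample t-test of the non-inferiority hypotheses
#' \deqn{H_0: \mu_{TT} - \mu_{ST} \ge \delta_{NI} \quad vs. \quad
#'       H_1: \mu_{TT} - \mu_{ST} < \delta_{NI},}
#' where \eqn{\mu_{TT}} (\eqn{\mu_{ST}}) is the mean day-3 pain under the
#' test treatment prednisolone (standard treatment colchicine) and
#' \eqn{\delta_{NI}} is the non-inferiority margin on the 0-10 NRS.
#'
#' `assumed_diff` is the planning value of the adjusted difference
#' \eqn{\mu_{TT} - \mu_{ST}} (positive = prednisolone assumed slightly
#' worse). The effective detectable shift of the test is
#' `ni_margin - assumed_diff`; the design is infeasible when
#' `|assumed_diff| >= ni_margin`.
#'
#' Note the deliberate asymmetry in the analysis plan: the trial is sized
#' with a one-sided 5\% test, but analyzed with two-sided 95\% confidence
#' intervals (an effective one-sided 2.5\% decision rule). Both
#' conventions are exposed; see [primary_ancova()] for the analysis side.
#'
#' @param alpha_one_sided one-sided significance level used for sizing
#'   (default 0.05).
#' @param power target power (default 0.90).
#' @param sigma common standard deviation of day-3 pain, NRS units
#'   (default 2.24).
#' @param ni_margin non-inferiority margin \eqn{\delta_{NI}}, NRS units
#'   (default 1).
#' @param assumed_diff planning value of \eqn{\mu_{TT}-\mu_{ST}}, NRS
#'   units (default 0.22).
#' @param dropout_rate anticipated patient dropout proportion used by
#'   [inflate_for_dropout()] (default 0.10).
#' @return An object of class `design_assumptions`.
#' @seealso [required_n_per_arm()], [achieved_power()]
#' @export
#' @examples
#' d <- design_assumptions()
#' required_n_per_arm(d)
design_assumptions <- function(alpha_one_sided = 0.05, power = 0.90,
                               sigma = 2.24, ni_margin = 1,
                               assumed_diff = 0.22, dropout_rate = 0.10) {
  assert_number(alpha_one_sided, "alpha_one_sided", 0, 0.5,
                open_lower = TRUE, open_upper = TRUE)
  assert_number(power, "power", 0, 1, open_lower = TRUE, open_upper = TRUE)
  assert_number(sigma, "sigma", 0, open_lower = TRUE)
  assert_number(ni_margin, "ni_margin", 0, open_lower = TRUE)
  assert_number(assumed_diff, "assumed_diff")
  assert_number(dropout_rate, "dropout_rate", 0, 1, open_upper = TRUE)
  structure(
    list(alpha_one_sided = alpha_one_sided, power = power, sigma = sigma,
         ni_margin = ni_margin, assumed_diff = assumed_diff,
         dropout_rate = dropout_rate),
    class = "design_assumptions"
  )
}

#' @export
print.design_assumptions <- function(x, ...) {
  cat("Non-inferiority design assumptions\n")
  cat(sprintf("  one-sided alpha : %.4g\n", x$alpha_one_sided))
  cat(sprintf("  target power    : %.4g\n", x$power))
  cat(sprintf("  common SD       : %.4g NRS units\n", x$sigma))
  cat(sprintf("  NI margin       : %.4g NRS units\n", x$ni_margin))
  cat(sprintf("  planning diff   : %.4g NRS units (TT - ST)\n",
              x$assumed_diff))
  cat(sprintf("  dropout rate    : %.4g\n", x$dropout_rate))
  invisible(x)
}

# effective shift of the sizing test; stops on an infeasible design
effective_shift <- function(d) {
  shift <- d$ni_margin - d$assumed_diff
  if (abs(d$assumed_diff) >= d$ni_margin)
    stop("infeasible design: |assumed_diff| >= ni_margin gives a ",
         "non-positive effective shift and an undefined sample size",
         call. = FALSE)
  shift
}

# exact power of the one-sided level-alpha two-sample t-test at true mean
# shift `shift`, common SD `sigma`, n per arm; noncentral t with 2n-2 df
power_two_sample_t <- function(n, shift, sigma, alpha) {
  df <- 2 * n - 2
  ncp <- shift / (sigma * sqrt(2 / n))
  1 - pt(qt(1 - alpha, df), df, ncp = ncp)
}

#' Required per-arm sample size
#'
#' Smallest integer `n` per arm such that the one-sided two-sample t-test
#' of the non-inferiority null attains at least the requested power when
#' the true difference equals the planning value. Power is evaluated
#' exactly through the noncentral t distribution with `2n - 2` degrees of
#' freedom (the behavior of standard power software), not the normal
#' approximation; see [normal_approx_n()] for the closed-form cross-check.
#'
#' @param d a [design_assumptions()] object.
#' @return Integer sample size per arm.
#' @export
#' @examples
#' required_n_per_arm(design_assumptions())  # 142
required_n_per_arm <- function(d) {
  stopifnot(inherits(d, "design_assumptions"))
  shift <- effective_shift(d)
  # start from the normal approximation and walk to the exact minimum
  n <- max(2L, as.integer(floor(normal_approx_n(d))) - 2L)
  while (power_two_sample_t(n, shift, d$sigma, d$alpha_one_sided) < d$power)
    n <- n + 1L
  while (n > 2L &&
         power_two_sample_t(n - 1L, shift, d$sigma, d$alpha_one_sided) >=
         d$power)
    n <- n - 1L
  n
}

#' Normal-approximation sample size (cross-check)
#'
#' Closed form \eqn{2\sigma^2 (z_{1-\alpha} + z_{power})^2 / \Delta^2}
#' with \eqn{\Delta} the effective shift `ni_margin - assumed_diff`.
#' Provided as a sanity cross-check of [required_n_per_arm()]; the exact
#' noncentral-t size is typically within about one patient of its ceiling.
#'
#' @inheritParams required_n_per_arm
#' @return Unrounded per-arm sample size.
#' @export
normal_approx_n <- function(d) {
  stopifnot(inherits(d, "design_assumptions"))
  shift <- effective_shift(d)
  2 * d$sigma^2 * (qnorm(1 - d$alpha_one_sided) + qnorm(d$power))^2 / shift^2
}

#' Inflate a per-arm sample size for anticipated dropout
#'
#' Adds the ceiling of `dropout_rate * n_per_arm` patients to each arm,
#' so e.g. 142 per arm at 10\% dropout gains 15 patients per arm for an
#' overall total of 314.
#'
#' @param n_per_arm evaluable sample size per arm (integer, >= 1).
#' @param dropout_rate anticipated dropout proportion in `[0, 1)`.
#' @return A list with `per_arm` (inflated per-arm size), `added`
#'   (patients added per arm) and `total` (both arms combined).
#' @export
#' @examples
#' inflate_for_dropout(142, 0.10)  # 157 per arm, 314 total
inflate_for_dropout <- function(n_per_arm, dropout_rate) {
  n_per_arm <- assert_count(n_per_arm, "n_per_arm", lower = 1)
  assert_number(dropout_rate, "dropout_rate", 0, 1, open_upper = TRUE)
  added <- as.integer(ceiling(dropout_rate * n_per_arm))
  per_arm <- n_per_arm + added
  list(per_arm = per_arm, added = added, total = 2L * per_arm)
}

#' Achieved power at a given per-arm sample size
#'
#' Exact power of the one-sided level-`alpha_one_sided` two-sample t-test
#' at the design's effective shift, via the noncentral t distribution.
#' Strictly increasing in `n_per_arm`.
#'
#' @inheritParams required_n_per_arm
#' @param n_per_arm per-arm sample size (integer, >= 2).
#' @return Power as a probability.
#' @export
#' @examples
#' achieved_power(design_assumptions(), 142)  # just above 0.90
achieved_power <- function(d, n_per_arm) {
  stopifnot(inherits(d, "design_assumptions"))
  n_per_arm <- assert_count(n_per_arm, "n_per_arm", lower = 2)
  power_two_sample_t(n_per_arm, effective_shift(d), d$sigma,
                     d$alpha_one_sided)
}

#' Monte-Carlo power of the sizing t-test
#'
#' Simulation counterpart of [achieved_power()]: draws `n_reps` trials of
#' two normal arms separated by the effective shift and applies the
#' one-sided two-sample t-test. Used to validate the analytic noncentral-t
#' computation.
#'
#' @inheritParams achieved_power
#' @param n_reps number of simulated trials (default 10000).
#' @param seed RNG seed.
#' @param shift optional true mean shift override; `shift = 0` simulates
#'   at the non-inferiority null boundary, where the rejection rate must
#'   equal `alpha_one_sided` (type-I error calibration).
#' @return A list with `power` (rejection proportion), `se` (binomial
#'   Monte-Carlo standard error) and `n_reps`.
#' @export
monte_carlo_power <- function(d, n_per_arm, n_reps = 10000, seed = NULL,
                              shift = NULL) {
  stopifnot(inherits(d, "design_assumptions"))
  n_per_arm <- assert_count(n_per_arm, "n_per_arm", lower = 2)
  n_reps <- assert_count(n_reps, "n_reps", lower = 1)
  if (is.null(shift)) shift <- effective_shift(d)
  assert_number(shift, "shift")
  with_seed_if(seed, {
    crit <- qt(1 - d$alpha_one_sided, 2 * n_per_arm - 2)
    rej <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      x <- rnorm(n_per_arm, mean = shift, sd = d$sigma)
      y <- rnorm(n_per_arm, mean = 0, sd = d$sigma)
      sp <- sqrt((var(x) + var(y)) / 2)
      tstat <- (mean(x) - mean(y)) / (sp * sqrt(2 / n_per_arm))
      rej[r] <- tstat > crit
    }
    p <- mean(rej)
    list(power = p, se = sqrt(p * (1 - p) / n_reps), n_reps = n_reps)
  })
}
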