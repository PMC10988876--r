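test_that("primary ANCOVA equals the normal-equations oracle", {
  df <- make_ancova_data(n = 8, beta1 = 0.5, seed = 5)
  res <- primary_ancova(df)

  X <- cbind(1, as.integer(df$arm == "TT"), df$pain_d0, df$age,
             as.integer(df$sex == "male"))
  beta <- solve(crossprod(X), crossprod(X, df$pain_d3))
  s2 <- sum((df$pain_d3 - X %*% beta)^2) / (8 - 5)
  se <- sqrt(s2 * solve(crossprod(X))[2, 2])

  expect_equal(res$estimate, beta[2], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(res$se, se, tolerance = 1e-10)
  expect_equal(res$ci_upper, beta[2] + qt(0.975, 3) * se,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("degenerate and ill-posed ANCOVA inputs are handled explicitly", {
  df <- make_ancova_data(n = 20, seed = 6)
  df$pain_d3 <- 5  # identical outcomes in both arms
  res <- primary_ancova(df)
  expect_equal(res$estimate, 0, tolerance = 1e-12)
  expect_equal(res$ci_upper - res$ci_lower, 0, tolerance = 1e-12)
  expect_true(res$ni_verdict)

  one_arm <- make_ancova_data(n = 20, seed = 7)
  one_arm$arm <- "TT"
  expect_error(primary_ancova(one_arm), "one arm")

  collinear <- make_ancova_data(n = 20, seed = 8)
  collinear$sex <- "male"  # constant factor -> rank-deficient design
  expect_error(primary_ancova(collinear), "rank-deficient")
})

test_that("ANCOVA recovers the simulated treatment effect", {
  est <- withr::with_seed(900, {
    replicate(300, primary_ancova(make_ancova_data(n = 284,
                                                   beta1 = 0.22))$estimate)
  })
  se <- sd(est) / sqrt(300)
  expect_lt(abs(mean(est) - 0.22), 3 * se)
})

test_that("the non-inferiority verdict is monotone in the margin", {
  df <- make_ancova_data(n = 200, beta1 = 0.22, seed = 10)
  verdicts <- vapply(c(0.3, 0.6, 1, 1.5, 2), function(m)
    primary_ancova(df, ni_margin = m)$ni_verdict, logical(1))
  expect_true(all(diff(as.integer(verdicts)) >= 0))
})

test_that("ANCOVA with unit baseline coefficient equals the change-score model", {
  df <- make_ancova_data(n = 120, beta1 = 0.4, seed = 11)
  df$treatment <- as.integer(df$arm == "TT")
  anc <- lm(pain_d3 ~ treatment + age + offset(pain_d0), data = df)
  chg <- lm(I(pain_d3 - pain_d0) ~ treatment + age, data = df)
  expect_equal(coef(anc)[["treatment"]], coef(chg)[["treatment"]],
               tolerance = 1e-10)

  # and the freely-estimated ANCOVA is no less efficient in simulation
  ests <- withr::with_seed(12, {
    t(replicate(200, {
      d <- make_ancova_data(n = 150, beta1 = 0.22)
      d$treatment <- as.integer(d$arm == "TT")
      c(anc = coef(lm(pain_d3 ~ treatment + pain_d0, data = d))[["treatment"]],
        chg = coef(lm(I(pain_d3 - pain_d0) ~ treatment, data = d))[["treatment"]])
    }))
  })
  expect_lte(var(ests[, "anc"]), var(ests[, "chg"]) * 1.05)
})

test_that("mixed model collapses to pooled OLS when centers are homogeneous", {
  ds <- small_trial(n_patients = 150, n_centers = 15, seed = 20,
                    center_sd = 0, dropout_rate = 0)
  res <- mean_pain_model(ds)
  expect_lt(res$center_var, 1e-4)

  long <- diary_long(ds, 1:6, "pain")
  long$treatment <- as.integer(long$arm == "TT")
  long$sex <- factor(ifelse(long$sex == "nonbinary", NA, long$sex),
                     levels = c("female", "male"))
  ols <- lm(pain ~ treatment + pain_d0 + age + sex, data = long)
  expect_equal(res$estimate, coef(ols)[["treatment"]], tolerance = 1e-4)
})

test_that("mixed model recovers a simulated treatment effect with center heterogeneity", {
  ests <- withr::with_seed(21, {
    replicate(30, {
      lists <- generate_pbr_lists(rand_config(n_centers = 20,
                                              seed = sample.int(1e6, 1)))
      ds <- generate_trial(trial_config(n_patients = 200,
                                        true_diff = 0.5, center_sd = 0.5,
                                        dropout_rate = 0,
                                        seed = sample.int(1e6, 1)), lists)
      mean_pain_model(ds)$estimate
    })
  })
  se <- sd(ests) / sqrt(30)
  expect_lt(abs(mean(ests) - 0.5), 3 * se)
})

test_that("mixed model tolerates a single center by collapsing to OLS", {
  lists <- generate_pbr_lists(rand_config(n_centers = 1, seed = 22))
  ds <- generate_trial(trial_config(n_patients = 30, seed = 23), lists)
  res <- mean_pain_model(ds)
  expect_identical(res$center_var, 0)
})

test_that("rank test agrees with exhaustive enumeration and handles edge cases", {
  ds <- data.frame(arm = c("TT", "TT", "TT", "ST", "ST", "ST"),
                   swelling_d3 = c(1, 1, 2, 3, 4, 4))
  res <- likert_rank_test(ds, "swelling_d3")

  # brute-force null distribution of the rank-sum over all 20 splits
  vals <- c(1, 1, 2, 3, 4, 4)
  r <- rank(vals)
  combs <- combn(6, 3)
  w_all <- apply(combs, 2, function(id) sum(r[id]) - 3 * 4 / 2)
  w_obs <- sum(r[1:3]) - 3 * 4 / 2
  p_oracle <- mean(abs(w_all - 4.5) >= abs(w_obs - 4.5))
  expect_equal(unname(res$statistic), w_obs)
  # tie-corrected approximation stays within Monte-Carlo-free reach of
  # the exact enumeration on this tiny fixture
  expect_lt(abs(res$p.value - p_oracle), 0.1)

  tiny <- data.frame(arm = c("TT", "ST"), swelling_d3 = c(2, 2))
  expect_equal(likert_rank_test(tiny, "swelling_d3")$p.value, 1)
  empty <- data.frame(arm = c("TT", "TT"), swelling_d3 = c(1, 2))
  expect_error(likert_rank_test(empty, "swelling_d3"), "empty arm")
})

test_that("rank test maintains its nominal size under the null", {
  pvals <- withr::with_seed(30, {
    replicate(1000, {
      ds <- data.frame(arm = rep(c("TT", "ST"), each = 25),
                       swelling_d3 = sample(1:4, 50, replace = TRUE))
      likert_rank_test(ds, "swelling_d3")$p.value
    })
  })
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 1000) + 0.01)
})

test_that("logistic model matches the cross-product odds ratio on a 2x2 table", {
  # 30 TT with 12 events, 30 ST with 6 events
  ds <- data.frame(arm = rep(c("TT", "ST"), each = 30),
                   additional_meds = c(rep(1, 12), rep(0, 18),
                                       rep(1, 6), rep(0, 24)),
                   pain_d0 = 7)
  res <- additional_meds_model(ds, covariates = character(0))
  or_oracle <- (12 * 24) / (18 * 6)
  expect_equal(exp(res$estimate), or_oracle, tolerance = 1e-6)
})

test_that("logistic model is calibrated under the null and flags separation", {
  logor <- withr::with_seed(31, {
    replicate(300, {
      ds <- data.frame(arm = rep(c("TT", "ST"), each = 80),
                       additional_meds = rbinom(160, 1, 0.3),
                       pain_d0 = sample(4:10, 160, replace = TRUE))
      additional_meds_model(ds)$estimate
    })
  })
  se <- sd(logor) / sqrt(300)
  expect_lt(abs(mean(logor)), 3 * se)

  const <- data.frame(arm = rep(c("TT", "ST"), each = 10),
                      additional_meds = 1, pain_d0 = 7)
  expect_error(additional_meds_model(const), "constant")
  sep <- data.frame(arm = rep(c("TT", "ST"), each = 10),
                    additional_meds = rep(c(1, 0), each = 10),
                    pain_d0 = rep(4:8, 4))
  expect_error(additional_meds_model(sep), "separation")
})

test_that("Holm adjustment follows the step-down definition and reports the family", {
  ds <- small_trial(n_patients = 200, n_centers = 20, seed = 40)
  sg <- subgroup_interactions(ds)
  expect_identical(attr(sg, "n_tests"), nrow(sg))
  expect_equal(sg$p_holm, holm_oracle(sg$p_raw), tolerance = 1e-12)

  one <- subgroup_interactions(ds, subgroups = "dect_positive")
  expect_equal(one$p_holm, one$p_raw, tolerance = 1e-12)

  # empty-cell subgroup is skipped with a reason, not an error
  ds$never <- 0L
  sk <- subgroup_interactions(ds, subgroups = c("dect_positive", "never"))
  expect_identical(nrow(sk), 1L)
  expect_match(attr(sk, "skipped")[["never"]], "empty")
})

test_that("familywise error of the subgroup family stays at level alpha", {
  hits <- withr::with_seed(41, {
    replicate(400, {
      n <- 160
      df <- data.frame(
        arm = rep(c("TT", "ST"), each = n / 2),
        pain_d3 = rnorm(n, 4, 2), pain_d0 = sample(5:9, n, TRUE),
        age = round(rnorm(n, 60, 10)),
        sex = sample(c("male", "female"), n, TRUE),
        s1 = rbinom(n, 1, 0.5), s2 = rbinom(n, 1, 0.5),
        s3 = rbinom(n, 1, 0.5), s4 = rbinom(n, 1, 0.5))
      sg <- subgroup_interactions(df, subgroups = c("s1", "s2", "s3", "s4"))
      any(sg$p_holm < 0.05)
    })
  })
  fwer <- mean(hits)
  expect_lte(fwer, 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("Clopper-Pearson interval matches its closed forms and is exact", {
  ci0 <- clopper_pearson(0, 10)
  expect_identical(ci0[["lower"]], 0)
  expect_equal(ci0[["upper"]], 1 - 0.025^(1 / 10), tolerance = 1e-12)
  cin <- clopper_pearson(10, 10)
  expect_identical(cin[["upper"]], 1)
  expect_equal(cin[["lower"]], 0.025^(1 / 10), tolerance = 1e-12)
  expect_true(all(is.na(clopper_pearson(0, 0))))
  expect_error(clopper_pearson(5, 4), "exceed")

  # agreement with the established exact test implementation
  bt <- binom.test(7, 157)$conf.int
  cp <- clopper_pearson(7, 157)
  expect_equal(unname(cp), as.numeric(bt), tolerance = 1e-10)

  # exact coverage at the per-arm trial size by binomial summation
  n <- 157
  for (p in c(0.01, 0.1, 0.5)) {
    covered <- vapply(0:n, function(x) {
      ci <- clopper_pearson(x, n)
      ci[["lower"]] <= p && p <= ci[["upper"]]
    }, logical(1))
    expect_gte(sum(dbinom(0:n, n, p)[covered]), 0.95)
  }
})

test_that("adverse-event summary tabulates both arms for every category", {
  ds <- small_trial(n_patients = 120, n_centers = 12, seed = 50)
  ae <- ae_rate_summary(ds)
  expect_identical(nrow(ae), 20L)  # 10 categories x 2 arms
  expect_true(all(ae$events <= ae$n))
  expect_true(all(ae$ci_lower <= ae$rate & ae$rate <= ae$ci_upper))
  i <- which(ae$category == "diarrhea" & ae$arm == "ST")
  manual <- sum(ds$ae_diarrhea[ds$arm == "ST"])
  expect_identical(ae$events[i], manual)
})

test_that("blood-pressure mixed model detects the prednisolone drift", {
  lists <- generate_pbr_lists(rand_config(n_centers = 40, seed = 60))
  ds <- generate_trial(trial_config(n_patients = 600, dropout_rate = 0,
                                    seed = 61), lists)
  res <- bp_course_model(ds, "sbp")
  # drift of 0.8 mmHg/day gives a mean day-1..6 offset of 2.8 mmHg
  expect_gt(res$estimate, 1)
  expect_gt(res$patient_var, 0)
  expect_equal(res$outcome, "sbp course days 1-6 (mmHg)")
})

test_that("population builder applies the day-3 rule inclusively", {
  ds <- small_trial(n_patients = 100, n_centers = 10, seed = 70,
                    deviation_rate = 0, dropout_rate = 0)
  pops <- build_populations(ds)
  expect_identical(nrow(pops$pp), nrow(pops$itt))

  # hand-crafted deviations: day 2 and day 3 exclude, day 4 does not
  ds$deviation_day[1] <- 2L; ds$dev_incomplete_use[1] <- TRUE
  ds$deviation_day[2] <- 3L; ds$dev_incomplete_use[2] <- TRUE
  ds$deviation_day[3] <- 4L; ds$dev_incomplete_use[3] <- TRUE
  pops <- build_populations(ds)
  expect_identical(nrow(pops$pp), nrow(ds) - 2L)
  expect_false(any(pops$pp$patient_id %in% ds$patient_id[1:2]))
  expect_true(ds$patient_id[3] %in% pops$pp$patient_id)
  expect_identical(sum(pops$reasons$n), 2L)

  # a withdrawal on day 2 leaves ITT intact but drops from PP
  ds2 <- small_trial(n_patients = 100, n_centers = 10, seed = 71,
                     deviation_rate = 0, dropout_rate = 0)
  ds2$withdrawal_day[5] <- 2L
  ds2$dev_attrition[5] <- TRUE
  ds2$deviation_day[5] <- 2L
  pops2 <- build_populations(ds2)
  expect_identical(nrow(pops2$itt), nrow(ds2))
  expect_false(ds2$patient_id[5] %in% pops2$pp$patient_id)
})

test_that("compliance summary respects both denominator conventions", {
  ds <- data.frame(arm = rep(c("TT", "ST"), each = 4),
                   pills_taken_by_d4 = c(12, 12, 8, NA, 12, 12, 12, 12))
  cs <- compliance_summary(ds, pills_full = 12)
  tt <- cs[cs$arm == "TT", ]
  expect_identical(tt$n_compliant, 2L)
  expect_identical(tt$n_missing, 1L)
  expect_equal(tt$pct_of_evaluable, 100 * 2 / 3)
  expect_equal(tt$pct_missing_as_noncompliant, 50)
  st <- cs[cs$arm == "ST", ]
  expect_equal(st$pct_of_evaluable, 100)
})
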