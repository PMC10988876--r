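lists60 <- generate_pbr_lists(rand_config(seed = 400))

test_that("generation is byte-identical under a fixed seed", {
  cfg <- trial_config(seed = 42)
  a <- generate_trial(cfg, lists60)
  b <- generate_trial(cfg, lists60)
  expect_identical(a, b)
  # and serializes to the identical CSV text
  csv_of <- function(d) {
    tc <- textConnection("out", "w", local = TRUE)
    write.csv(d, tc, row.names = FALSE)
    close(tc)
    paste(out, collapse = "\n")
  }
  expect_identical(csv_of(a), csv_of(b))
  d2 <- generate_trial(trial_config(seed = 43), lists60)
  expect_false(identical(a, d2))
})

test_that("arms come from the allocation lists, never ad hoc", {
  ds <- generate_trial(trial_config(n_patients = 120, seed = 9), lists60)
  for (cid in unique(ds$center_id)) {
    sub <- ds[ds$center_id == cid, ]
    sub <- sub[order(sub$recruit_index), ]
    expect_identical(sub$arm,
                     lists60[[cid]]$entries[seq_len(nrow(sub))])
  }
  expect_error(
    generate_trial(trial_config(n_patients = 10000, seed = 1), lists60),
    "capacity")
})

test_that("generated values respect their scales and truncation rules", {
  ds <- generate_trial(trial_config(seed = 77), lists60)
  for (t in 0:6) {
    v <- ds[[paste0("pain_d", t)]]
    expect_true(all(is.na(v) | (v >= 0 & v <= 10 & v == round(v))))
  }
  expect_true(all(is.na(ds$swelling_d3) | ds$swelling_d3 %in% 1:4))
  expect_true(all(is.na(ds$tenderness_d3) | ds$tenderness_d3 %in% 1:4))
  expect_true(all(is.na(ds$global_success_d6) |
                    ds$global_success_d6 %in% 1:5))
  for (t in 0:6) {
    expect_true(all(is.na(ds[[paste0("sbp_d", t)]]) |
                      ds[[paste0("sbp_d", t)]] > 0))
    expect_true(all(is.na(ds[[paste0("dbp_d", t)]]) |
                      ds[[paste0("dbp_d", t)]] > 0))
  }
  # withdrawal at day d blanks the diary strictly after day d
  wd <- which(!is.na(ds$withdrawal_day))
  for (i in wd) {
    d <- ds$withdrawal_day[i]
    if (d < 6) {
      after <- paste0("pain_d", (d + 1):6)
      expect_true(all(is.na(ds[i, after])))
    }
    upto <- paste0("pain_d", 0:d)
    expect_true(all(!is.na(ds[i, upto])))
  }
})

test_that("day-3 dispersion and treatment difference match the design targets", {
  ds <- generate_trial(trial_config(seed = 31), lists60)
  sds <- tapply(ds$pain_d3, ds$arm, sd, na.rm = TRUE)
  expect_true(all(sds >= 2.0 & sds <= 2.5))

  # under the null configuration the arm means coincide
  big <- trial_config(n_patients = 1500, true_diff = 0, center_sd = 0,
                      dropout_rate = 0, seed = 52)
  lists_big <- generate_pbr_lists(rand_config(n_centers = 60,
                                              seed = 53))
  ds0 <- generate_trial(big, lists_big)
  diff <- mean(ds0$pain_d3[ds0$arm == "TT"]) -
    mean(ds0$pain_d3[ds0$arm == "ST"])
  se <- sd(ds0$pain_d3) * sqrt(2 / 750)
  expect_lt(abs(diff), 3 * se)
})

test_that("patient dropout hits its target rate and MAR depends on baseline pain", {
  ds <- generate_trial(trial_config(seed = 60), lists60)
  frac <- mean(!is.na(ds$withdrawal_day))
  expect_lt(abs(frac - 0.10), 3 * sqrt(0.1 * 0.9 / nrow(ds)))
  # any-missing-diary fraction equals the withdrawal fraction by design
  diary <- as.matrix(ds[paste0("pain_d", 1:6)])
  expect_identical(mean(apply(diary, 1, anyNA)), frac)

  lists_big <- generate_pbr_lists(rand_config(n_centers = 80, seed = 61))
  mar <- generate_trial(trial_config(n_patients = 2000,
                                     dropout_rate = 0.2,
                                     missing_mechanism = "MAR",
                                     seed = 62), lists_big)
  fit <- glm(!is.na(withdrawal_day) ~ pain_d0, family = binomial(),
             data = mar)
  z <- coef(summary(fit))["pain_d0", "z value"]
  expect_gt(z, 2)  # steeper baseline pain -> higher withdrawal odds
  expect_lt(abs(mean(!is.na(mar$withdrawal_day)) - 0.2), 0.04)
})

test_that("deviations drive the per-protocol set as specified", {
  lists <- generate_pbr_lists(rand_config(n_centers = 40, seed = 70))
  none <- generate_trial(trial_config(n_patients = 200,
                                      deviation_rate = 0,
                                      dropout_rate = 0, seed = 71),
                         lists)
  pops <- build_populations(none)
  expect_identical(nrow(pops$pp), nrow(pops$itt))

  all_dev <- generate_trial(trial_config(n_patients = 200,
                                         deviation_rate = 1,
                                         dropout_rate = 0, seed = 72),
                            lists)
  # every deviation kind except day-4 incomplete use excludes from PP
  pops <- build_populations(all_dev)
  expect_lt(nrow(pops$pp), 0.4 * nrow(pops$itt))

  mid <- generate_trial(trial_config(n_patients = 300,
                                     deviation_rate = 0.3,
                                     dropout_rate = 0, seed = 73),
                        generate_pbr_lists(rand_config(seed = 74)))
  frac_pp <- nrow(build_populations(mid)$pp) / nrow(mid)
  expect_lt(abs(frac_pp - 0.7), 0.08)

  # incomplete medication use is reflected in the pill count
  inc <- mid$dev_incomplete_use
  expect_true(all(is.na(mid$pills_taken_by_d4[inc]) |
                    mid$pills_taken_by_d4[inc] < 12))
})

test_that("non-binary gender masks a recoverable latent biological sex", {
  lists <- generate_pbr_lists(rand_config(n_centers = 80, seed = 80))
  ds <- generate_trial(trial_config(n_patients = 2000,
                                    nonbinary_count = 40, seed = 81),
                       lists)
  nb <- ds$sex == "nonbinary"
  expect_gt(sum(nb), 10)
  expect_true(all(ds$sex_latent %in% c("male", "female")))
  expect_identical(ds$sex[!nb], ds$sex_latent[!nb])
})
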