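#' Configuration of the synthetic trial generator
#'
#' Parameters of the patient-level data generator used to exercise every
#' analysis stage without real data. Defaults reproduce the planning
#' assumptions of the trial: 314 randomized patients, an adjusted day-3
#' pain difference (prednisolone minus colchicine) of 0.22 NRS units, a
#' day-3 standard deviation of 2.24, 10\% patient dropout, at least 30\%
#' protocol deviations, and around 3 patients reporting a non-binary
#' gender (whose biological sex is treated as unknown downstream).
#'
#' Values the analysis plan does not pin down (baseline pain mean 7, SD
#' 1.5, baseline/day-3 correlation 0.4, center-intercept SD 0.3, the
#' daily pain-decay profile, adverse-event and blood-pressure parameters)
#' are generator defaults chosen to be clinically plausible for acute
#' gout; they are not protocol values and are all configurable.
#'
#' @param n_patients number randomized (default 314).
#' @param true_diff adjusted day-3 pain difference, test minus standard
#'   treatment (positive = prednisolone worse); default 0.22 NRS units.
#' @param sigma_day3 marginal SD of day-3 pain (default 2.24).
#' @param baseline_pain_mean,baseline_pain_sd baseline (day-0) pain
#'   distribution on the latent scale.
#' @param baseline_cor correlation between baseline and day-3 pain.
#' @param daily_decay mean pain reduction from baseline for days 1-6.
#' @param center_sd SD of center random intercepts.
#' @param dropout_rate probability that a patient withdraws before day 6
#'   (diary entries after the withdrawal day are missing).
#' @param missing_mechanism `"MCAR"` (withdrawal independent of
#'   everything) or `"MAR"` (withdrawal probability increases with
#'   observed baseline pain, calibrated to `dropout_rate` on average).
#' @param deviation_rate probability of a non-attrition protocol
#'   deviation (default 0.30); see [inject_deviations()].
#' @param nonbinary_count expected number of patients with a non-binary
#'   gender label (default 3).
#' @param ae_rates named list of per-category adverse-event probabilities,
#'   each a length-2 vector `c(TT = , ST = )`.
#' @param bp_params list with `sbp_mean`, `sbp_sd`, `dbp_mean`, `dbp_sd`
#'   (baseline levels, mmHg) and `sbp_slope_tt`, `dbp_slope_tt`
#'   (additional daily drift under prednisolone, mmHg/day).
#' @param pills_full number of pills a fully compliant patient has taken
#'   by day 4 (both arms identical under double-dummy dosing).
#' @param seed integer RNG seed (required for generation).
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(n_patients = 314, true_diff = 0.22,
                         sigma_day3 = 2.24, baseline_pain_mean = 7,
                         baseline_pain_sd = 1.5, baseline_cor = 0.4,
                         daily_decay = c(1.2, 2.2, 3.2, 3.8, 4.2, 4.5),
                         center_sd = 0.3, dropout_rate = 0.10,
                         missing_mechanism = c("MCAR", "MAR"),
                         deviation_rate = 0.30, nonbinary_count = 3,
                         ae_rates = default_ae_rates(),
                         bp_params = default_bp_params(),
                         pills_full = 12, seed = NULL) {
  missing_mechanism <- match.arg(missing_mechanism)
  n_patients <- assert_count(n_patients, "n_patients", lower = 2)
  assert_number(true_diff, "true_diff")
  assert_number(sigma_day3, "sigma_day3", 0, open_lower = TRUE)
  assert_number(baseline_cor, "baseline_cor", -1, 1)
  assert_number(center_sd, "center_sd", 0)
  assert_number(dropout_rate, "dropout_rate", 0, 1)
  assert_number(deviation_rate, "deviation_rate", 0, 1)
  if (length(daily_decay) != 6)
    stop("`daily_decay` must give the mean reduction for days 1-6",
         call. = FALSE)
  # residual SD so that day-3 marginal SD matches sigma_day3 after adding
  # the baseline carry-over and center components
  carry <- baseline_cor * sigma_day3
  resid_var <- sigma_day3^2 - carry^2 - center_sd^2
  if (resid_var <= 0)
    stop("sigma_day3 too small for the requested baseline_cor/center_sd",
         call. = FALSE)
  if (!is.null(seed)) seed <- assert_count(seed, "seed")
  structure(
    list(n_patients = n_patients, true_diff = true_diff,
         sigma_day3 = sigma_day3, baseline_pain_mean = baseline_pain_mean,
         baseline_pain_sd = baseline_pain_sd, baseline_cor = baseline_cor,
         daily_decay = daily_decay, center_sd = center_sd,
         dropout_rate = dropout_rate, missing_mechanism = missing_mechanism,
         deviation_rate = deviation_rate, nonbinary_count = nonbinary_count,
         ae_rates = ae_rates, bp_params = bp_params,
         pills_full = as.integer(pills_full),
         sigma_resid = sqrt(resid_var), seed = seed),
    class = "trial_config"
  )
}

#' Default adverse-event probabilities per arm
#'
#' Generator defaults (not protocol values): gastrointestinal events are
#' more frequent under colchicine, dizziness slightly more frequent under
#' prednisolone; categories follow the trial's solicited list.
#' @return Named list of `c(TT = , ST = )` probabilities.
#' @export
default_ae_rates <- function() {
  list(dizziness      = c(TT = 0.05, ST = 0.04),
       nausea         = c(TT = 0.05, ST = 0.08),
       vomiting       = c(TT = 0.02, ST = 0.03),
       dyspepsia      = c(TT = 0.05, ST = 0.04),
       diarrhea       = c(TT = 0.04, ST = 0.12),
       constipation   = c(TT = 0.03, ST = 0.02),
       abdominal_pain = c(TT = 0.04, ST = 0.07),
       headache       = c(TT = 0.06, ST = 0.06),
       skin_rash      = c(TT = 0.02, ST = 0.02),
       other          = c(TT = 0.05, ST = 0.05))
}

#' Default blood-pressure generator parameters
#'
#' Baseline levels typical of an older hypertension-prone gout
#' population, with a small upward daily drift of systolic/diastolic
#' pressure under prednisolone (a known corticosteroid effect the safety
#' analysis is designed to detect).
#' @return A list of means, SDs (mmHg) and per-day arm drifts (mmHg/day).
#' @export
default_bp_params <- function() {
  list(sbp_mean = 135, sbp_sd = 13, dbp_mean = 85, dbp_sd = 9,
       sbp_slope_tt = 0.8, dbp_slope_tt = 0.4, day_sd = 6)
}

ae_categories <- function() names(default_ae_rates())

#' Generate a synthetic patient-level trial dataset
#'
#' Draws one complete trial: patients are distributed over the recruiting
#' centers (multinomially, equal weights, capped at each center's list
#' length) and receive their arm from the center's predefined allocation
#' list — never ad hoc. Daily pain follows a latent-normal model (shared
#' center intercept, baseline carry-over, arm effect, residual noise)
#' rounded to the integer 0-10 NRS grid; Likert secondaries are
#' thresholded from latent pain improvement; withdrawal truncates the
#' diary; adverse events, blood pressure, adherence, baseline
#' characteristics and subgroup flags complete the record.
#'
#' The non-binary gender label is generated on top of a latent biological
#' sex which is then masked in the `sex` column (kept in `sex_latent` as
#' synthetic ground truth for imputation recovery tests only — analyses
#' must not use it).
#'
#' With `deviations = TRUE` (default), [inject_deviations()] is applied
#' before returning.
#'
#' @param cfg a [trial_config()]; its `seed` must be set.
#' @param lists per-center allocation lists from [generate_pbr_lists()]
#'   (or [generate_cr_lists()]).
#' @param deviations also draw protocol deviations.
#' @return A data frame (one row per patient) of class
#'   `c("trial_dataset", "data.frame")` with the config in attribute
#'   `config`. Regenerating with the same seed yields an identical
#'   dataset.
#' @export
#' @examples
#' lists <- generate_pbr_lists(rand_config(seed = 20))
#' ds <- generate_trial(trial_config(n_patients = 40, seed = 21), lists)
#' table(ds$arm)
generate_trial <- function(cfg, lists, deviations = TRUE) {
  stopifnot(inherits(cfg, "trial_config"))
  if (is.null(cfg$seed)) stop("`cfg$seed` must be set", call. = FALSE)
  n <- cfg$n_patients
  caps <- vapply(lists, function(l) length(l$entries), integer(1))
  if (sum(caps) < n)
    stop(sprintf("allocation capacity (%d) below n_patients (%d)",
                 sum(caps), n), call. = FALSE)

  ds <- with_seed_if(cfg$seed, {
    n_centers <- length(lists)
    # spread patients over centers; cap at list length, reallocating
    counts <- as.vector(rmultinom(1, n, prob = rep(1, n_centers)))
    repeat {
      excess <- sum(pmax(counts - caps, 0L))
      counts <- pmin(counts, caps)
      if (excess == 0L) break
      room <- counts < caps
      counts[room] <- counts[room] +
        as.vector(rmultinom(1, excess, prob = rep(1, sum(room))))
    }
    center_id <- rep(names(lists), counts)
    recruit_index <- unlist(lapply(counts, seq_len), use.names = FALSE)
    arm <- unlist(mapply(function(l, k) l$entries[seq_len(k)],
                         lists, counts, SIMPLIFY = FALSE),
                  use.names = FALSE)
    tt <- as.integer(arm == "TT")

    u_center <- rnorm(n_centers, 0, cfg$center_sd)
    names(u_center) <- names(lists)
    u <- u_center[center_id]

    age <- pmin(95L, pmax(18L, as.integer(round(rnorm(n, 62, 12)))))
    sex_latent <- ifelse(runif(n) < 0.8, "male", "female")
    nonbinary <- runif(n) < cfg$nonbinary_count / n
    sex <- ifelse(nonbinary, "nonbinary", sex_latent)

    # latent daily pain: baseline carry-over + center + arm effect + noise
    bl_latent <- rnorm(n, cfg$baseline_pain_mean, cfg$baseline_pain_sd)
    pain_d0 <- clamp_nrs(bl_latent)
    carry <- cfg$baseline_cor * cfg$sigma_day3 / cfg$baseline_pain_sd
    pain_days <- matrix(NA_integer_, n, 6)
    improvement <- matrix(NA_real_, n, 6)
    for (t in 1:6) {
      lat <- cfg$baseline_pain_mean - cfg$daily_decay[t] +
        carry * (bl_latent - cfg$baseline_pain_mean) + u +
        cfg$true_diff * tt + rnorm(n, 0, cfg$sigma_resid)
      pain_days[, t] <- clamp_nrs(lat)
      improvement[, t] <- bl_latent - lat
    }

    # Likert secondaries from latent improvement (higher improvement ->
    # less swelling/tenderness, better global assessment)
    swelling_d3 <- pmin(4L, pmax(1L, as.integer(round(
      2.8 - 0.3 * improvement[, 3] + rnorm(n, 0, 0.9)))))
    tenderness_d3 <- pmin(4L, pmax(1L, as.integer(round(
      3.0 - 0.33 * improvement[, 3] + rnorm(n, 0, 0.9)))))
    global_success_d6 <- pmin(5L, pmax(1L, as.integer(round(
      1.8 + 0.45 * improvement[, 6] + rnorm(n, 0, 0.9)))))

    physfun_d0 <- round(rnorm(n, 40, 10), 1)
    physfun_d6 <- round(20 + 0.6 * physfun_d0 + 2 * improvement[, 6] +
                          rnorm(n, 0, 6), 1)

    disease_duration <- round(rgamma(n, shape = 2, scale = 3), 1)
    time_since_onset_h <- round(runif(n, 2, 48), 1)
    first_instance <- as.integer(runif(n) < 0.4)
    prior_pain_med <- as.integer(runif(n) < 0.5)
    affected_part <- sample(c("first_mtpj", "other_foot", "hand"), n,
                            replace = TRUE, prob = c(0.6, 0.25, 0.15))
    n_affected_parts <- sample(1:3, n, replace = TRUE,
                               prob = c(0.7, 0.2, 0.1))
    swollen_joint_count <- sample(1:3, n, replace = TRUE,
                                  prob = c(0.75, 0.18, 0.07))
    tender_joint_count <- sample(1:3, n, replace = TRUE,
                                 prob = c(0.7, 0.2, 0.1))
    diabetes <- as.integer(runif(n) < 0.2)
    cv_event <- as.integer(runif(n) < 0.15)
    hypertension <- as.integer(runif(n) < 0.5)

    # baseline laboratory panel, with sporadic missing values (MCAR 5%)
    lab <- function(mean, sd, digits = 1) {
      x <- round(rnorm(n, mean, sd), digits)
      x[runif(n) < 0.05] <- NA
      x
    }
    leukocytes <- lab(7.5, 1.8)
    platelets <- lab(250, 60, 0)
    erythrocytes <- lab(4.8, 0.5, 2)
    hemoglobin <- lab(9.0, 0.9)
    hematocrit <- lab(0.43, 0.04, 3)
    crp <- round(exp(rnorm(n, log(12), 0.8)), 1)
    crp[runif(n) < 0.05] <- NA
    uric_acid <- lab(8.0, 1.5)
    creatinine <- lab(1.0, 0.22, 2)
    got <- lab(28, 8, 0)
    gpt <- lab(30, 10, 0)
    egfr <- lab(75, 18, 0)

    dect_positive <- as.integer(runif(n) < 0.6)
    urate_volume <- ifelse(dect_positive == 1,
                           round(exp(rnorm(n, log(0.5), 1)), 3), 0)

    # withdrawal: MCAR uniform, or MAR increasing with observed baseline
    # pain (logistic, intercept calibrated to the target rate)
    if (cfg$dropout_rate == 0) {
      withdrew <- rep(FALSE, n)
    } else if (cfg$missing_mechanism == "MCAR") {
      withdrew <- runif(n) < cfg$dropout_rate
    } else {
      lp <- 0.35 * (pain_d0 - mean(pain_d0))
      a <- uniroot(function(a) mean(plogis(a + lp)) - cfg$dropout_rate,
                   c(-20, 20))$root
      withdrew <- runif(n) < plogis(a + lp)
    }
    # attrition prior to day 6: a withdrawal always truncates the diary
    withdrawal_day <- ifelse(withdrew, sample(1:5, n, replace = TRUE), NA)
    withdrawal_reason <- ifelse(
      withdrew, sample(c("adverse event", "lack of efficacy",
                         "withdrew consent", "lost to follow-up"),
                       n, replace = TRUE, prob = c(0.3, 0.25, 0.25, 0.2)),
      NA_character_)

    # adverse events: independent Bernoulli per category, arm-specific
    ae <- lapply(cfg$ae_rates, function(p)
      as.integer(runif(n) < ifelse(tt == 1L, p[["TT"]], p[["ST"]])))
    names(ae) <- paste0("ae_", names(cfg$ae_rates))

    # blood pressure: patient baseline + arm drift per day + noise
    bp <- cfg$bp_params
    sbp_base <- rnorm(n, bp$sbp_mean, bp$sbp_sd)
    dbp_base <- rnorm(n, bp$dbp_mean, bp$dbp_sd)
    sbp <- sapply(0:6, function(t)
      pmax(70, round(sbp_base + bp$sbp_slope_tt * t * tt +
                       rnorm(n, 0, bp$day_sd))))
    dbp <- sapply(0:6, function(t)
      pmax(40, round(dbp_base + bp$dbp_slope_tt * t * tt +
                       rnorm(n, 0, bp$day_sd * 0.7))))

    pills_taken_by_d4 <- rep(cfg$pills_full, n)

    ds <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      center_id = center_id, recruit_index = recruit_index, arm = arm,
      age = age, sex = sex, sex_latent = sex_latent,
      disease_duration = disease_duration,
      time_since_onset_h = time_since_onset_h,
      first_instance = first_instance, prior_pain_med = prior_pain_med,
      affected_part = affected_part, n_affected_parts = n_affected_parts,
      swollen_joint_count = swollen_joint_count,
      tender_joint_count = tender_joint_count,
      diabetes = diabetes, cv_event = cv_event,
      hypertension = hypertension,
      leukocytes = leukocytes, platelets = platelets,
      erythrocytes = erythrocytes, hemoglobin = hemoglobin,
      hematocrit = hematocrit, crp = crp, uric_acid = uric_acid,
      creatinine = creatinine, got = got, gpt = gpt, egfr = egfr,
      elevated_uric_acid = as.integer(!is.na(uric_acid) & uric_acid > 7),
      elevated_crp = as.integer(!is.na(crp) & crp > 5),
      dect_positive = dect_positive, urate_volume = urate_volume,
      pain_d0 = pain_d0,
      stringsAsFactors = FALSE)
    for (t in 1:6) ds[[paste0("pain_d", t)]] <- pain_days[, t]
    ds$swelling_d3 <- swelling_d3
    ds$tenderness_d3 <- tenderness_d3
    ds$global_success_d6 <- global_success_d6
    ds$physfun_d0 <- physfun_d0
    ds$physfun_d6 <- physfun_d6
    ds$additional_meds <- as.integer(
      runif(n) < plogis(-2 + 0.35 * (pain_days[, 3] - 4)))
    ds$nonpharm_therapy <- as.integer(
      runif(n) < plogis(-1.5 + 0.12 * (pain_d0 - 7)))
    for (nm in names(ae)) ds[[nm]] <- ae[[nm]]
    for (t in 0:6) ds[[paste0("sbp_d", t)]] <- sbp[, t + 1]
    for (t in 0:6) ds[[paste0("dbp_d", t)]] <- dbp[, t + 1]
    ds$pills_taken_by_d4 <- pills_taken_by_d4
    ds$withdrawal_day <- withdrawal_day
    ds$withdrawal_reason <- withdrawal_reason

    # withdrawal at day d: all diary fields after day d are missing
    for (t in 1:6) {
      gone <- !is.na(withdrawal_day) & withdrawal_day < t
      ds[[paste0("pain_d", t)]][gone] <- NA
      ds[[paste0("sbp_d", t)]][gone] <- NA
      ds[[paste0("dbp_d", t)]][gone] <- NA
    }
    d6_gone <- !is.na(withdrawal_day) & withdrawal_day < 6
    ds$global_success_d6[d6_gone] <- NA
    ds$physfun_d6[d6_gone] <- NA
    d3_gone <- !is.na(withdrawal_day) & withdrawal_day < 3
    ds$swelling_d3[d3_gone] <- NA
    ds$tenderness_d3[d3_gone] <- NA
    ds$pills_taken_by_d4[!is.na(withdrawal_day) & withdrawal_day <= 4] <- NA
    ds
  })

  class(ds) <- c("trial_dataset", "data.frame")
  attr(ds, "config") <- cfg
  if (deviations) ds <- inject_deviations(ds, cfg)
  ds
}

#' Inject protocol deviations
#'
#' Draws deviations from the protocol's qualifying list at
#' `cfg$deviation_rate` per patient: incomplete use of medication (with
#' the pill count made consistent), late presentation of the gout flare,
#' subsequently realized exclusion criteria, or a different underlying
#' disease. Attrition prior to day 6 is additionally flagged from the
#' withdrawal day (not drawn; it already exists in the data). Each
#' deviation carries the first day it affects (baseline-qualifying
#' deviations count as day 0), from which per-protocol membership up to
#' day 3 is derivable — see [build_populations()].
#'
#' Runs on a seed derived from `cfg$seed`, so a dataset generated with
#' `deviations = TRUE` is reproducible end to end.
#'
#' @param ds a `trial_dataset`.
#' @param cfg the [trial_config()] used to generate it (defaults to the
#'   attached config).
#' @return The dataset with logical columns `dev_incomplete_use`,
#'   `dev_late_flare`, `dev_exclusion_criteria`, `dev_other_disease`,
#'   `dev_attrition` and integer `deviation_day` (first affected day, NA
#'   if none).
#' @export
inject_deviations <- function(ds, cfg = attr(ds, "config")) {
  stopifnot(inherits(ds, "trial_dataset"), inherits(cfg, "trial_config"))
  n <- nrow(ds)
  out <- with_seed_if(substream_seed(cfg$seed, 999983), {
    dev <- runif(n) < cfg$deviation_rate
    kind <- rep(NA_character_, n)
    kind[dev] <- sample(c("incomplete_use", "late_flare",
                          "exclusion_criteria", "other_disease"),
                        sum(dev), replace = TRUE,
                        prob = c(0.5, 0.2, 0.15, 0.15))
    day <- rep(NA_integer_, n)
    day[dev] <- 0L
    inc <- which(!is.na(kind) & kind == "incomplete_use")
    day[inc] <- sample(1:4, length(inc), replace = TRUE)

    ds$dev_incomplete_use <- !is.na(kind) & kind == "incomplete_use"
    ds$dev_late_flare <- !is.na(kind) & kind == "late_flare"
    ds$dev_exclusion_criteria <- !is.na(kind) & kind == "exclusion_criteria"
    ds$dev_other_disease <- !is.na(kind) & kind == "other_disease"
    ds$dev_attrition <- !is.na(ds$withdrawal_day) & ds$withdrawal_day <= 5

    att_day <- ifelse(ds$dev_attrition, ds$withdrawal_day, NA_integer_)
    ds$deviation_day <- pmin(day, att_day, na.rm = TRUE)

    # pill count consistent with incomplete use of medication
    if (length(inc))  # NA stays NA: an unreturned diary has no pill count
      ds$pills_taken_by_d4[inc] <- pmin(
        ds$pills_taken_by_d4[inc],
        sample(seq_len(cfg$pills_full) - 1L, length(inc), replace = TRUE))
    ds
  })
  class(out) <- c("trial_dataset", "data.frame")
  attr(out, "config") <- cfg
  out
}

#' Long-format daily diary
#'
#' Reshapes the wide diary columns into one row per patient-day for the
#' mixed-model analyses.
#'
#' @param ds a `trial_dataset`.
#' @param days which follow-up days to include (default 1:6).
#' @param measure `"pain"`, `"sbp"` or `"dbp"`.
#' @return A data frame with `patient_id`, `center_id`, `arm`, `day`,
#'   the measure column, and baseline covariates; rows with a missing
#'   measurement are dropped.
#' @export
diary_long <- function(ds, days = 1:6, measure = c("pain", "sbp", "dbp")) {
  measure <- match.arg(measure)
  rows <- lapply(days, function(t) {
    val <- ds[[paste0(measure, "_d", t)]]
    data.frame(patient_id = ds$patient_id, center_id = ds$center_id,
               arm = ds$arm, day = t, value = val,
               pain_d0 = ds$pain_d0, age = ds$age, sex = ds$sex,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "value"] <- measure
  out <- out[!is.na(out[[measure]]), ]
  rownames(out) <- NULL
  out
}
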