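# baseline characteristics and flow tables

fmt_mean_sd <- function(x) {
  if (!sum(!is.na(x))) return("n/a")
  sprintf("%.2f (%.2f)", mean(x, na.rm = TRUE), sd(x, na.rm = TRUE))
}

fmt_n_pct <- function(k, n) sprintf("%d (%.1f)", k, 100 * k / n)

#' Baseline characteristics table
#'
#' Per-arm and overall summaries of the baseline items: continuous items
#' as mean (SD) to two decimals, categorical items as n (\%) to one
#' decimal with percentages on the column N, and an explicit Missing
#' row per item. No hypothesis tests are computed on baseline
#' characteristics. Unknown requested columns are skipped with a
#' warning.
#'
#' @param ds a `trial_dataset` (or any data frame with the documented
#'   schema).
#' @return A data frame of class `baseline_table` with columns `item`,
#'   `level`, `colchicine` (ST), `prednisolone` (TT), `all`; the
#'   unformatted numeric counts are kept in attribute `counts`.
#' @export
baseline_table <- function(ds) {
  arms <- list(colchicine = ds[ds$arm == "ST", , drop = FALSE],
               prednisolone = ds[ds$arm == "TT", , drop = FALSE],
               all = ds)
  rows <- list()
  counts <- list()
  add <- function(item, level, vals) {
    rows[[length(rows) + 1L]] <<- data.frame(
      item = item, level = level,
      colchicine = vals[1], prednisolone = vals[2], all = vals[3],
      stringsAsFactors = FALSE)
  }
  add_missing <- function(item, col) {
    ks <- vapply(arms, function(a) sum(is.na(a[[col]])), numeric(1))
    ns <- vapply(arms, nrow, numeric(1))
    add(item, "Missing, n (%)", mapply(fmt_n_pct, ks, ns))
    counts[[paste0(item, ":Missing")]] <<- ks
  }
  cont <- function(item, col, missing_row = TRUE) {
    if (is.null(ds[[col]])) {
      warning(sprintf("column `%s` not found; item skipped", col))
      return(invisible())
    }
    add(item, "mean (SD)",
        vapply(arms, function(a) fmt_mean_sd(a[[col]]), character(1)))
    if (missing_row) add_missing(item, col)
  }
  catn <- function(item, col, levels, labels = levels,
                   missing_row = TRUE) {
    if (is.null(ds[[col]])) {
      warning(sprintf("column `%s` not found; item skipped", col))
      return(invisible())
    }
    for (j in seq_along(levels)) {
      ks <- vapply(arms, function(a)
        sum(a[[col]] == levels[j], na.rm = TRUE), numeric(1))
      ns <- vapply(arms, nrow, numeric(1))
      add(item, sprintf("%s, n (%%)", labels[j]),
          mapply(fmt_n_pct, ks, ns))
      counts[[paste0(item, ":", labels[j])]] <<- ks
    }
    if (missing_row) add_missing(item, col)
  }

  add("N", "", vapply(arms, function(a) as.character(nrow(a)),
                      character(1)))
  cont("Age, years", "age", missing_row = FALSE)
  catn("Gender", "sex", c("male", "female", "nonbinary"),
       c("Male", "Female", "Non-binary"), missing_row = FALSE)
  cont("Disease duration, years", "disease_duration")
  if (!is.null(ds$disease_duration)) {
    dur_cat <- cut(ds$disease_duration, c(-Inf, 2, 5, 10, Inf),
                   labels = c("< 2 years", "2-5 years", "6-10 years",
                              "> 10 years"), right = FALSE)
    tmp <- ds
    tmp$._dur_cat <- as.character(dur_cat)
    arms_dur <- list(tmp[tmp$arm == "ST", ], tmp[tmp$arm == "TT", ], tmp)
    for (lv in c("< 2 years", "2-5 years", "6-10 years", "> 10 years")) {
      ks <- vapply(arms_dur, function(a)
        sum(a$._dur_cat == lv, na.rm = TRUE), numeric(1))
      ns <- vapply(arms_dur, nrow, numeric(1))
      add("Disease duration category", sprintf("%s, n (%%)", lv),
          mapply(fmt_n_pct, ks, ns))
      counts[[paste0("Disease duration category:", lv)]] <- ks
    }
  }
  catn("First instance of gout", "first_instance", 1, "Yes")
  cont("Time since symptom onset, hours", "time_since_onset_h")
  catn("Prior pain medication", "prior_pain_med", 1, "Yes")
  catn("Affected body part", "affected_part",
       c("first_mtpj", "other_foot", "hand"),
       c("First MTPJ", "Other foot joint", "Joint of finger and/or hand"))
  catn("No. of affected body parts", "n_affected_parts", 1:3,
       c("1", "2", "3"))
  cont("Pain (NRS)", "pain_d0")
  catn("Swollen joint count", "swollen_joint_count", 1:3,
       c("1", "2", ">= 3"))
  catn("Tender joint count", "tender_joint_count", 1:3,
       c("1", "2", ">= 3"))
  catn("Diabetes (type I/II)", "diabetes", 1, "Yes", missing_row = FALSE)
  catn("Previous cardiovascular event", "cv_event", 1, "Yes",
       missing_row = FALSE)
  catn("Hypertension", "hypertension", 1, "Yes", missing_row = FALSE)
  cont("Systolic blood pressure, mmHg", "sbp_d0")
  cont("Diastolic blood pressure, mmHg", "dbp_d0")
  cont("Leukocytes (10^3/uL)", "leukocytes")
  cont("Platelets (/nL)", "platelets")
  cont("Erythrocytes (/pL)", "erythrocytes")
  cont("Hemoglobin (mmol/L)", "hemoglobin")
  cont("Hematocrit", "hematocrit")
  cont("C-reactive protein (mg/L)", "crp")
  cont("Uric acid (mg/dL)", "uric_acid")
  cont("Creatinine (mg/dL)", "creatinine")
  cont("GOT (U/L)", "got")
  cont("GPT (U/L)", "gpt")
  cont("eGFR (mL/min/1.73m2)", "egfr")

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "counts") <- counts
  class(out) <- c("baseline_table", "data.frame")
  out
}

#' Trial flow summary
#'
#' CONSORT-style counts: randomized (and per arm), treated, withdrawn
#' with a tabulation of withdrawal reasons, and the sizes of the ITT and
#' per-protocol analysis sets. Consistency is guaranteed by
#' construction: ITT equals all randomized patients and PP is a subset.
#'
#' @param ds a `trial_dataset` with deviation columns.
#' @return A list with `counts` (named integer vector) and
#'   `withdrawal_reasons` (data frame).
#' @export
flow_summary <- function(ds) {
  pops <- build_populations(ds)
  withdrawn <- !is.na(ds$withdrawal_day)
  reasons <- if (any(withdrawn)) {
    tab <- table(ds$withdrawal_reason[withdrawn], useNA = "ifany")
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(df) <- c("reason", "n")
    df
  } else data.frame(reason = character(0), n = integer(0))
  counts <- c(randomized = nrow(ds),
              randomized_TT = sum(ds$arm == "TT"),
              randomized_ST = sum(ds$arm == "ST"),
              treated = nrow(ds),
              withdrawn = sum(withdrawn),
              analyzed_itt = nrow(pops$itt),
              analyzed_pp = nrow(pops$pp))
  list(counts = counts, withdrawal_reasons = reasons)
}
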