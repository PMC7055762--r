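#' Clinical code lists and thresholds driving phenotyping
#'
#' Phenotyping is vocabulary-agnostic: feature codes are opaque strings and
#' every criterion is driven by caller-supplied code lists.  The defaults
#' match the codes emitted by [generate_cohort()].
#'
#' @param hba1c,random_glucose,fasting_glucose Laboratory codes for the
#'   glycaemic labs (percent and mg/dL respectively).
#' @param creatinine,acr,pcr Codes for serum creatinine (mg/dL), urine
#'   albumin-to-creatinine ratio (mg/g) and protein-to-creatinine ratio
#'   (mg/g).
#' @param glucose_med Codes of glucose-lowering medications.
#' @param dm_dx Diagnosis codes for type 1/2 diabetes.
#' @param t1dm_dx,cfdm_dx Codes flagging type 1 and cystic-fibrosis-related
#'   diabetes (exclusion criteria).
#' @param gestational Codes flagging gestational diabetes; such events
#'   never count toward any onset criterion.
#' @param hba1c_threshold,random_glucose_threshold,fasting_glucose_threshold
#'   Qualifying glycaemic thresholds (6.5%, 200 mg/dL, 126 mg/dL).
#' @param egfr_threshold eGFR below this (mL/min/1.73m2) is abnormal.
#' @param ratio_threshold ACR/PCR at or above this (mg/g) is abnormal.
#' @param pair_window_days Window within which two qualifying events must
#'   fall (2 years).
#' @return A list of class `"clinical_codes"`.
#' @export
clinical_codes <- function(hba1c = "hba1c",
                           random_glucose = "random_glucose",
                           fasting_glucose = "fasting_glucose",
                           creatinine = "serum_creatinine",
                           acr = "uacr", pcr = "upcr",
                           glucose_med = "glucose_lowering_med",
                           dm_dx = "dm_dx",
                           t1dm_dx = "t1dm_dx", cfdm_dx = "cfdm_dx",
                           gestational = "gestational_dm",
                           hba1c_threshold = 6.5,
                           random_glucose_threshold = 200,
                           fasting_glucose_threshold = 126,
                           egfr_threshold = 60, ratio_threshold = 30,
                           pair_window_days = 730L) {
  structure(list(hba1c = hba1c, random_glucose = random_glucose,
                 fasting_glucose = fasting_glucose,
                 creatinine = creatinine, acr = acr, pcr = pcr,
                 glucose_med = glucose_med, dm_dx = dm_dx,
                 t1dm_dx = t1dm_dx, cfdm_dx = cfdm_dx,
                 gestational = gestational,
                 hba1c_threshold = hba1c_threshold,
                 random_glucose_threshold = random_glucose_threshold,
                 fasting_glucose_threshold = fasting_glucose_threshold,
                 egfr_threshold = egfr_threshold,
                 ratio_threshold = ratio_threshold,
                 pair_window_days = as.integer(pair_window_days)),
            class = "clinical_codes")
}

#' Estimated glomerular filtration rate (MDRD)
#'
#' Four-variable MDRD study equation with the IDMS-traceable 175
#' coefficient:
#' \deqn{eGFR = 175 \cdot SCr^{-1.154} \cdot age^{-0.203} \cdot 0.742^{[female]} \cdot 1.212^{[black]}}
#' in mL/min/1.73m2.
#'
#' @param serum_creatinine Serum creatinine, mg/dL (must be positive).
#' @param age Age in years at the laboratory date (must be at least 18).
#' @param sex `"male"` or `"female"`.
#' @param race Race category; the 1.212 multiplier applies when `"black"`.
#' @return eGFR in mL/min/1.73m2 (vectorised).
#' @export
compute_egfr <- function(serum_creatinine, age, sex, race = "other") {
  if (any(serum_creatinine <= 0)) stop("serum creatinine must be positive")
  if (any(age < 18)) stop("age must be at least 18")
  sex <- match.arg(rep_len(sex, length(serum_creatinine)),
                   c("male", "female"), several.ok = TRUE)
  race <- rep_len(race, length(serum_creatinine))
  175 * serum_creatinine^(-1.154) * age^(-0.203) *
    ifelse(sex == "female", 0.742, 1) *
    ifelse(race == "black", 1.212, 1)
}

#' Classify a kidney lab panel as abnormal
#'
#' Abnormal means impaired filtration (eGFR strictly below 60
#' mL/min/1.73m2) or micro-/proteinuria (albumin- or
#' protein-to-creatinine ratio of 30 mg/g or greater).  At least one
#' measurement must be supplied.
#'
#' @param egfr Optional eGFR, mL/min/1.73m2.
#' @param acr Optional albumin-to-creatinine ratio, mg/g.
#' @param pcr Optional protein-to-creatinine ratio, mg/g.
#' @param egfr_threshold,ratio_threshold Decision thresholds.
#' @return `TRUE` if any supplied measurement is abnormal.
#' @export
classify_kidney_abnormal <- function(egfr = NULL, acr = NULL, pcr = NULL,
                                     egfr_threshold = 60,
                                     ratio_threshold = 30) {
  vals <- list(egfr = egfr, acr = acr, pcr = pcr)
  if (all(vapply(vals, function(v) is.null(v) || all(is.na(v)), TRUE)))
    stop("at least one measurement must be supplied")
  abn <- FALSE
  if (!is.null(egfr) && !all(is.na(egfr)))
    abn <- abn | (!is.na(egfr) & egfr < egfr_threshold)
  if (!is.null(acr) && !all(is.na(acr)))
    abn <- abn | (!is.na(acr) & acr >= ratio_threshold)
  if (!is.null(pcr) && !all(is.na(pcr)))
    abn <- abn | (!is.na(pcr) & pcr >= ratio_threshold)
  abn
}

# earliest day d in a sorted unique day vector that has a partner within
# `window` days; NA if none
.lb_first_paired_day <- function(days, window) {
  days <- sort(unique(days))
  if (length(days) < 2L) return(NA_integer_)
  ok <- which(diff(days) <= window)
  if (!length(ok)) NA_integer_ else days[ok[1L]]
}

#' Detect diabetes onset in a patient timeline
#'
#' Diabetes is established by any of: (1) use of a glucose-lowering
#' medication; (2) qualifying glycaemic labs (HbA1c at or above 6.5%,
#' random glucose at or above 200 mg/dL, or fasting glucose at or above
#' 126 mg/dL) on at least two different dates within two years; (3) two
#' diabetes diagnoses on two different days within two years; (4) any two
#' distinct types of events among (1)--(3).  Events flagged gestational
#' never count.  Onset is the earliest day of the qualifying events; a
#' single medication record suffices for (1), and criterion (4) imposes
#' no proximity window.
#'
#' @param timeline Event data frame for one patient (columns as in the
#'   event-table schema).
#' @param codes A [clinical_codes()] object.
#' @return Integer onset day, or `NA` when no criterion is met.
#' @export
detect_dm_onset <- function(timeline, codes = clinical_codes()) {
  ev <- timeline[!(timeline$feature_code %in% codes$gestational), ]
  lab_day <- function(code_set, threshold) {
    rows <- ev$feature_code %in% code_set & !is.na(ev$value) &
      ev$value >= threshold
    ev$day[rows]
  }
  qual_days <- c(lab_day(codes$hba1c, codes$hba1c_threshold),
                 lab_day(codes$random_glucose,
                         codes$random_glucose_threshold),
                 lab_day(codes$fasting_glucose,
                         codes$fasting_glucose_threshold))
  med_days <- ev$day[ev$feature_code %in% codes$glucose_med]
  dx_days <- ev$day[ev$feature_code %in% codes$dm_dx]

  w <- codes$pair_window_days
  cand <- c(if (length(med_days)) min(med_days) else NA_integer_,
            .lb_first_paired_day(qual_days, w),
            .lb_first_paired_day(dx_days, w))
  # criterion (4): two distinct event types, no proximity window
  firsts <- c(if (length(med_days)) min(med_days) else NA_integer_,
              if (length(qual_days)) min(qual_days) else NA_integer_,
              if (length(dx_days)) min(dx_days) else NA_integer_)
  if (sum(!is.na(firsts)) >= 2L) cand <- c(cand, min(firsts, na.rm = TRUE))
  if (all(is.na(cand))) NA_integer_ else as.integer(min(cand, na.rm = TRUE))
}

# qualifying kidney labs of one patient: valid (positive numeric) serum
# creatinine / ACR / PCR records, with abnormality classified per record
.lb_kidney_labs <- function(timeline, demo, codes,
                            outpatient_only = TRUE) {
  kid <- c(codes$creatinine, codes$acr, codes$pcr)
  rows <- timeline$feature_code %in% kid & !is.na(timeline$value) &
    timeline$value > 0
  if (outpatient_only) rows <- rows & timeline$encounter_type == "outpatient"
  labs <- timeline[rows, , drop = FALSE]
  if (nrow(labs) == 0L)
    return(data.frame(day = integer(0), abnormal = logical(0)))
  abn <- logical(nrow(labs))
  is_cr <- labs$feature_code %in% codes$creatinine
  if (any(is_cr)) {
    # age at the lab date = age at onset + elapsed full years
    age_lab <- pmax(18, demo$age_at_onset +
                      floor((labs$day[is_cr] - demo$dm_onset_day) / 365))
    eg <- compute_egfr(labs$value[is_cr], age_lab, demo$sex, demo$race)
    abn[is_cr] <- eg < codes$egfr_threshold
  }
  is_ratio <- !is_cr
  abn[is_ratio] <- labs$value[is_ratio] >= codes$ratio_threshold
  data.frame(day = labs$day, abnormal = abn)[order(labs$day), ]
}

#' Yearly outcome sequence from a patient timeline
#'
#' For each yearly window `t` (days `[365 t, 365 (t+1))` from diabetes
#' onset) the status is taken from the last valid outpatient kidney lab in
#' the window: 1 if abnormal, 0 if normal, `NA` when no qualifying lab was
#' collected (no imputation).  The sequence truncates after the first 1,
#' so e.g. a patient normal in year 0, unmeasured in year 1 and abnormal
#' in year 2 has sequence `(0, NA, 1)`.
#'
#' @param timeline Event data frame for one patient.
#' @param dm_onset_day Onset day (absolute, as in the timeline).
#' @param horizon_T Number of yearly windows.
#' @param demographics List/row with `age_at_onset`, `sex`, `race`; when
#'   `NULL` it is read from the timeline's demographics events.
#' @param codes A [clinical_codes()] object.
#' @return Object of class `"outcome_sequence"`: `statuses` (integer
#'   vector with `NA`s, truncated after the first 1), `dm_onset_day`,
#'   `end_point_day` (day of the first abnormal lab for cases, last
#'   normal lab day for controls, relative to onset).
#' @export
build_outcome_sequence <- function(timeline, dm_onset_day, horizon_T = 5L,
                                   demographics = NULL,
                                   codes = clinical_codes()) {
  stopifnot(!is.na(dm_onset_day))
  demo <- if (is.null(demographics))
    .lb_timeline_demographics(timeline) else as.list(demographics)
  demo$dm_onset_day <- dm_onset_day
  labs <- .lb_kidney_labs(timeline, demo, codes)
  labs$rel <- labs$day - dm_onset_day
  statuses <- rep(NA_integer_, horizon_T)
  for (t in seq_len(horizon_T) - 1L) {
    inwin <- labs$rel >= 365 * t & labs$rel < 365 * (t + 1)
    if (!any(inwin)) next
    last <- which(inwin)[sum(inwin)]
    statuses[t + 1L] <- as.integer(labs$abnormal[last])
    if (statuses[t + 1L] == 1L) {
      statuses <- statuses[seq_len(t + 1L)]
      break
    }
  }
  post <- labs[labs$rel >= 0, , drop = FALSE]
  end_point <- if (any(post$abnormal)) post$rel[which(post$abnormal)[1L]]
  else if (nrow(post)) post$rel[max(which(!post$abnormal))]
  else NA_integer_
  structure(list(statuses = statuses, dm_onset_day = dm_onset_day,
                 end_point_day = end_point),
            class = "outcome_sequence")
}

#' @export
print.outcome_sequence <- function(x, ...) {
  cat("Outcome sequence:",
      paste(ifelse(is.na(x$statuses), "NA", x$statuses), collapse = ","),
      "| onset day", x$dm_onset_day, "\n")
  invisible(x)
}

# demographics parsed from a timeline's demographics events
.lb_timeline_demographics <- function(timeline) {
  d <- timeline[timeline$domain == "demographics", , drop = FALSE]
  age <- d$value[d$feature_code == "age_at_onset"]
  sex <- d$modifier[d$feature_code == "sex"]
  race <- d$modifier[d$feature_code == "race"]
  list(age_at_onset = if (length(age)) age[1L] else NA_real_,
       sex = if (length(sex)) sex[1L] else NA_character_,
       race = if (length(race)) race[1L] else "other")
}

#' Landmark eligibility from an outcome sequence
#'
#' A patient is eligible at landmark `t` when the status at `t` is
#' non-missing and no earlier status equals 1.  Missing (`NA`) years do
#' not censor later eligibility: sequence `(0, NA, 1)` is eligible at
#' `t = 0` and `t = 2` but not at `t = 1`.
#'
#' @param statuses Integer status vector (or an `"outcome_sequence"`).
#' @param t Zero-based landmark index.
#' @return Logical.
#' @export
landmark_eligibility <- function(statuses, t) {
  if (inherits(statuses, "outcome_sequence")) statuses <- statuses$statuses
  stopifnot(t >= 0)
  if (t + 1L > length(statuses)) return(FALSE)
  if (is.na(statuses[t + 1L])) return(FALSE)
  if (t >= 1L && any(statuses[seq_len(t)] == 1L, na.rm = TRUE))
    return(FALSE)
  TRUE
}

#' Apply cohort inclusion and exclusion rules
#'
#' Given a multi-patient event table, detects diabetes onset, derives
#' yearly outcome sequences, and applies the study filters: adults (age at
#' onset at least 18) with at least one valid outpatient kidney lab;
#' exclusion of patients with type 1 or cystic-fibrosis-related diabetes
#' diagnoses and of patients with kidney disease manifestation before
#' diabetes onset.  Cases are patients whose first abnormal kidney lab
#' after onset defines their end point; controls are always-normal
#' patients whose end point is their last normal lab.  One patient may hit
#' several exclusion criteria, so the per-criterion counts can sum to more
#' than the number of excluded patients.
#'
#' @param events Event table (multiple patients).
#' @param horizon_T Number of yearly outcome windows.
#' @param codes A [clinical_codes()] object.
#' @return List: `cohort` (data frame: `patient_id`, `dm_onset_day`,
#'   `group`, `end_point_day`, `sequence` as a string like `"0,NA,1"`),
#'   `sequences` (named list of status vectors), `exclusions`
#'   (per-criterion counts), `demographics`.
#' @export
apply_cohort_filters <- function(events, horizon_T = 5L,
                                 codes = clinical_codes()) {
  pheno_codes <- c(codes$hba1c, codes$random_glucose,
                   codes$fasting_glucose, codes$creatinine, codes$acr,
                   codes$pcr, codes$glucose_med, codes$dm_dx,
                   codes$t1dm_dx, codes$cfdm_dx, codes$gestational)
  rel <- events[events$feature_code %in% pheno_codes |
                  events$domain == "demographics", , drop = FALSE]
  by_pat <- split(rel, rel$patient_id)
  ids <- names(by_pat)

  n_no_onset <- 0L; n_minor <- 0L; n_t1cf <- 0L
  n_prior_kidney <- 0L; n_no_lab <- 0L
  np <- length(ids)
  k_pid <- character(np); k_onset <- integer(np); k_group <- character(np)
  k_end <- integer(np); k_seq <- character(np)
  k_age <- numeric(np); k_sex <- character(np); k_race <- character(np)
  k <- 0L
  seqs <- list()

  for (pid in ids) {
    tl <- by_pat[[pid]]
    onset <- detect_dm_onset(tl, codes)
    excl <- FALSE
    if (is.na(onset)) { n_no_onset <- n_no_onset + 1L; next }
    demo <- .lb_timeline_demographics(tl)
    if (is.na(demo$age_at_onset) || demo$age_at_onset < 18) {
      n_minor <- n_minor + 1L; excl <- TRUE
    }
    if (any(tl$feature_code %in% c(codes$t1dm_dx, codes$cfdm_dx))) {
      n_t1cf <- n_t1cf + 1L; excl <- TRUE
    }
    if (is.na(demo$age_at_onset)) next  # demographics required below
    dm <- c(demo, dm_onset_day = onset)
    all_labs <- .lb_kidney_labs(tl, dm, codes, outpatient_only = FALSE)
    if (any(all_labs$abnormal & all_labs$day < onset)) {
      n_prior_kidney <- n_prior_kidney + 1L; excl <- TRUE
    }
    out_labs <- .lb_kidney_labs(tl, dm, codes, outpatient_only = TRUE)
    if (nrow(out_labs) == 0L) { n_no_lab <- n_no_lab + 1L; excl <- TRUE }
    if (excl) next
    os <- build_outcome_sequence(tl, onset, horizon_T, demo, codes)
    k <- k + 1L
    k_pid[k] <- pid
    k_onset[k] <- onset
    k_group[k] <- if (any(out_labs$abnormal & out_labs$day >= onset))
      "case" else "control"
    k_end[k] <- os$end_point_day
    k_seq[k] <- paste(ifelse(is.na(os$statuses), "NA", os$statuses),
                      collapse = ",")
    k_age[k] <- demo$age_at_onset
    k_sex[k] <- demo$sex
    k_race[k] <- demo$race
    seqs[[pid]] <- os$statuses
  }

  idx <- seq_len(k)
  cohort <- data.frame(patient_id = k_pid[idx], dm_onset_day = k_onset[idx],
                       group = k_group[idx], end_point_day = k_end[idx],
                       sequence = k_seq[idx], stringsAsFactors = FALSE)
  demographics <- if (k > 0L)
    data.frame(patient_id = k_pid[idx], age_at_onset = k_age[idx],
               sex = k_sex[idx], race = k_race[idx],
               stringsAsFactors = FALSE) else NULL
  exclusions <- data.frame(
    criterion = c("no_dm_onset", "age_under_18", "t1dm_or_cf_diabetes",
                  "kidney_disease_before_onset",
                  "no_valid_outpatient_kidney_lab"),
    n_excluded = c(n_no_onset, n_minor, n_t1cf, n_prior_kidney, n_no_lab),
    stringsAsFactors = FALSE)
  list(cohort = cohort, sequences = seqs, exclusions = exclusions,
       demographics = demographics)
}
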