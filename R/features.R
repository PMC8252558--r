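#' Names of the twelve HoNOS items
#'
#' Standard item order of the Health of the Nation Outcome Scales. The
#' seven items analysed for CSA correlates are aggression (item 1),
#' self-harm (2), substance misuse (3), hallucinations/delusions (6),
#' depressed mood (7), relationships (9) and living conditions (11).
#'
#' @return Character vector of length 12.
#' @export
honos_item_names <- function() {
  c("overactive_aggressive", "self_harm", "substance_misuse",
    "cognitive_problems", "physical_illness", "hallucinations_delusions",
    "depressed_mood", "other_symptoms", "relationships",
    "activities_daily_living", "living_conditions", "occupation_activities")
}

#' HoNOS items analysed as CSA correlates
#' @return Character vector of length 7.
#' @export
honos_analysis_items <- function() {
  honos_item_names()[c(1L, 2L, 3L, 6L, 7L, 9L, 11L)]
}

smi_pattern <- "^F2[0-9]|^F3[01]"
icd10_pattern <- "^F[0-9]{2}(\\.[0-9])?$"

#' Apply the cohort eligibility filters
#'
#' Keeps patients with a severe-mental-illness diagnosis (ICD-10 F20-F29
#' non-organic psychotic disorders or F30-F31 bipolar disorder), a first
#' contact inside the study window leaving at least one year of follow-up
#' to the window end, and at least one HoNOS assessment. Patients with a
#' missing first-contact date are removed (follow-up cannot be computed).
#' Unparseable diagnosis codes are skipped with a warning. The filter is
#' idempotent.
#'
#' @param registry Data frame with `patient_id`, `first_contact_date`
#'   (Date or ISO-8601 string) and `diagnosis_codes` (`;`-separated ICD-10
#'   codes).
#' @param honos HoNOS assessments data frame with `patient_id`.
#' @param window Length-2 Date vector, default 2009-01-01 to 2017-12-31.
#' @return The eligible subset of `registry`, with a `follow_up_years`
#'   column added.
#' @export
filter_cohort <- function(registry, honos,
                          window = as.Date(c("2009-01-01", "2017-12-31"))) {
  fc <- as.Date(registry$first_contact_date)
  codes <- strsplit(ifelse(is.na(registry$diagnosis_codes), "",
                           registry$diagnosis_codes), ";", fixed = TRUE)
  codes <- lapply(codes, trimws)
  bad <- unique(unlist(lapply(codes, function(cc) {
    cc[nzchar(cc) & !grepl(icd10_pattern, cc)]
  })))
  if (length(bad)) {
    warning("skipping unparseable ICD-10 code(s): ",
            paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  has_smi <- vapply(codes, function(cc) {
    cc <- cc[grepl(icd10_pattern, cc)]
    any(grepl(smi_pattern, cc))
  }, logical(1))
  in_window <- !is.na(fc) & fc >= window[1L] & fc <= window[2L]
  follow_up_days <- as.numeric(window[2L] - fc)
  enough_follow_up <- !is.na(fc) & follow_up_days >= 365
  has_honos <- registry$patient_id %in% honos$patient_id
  keep <- has_smi & in_window & enough_follow_up & has_honos
  out <- registry[keep, , drop = FALSE]
  out$follow_up_years <- follow_up_days[keep] / 365.25
  rownames(out) <- NULL
  out
}

#' Lifetime dichotomization of HoNOS items
#'
#' An item flag is true when any assessment of the patient scores the item
#' at or above the threshold (default 3, the moderate-severe anchor of the
#' 0-4 scale; the cut is configurable because both 2 and 3 are used in the
#' routine-outcome literature). Lowering the threshold can only turn flags
#' on, never off.
#'
#' @param honos Data frame with `patient_id` and one column per item named
#'   as in [honos_item_names()], scores 0-4.
#' @param threshold Score at or above which an item counts, default 3.
#' @param items Which items to dichotomize, default all twelve.
#' @return Data frame `patient_id` plus one logical column per item.
#' @export
dichotomize_honos <- function(honos, threshold = 3, items = honos_item_names()) {
  missing_cols <- setdiff(items, names(honos))
  if (length(missing_cols)) {
    stop("honos lacks item column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  scores <- as.matrix(honos[, items, drop = FALSE])
  if (any(is.na(scores)) || any(scores < 0 | scores > 4)) {
    stop("HoNOS scores must be integers in 0-4", call. = FALSE)
  }
  pid <- factor(honos$patient_id, levels = unique(honos$patient_id))
  flags <- do.call(cbind, lapply(items, function(it) {
    tapply(honos[[it]] >= threshold, pid, any)
  }))
  colnames(flags) <- items
  out <- data.frame(patient_id = levels(pid), stringsAsFactors = FALSE)
  cbind(out, as.data.frame(flags, row.names = seq_len(nrow(flags))))
}

#' Comorbid psychiatric diagnosis flags
#'
#' Maps ICD-10 codes to the three comorbidity groups analysed: major
#' depressive disorder (F32-F33), post-traumatic stress disorder (F43.1)
#' and personality disorders (F60-F61). Any recorded code counts
#' (lifetime reading).
#'
#' @param diagnosis_codes Character vector, each element a `;`-separated
#'   list of ICD-10 codes for one patient.
#' @return Data frame with logical columns `mdd`, `ptsd`, `pd`.
#' @export
comorbidity_flags <- function(diagnosis_codes) {
  codes <- strsplit(ifelse(is.na(diagnosis_codes), "", diagnosis_codes),
                    ";", fixed = TRUE)
  codes <- lapply(codes, trimws)
  flag <- function(pattern) {
    vapply(codes, function(cc) any(grepl(pattern, cc)), logical(1))
  }
  data.frame(mdd = flag("^F3[23]"),
             ptsd = flag("^F43\\.1"),
             pd = flag("^F6[01]"))
}

# Union of possibly overlapping admission episodes. Episodes sharing or
# abutting days are merged; day counting is inclusive (same-day admission
# and discharge is 1 day), so splitting an episode into adjacent
# sub-episodes never changes the total.
merge_episodes <- function(start, end) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (any(is.na(start) | is.na(end))) stop("missing episode date", call. = FALSE)
  if (any(end < start)) stop("episode end precedes start", call. = FALSE)
  ord <- order(start, end)
  start <- start[ord]
  end <- end[ord]
  ms <- start[1L]
  me <- end[1L]
  out_s <- ms
  out_e <- me
  k <- 1L
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me + 1L) {
      if (end[i] > me) me <- end[i]
      out_e[k] <- me
    } else {
      k <- k + 1L
      ms <- start[i]
      me <- end[i]
      out_s[k] <- ms
      out_e[k] <- me
    }
  }
  data.frame(start = out_s, end = out_e)
}

#' Derive admission outcomes per patient
#'
#' Merges overlapping episodes, counts inpatient days inclusively
#' (admission and discharge days both count; a same-day stay is 1 day) and
#' divides by follow-up years. The above-median flag uses the median of
#' days-per-year *among admitted patients only* and is undefined (NA) for
#' patients never admitted.
#'
#' @param admissions Data frame `patient_id`, `start_date`, `end_date`.
#' @param follow_up Data frame `patient_id`, `follow_up_years`
#'   (all >= 1, as guaranteed by [filter_cohort()]).
#' @return Data frame `patient_id`, `any_admission`, `admission_days`,
#'   `days_per_year`, `above_median_days` and an attribute
#'   `median_days_per_year`.
#' @export
derive_admission_outcomes <- function(admissions, follow_up) {
  if (any(follow_up$follow_up_years < 1)) {
    stop("follow-up below one year; apply filter_cohort() first", call. = FALSE)
  }
  out <- data.frame(patient_id = follow_up$patient_id,
                    any_admission = FALSE,
                    admission_days = 0,
                    stringsAsFactors = FALSE)
  if (nrow(admissions) > 0L) {
    adm <- admissions[admissions$patient_id %in% follow_up$patient_id, , drop = FALSE]
    if (nrow(adm) > 0L) {
      days <- vapply(split(adm, adm$patient_id), function(a) {
        m <- merge_episodes(a$start_date, a$end_date)
        sum(as.numeric(m$end - m$start) + 1)
      }, numeric(1))
      hit <- match(names(days), out$patient_id)
      out$any_admission[hit] <- TRUE
      out$admission_days[hit] <- unname(days)
    }
  }
  out$days_per_year <- out$admission_days / follow_up$follow_up_years
  out$above_median_days <- NA
  if (any(out$any_admission)) {
    adm_rates <- out$days_per_year[out$any_admission]
    d <- dichotomize_at_median(adm_rates)
    out$above_median_days[out$any_admission] <- d$above
    attr(out, "median_days_per_year") <- d$median
  }
  out
}
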