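#' Cohort accounting: eligibility, removals and detected prevalence
#'
#' Reproduces the analytic-cohort flow: patients identified (severe mental
#' illness diagnosis, at least one HoNOS assessment, first contact inside
#' the study window or missing), minus those whose first-contact date is
#' missing (follow-up cannot be computed), minus those whose only abuse
#' evidence is an indeterminate "historical sexual abuse" mention. The
#' detected-CSA fraction is reported over the remaining analytic cohort.
#'
#' @param registry,honos,notes Input tables (see [generate_cohort()] for
#'   the column layout).
#' @param lexicon A `csa_lexicon`; default the shipped one.
#' @param window Study window (Dates).
#' @param childhood_cutoff Age cutoff for childhood classification.
#' @return List with the flow counts (`n_identified`,
#'   `n_missing_first_contact`, `n_removed_indeterminate`, `n_analytic`,
#'   `n_detected`, `pct_detected`), the patient-level `labels` data frame
#'   and the analytic registry (`analytic`, with `follow_up_years` and
#'   logical `csa`).
#' @export
cohort_accounting <- function(registry, honos, notes,
                              lexicon = default_lexicon(),
                              window = as.Date(c("2009-01-01", "2017-12-31")),
                              childhood_cutoff = 18) {
  fc <- as.Date(registry$first_contact_date)
  codes <- strsplit(ifelse(is.na(registry$diagnosis_codes), "",
                           registry$diagnosis_codes), ";", fixed = TRUE)
  has_smi <- vapply(codes, function(cc) any(grepl(smi_pattern, trimws(cc))),
                    logical(1))
  has_honos <- registry$patient_id %in% honos$patient_id
  fc_ok <- !is.na(fc) & fc >= window[1L] & fc <= window[2L] &
    as.numeric(window[2L] - fc) >= 365
  identified <- has_smi & has_honos & (fc_ok | is.na(fc))
  missing_fc <- identified & is.na(fc)
  eligible <- identified & fc_ok

  elig_ids <- registry$patient_id[eligible]
  spans <- scan_notes(notes[notes$patient_id %in% elig_ids, , drop = FALSE],
                      lexicon)
  labels <- classify_patients(spans, elig_ids, childhood_cutoff)
  removed <- labels$patient_id[labels$status == "removed_indeterminate"]
  analytic_ids <- setdiff(elig_ids, removed)

  analytic <- registry[registry$patient_id %in% analytic_ids, , drop = FALSE]
  analytic$follow_up_years <-
    as.numeric(window[2L] - as.Date(analytic$first_contact_date)) / 365.25
  analytic$csa <- labels$status[match(analytic$patient_id,
                                      labels$patient_id)] == "exposed"
  rownames(analytic) <- NULL

  n_detected <- sum(analytic$csa)
  list(n_identified = sum(identified),
       n_missing_first_contact = sum(missing_fc),
       n_removed_indeterminate = length(removed),
       n_analytic = length(analytic_ids),
       n_detected = n_detected,
       pct_detected = 100 * n_detected / length(analytic_ids),
       labels = labels,
       analytic = analytic,
       spans = spans)
}

#' Per-item HoNOS prevalence by exposure group
#'
#' The figure-style output: for each dichotomized item, the percentage of
#' patients flagged, separately for the unexposed and exposed groups.
#'
#' @param honos_flags Output of [dichotomize_honos()] restricted to the
#'   analytic cohort.
#' @param exposure Data frame `patient_id`, `csa` (logical).
#' @param items Items to report, default the seven analysis items.
#' @return Data frame `item`, `pct_no_csa`, `pct_csa`.
#' @export
render_prevalence_figure_data <- function(honos_flags, exposure,
                                          items = honos_analysis_items()) {
  merged <- merge(honos_flags, exposure, by = "patient_id")
  if (!sum(merged$csa) || !sum(!merged$csa)) {
    stop("empty exposure group; prevalence by group is undefined", call. = FALSE)
  }
  data.frame(
    item = items,
    pct_no_csa = vapply(items, function(it) {
      100 * mean(merged[[it]][!merged$csa])
    }, numeric(1)),
    pct_csa = vapply(items, function(it) {
      100 * mean(merged[[it]][merged$csa])
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' simulate -> detect -> doses -> features -> analyze -> report. Emits the
#' demographic, comorbidity, HoNOS-prevalence and outcomes tables as CSV
#' plus a JSON run manifest (config snapshot, seed, lexicon version, file
#' digests) and a markdown summary. Deterministic given the config seed:
#' rerunning writes byte-identical tables.
#'
#' @param config A [cohort_config()].
#' @param out_dir Report directory, created if needed.
#' @param honos_threshold Moderate-severe cut for HoNOS dichotomization.
#' @param lexicon,gazetteer Detection resources, defaulting to the shipped
#'   files.
#' @return Invisibly, a list with the analysis objects and output paths.
#' @export
run_pipeline <- function(config, out_dir, honos_threshold = 3,
                         lexicon = default_lexicon(),
                         gazetteer = default_gazetteer()) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  }

  cohort <- stage("simulate", generate_cohort(config))
  message(sprintf("simulate: %d patients, %d notes",
                  nrow(cohort$registry), nrow(cohort$notes)))

  acc <- stage("detect", cohort_accounting(cohort$registry, cohort$honos,
                                           cohort$notes, lexicon,
                                           config$study_window))
  message(sprintf(
    "detect: %d identified -> -%d missing first contact -> -%d indeterminate -> %d analytic; %d (%.1f%%) CSA",
    acc$n_identified, acc$n_missing_first_contact,
    acc$n_removed_indeterminate, acc$n_analytic, acc$n_detected,
    acc$pct_detected))

  dose_records <- stage("doses", extract_medications(cohort$notes, gazetteer))
  dosing <- summarize_dosing(dose_records, acc$analytic$patient_id)
  message(sprintf("doses: %d dose records (%d excluded > 200%% max)",
                  nrow(dose_records), sum(dose_records$excluded)))

  analytic <- acc$analytic
  honos_flags <- stage("features", dichotomize_honos(
    cohort$honos[cohort$honos$patient_id %in% analytic$patient_id, ],
    threshold = honos_threshold))
  adm <- derive_admission_outcomes(
    cohort$admissions[cohort$admissions$patient_id %in% analytic$patient_id, ],
    analytic[, c("patient_id", "follow_up_years")])
  comorb <- comorbidity_flags(analytic$diagnosis_codes)

  analysis <- stage("analyze", analyze_cohort(analytic, honos_flags, adm,
                                              dosing, comorb))

  paths <- stage("report", write_report(out_dir, config, acc, analysis,
                                        lexicon))
  message("report: ", length(paths), " files in ", out_dir)
  invisible(list(cohort = cohort, accounting = acc, dosing = dosing,
                 dose_records = dose_records, analysis = analysis,
                 paths = paths))
}

# The statistical layer applied to the assembled analytic data set.
analyze_cohort <- function(analytic, honos_flags, adm, dosing, comorb) {
  df <- analytic
  df$mdd <- comorb$mdd
  df$ptsd <- comorb$ptsd
  df$pd <- comorb$pd
  df <- merge(df, adm[, c("patient_id", "any_admission", "days_per_year",
                          "above_median_days")], by = "patient_id")
  df <- merge(df, dosing, by = "patient_id")
  if (any(!is.na(df$max_pct))) {
    dd <- dichotomize_at_median(df$max_pct)
    df$above_median_dose <- dd$above
    median_dose <- dd$median
  } else {
    df$above_median_dose <- NA
    median_dose <- NA_real_
  }

  demo_vars <- c("sex", "ethnicity", "marital", "imd_quartile")
  demographics <- do.call(rbind, lapply(demo_vars, function(v) {
    tab <- build_table(df, v, "csa")
    est <- pearson_chi_square(tab)
    data.frame(variable = v, category = rownames(tab),
               n_no_csa = tab[, "No CSA"], n_csa = tab[, "CSA"],
               pct_no_csa = 100 * tab[, "No CSA"] / sum(tab[, "No CSA"]),
               pct_csa = 100 * tab[, "CSA"] / sum(tab[, "CSA"]),
               chi_square = est$statistic, df = est$df, p_value = est$p_value,
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  comorbidity <- do.call(rbind, lapply(c("mdd", "ptsd", "pd"), function(v) {
    tab <- build_table(df, v, "csa")
    est <- pearson_chi_square(tab)
    data.frame(diagnosis = v,
               n_no_csa = tab["TRUE", "No CSA"], n_csa = tab["TRUE", "CSA"],
               pct_no_csa = 100 * tab["TRUE", "No CSA"] / sum(tab[, "No CSA"]),
               pct_csa = 100 * tab["TRUE", "CSA"] / sum(tab[, "CSA"]),
               chi_square = est$statistic, df = est$df, p_value = est$p_value,
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  prevalence <- render_prevalence_figure_data(
    honos_flags, df[, c("patient_id", "csa")])

  outcomes <- do.call(rbind, list(
    outcome_row(df, "any_admission", "Inpatient admission"),
    outcome_row(df[!is.na(df$above_median_days), ], "above_median_days",
                "Above-median inpatient days per year"),
    outcome_row(df, "any_antipsychotic", "Antipsychotic medication"),
    outcome_row(df[!is.na(df$above_median_dose), ], "above_median_dose",
                "Above-median % of maximum recommended dose")))

  list(data = df, demographics = demographics, comorbidity = comorbidity,
       honos_prevalence = prevalence, outcomes = outcomes,
       median_dose_pct = median_dose)
}

# One outcomes-table row: group percentages, unadjusted 2x2 OR and the
# covariate-adjusted logistic OR.
outcome_row <- function(df, outcome, label) {
  y <- as.logical(df[[outcome]])
  e <- df$csa
  a <- sum(!e & !y); b <- sum(!e & y); c <- sum(e & !y); d <- sum(e & y)
  unadj <- odds_ratio_2x2(a, b, c, d)
  # separation in a small or extreme cohort is reported, not hidden, and the
  # unadjusted estimate is still emitted
  adj <- tryCatch(
    fit_logistic(df, outcome, "csa",
                 covariates = c("sex", "age_at_first_presentation",
                                "ethnicity")),
    error = function(e2) {
      warning("adjusted OR unavailable for '", label, "': ",
              conditionMessage(e2), call. = FALSE)
      effect_estimate("OR", adjusted = TRUE)
    })
  data.frame(outcome = label,
             pct_no_csa = 100 * b / (a + b), pct_csa = 100 * d / (c + d),
             or = unadj$point, or_low = unadj$ci_low, or_high = unadj$ci_high,
             adj_or = adj$point, adj_or_low = adj$ci_low,
             adj_or_high = adj$ci_high,
             row.names = NULL, stringsAsFactors = FALSE)
}

write_report <- function(out_dir, config, acc, analysis, lexicon) {
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  flow <- data.frame(
    stage = c("identified", "missing_first_contact_removed",
              "indeterminate_age_removed", "analytic_cohort",
              "detected_csa"),
    n = c(acc$n_identified, acc$n_missing_first_contact,
          acc$n_removed_indeterminate, acc$n_analytic, acc$n_detected))
  put(flow, "cohort_flow.csv")
  put(analysis$demographics, "demographics.csv")
  put(analysis$comorbidity, "comorbidity.csv")
  put(analysis$honos_prevalence, "honos_prevalence.csv")
  put(analysis$outcomes, "outcomes.csv")

  manifest <- list(
    package = "csascreenr",
    version = as.character(utils::packageVersion("csascreenr")),
    created = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    lexicon_version = attr(lexicon, "version"),
    config = config_snapshot(config),
    file_md5 = as.list(stats::setNames(unname(tools::md5sum(unlist(paths))),
                                       names(paths))))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths[["manifest.json"]] <- mp

  md <- c(
    "# Synthetic cohort analysis report", "",
    sprintf("Seed %d; lexicon %s.", config$seed, attr(lexicon, "version")),
    "",
    sprintf("Cohort flow: %d identified, %d removed (missing first contact), %d removed (indeterminate age), %d analytic; %d (%.1f%%) with recorded CSA.",
            acc$n_identified, acc$n_missing_first_contact,
            acc$n_removed_indeterminate, acc$n_analytic, acc$n_detected,
            acc$pct_detected),
    "",
    "Tables: cohort_flow.csv, demographics.csv, comorbidity.csv, honos_prevalence.csv, outcomes.csv.",
    "Every numeric cell is reproducible from manifest.json alone.")
  sp <- file.path(out_dir, "summary.md")
  writeLines(md, sp)
  paths[["summary.md"]] <- sp
  paths
}

config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$study_window <- format(snap$study_window, "%Y-%m-%d")
  snap
}
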