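#' Configuration for the synthetic SMI cohort generator
#'
#' Defines the statistical structure of the generated registry, notes,
#' HoNOS assessments, admissions and diagnoses. Defaults emulate a
#' 7000-patient severe-mental-illness cohort with an 8.8% rate of recorded
#' childhood sexual abuse, demographic marginals matching a large
#' inner-London secondary-care cohort, and exposure-dependent outcome rates
#' drawn from logistic models.
#'
#' @param n_patients Number of registry rows.
#' @param csa_prevalence Probability a patient has a true recorded CSA
#'   history.
#' @param demographic_marginals Named list (`sex`, `ethnicity`, `marital`,
#'   `deprivation`) of category-probability vectors; each must sum to 1.
#' @param demographic_shifts Same shape; per-category log-odds tilts applied
#'   to CSA patients (induces the direction of the observed demographic
#'   differences: CSA more often female, White, single).
#' @param outcome_effects Per-outcome `list(baseline =, log_or =)` for the
#'   Bernoulli outcomes (inpatient admission, antipsychotic receipt);
#'   `log_or` is the exposure effect on the logit scale.
#' @param comorbidity_effects As above for the comorbid diagnoses (major
#'   depressive disorder, PTSD, personality disorder).
#' @param honos_baseline Per-item probability that a single assessment
#'   scores the item at moderate-severe level (3+).
#' @param honos_log_or Per-item exposure log-odds shift on that probability.
#' @param note_rate Mean clinical notes per patient-year.
#' @param distractor_rates Patient-level probabilities (applied to non-CSA
#'   patients) of carrying a `negated`, `uncertain`, `adult_onset` or
#'   `hearsay` abuse mention in their notes. Hearsay mentions (abuse of a
#'   relative, phrased with the same vocabulary) are the deliberate
#'   false-positive channel that keeps the chart-review audit informative.
#' @param uncertain_indeterminate_frac Fraction of `uncertain` mentions
#'   phrased as unconfirmable "historical sexual abuse" (indeterminate
#'   polarity, triggering patient removal) rather than "possible history"
#'   (exclude polarity).
#' @param positive_extra_rate Probability each additional note of a CSA
#'   patient repeats a positive mention (one positive note is guaranteed).
#' @param p_missing_first_contact Probability the first-contact date is
#'   missing, so follow-up cannot be computed and the patient is dropped by
#'   the eligibility filter.
#' @param med_params List: `p_no_dose` (mention without a parseable dose),
#'   `p_dose_error` (data-entry error placing the dose above 200% of the
#'   maximum, exercising the exclusion filter), `mean_extra_mentions`,
#'   `dose_tilt` (log-scale tilt of CSA patients toward higher grid doses).
#' @param admission_params List: `mean_extra_episodes`, `meanlog_days`,
#'   `sdlog_days` (log-normal episode length), `log_duration_shift`
#'   (multiplicative CSA effect on episode length).
#' @param mean_extra_assessments Extra HoNOS assessments per patient beyond
#'   the guaranteed one (Poisson mean).
#' @param childhood_ages,adult_ages Integer ranges the age-slot templates
#'   draw from for childhood and adult-onset mentions.
#' @param study_window Length-2 Date vector; first-contact dates are drawn
#'   so that at least one year of follow-up to the window end always holds.
#' @param include_notes Generate note text and truth labels (disable for
#'   large cohorts used only to check outcome-model recovery).
#' @param seed Integer seed; a fixed seed makes every output byte-identical.
#' @return A validated object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 7000,
                          csa_prevalence = 0.088,
                          demographic_marginals = default_demographic_marginals(),
                          demographic_shifts = default_demographic_shifts(),
                          outcome_effects = default_outcome_effects(),
                          comorbidity_effects = default_comorbidity_effects(),
                          honos_baseline = default_honos_baseline(),
                          honos_log_or = default_honos_log_or(),
                          note_rate = 0.75,
                          distractor_rates = list(negated = 0.05,
                                                  uncertain = 0.01,
                                                  adult_onset = 0.01,
                                                  hearsay = 0.002),
                          uncertain_indeterminate_frac = 0.2,
                          positive_extra_rate = 0.15,
                          p_missing_first_contact = 15 / 7030,
                          med_params = list(p_no_dose = 0.2,
                                            p_dose_error = 0.01,
                                            mean_extra_mentions = 0.8,
                                            dose_tilt = 0.4),
                          admission_params = list(mean_extra_episodes = 0.8,
                                                  meanlog_days = log(12),
                                                  sdlog_days = 0.9,
                                                  log_duration_shift = 0.3),
                          mean_extra_assessments = 1.5,
                          childhood_ages = 4:16,
                          adult_ages = 19:60,
                          study_window = as.Date(c("2009-01-01", "2017-12-31")),
                          include_notes = TRUE,
                          seed = 1L) {
  cfg <- list(n_patients = n_patients, csa_prevalence = csa_prevalence,
              demographic_marginals = demographic_marginals,
              demographic_shifts = demographic_shifts,
              outcome_effects = outcome_effects,
              comorbidity_effects = comorbidity_effects,
              honos_baseline = honos_baseline, honos_log_or = honos_log_or,
              note_rate = note_rate, distractor_rates = distractor_rates,
              uncertain_indeterminate_frac = uncertain_indeterminate_frac,
              positive_extra_rate = positive_extra_rate,
              p_missing_first_contact = p_missing_first_contact,
              med_params = med_params, admission_params = admission_params,
              mean_extra_assessments = mean_extra_assessments,
              childhood_ages = childhood_ages, adult_ages = adult_ages,
              study_window = as.Date(study_window),
              include_notes = isTRUE(include_notes),
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 1) {
    stop("n_patients must be >= 1", call. = FALSE)
  }
  probs <- c(csa_prevalence = cfg$csa_prevalence,
             p_missing_first_contact = cfg$p_missing_first_contact,
             positive_extra_rate = cfg$positive_extra_rate,
             uncertain_indeterminate_frac = cfg$uncertain_indeterminate_frac,
             unlist(cfg$distractor_rates),
             p_no_dose = cfg$med_params$p_no_dose,
             p_dose_error = cfg$med_params$p_dose_error)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop("probability out of [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  }
  for (nm in c("sex", "ethnicity", "marital", "deprivation")) {
    m <- cfg$demographic_marginals[[nm]]
    if (is.null(m) || !length(m)) {
      stop("empty demographic marginal: ", nm, call. = FALSE)
    }
    if (any(m < 0) || abs(sum(m) - 1) > 1e-9) {
      stop("marginal '", nm, "' must be non-negative and sum to 1", call. = FALSE)
    }
  }
  for (eff in c(cfg$outcome_effects, cfg$comorbidity_effects)) {
    if (eff$baseline < 0 || eff$baseline > 1) {
      stop("outcome baseline out of [0, 1]", call. = FALSE)
    }
  }
  if (any(cfg$honos_baseline < 0 | cfg$honos_baseline > 1)) {
    stop("HoNOS baseline probabilities out of [0, 1]", call. = FALSE)
  }
  if (diff(as.numeric(cfg$study_window)) < 365) {
    stop("study window shorter than one year", call. = FALSE)
  }
  invisible(cfg)
}

# Whole-cohort demographic marginals of the emulated 7000-patient cohort.
default_demographic_marginals <- function() {
  list(
    sex = c(M = 3833, F = 3167) / 7000,
    ethnicity = c(White = 3873, Black = 1526, Asian = 510, Mixed = 300,
                  Other = 487, Unknown = 304) / 7000,
    marital = c(Single = 4720, Married = 790, Divorced = 738, Widowed = 197,
                Unknown = 555) / 7000,
    deprivation = c(Q1 = 1040, Q2 = 1563, Q3 = 1892, Q4 = 1912,
                    Unknown = 593) / 7000
  )
}

# Log-odds tilts applied to CSA patients; directions follow the observed
# group differences (CSA more often female, White or Mixed, single, and
# slightly more deprived), magnitudes chosen to land near the observed
# group-specific percentages.
default_demographic_shifts <- function() {
  list(
    sex = c(M = 0, F = 0.83),
    ethnicity = c(White = 0.5, Black = -0.3, Asian = -0.65, Mixed = 0.55,
                  Other = -0.7, Unknown = -1.0),
    marital = c(Single = 0.5, Married = -0.4, Divorced = -0.1,
                Widowed = -0.8, Unknown = -0.6),
    deprivation = c(Q1 = -0.1, Q2 = 0, Q3 = 0, Q4 = 0.1, Unknown = -0.5)
  )
}

# Baseline rate in the unexposed group and exposure log-odds-ratio for the
# Bernoulli clinical outcomes.
default_outcome_effects <- function() {
  list(admission = list(baseline = 0.511, log_or = 0.67),
       antipsychotic = list(baseline = 0.895, log_or = 0.91))
}

default_comorbidity_effects <- function() {
  list(mdd = list(baseline = 0.076, log_or = 0.63, code = "F33.1"),
       ptsd = list(baseline = 0.014, log_or = 1.24, code = "F43.1"),
       pd = list(baseline = 0.058, log_or = 1.52, code = "F60.3"))
}

# Per-assessment probability of a moderate-severe (3+) item score.
default_honos_baseline <- function() {
  stats::setNames(
    c(0.12, 0.08, 0.15, 0.08, 0.08, 0.25, 0.15, 0.10, 0.25, 0.10, 0.12, 0.12),
    honos_item_names())
}

# Exposure shift on the same logit scale; the seven analysis items move,
# the rest do not.
default_honos_log_or <- function() {
  lo <- stats::setNames(rep(0, 12L), honos_item_names())
  lo[honos_analysis_items()] <- 0.55
  lo
}

#' Read a cohort configuration from YAML
#'
#' Any field of [cohort_config()] may be overridden; omitted fields keep
#' their defaults. `study_window` is given as ISO-8601 dates.
#'
#' @param path YAML file path.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in c("demographic_marginals", "demographic_shifts",
               "honos_baseline", "honos_log_or")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- rapply(raw[[nm]], unlist, how = "replace")
  }
  do.call(cohort_config, raw)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic SMI cohort configuration\n")
  cat(sprintf("  patients: %d, CSA prevalence: %.3f, seed: %d\n",
              x$n_patients, x$csa_prevalence, x$seed))
  cat(sprintf("  study window: %s to %s, notes/patient-year: %.2f\n",
              x$study_window[1], x$study_window[2], x$note_rate))
  dr <- x$distractor_rates
  cat(sprintf("  distractors (negated/uncertain/adult/hearsay): %.3f/%.3f/%.3f/%.3f\n",
              dr$negated, dr$uncertain, dr$adult_onset, dr$hearsay))
  invisible(x)
}
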