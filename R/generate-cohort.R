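#' Generate a synthetic SMI cohort
#'
#' Draws a complete synthetic data set — registry, free-text notes, HoNOS
#' assessments, admission episodes, diagnosis table and per-note ground
#' truth — with the statistical structure set by a [cohort_config()].
#' Output is deterministic for a fixed seed.
#'
#' Every patient gets at least one HoNOS assessment and a first-contact
#' date (when not deliberately missing) leaving at least one year of
#' follow-up to the study-window end, so the downstream eligibility filter
#' is exercisable but non-destructive by default. Binary clinical outcomes
#' (admission, antipsychotic receipt) and comorbid diagnoses are Bernoulli
#' draws from logistic models with the configured exposure log-odds-ratios,
#' which makes parameter recovery testable by refitting.
#'
#' @param config A `cohort_config`.
#' @return A list of class `synthetic_cohort` with data frames `registry`,
#'   `notes`, `honos`, `admissions`, `diagnoses`, `truth` and the `config`
#'   used.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- as.integer(config$n_patients)
  window <- config$study_window
  patient_id <- sprintf("P%05d", seq_len(n))
  true_csa <- stats::rbinom(n, 1L, config$csa_prevalence) == 1L

  registry <- data.frame(patient_id = patient_id, stringsAsFactors = FALSE)
  registry$sex <- sample_demographic(true_csa, config, "sex")
  registry$ethnicity <- sample_demographic(true_csa, config, "ethnicity")
  registry$marital <- sample_demographic(true_csa, config, "marital")
  registry$imd_quartile <- sample_demographic(true_csa, config, "deprivation")
  registry$age_at_first_presentation <-
    pmin(90, pmax(16, round(stats::rnorm(n, 40, 13))))

  # uniform over dates leaving >= 1 year of follow-up; a configured
  # fraction is missing and will drop out of the analytic cohort
  last_start <- window[2L] - 366L
  fc <- window[1L] + floor(stats::runif(n) * (as.numeric(last_start - window[1L]) + 1))
  fc[stats::runif(n) < config$p_missing_first_contact] <- NA
  registry$first_contact_date <- fc
  follow_days <- as.numeric(window[2L] - fc)
  follow_years <- follow_days / 365.25
  mean_fy <- mean(follow_years, na.rm = TRUE)
  fy_filled <- ifelse(is.na(follow_years), mean_fy, follow_years)

  diagnoses <- draw_diagnoses(patient_id, true_csa, config)
  registry$diagnosis_codes <- vapply(
    split(diagnoses$code, factor(diagnoses$patient_id, levels = patient_id)),
    paste, character(1), collapse = ";")

  honos <- draw_honos(patient_id, true_csa, fc, window, config)

  eff <- config$outcome_effects
  any_admission <- stats::rbinom(n, 1L,
    stats::plogis(stats::qlogis(eff$admission$baseline) +
                    eff$admission$log_or * true_csa)) == 1L
  any_antipsychotic <- stats::rbinom(n, 1L,
    stats::plogis(stats::qlogis(eff$antipsychotic$baseline) +
                    eff$antipsychotic$log_or * true_csa)) == 1L
  admissions <- draw_admissions(patient_id, true_csa, any_admission,
                                fc, window, config)

  if (config$include_notes) {
    nt <- draw_notes(patient_id, true_csa, any_antipsychotic, fc, window,
                     fy_filled, config)
    notes <- nt$notes
    truth <- nt$truth
  } else {
    notes <- data.frame(note_id = character(0), patient_id = character(0),
                        date = as.Date(character(0)), text = character(0),
                        stringsAsFactors = FALSE)
    truth <- data.frame(note_id = character(0), patient_id = character(0),
                        true_csa = logical(0), label = character(0),
                        stringsAsFactors = FALSE)
  }

  outcomes_truth <- data.frame(patient_id = patient_id, true_csa = true_csa,
                               any_admission = any_admission,
                               any_antipsychotic = any_antipsychotic,
                               stringsAsFactors = FALSE)

  structure(list(registry = registry, notes = notes, honos = honos,
                 admissions = admissions, diagnoses = diagnoses,
                 truth = truth, outcomes_truth = outcomes_truth,
                 config = config),
            class = "synthetic_cohort")
}

# Category sampling with CSA log-odds tilts applied on top of the marginal.
sample_demographic <- function(true_csa, config, var) {
  m <- config$demographic_marginals[[var]]
  shift <- config$demographic_shifts[[var]]
  shift <- shift[names(m)]
  shift[is.na(shift)] <- 0
  tilted <- m * exp(shift)
  tilted <- tilted / sum(tilted)
  out <- character(length(true_csa))
  n0 <- sum(!true_csa)
  n1 <- sum(true_csa)
  if (n0) out[!true_csa] <- sample(names(m), n0, TRUE, m)
  if (n1) out[true_csa] <- sample(names(m), n1, TRUE, tilted)
  out
}

smi_codes <- c("F20.0", "F20.3", "F22", "F25.0", "F25.1", "F29",
               "F31.1", "F31.3", "F31.8")
smi_code_probs <- c(0.28, 0.07, 0.06, 0.10, 0.05, 0.14, 0.12, 0.12, 0.06)

draw_diagnoses <- function(patient_id, true_csa, config) {
  n <- length(patient_id)
  rows <- list(data.frame(patient_id = patient_id,
                          code = sample(smi_codes, n, TRUE, smi_code_probs),
                          stringsAsFactors = FALSE))
  for (eff in config$comorbidity_effects) {
    p <- stats::plogis(stats::qlogis(eff$baseline) + eff$log_or * true_csa)
    hit <- stats::rbinom(n, 1L, p) == 1L
    if (any(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(patient_id = patient_id[hit],
                                              code = eff$code,
                                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(match(out$patient_id, patient_id)), , drop = FALSE]
}

draw_honos <- function(patient_id, true_csa, fc, window, config) {
  n <- length(patient_id)
  k <- 1L + stats::rpois(n, config$mean_extra_assessments)
  pid <- rep(patient_id, k)
  csa <- rep(true_csa, k)
  start <- rep(ifelse(is.na(fc), window[1L], fc), k)
  date <- as.Date(start + floor(stats::runif(sum(k)) *
                                  (as.numeric(window[2L]) - start + 1)),
                  origin = "1970-01-01")
  m <- sum(k)
  items <- matrix(0L, nrow = m, ncol = 12L,
                  dimnames = list(NULL, honos_item_names()))
  for (j in seq_len(12L)) {
    base <- config$honos_baseline[j]
    p <- stats::plogis(stats::qlogis(base) + config$honos_log_or[j] * csa)
    severe <- stats::rbinom(m, 1L, p) == 1L
    score <- integer(m)
    score[severe] <- sample(3:4, sum(severe), TRUE, c(0.75, 0.25))
    score[!severe] <- sample(0:2, sum(!severe), TRUE, c(0.45, 0.35, 0.20))
    items[, j] <- score
  }
  cbind(data.frame(patient_id = pid, date = date, stringsAsFactors = FALSE),
        as.data.frame(items))
}

draw_admissions <- function(patient_id, true_csa, any_admission,
                            fc, window, config) {
  ap <- config$admission_params
  idx <- which(any_admission)
  if (!length(idx)) {
    return(data.frame(patient_id = character(0),
                      start_date = as.Date(character(0)),
                      end_date = as.Date(character(0)),
                      stringsAsFactors = FALSE))
  }
  k <- 1L + stats::rpois(length(idx), ap$mean_extra_episodes)
  pid <- rep(patient_id[idx], k)
  csa <- rep(true_csa[idx], k)
  ep_start0 <- rep(ifelse(is.na(fc[idx]), window[1L], fc[idx]), k)
  m <- sum(k)
  span <- as.numeric(window[2L]) - ep_start0 - 30
  start <- as.Date(ep_start0 + floor(stats::runif(m) * pmax(span, 1)),
                   origin = "1970-01-01")
  len <- pmax(1, round(stats::rlnorm(m, ap$meanlog_days, ap$sdlog_days) *
                         exp(ap$log_duration_shift * csa)))
  end <- pmin(start + len - 1L, window[2L])
  data.frame(patient_id = pid, start_date = start, end_date = end,
             stringsAsFactors = FALSE)
}

draw_notes <- function(patient_id, true_csa, any_antipsychotic, fc, window,
                       fy_filled, config) {
  n <- length(patient_id)
  templates <- note_templates()
  gaz <- default_gazetteer()
  strengths <- attr(gaz, "strengths")
  generics <- names(strengths)

  n_notes <- pmax(1L, stats::rpois(n, config$note_rate * fy_filled))

  # patient-level distractor draws (non-CSA patients only)
  dr <- config$distractor_rates
  has_negated <- !true_csa & stats::runif(n) < dr$negated
  has_uncertain <- !true_csa & stats::runif(n) < dr$uncertain
  uncertain_indet <- has_uncertain &
    stats::runif(n) < config$uncertain_indeterminate_frac
  has_adult <- !true_csa & stats::runif(n) < dr$adult_onset
  has_hearsay <- !true_csa & stats::runif(n) < dr$hearsay
  n_distract <- has_negated + has_uncertain + has_adult + has_hearsay
  n_notes <- pmax(n_notes, n_distract, true_csa * 1L)

  note_pid_idx <- rep(seq_len(n), n_notes)
  m <- sum(n_notes)
  note_id <- sprintf("N%07d", seq_len(m))
  start0 <- rep(ifelse(is.na(fc), window[1L], fc), n_notes)
  date <- as.Date(start0 + floor(stats::runif(m) *
                                   (as.numeric(window[2L]) - start0 + 1)),
                  origin = "1970-01-01")

  label <- rep("none", m)
  ages <- rep(NA_integer_, m)
  indet <- rep(FALSE, m)
  first_note <- match(seq_len(n), note_pid_idx)

  # CSA patients: one guaranteed positive note, extras at the repeat rate
  for (i in which(true_csa)) {
    slots <- which(note_pid_idx == i)
    main <- slots[sample.int(length(slots), 1L)]
    label[main] <- "positive"
    rest <- setdiff(slots, main)
    if (length(rest)) {
      extra <- rest[stats::runif(length(rest)) < config$positive_extra_rate]
      label[extra] <- "positive"
    }
  }
  pos <- which(label == "positive")
  with_age <- pos[stats::runif(length(pos)) < 0.4]
  ages[with_age] <- sample(config$childhood_ages, length(with_age), TRUE)

  # distractors: one note per triggered type, distinct notes per patient
  distract_idx <- which(n_distract > 0L)
  for (i in distract_idx) {
    slots <- which(note_pid_idx == i)
    types <- c(if (has_negated[i]) "negated",
               if (has_uncertain[i]) "uncertain",
               if (has_adult[i]) "adult_onset",
               if (has_hearsay[i]) "hearsay")
    chosen <- slots[sample.int(length(slots), length(types))]
    label[chosen] <- types
    indet[chosen[types == "uncertain"]] <- uncertain_indet[i]
  }
  adult <- which(label == "adult_onset")
  ages[adult] <- sample(config$adult_ages, length(adult), TRUE)

  # medication sentences for antipsychotic patients
  med_sent <- rep(NA_character_, m)
  mp <- config$med_params
  for (i in which(any_antipsychotic)) {
    slots <- which(note_pid_idx == i)
    n_ment <- 1L + stats::rpois(1L, mp$mean_extra_mentions)
    target <- slots[sample.int(length(slots), min(n_ment, length(slots)),
                               replace = FALSE)]
    for (s in target) {
      g <- generics[sample.int(length(generics), 1L)]
      grid <- strengths[[g]]
      dosed <- stats::runif(1) >= mp$p_no_dose
      if (!dosed) {
        med_sent[s] <- med_sentence(g, NA, NA, FALSE, templates)
        next
      }
      freq <- sample(c("od", "bd", "tds"), 1L, prob = c(0.45, 0.40, 0.15))
      mult <- unname(freq_multipliers[freq])
      # plausible prescriptions stay at or below 150% of the daily maximum;
      # only injected data-entry errors cross the 200% exclusion cut
      max_mg <- gaz$max_daily_mg[match(g, gaz$name)]
      ok <- grid[grid * mult <= 1.5 * max_mg]
      if (!length(ok)) ok <- grid[1L]
      w <- exp(mp$dose_tilt * true_csa[i] * seq_along(ok))
      amount <- ok[sample.int(length(ok), 1L, prob = w / sum(w))]
      if (stats::runif(1) < mp$p_dose_error) {
        # data-entry error: amount lands far above the daily maximum
        amount <- max_mg * sample(c(3, 5, 10), 1L)
      }
      med_sent[s] <- med_sentence(g, amount, freq, TRUE, templates)
    }
  }

  text <- character(m)
  for (s in seq_len(m)) {
    text[s] <- generate_note_text(
      label = label[s],
      age = if (!is.na(ages[s])) ages[s] else NULL,
      indeterminate = indet[s],
      med_sentence = if (!is.na(med_sent[s])) med_sent[s] else NULL,
      templates = templates)
  }

  notes <- data.frame(note_id = note_id,
                      patient_id = patient_id[note_pid_idx],
                      date = date, text = text, stringsAsFactors = FALSE)
  truth <- data.frame(note_id = note_id,
                      patient_id = patient_id[note_pid_idx],
                      true_csa = true_csa[note_pid_idx],
                      label = label, stringsAsFactors = FALSE)
  list(notes = notes, truth = truth)
}

#' Write a synthetic cohort to disk
#'
#' Registry, HoNOS, admissions, diagnoses and truth as CSV with ISO-8601
#' dates; notes as JSON-lines with fields `note_id`, `patient_id`, `date`,
#' `text`. Output is byte-identical across runs with the same config.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(registry = file.path(dir, "registry.csv"),
             honos = file.path(dir, "honos.csv"),
             admissions = file.path(dir, "admissions.csv"),
             diagnoses = file.path(dir, "diagnoses.csv"),
             truth = file.path(dir, "truth.csv"),
             notes = file.path(dir, "notes.jsonl"))
  for (nm in c("registry", "honos", "admissions", "diagnoses", "truth")) {
    df <- cohort[[nm]]
    for (cl in names(df)) if (inherits(df[[cl]], "Date")) {
      df[[cl]] <- format(df[[cl]], "%Y-%m-%d")
    }
    utils::write.csv(df, paths[[nm]], row.names = FALSE)
  }
  con <- file(paths[["notes"]], open = "wb")
  on.exit(close(con))
  nt <- cohort$notes
  lines <- vapply(seq_len(nrow(nt)), function(i) {
    jsonlite::toJSON(list(note_id = nt$note_id[i],
                          patient_id = nt$patient_id[i],
                          date = format(nt$date[i], "%Y-%m-%d"),
                          text = nt$text[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, con)
  invisible(paths)
}

#' Read a notes JSON-lines file
#' @param path Path to a `notes.jsonl` written by [write_cohort()].
#' @return Data frame `note_id`, `patient_id`, `date`, `text`.
#' @export
read_notes <- function(path) {
  out <- jsonlite::stream_in(file(path), verbose = FALSE)
  out$date <- as.Date(out$date)
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic SMI cohort\n")
  cat(sprintf("  %d patients (%d true CSA), %d notes, %d HoNOS rows, %d admission episodes\n",
              nrow(x$registry), sum(x$outcomes_truth$true_csa),
              nrow(x$notes), nrow(x$honos), nrow(x$admissions)))
  invisible(x)
}
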