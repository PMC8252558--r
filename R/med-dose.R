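#' Read an antipsychotic gazetteer
#'
#' YAML file with a `drugs:` list of `{generic, synonyms[], max_daily_mg}`
#' entries (an optional `strengths_mg` grid is used by the synthetic
#' generator). Names must be unique across the whole gazetteer and every
#' maximum dose positive.
#'
#' @param path Path to the YAML file.
#' @return Data frame of class `drug_gazetteer`: one row per name (generic
#'   or synonym) with its `generic_name` and `max_daily_mg`.
#' @export
read_gazetteer <- function(path) {
  if (!file.exists(path)) stop("gazetteer file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$drugs) || !length(raw$drugs)) {
    stop("gazetteer has no `drugs` entries", call. = FALSE)
  }
  rows <- lapply(raw$drugs, function(d) {
    if (is.null(d$generic) || is.null(d$max_daily_mg)) {
      stop("gazetteer entry lacks generic or max_daily_mg", call. = FALSE)
    }
    if (d$max_daily_mg <= 0) {
      stop("max_daily_mg must be positive for ", d$generic, call. = FALSE)
    }
    names <- tolower(c(d$generic, unlist(d$synonyms)))
    data.frame(name = names,
               generic_name = tolower(d$generic),
               max_daily_mg = as.numeric(d$max_daily_mg),
               stringsAsFactors = FALSE)
  })
  gaz <- do.call(rbind, rows)
  if (anyDuplicated(gaz$name)) {
    stop("duplicate drug name(s) in gazetteer: ",
         paste(unique(gaz$name[duplicated(gaz$name)]), collapse = ", "),
         call. = FALSE)
  }
  attr(gaz, "strengths") <- lapply(
    stats::setNames(raw$drugs, vapply(raw$drugs, function(d) tolower(d$generic), "")),
    function(d) as.numeric(unlist(d$strengths_mg)))
  class(gaz) <- c("drug_gazetteer", "data.frame")
  gaz
}

#' Default shipped antipsychotic gazetteer
#' @return A `drug_gazetteer` data frame.
#' @export
default_gazetteer <- function() {
  read_gazetteer(system.file("extdata", "antipsychotics.yml", package = "csascreenr"))
}

# frequency token -> administrations per day
freq_multipliers <- c(od = 1, mane = 1, nocte = 1, bd = 2, tds = 3, qds = 4)

#' Extract antipsychotic mentions and doses from one note
#'
#' Case-insensitive gazetteer lookup within sentences; a dose is parsed from
#' `"<number> mg"` in the same sentence, optionally followed by a frequency
#' token (`od`/`bd`/`tds`/`qds` giving 1/2/3/4 administrations per day;
#' unstated frequency defaults to once daily). The daily dose is the
#' per-administration dose times the frequency multiplier. A mention with no
#' parseable dose still counts as antipsychotic-receipt evidence but yields
#' no dose percentage.
#'
#' @param text Note text.
#' @param gazetteer A `drug_gazetteer`.
#' @param note_id,patient_id Identifiers copied into the result.
#' @return Data frame with columns `patient_id`, `note_id`, `generic_name`,
#'   `daily_dose_mg` (NA when absent), `pct_max` (NA when no dose) and
#'   `excluded` (`pct_max > 200`, the data-quality cut).
#' @examples
#' gaz <- default_gazetteer()
#' extract_medication_mentions("started olanzapine 10 mg bd", gaz)
#' @export
extract_medication_mentions <- function(text, gazetteer,
                                        note_id = NA_character_,
                                        patient_id = NA_character_) {
  stopifnot(inherits(gazetteer, "drug_gazetteer"))
  norm <- normalize_texts(text)
  sentences <- strsplit(norm, "[.!?;\n]+")[[1L]]
  recs <- lapply(sentences, parse_med_sentence, gazetteer = gazetteer)
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) {
    return(data.frame(patient_id = character(0), note_id = character(0),
                      generic_name = character(0), daily_dose_mg = numeric(0),
                      pct_max = numeric(0), excluded = logical(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  out$pct_max <- ifelse(is.na(out$daily_dose_mg), NA_real_,
                        compute_pct_max(out$daily_dose_mg, out$max_daily_mg))
  out$excluded <- !is.na(out$pct_max) & out$pct_max > 200
  data.frame(patient_id = patient_id, note_id = note_id,
             generic_name = out$generic_name,
             daily_dose_mg = out$daily_dose_mg,
             pct_max = out$pct_max, excluded = out$excluded,
             stringsAsFactors = FALSE)
}

# One sentence -> zero or more (drug, daily dose) rows. Each dose number is
# assigned to the nearest drug mention on its left; dose-less drugs are kept.
parse_med_sentence <- function(sentence, gazetteer) {
  drug_re <- paste0("(?<![a-z0-9])(",
                    paste(escape_regex(gazetteer$name), collapse = "|"),
                    ")(?![a-z0-9])")
  dm <- gregexpr(drug_re, sentence, perl = TRUE)[[1L]]
  if (dm[1L] == -1L) return(NULL)
  d_start <- as.integer(dm)
  d_name <- substring(sentence, d_start, d_start + attr(dm, "match.length") - 1L)
  generic <- gazetteer$generic_name[match(d_name, gazetteer$name)]
  max_mg <- gazetteer$max_daily_mg[match(d_name, gazetteer$name)]

  dose_re <- "([0-9]+(?:\\.[0-9]+)?) ?mg(?![a-z0-9])( ?(od|bd|tds|qds|mane|nocte)(?![a-z0-9]))?"
  gm <- gregexpr(dose_re, sentence, perl = TRUE)[[1L]]
  daily <- rep(NA_real_, length(d_start))
  if (gm[1L] != -1L) {
    cs <- attr(gm, "capture.start")
    cl <- attr(gm, "capture.length")
    for (j in seq_along(as.integer(gm))) {
      amount <- as.numeric(substring(sentence, cs[j, 1L], cs[j, 1L] + cl[j, 1L] - 1L))
      freq <- 1
      if (cl[j, 3L] > 0L) {
        tok <- substring(sentence, cs[j, 3L], cs[j, 3L] + cl[j, 3L] - 1L)
        freq <- unname(freq_multipliers[tok])
      }
      owner <- which(d_start < as.integer(gm)[j])
      if (length(owner)) {
        owner <- owner[length(owner)]
        if (is.na(daily[owner])) daily[owner] <- amount * freq
      }
    }
  }
  data.frame(generic_name = generic, daily_dose_mg = daily,
             max_daily_mg = max_mg, stringsAsFactors = FALSE)
}

#' Extract medication mentions across a notes table
#'
#' @param notes Data frame with `note_id`, `patient_id`, `text`.
#' @inheritParams extract_medication_mentions
#' @return Row-bound dose records (see [extract_medication_mentions()]).
#' @export
extract_medications <- function(notes, gazetteer) {
  stopifnot(inherits(gazetteer, "drug_gazetteer"))
  # cheap prefilter: only notes naming a drug get sentence-level parsing
  any_drug <- grepl(paste(escape_regex(gazetteer$name), collapse = "|"),
                    tolower(notes$text), perl = TRUE)
  idx <- which(any_drug)
  recs <- lapply(idx, function(i) {
    extract_medication_mentions(notes$text[i], gazetteer,
                                note_id = notes$note_id[i],
                                patient_id = notes$patient_id[i])
  })
  recs <- recs[vapply(recs, nrow, integer(1)) > 0L]
  if (!length(recs)) {
    return(extract_medication_mentions("", gazetteer)[0L, ])
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Percentage of the maximum recommended daily dose
#'
#' @param daily_dose_mg,max_daily_dose_mg Positive quantities in mg.
#' @return `100 * daily_dose_mg / max_daily_dose_mg`. Values above 200 are
#'   treated as data-entry or parsing errors downstream and excluded from
#'   per-patient maxima.
#' @export
compute_pct_max <- function(daily_dose_mg, max_daily_dose_mg) {
  if (any(!is.na(daily_dose_mg) & daily_dose_mg <= 0) ||
      any(!is.na(max_daily_dose_mg) & max_daily_dose_mg <= 0)) {
    stop("doses must be positive", call. = FALSE)
  }
  100 * daily_dose_mg / max_daily_dose_mg
}

#' Summarize a patient's antipsychotic dosing
#'
#' The analysis quantity is the highest percentage of the maximum
#' recommended daily dose seen for the patient, after dropping records
#' above the 200% data-quality cut. Any mention at all (dosed or not)
#' establishes antipsychotic receipt.
#'
#' @param records Dose records for one patient.
#' @return List with `any_antipsychotic`, `max_pct` (NA when no usable
#'   dosed record exists).
#' @export
summarize_patient_dosing <- function(records) {
  if (nrow(records) > 0L && length(unique(records$patient_id)) > 1L) {
    stop("records span multiple patients", call. = FALSE)
  }
  usable <- records$pct_max[!records$excluded & !is.na(records$pct_max)]
  list(any_antipsychotic = nrow(records) > 0L,
       max_pct = if (length(usable)) max(usable) else NA_real_)
}

#' Summarize dosing for every patient in a cohort
#'
#' @param records Corpus-level dose records ([extract_medications()]).
#' @param patient_ids All cohort patient ids.
#' @return Data frame `patient_id`, `any_antipsychotic`, `max_pct`.
#' @export
summarize_dosing <- function(records, patient_ids) {
  out <- data.frame(patient_id = patient_ids,
                    any_antipsychotic = FALSE,
                    max_pct = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(records) > 0L) {
    out$any_antipsychotic <- patient_ids %in% records$patient_id
    usable <- records[!records$excluded & !is.na(records$pct_max), ]
    if (nrow(usable) > 0L) {
      mx <- tapply(usable$pct_max, usable$patient_id, max)
      out$max_pct <- unname(mx[match(patient_ids, names(mx))])
    }
  }
  out
}

#' Dichotomize values at the cohort median
#'
#' The median is the empirical 50th percentile (average of the middle pair
#' for even n). "Above" is strict: ties with the median sit in the lower
#' stratum, so e.g. a cohort where every value equals the median has no one
#' above it.
#'
#' @param values Numeric vector (NAs are dropped for the median and yield
#'   NA flags).
#' @return List with `median` and `above` (logical, same length as input).
#' @export
dichotomize_at_median <- function(values) {
  usable <- values[!is.na(values)]
  if (!length(usable)) stop("no non-missing values to dichotomize", call. = FALSE)
  med <- stats::median(usable)
  list(median = med, above = values > med)
}
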