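#' Classify a patient's exposure status from lexicon matches
#'
#' A patient is `exposed` if at least one surviving include match is
#' childhood evidence: its extracted ages, if any, are all below the
#' childhood cutoff. An include match carrying any age at or above the
#' cutoff describes adult abuse and is demoted to non-evidence. A patient
#' with no childhood evidence but at least one indeterminate match (a
#' "historical sexual abuse" mention whose age cannot be confirmed) is
#' `removed_indeterminate` and is dropped from the analytic cohort
#' downstream. Everyone else is `unexposed`.
#'
#' @param spans Matches for one patient, as returned by [scan_note()] /
#'   [scan_notes()].
#' @param childhood_cutoff Age (years) below which abuse counts as
#'   childhood. Default 18, the convention of the trauma literature.
#' @return A list with `status` (one of `"exposed"`, `"unexposed"`,
#'   `"removed_indeterminate"`) and `evidence` (the childhood-evidence
#'   rows of `spans`, empty unless exposed).
#' @export
classify_patient <- function(spans, childhood_cutoff = 18) {
  ev <- childhood_evidence(spans, childhood_cutoff)
  status <- if (any(ev)) {
    "exposed"
  } else if (nrow(spans) > 0L && any(spans$polarity == "indeterminate")) {
    "removed_indeterminate"
  } else {
    "unexposed"
  }
  list(status = status, evidence = spans[ev, , drop = FALSE])
}

#' Classify every patient in a cohort
#'
#' @param spans Corpus-level matches from [scan_notes()] (must carry
#'   `patient_id`).
#' @param patient_ids Character vector of all patient ids in the cohort;
#'   patients with no matches are labelled `unexposed`.
#' @inheritParams classify_patient
#' @return Data frame `patient_id`, `status`.
#' @export
classify_patients <- function(spans, patient_ids, childhood_cutoff = 18) {
  status <- rep("unexposed", length(patient_ids))
  names(status) <- patient_ids
  if (nrow(spans) > 0L) {
    unknown <- setdiff(unique(spans$patient_id), patient_ids)
    if (length(unknown)) {
      stop("spans reference patient ids absent from `patient_ids`: ",
           paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
    }
    ev <- childhood_evidence(spans, childhood_cutoff)
    exposed <- unique(spans$patient_id[ev])
    indet <- unique(spans$patient_id[spans$polarity == "indeterminate"])
    status[indet] <- "removed_indeterminate"
    status[exposed] <- "exposed"
  }
  data.frame(patient_id = patient_ids, status = unname(status),
             stringsAsFactors = FALSE)
}

# An include span whose ages (if any) are all < cutoff.
childhood_evidence <- function(spans, childhood_cutoff) {
  if (nrow(spans) == 0L) return(logical(0))
  spans$polarity == "include" &
    vapply(spans$ages, function(a) length(a) == 0L || all(a < childhood_cutoff),
           logical(1))
}

#' Note-level detector flags
#'
#' A note is flagged as a positive instance when it contains at least one
#' surviving include match that is childhood evidence (no extracted age at
#' or above the cutoff). These are the notes a chart-review audit samples
#' from.
#'
#' @inheritParams classify_patients
#' @return Character vector of flagged `note_id`s.
#' @export
flag_notes <- function(spans, childhood_cutoff = 18) {
  unique(spans$note_id[childhood_evidence(spans, childhood_cutoff)])
}

#' Positive-predictive-value audit of flagged notes
#'
#' Emulates a manual chart review: samples flagged notes uniformly without
#' replacement and computes the fraction whose ground-truth label is a
#' genuine childhood-abuse mention, with an exact Clopper-Pearson 95%
#' binomial confidence interval.
#'
#' @param flagged_note_ids Note ids flagged by the detector ([flag_notes()]).
#' @param truth Data frame with columns `note_id`, `label`; a note counts as
#'   a true positive when `label == "positive"`.
#' @param sample_size Number of notes to review (default 100).
#' @param seed Optional integer seed for the sampling.
#' @return List with `ppv`, `ci_low`, `ci_high`, `n_sampled`, `n_true`.
#' @export
ppv_audit <- function(flagged_note_ids, truth, sample_size = 100, seed = NULL) {
  n_flagged <- length(flagged_note_ids)
  if (n_flagged == 0L) {
    stop("no flagged notes to audit", call. = FALSE)
  }
  if (sample_size > n_flagged) {
    stop("sample_size (", sample_size, ") exceeds number of flagged notes (",
         n_flagged, ")", call. = FALSE)
  }
  if (!all(c("note_id", "label") %in% names(truth))) {
    stop("`truth` needs columns note_id, label", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sampled <- sample(flagged_note_ids, sample_size, replace = FALSE)
  labels <- truth$label[match(sampled, truth$note_id)]
  if (anyNA(labels)) {
    stop("sampled note(s) missing from `truth`", call. = FALSE)
  }
  x <- sum(labels == "positive")
  n <- sample_size
  ci_low <- if (x == 0L) 0 else stats::qbeta(0.025, x, n - x + 1)
  ci_high <- if (x == n) 1 else stats::qbeta(0.975, x + 1, n - x)
  list(ppv = x / n, ci_low = ci_low, ci_high = ci_high,
       n_sampled = n, n_true = x)
}
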