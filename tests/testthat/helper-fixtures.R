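# Fixtures are built in code at test time. The shared mid-size synthetic
# cohort is generated once per test run and reused across files.

.fixtures <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    cfg <- cohort_config(n_patients = 1500, seed = 424)
    .fixtures$cohort <- generate_cohort(cfg)
    .fixtures$spans <- scan_notes(.fixtures$cohort$notes, default_lexicon())
  }
  list(cohort = .fixtures$cohort, spans = .fixtures$spans,
       config = .fixtures$cohort$config)
}

# Deterministic registry reproducing the analytic-cohort flow: 7030
# patients identified, 15 with a missing first-contact date, 15 whose only
# mention is indeterminate "historical sexual abuse", 619 with a positive
# mention among the remaining 7000.
flow_fixture <- function() {
  n <- 7030L
  ids <- sprintf("F%05d", seq_len(n))
  registry <- data.frame(
    patient_id = ids,
    sex = rep(c("M", "F"), length.out = n),
    ethnicity = "White",
    marital = "Single",
    imd_quartile = "Q2",
    age_at_first_presentation = 35L,
    first_contact_date = as.Date("2010-06-01"),
    diagnosis_codes = "F20.0",
    stringsAsFactors = FALSE)
  registry$first_contact_date[1:15] <- NA  # follow-up not computable
  honos <- data.frame(patient_id = ids, date = as.Date("2011-01-01"),
                      stringsAsFactors = FALSE)
  indet_ids <- ids[16:30]
  pos_ids <- ids[31:649]
  notes <- data.frame(
    note_id = sprintf("FN%04d", seq_len(length(indet_ids) + length(pos_ids))),
    patient_id = c(indet_ids, pos_ids),
    date = as.Date("2012-03-01"),
    text = c(rep("old notes mention historical sexual abuse, age unclear.",
                 length(indet_ids)),
             rep("she disclosed childhood sexual abuse during today's session.",
                 length(pos_ids))),
    stringsAsFactors = FALSE)
  list(registry = registry, honos = honos, notes = notes)
}
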