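test_that("configuration validation catches invalid inputs", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(csa_prevalence = 1.2), "probability")
  expect_error(cohort_config(demographic_marginals = list(
    sex = c(M = 0.6, F = 0.5),
    ethnicity = c(White = 1), marital = c(Single = 1),
    deprivation = c(Q1 = 1))), "sum to 1")
  m <- default_demographic_marginals()
  m$marital <- numeric(0)
  expect_error(cohort_config(demographic_marginals = m), "empty demographic")
})

test_that("a fixed seed makes generated files byte-identical", {
  cfg <- cohort_config(n_patients = 60, seed = 7)
  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  # and a different seed changes the data
  d3 <- file.path(tempdir(), "cohort_c")
  write_cohort(generate_cohort(cohort_config(n_patients = 60, seed = 8)), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "notes.jsonl"))),
                         unname(tools::md5sum(file.path(d3, "notes.jsonl")))))
})

test_that("true-CSA count is binomially consistent at the default prevalence", {
  cfg <- cohort_config(n_patients = 7000, csa_prevalence = 0.088, seed = 1,
                       include_notes = FALSE)
  ch <- generate_cohort(cfg)
  n_true <- sum(ch$outcomes_truth$true_csa)
  expect_lt(abs(n_true - 7000 * 0.088), 3 * sqrt(7000 * 0.088 * 0.912))
})

test_that("zero prevalence yields no true cases and no positive mentions", {
  ch <- generate_cohort(cohort_config(n_patients = 10, csa_prevalence = 0,
                                      seed = 7))
  expect_identical(sum(ch$outcomes_truth$true_csa), 0L)
  expect_false(any(ch$truth$label == "positive"))
})

test_that("generated structure honours the documented guarantees", {
  sc <- shared_cohort()
  ch <- sc$cohort
  reg <- ch$registry
  window <- ch$config$study_window

  # every patient has at least one HoNOS assessment
  expect_true(all(reg$patient_id %in% ch$honos$patient_id))
  # non-missing first contact leaves >= 1 year of follow-up
  fc <- reg$first_contact_date
  expect_true(all(is.na(fc) | (fc >= window[1] &
                                 as.numeric(window[2] - fc) >= 365)))
  # exactly one mention label per note, from the documented label set
  expect_identical(nrow(ch$truth), nrow(ch$notes))
  expect_true(all(ch$truth$label %in%
                    c("none", "positive", "negated", "uncertain",
                      "adult_onset", "hearsay")))
  # no unexposed patient carries an unqualified positive mention
  expect_false(any(ch$truth$label == "positive" & !ch$truth$true_csa))
  # every true-CSA patient has at least one positive note
  pos_pat <- unique(ch$truth$patient_id[ch$truth$label == "positive"])
  csa_pat <- reg$patient_id[ch$outcomes_truth$true_csa]
  expect_true(all(csa_pat %in% pos_pat))
})

test_that("detected prevalence tracks configured prevalence plus the hearsay channel", {
  sc <- shared_cohort()
  cfg <- sc$config
  labels <- classify_patients(sc$spans, sc$cohort$registry$patient_id)
  detected <- mean(labels$status == "exposed")
  expected <- cfg$csa_prevalence +
    (1 - cfg$csa_prevalence) * cfg$distractor_rates$hearsay
  sd3 <- 3 * sqrt(expected * (1 - expected) / cfg$n_patients)
  expect_lt(abs(detected - expected), sd3)
})

test_that("dose-entry errors appear at the configured rate and only they exceed 200%", {
  sc <- shared_cohort()
  recs <- extract_medications(sc$cohort$notes, default_gazetteer())
  dosed <- recs[!is.na(recs$pct_max), ]
  p <- sc$config$med_params$p_dose_error
  expect_lt(abs(mean(dosed$excluded) - p),
            3 * sqrt(p * (1 - p) / nrow(dosed)))
  expect_true(all(dosed$pct_max[dosed$excluded] > 200))
  expect_true(all(dosed$pct_max[!dosed$excluded] <= 200))
})

test_that("note text generation embeds the phrases its label promises", {
  lex <- default_lexicon()
  set.seed(5)
  for (i in 1:25) {
    pos <- generate_note_text("positive")
    s <- scan_note(pos, lex)
    expect_identical(sum(s$polarity == "include"), 1L)

    neg <- generate_note_text("negated")
    expect_false(any(scan_note(neg, lex)$polarity == "include"))

    adult <- generate_note_text("adult_onset", age = 35)
    expect_identical(classify_patient(scan_note(adult, lex))$status,
                     "unexposed")
  }
  expect_error(generate_note_text("banana"), "unknown mention label")
})

test_that("round-tripping notes through JSON-lines preserves them", {
  sc <- shared_cohort()
  d <- file.path(tempdir(), "cohort_rt")
  write_cohort(sc$cohort, d)
  back <- read_notes(file.path(d, "notes.jsonl"))
  expect_identical(nrow(back), nrow(sc$cohort$notes))
  expect_identical(back$text, sc$cohort$notes$text)
  expect_identical(back$date, sc$cohort$notes$date)
})

test_that("YAML configs override defaults and reject unknown fields", {
  p <- tempfile(fileext = ".yml")
  writeLines(c("n_patients: 25", "csa_prevalence: 0.2", "seed: 3"), p)
  cfg <- read_cohort_config(p)
  expect_equal(cfg$n_patients, 25)
  expect_equal(cfg$csa_prevalence, 0.2)
  expect_equal(cfg$note_rate, 0.75)
  writeLines(c("n_patients: 25", "frobnicate: 1"), p)
  expect_error(read_cohort_config(p), "unknown config field")
})
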