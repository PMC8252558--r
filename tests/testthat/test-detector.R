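lex <- default_lexicon()

test_that("normalization folds case and whitespace and maps offsets back", {
  n <- normalize_text("Childhood   Sexual ABUSE")
  expect_identical(n$text, "childhood sexual abuse")
  expect_identical(normalize_text("")$text, "")
  expect_identical(normalize_text("")$map, integer(0))
  expect_identical(normalize_text("Hx  of\tsexual abuse")$text,
                   "hx of sexual abuse")
  # every normalized character maps to the raw character it came from
  raw <- "  A  b\t\nC d "
  nn <- normalize_text(raw)
  expect_identical(nchar(nn$text), length(nn$map))
  for (i in seq_len(nchar(nn$text))) {
    rc <- tolower(substr(raw, nn$map[i] + 1, nn$map[i] + 1))
    nc <- substr(nn$text, i, i)
    if (nc != " ") expect_identical(rc, nc)
  }
})

test_that("scan_note reproduces the documented phrase behaviour", {
  s <- scan_note("she was sexually abused as a child", lex)
  expect_identical(s$polarity, "include")
  expect_identical(nrow(s), 1L)

  s <- scan_note("nil csa, no other trauma", lex)
  expect_identical(s$polarity, "exclude")
  expect_false(any(s$polarity == "include"))

  s <- scan_note("sexually abused between the ages of 6-9", lex)
  expect_identical(s$polarity, "include")
  expect_identical(s$ages[[1]], c(6L, 9L))

  s <- scan_note("patient denied a childhood history of sexual abuse", lex)
  expect_false(any(s$polarity == "include"))
})

test_that("match offsets are 0-based half-open on the raw text", {
  raw <- "Hx  Of   SEXUAL abuse noted"
  s <- scan_note(raw, lex)
  expect_identical(nrow(s), 1L)
  frag <- substr(raw, s$start + 1, s$end)
  expect_identical(normalize_text(frag)$text, "hx of sexual abuse")
})

test_that("acronym matches respect token boundaries", {
  expect_identical(nrow(scan_note("csataxonomy discussed", lex)), 0L)
  expect_identical(nrow(scan_note("discussed csa today", lex)), 1L)
  expect_identical(nrow(scan_note("macsa protocol", lex)), 0L)
})

test_that("lexicon validation rejects malformed input at load time", {
  write_lex <- function(lines) {
    p <- tempfile(fileext = ".csv")
    writeLines(c("pattern_id,surface,polarity", lines), p)
    p
  }
  expect_error(read_lexicon(write_lex(c("a,foo {AGE bar,include"))),
               "malformed age-slot")
  expect_error(read_lexicon(write_lex(c("a,foo,include", "a,bar,include"))),
               "duplicate pattern_id")
  expect_error(read_lexicon(write_lex(c("a,foo,sometimes"))),
               "invalid polarity")
  expect_error(read_lexicon(write_lex(c("a,,include"))), "empty surface")
})

test_that("patient classification follows the evidence hierarchy", {
  one_include <- scan_note("there is a history of sexual abuse", lex)
  expect_identical(classify_patient(one_include)$status, "exposed")

  indet <- scan_note("historical sexual abuse mentioned in old notes", lex)
  expect_identical(classify_patient(indet)$status, "removed_indeterminate")

  none <- scan_note("attended clinic, mood stable", lex)
  expect_identical(classify_patient(none)$status, "unexposed")

  adult <- scan_note("reports being sexually abused at the age of 35", lex)
  expect_identical(adult$polarity, "include")
  expect_identical(classify_patient(adult, childhood_cutoff = 18)$status,
                   "unexposed")

  # include evidence dominates indeterminate evidence across notes
  both <- rbind(one_include, indet)
  expect_identical(classify_patient(both)$status, "exposed")

  # the cutoff is configurable
  teen <- scan_note("sexual abuse at age 16 disclosed", lex)
  expect_identical(classify_patient(teen, childhood_cutoff = 18)$status, "exposed")
  expect_identical(classify_patient(teen, childhood_cutoff = 16)$status, "unexposed")
})

test_that("detector output is invariant to case and interior whitespace", {
  set.seed(99)
  texts <- c(
    "she disclosed childhood sexual abuse during today's session.",
    "nil csa, no other trauma disclosed.",
    "was sexually abused between the ages of 6-9.",
    "possible history of sexual abuse, to be explored.",
    "reports being sexually abused at the age of 35.",
    "risk history includes csa.")
  mangle <- function(x) {
    ch <- strsplit(x, "")[[1]]
    up <- runif(length(ch)) < 0.5
    ch[up] <- toupper(ch[up])
    x <- paste(ch, collapse = "")
    gsub(" ", paste(rep(c(" ", "\t", "  "), 5)[sample.int(15, 1)], ""), x)
  }
  for (tx in texts) {
    a <- scan_note(tx, lex)
    b <- scan_note(mangle(tx), lex)
    expect_identical(a$pattern_id, b$pattern_id)
    expect_identical(a$polarity, b$polarity)
    expect_identical(a$ages, b$ages)
  }
})

test_that("adding an include phrase never flips an exposed patient to unexposed", {
  extended_path <- tempfile(fileext = ".csv")
  base_lines <- readLines(system.file("extdata", "csa_lexicon.csv",
                                      package = "csascreenr"))
  writeLines(c(base_lines, "inc_extra_survivor,survivor of childhood abuse,include,added"),
             extended_path)
  lex2 <- read_lexicon(extended_path)

  sc <- shared_cohort()
  ids <- sc$cohort$registry$patient_id
  before <- classify_patients(sc$spans, ids)
  after <- classify_patients(scan_notes(sc$cohort$notes, lex2), ids)
  flipped <- before$status == "exposed" & after$status != "exposed"
  expect_identical(sum(flipped), 0L)
})

test_that("patients with only distractor mentions are never labelled exposed", {
  sc <- shared_cohort()
  truth <- sc$cohort$truth
  per_pat <- split(truth$label, truth$patient_id)
  only_distractor <- vapply(per_pat, function(l) {
    any(l %in% c("negated", "uncertain", "adult_onset")) &&
      !any(l %in% c("positive", "hearsay"))
  }, logical(1))
  labels <- classify_patients(sc$spans, sc$cohort$registry$patient_id)
  status <- labels$status[match(names(per_pat), labels$patient_id)]
  expect_true(sum(only_distractor) > 20)  # the property is actually exercised
  expect_false(any(status[only_distractor] == "exposed"))
})

test_that("ppv_audit matches the closed-form binomial interval", {
  flagged <- sprintf("n%03d", 1:100)
  truth <- data.frame(note_id = flagged,
                      label = c(rep("positive", 95), rep("hearsay", 5)))
  a <- ppv_audit(flagged, truth, sample_size = 100, seed = 3)
  expect_identical(a$ppv, 0.95)

  all_true <- data.frame(note_id = flagged, label = "positive")
  b <- ppv_audit(flagged, all_true, sample_size = 100, seed = 3)
  expect_identical(b$ppv, 1)
  expect_identical(b$ci_high, 1)

  truth10 <- data.frame(note_id = sprintf("m%02d", 1:10),
                        label = c(rep("positive", 7), rep("negated", 3)))
  cc <- ppv_audit(truth10$note_id, truth10, sample_size = 10, seed = 1)
  expect_equal(cc$ppv, 0.7)
  expect_equal(cc$ci_low, 0.3475, tolerance = 1e-3)
  expect_equal(cc$ci_high, 0.9333, tolerance = 1e-3)

  expect_error(ppv_audit(character(0), truth), "no flagged notes")
  expect_error(ppv_audit(flagged[1:10], truth, sample_size = 50), "exceeds")
})
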