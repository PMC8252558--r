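# Template banks for synthetic note text. Realism is template-level only:
# enough lexical variety to exercise the matcher, no clinical language
# modelling. Filler sentences are screened to contain no lexicon phrase and
# no gazetteer drug name.

#' Sentence templates used by the synthetic note generator
#'
#' Each mention label maps to a bank of sentence templates. Positive
#' templates embed inclusion-lexicon phrases (some with age slots filled
#' from the childhood range); negated and possible-history templates embed
#' exclusion phrases; indeterminate templates embed the unconfirmable
#' "historical sexual abuse" phrasing; adult-onset templates use age slots
#' filled from the adult range; hearsay templates describe abuse of a
#' relative with the same vocabulary, which pure string matching cannot
#' tell apart.
#'
#' @return Named list of character vectors (`%d` marks an age slot).
#' @export
note_templates <- function() {
  list(
    filler = c(
      "attended outpatient clinic accompanied by care coordinator.",
      "mental state settled, sleep remains poor.",
      "care plan reviewed and agreed with patient.",
      "no acute risk concerns identified today.",
      "engaging well with the community team.",
      "discussed employment goals and daytime structure.",
      "appetite fair, concentration variable.",
      "home visit completed, flat adequately maintained.",
      "will be reviewed again in four weeks.",
      "bloods requested at today's appointment."),
    positive = c(
      "she disclosed childhood sexual abuse during today's session.",
      "background notable for a childhood hx of sexual abuse.",
      "there is a documented history of sexual abuse in childhood.",
      "was sexually abused as a child and finds anniversaries difficult.",
      "risk history includes csa.",
      "reports childhood experiences of sexual abuse."),
    positive_age = c(
      "reports being sexually abused at the age of %d.",
      "discloses sexual abuse at age %d.",
      "was sexually abused aged %d by a neighbour."),
    positive_range = c(
      "was sexually abused between the ages of %d-%d."),
    negated = c(
      "denied a childhood history of sexual abuse when asked directly.",
      "no csa or other childhood trauma reported.",
      "nil csa, no other trauma disclosed.",
      "denies any history of sexual abuse.",
      "trauma screening negative: no history of sexual abuse."),
    possible = c(
      "possible history of sexual abuse, to be explored in psychology.",
      "? childhood sexual abuse mentioned in the referral letter.",
      "possible csa per previous team, unconfirmed."),
    indeterminate = c(
      "old notes mention historical sexual abuse, age at the time unclear.",
      "historic sexual abuse referenced in the transfer summary."),
    adult_onset = c(
      "reports being sexually abused at the age of %d.",
      "discloses sexual abuse at age %d, after leaving home."),
    hearsay = c(
      "her sister disclosed childhood sexual abuse to the family.",
      "mother has a history of sexual abuse and finds disclosure difficult.",
      "partner reports childhood experiences of sexual abuse of her own."),
    med_dosed = c(
      "started %s %s mg %s.",
      "continue %s %s mg %s.",
      "%s increased to %s mg %s."),
    med_undosed = c(
      "remains on %s.",
      "continue %s, adherence reported as good.")
  )
}

#' Generate the text of one synthetic note
#'
#' Assembles one to two filler sentences, the mention sentence implied by
#' the truth label (if any) and an optional medication sentence. A positive
#' note contains exactly one inclusion phrase; negated / possible notes
#' embed exclusion phrases; adult-onset notes fill an age slot at or above
#' the childhood cutoff.
#'
#' @param label Mention label: one of `"none"`, `"positive"`, `"negated"`,
#'   `"uncertain"`, `"adult_onset"`, `"hearsay"`.
#' @param age Age to fill into an age-slot template (positive and
#'   adult-onset labels; a range template uses `age` and `age + 2`).
#' @param indeterminate For `"uncertain"`: use the unconfirmable
#'   "historical" phrasing instead of a "possible history" exclusion.
#' @param med_sentence Optional pre-built medication sentence to append.
#' @param templates Template bank, see [note_templates()].
#' @return A single note string.
#' @export
generate_note_text <- function(label = "none", age = NULL,
                               indeterminate = FALSE, med_sentence = NULL,
                               templates = note_templates()) {
  if (!length(templates$filler)) stop("empty template bank", call. = FALSE)
  pick <- function(bank) bank[sample.int(length(bank), 1L)]
  body <- pick(templates$filler)
  mention <- switch(label,
    none = NULL,
    positive = {
      if (is.null(age)) {
        pick(templates$positive)
      } else if (stats::runif(1) < 0.3) {
        sprintf(pick(templates$positive_range), age, age + 2L)
      } else {
        sprintf(pick(templates$positive_age), age)
      }
    },
    negated = pick(templates$negated),
    uncertain = if (indeterminate) pick(templates$indeterminate) else pick(templates$possible),
    adult_onset = sprintf(pick(templates$adult_onset), age),
    hearsay = pick(templates$hearsay),
    stop("unknown mention label: ", label, call. = FALSE))
  parts <- c(body, mention,
             if (stats::runif(1) < 0.5) pick(templates$filler),
             med_sentence)
  paste(parts, collapse = " ")
}

# Build a medication sentence for one mention.
med_sentence <- function(drug, amount, freq, dosed, templates) {
  pick <- function(bank) bank[sample.int(length(bank), 1L)]
  if (!dosed) {
    sprintf(pick(templates$med_undosed), drug)
  } else {
    sprintf(pick(templates$med_dosed), drug, format(amount), freq)
  }
}
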