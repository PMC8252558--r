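#' Scan a clinical note for lexicon matches
#'
#' Matches every lexicon phrase against the normalized note text and resolves
#' overlaps under a fixed precedence: exclude and indeterminate patterns are
#' placed before include patterns, longer matches before shorter, earlier
#' before later; a candidate overlapping an already-placed span is dropped.
#' In particular an include match wholly or partly covered by an exclude
#' match is suppressed ("blocked"), which is how negations such as
#' "nil csa" prevent the embedded acronym from counting as evidence.
#'
#' Offsets are 0-based half-open on the *raw* (pre-normalization) text,
#' recovered through the offset map of [normalize_text()].
#'
#' @param text Note text (single string).
#' @param lexicon A `csa_lexicon` from [read_lexicon()] / [default_lexicon()].
#' @param note_id Optional identifier copied into the result.
#' @return A data frame with one row per surviving match: `note_id`, `start`,
#'   `end`, `pattern_id`, `polarity`, and `ages` (list column of extracted
#'   integer ages; empty unless the pattern has an age slot).
#' @examples
#' lex <- default_lexicon()
#' scan_note("She was sexually abused between the ages of 6-9.", lex)
#' scan_note("nil csa, no other trauma", lex)
#' @export
scan_note <- function(text, lexicon, note_id = NA_character_) {
  stopifnot(inherits(lexicon, "csa_lexicon"))
  norm <- normalize_text(text)
  cand <- find_candidates(norm$text, lexicon)
  spans <- resolve_spans(cand)
  if (nrow(spans) > 0L) {
    raw <- t(vapply(seq_len(nrow(spans)),
                    function(i) span_to_raw(spans$start[i], spans$end[i], norm$map),
                    integer(2)))
    spans$start <- raw[, 1L]
    spans$end <- raw[, 2L]
  }
  cbind(data.frame(note_id = rep(note_id, nrow(spans))), spans)
}

#' Scan a corpus of notes
#'
#' Vectorized equivalent of [scan_note()] over a notes table. Notes without
#' any candidate match are skipped cheaply; offset maps are built only for
#' notes that need them.
#'
#' @param notes Data frame with columns `note_id`, `patient_id`, `text`.
#' @param lexicon A `csa_lexicon`.
#' @return A data frame of surviving matches with columns `note_id`,
#'   `patient_id`, `start`, `end`, `pattern_id`, `polarity`, `ages`
#'   (raw-text offsets, as in [scan_note()]).
#' @export
scan_notes <- function(notes, lexicon) {
  stopifnot(inherits(lexicon, "csa_lexicon"))
  required <- c("note_id", "patient_id", "text")
  if (!all(required %in% names(notes))) {
    stop("`notes` needs columns: ", paste(required, collapse = ", "), call. = FALSE)
  }
  norm <- normalize_texts(notes$text)
  cand <- find_candidates_vec(norm, lexicon)
  if (nrow(cand) == 0L) {
    return(empty_span_frame(patient = TRUE))
  }
  pieces <- lapply(split(cand, cand$idx), function(ci) {
    idx <- ci$idx[1L]
    spans <- resolve_spans(ci[setdiff(names(ci), "idx")])
    if (nrow(spans) == 0L) return(NULL)
    map <- normalize_text(notes$text[idx])$map
    raw <- t(vapply(seq_len(nrow(spans)),
                    function(i) span_to_raw(spans$start[i], spans$end[i], map),
                    integer(2)))
    spans$start <- raw[, 1L]
    spans$end <- raw[, 2L]
    cbind(data.frame(note_id = notes$note_id[idx],
                     patient_id = notes$patient_id[idx],
                     stringsAsFactors = FALSE),
          spans)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) {
    return(empty_span_frame(patient = TRUE))
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

empty_span_frame <- function(patient = FALSE) {
  base <- data.frame(note_id = character(0), stringsAsFactors = FALSE)
  if (patient) base$patient_id <- character(0)
  base$start <- integer(0)
  base$end <- integer(0)
  base$pattern_id <- character(0)
  base$polarity <- character(0)
  base$ages <- I(list())
  base
}

# Candidate matches of every pattern in one normalized text:
# data.frame(start, end, pattern_id, polarity, pclass, ages) with 0-based
# half-open offsets on the normalized text.
find_candidates <- function(norm_text, lexicon) {
  cand <- find_candidates_vec(norm_text, lexicon)
  cand$idx <- NULL
  cand
}

find_candidates_vec <- function(norm_texts, lexicon) {
  rows <- vector("list", nrow(lexicon))
  for (p in seq_len(nrow(lexicon))) {
    hits <- gregexpr(lexicon$regex[p], norm_texts, perl = TRUE)
    for (i in seq_along(hits)) {
      m <- hits[[i]]
      starts <- as.integer(m)
      if (starts[1L] == -1L) next
      lens <- attr(m, "match.length")
      ages <- rep(list(integer(0)), length(starts))
      if (lexicon$is_template[p]) {
        cs <- attr(m, "capture.start")
        cl <- attr(m, "capture.length")
        for (j in seq_along(starts)) {
          caps <- substring(norm_texts[i], cs[j, ], cs[j, ] + cl[j, ] - 1L)
          ages[[j]] <- as.integer(unlist(regmatches(caps, gregexpr("[0-9]{1,2}", caps))))
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        idx = i,
        start = starts - 1L,
        end = starts - 1L + lens,
        pattern_id = lexicon$pattern_id[p],
        polarity = lexicon$polarity[p],
        pclass = lexicon$pclass[p],
        ages = I(ages),
        stringsAsFactors = FALSE
      )
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- empty_span_frame()
    out$idx <- integer(0)
    out$pclass <- integer(0)
    out$note_id <- NULL
    return(out)
  }
  do.call(rbind, rows)
}

# Greedy precedence resolution; drops the internal pclass column.
resolve_spans <- function(cand) {
  if (nrow(cand) == 0L) {
    out <- empty_span_frame()
    out$note_id <- NULL
    return(out)
  }
  ord <- order(cand$pclass, -(cand$end - cand$start), cand$start)
  cand <- cand[ord, , drop = FALSE]
  acc_start <- integer(0)
  acc_end <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]
    e <- cand$end[i]
    if (!any(s < acc_end & acc_start < e)) {
      keep[i] <- TRUE
      acc_start <- c(acc_start, s)
      acc_end <- c(acc_end, e)
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  out$pclass <- NULL
  rownames(out) <- NULL
  out
}
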