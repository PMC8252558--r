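# Independent oracles used to cross-check the implementation. These
# deliberately avoid the code paths they validate: the chi-square oracle is
# the textbook formula, the scan oracle is an exhaustive substring search
# with a hand-written age parser (no PCRE), and the admission-day oracle
# materializes day sets.

chisq_oracle <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - e)^2 / e)
}

dayset_days <- function(start, end) {
  days <- unlist(mapply(function(s, e) seq(as.Date(s), as.Date(e), by = "day"),
                        start, end, SIMPLIFY = FALSE))
  length(unique(days))
}

# --- exhaustive substring scan oracle -------------------------------------
# Operates on already-normalized text (lowercase, single spaces). All
# shipped age-slot templates have the slot at the end of the surface.

oracle_is_boundary <- function(ch) !grepl("[a-z0-9]", ch)

oracle_char_at <- function(text, i) {
  if (i < 1L || i > nchar(text)) "" else substr(text, i, i)
}

# Hand-rolled parse of an age slot starting at 1-based position `pos`:
# greedy digits (2 then 1), then an optional range tail, then a boundary.
# Returns list(len, ages) or NULL.
oracle_parse_age <- function(text, pos) {
  digits_at <- function(p) {
    two <- substr(text, p, p + 1L)
    one <- substr(text, p, p)
    out <- list()
    if (grepl("^[0-9]{2}$", two)) out <- c(out, list(list(len = 2L, val = as.integer(two))))
    if (grepl("^[0-9]$", one)) out <- c(out, list(list(len = 1L, val = as.integer(one))))
    out
  }
  seps <- c("-", "‐", "–", "to", "and")
  for (d1 in digits_at(pos)) {
    p <- pos + d1$len
    # try the range tail, longest interpretation first
    tails <- list()
    for (sp1 in c(" ", "")) for (sep in seps) for (sp2 in c(" ", "")) {
      lead <- paste0(sp1, sep, sp2)
      if (substr(text, p, p + nchar(lead) - 1L) == lead) {
        for (d2 in digits_at(p + nchar(lead))) {
          tails <- c(tails, list(list(len = nchar(lead) + d2$len, val = d2$val)))
        }
      }
    }
    tails <- c(tails, list(NULL))  # rangeless fallback
    for (tl in tails) {
      total <- d1$len + if (is.null(tl)) 0L else tl$len
      if (oracle_is_boundary(oracle_char_at(text, pos + total))) {
        ages <- c(d1$val, if (!is.null(tl)) tl$val)
        return(list(len = total, ages = ages))
      }
    }
  }
  NULL
}

# All candidate matches of one lexicon row by exhaustive position search.
oracle_candidates <- function(text, surface, is_template) {
  n <- nchar(text)
  out <- list()
  if (!is_template) {
    L <- nchar(surface)
    if (L > n) return(out)
    starts <- which(substring(text, 1:(n - L + 1L), L:(n)) == surface)
    for (s in starts) {
      if (oracle_is_boundary(oracle_char_at(text, s - 1L)) &&
          oracle_is_boundary(oracle_char_at(text, s + L))) {
        out[[length(out) + 1L]] <- list(start = s - 1L, end = s - 1L + L,
                                        ages = integer(0))
      }
    }
  } else {
    prefix <- sub("\\{AGE\\}$", "", surface)
    L <- nchar(prefix)
    if (L + 1L > n) return(out)
    starts <- which(substring(text, 1:(n - L), L:(n - 1L)) == prefix)
    for (s in starts) {
      if (!oracle_is_boundary(oracle_char_at(text, s - 1L))) next
      hit <- oracle_parse_age(text, s + L)
      if (!is.null(hit)) {
        out[[length(out) + 1L]] <- list(start = s - 1L, end = s - 1L + L + hit$len,
                                        ages = hit$ages)
      }
    }
  }
  out
}

# Precedence re-stated from scratch: exclusions and indeterminates placed
# before inclusions, longer before shorter, earlier before later; greedy
# non-overlap. Returns the surviving include spans.
oracle_effective_includes <- function(text, lexicon) {
  cand <- list()
  for (k in seq_len(nrow(lexicon))) {
    for (m in oracle_candidates(text, lexicon$surface[k], lexicon$is_template[k])) {
      m$polarity <- lexicon$polarity[k]
      m$pattern_id <- lexicon$pattern_id[k]
      cand[[length(cand) + 1L]] <- m
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(0), end = integer(0),
                      pattern_id = character(0)))
  }
  pc <- vapply(cand, function(m) {
    match(m$polarity, c("exclude", "indeterminate", "include"))
  }, integer(1))
  len <- vapply(cand, function(m) m$end - m$start, integer(1))
  st <- vapply(cand, function(m) m$start, integer(1))
  ord <- order(pc, -len, st)
  placed <- list()
  for (i in ord) {
    m <- cand[[i]]
    clash <- any(vapply(placed, function(p) {
      m$start < p$end && p$start < m$end
    }, logical(1)))
    if (!clash) placed[[length(placed) + 1L]] <- m
  }
  inc <- Filter(function(p) p$polarity == "include", placed)
  out <- data.frame(
    start = vapply(inc, function(p) p$start, integer(1)),
    end = vapply(inc, function(p) p$end, integer(1)),
    pattern_id = vapply(inc, function(p) p$pattern_id, character(1)),
    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

# Random already-normalized note text that stresses the matcher: lexicon
# phrases (ages instantiated), phrase fragments and neutral words glued
# together so negations, acronyms and age slots collide in odd ways.
random_oracle_note <- function(lexicon, max_chars = 200) {
  phrases <- vapply(seq_len(nrow(lexicon)), function(k) {
    s <- lexicon$surface[k]
    if (lexicon$is_template[k]) {
      age <- sample(1:99, 1)
      tail <- sample(c(as.character(age),
                       paste0(age, "-", sample(1:99, 1)),
                       paste0(age, " to ", sample(1:99, 1))), 1)
      sub("\\{AGE\\}", tail, s)
    } else s
  }, character(1))
  words <- c("the", "patient", "clinic", "review", "today", "risk", "denied",
             "no", "nil", "history", "of", "sexual", "abuse", "childhood",
             "csa", "historical", "possible", "aged", "child", "?", "12",
             "7", "45", "abused", "sexually")
  pool <- c(phrases, words, words)
  out <- character(0)
  size <- 0L
  while (size < max_chars - 30L) {
    tok <- sample(pool, 1)
    out <- c(out, tok)
    size <- size + nchar(tok) + 1L
  }
  substr(paste(out, collapse = " "), 1L, max_chars)
}
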