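#' Normalize clinical note text for lexicon matching
#'
#' Case-folds the text and collapses every run of whitespace (spaces, tabs,
#' newlines) to a single space, trimming leading and trailing whitespace.
#' Matching is performed on the normalized string; the returned offset map
#' allows any normalized span to be projected back onto the raw text.
#'
#' @param text A single character string (`NA` is treated as empty).
#'
#' @return A list with elements:
#'   \describe{
#'     \item{text}{the normalized string}
#'     \item{map}{integer vector; `map[i]` is the 0-based offset in the raw
#'       text of the character at 0-based position `i - 1` of the normalized
#'       text. A collapsed space maps to the first whitespace character of
#'       the run it replaces.}
#'   }
#'
#' @examples
#' normalize_text("Childhood   Sexual ABUSE")$text
#' @export
normalize_text <- function(text) {
  if (!is.character(text) || length(text) != 1L) {
    stop("`text` must be a single character string", call. = FALSE)
  }
  if (is.na(text)) text <- ""
  chars <- strsplit(tolower(text), "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) {
    return(list(text = "", map = integer(0)))
  }
  is_ws <- grepl("^\\s$", chars, perl = TRUE)
  nz <- which(!is_ws)
  if (length(nz) == 0L) {
    return(list(text = "", map = integer(0)))
  }
  gap <- c(FALSE, diff(nz) > 1L)
  pos <- seq_along(nz) + cumsum(gap)  # 1-based positions of non-ws chars in output
  n_out <- pos[length(pos)]
  out <- character(n_out)
  map <- integer(n_out)
  out[pos] <- chars[nz]
  map[pos] <- nz - 1L
  if (any(gap)) {
    sp <- pos[gap] - 1L
    out[sp] <- " "
    map[sp] <- nz[which(gap) - 1L]  # first ws char after the previous kept char
  }
  list(text = paste(out, collapse = ""), map = map)
}

# Vectorized normalization without an offset map (corpus scanning fast path).
normalize_texts <- function(texts) {
  texts[is.na(texts)] <- ""
  out <- gsub("\\s+", " ", tolower(texts), perl = TRUE)
  gsub("^ | $", "", out, perl = TRUE)
}

# Project a 0-based half-open span on normalized text back to raw offsets.
span_to_raw <- function(start, end, map) {
  if (length(map) == 0L || end <= start) {
    return(c(start = 0L, end = 0L))
  }
  c(start = map[start + 1L], end = map[end] + 1L)
}
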