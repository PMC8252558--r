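#' Read and validate a CSA phrase lexicon
#'
#' The lexicon drives the string-matching detector. It is a CSV file with
#' columns `pattern_id`, `surface`, `polarity` and (optionally) `notes`.
#' Surfaces are matched literally after [normalize_text()] folding; the token
#' `{AGE}` marks an age slot that matches a 1-2 digit integer or an integer
#' range (`"6-9"`, `"6 to 9"`), whose endpoints are extracted.
#'
#' Polarities:
#' \describe{
#'   \item{include}{affirms a childhood history of sexual abuse}
#'   \item{exclude}{negates the history or marks it as merely possible;
#'     an include match overlapped by an exclude match is suppressed}
#'   \item{indeterminate}{a historical mention whose age at abuse cannot be
#'     confirmed; a patient with only such evidence is removed from the
#'     analytic cohort}
#' }
#'
#' Malformed templates (unbalanced braces, empty surfaces, duplicate ids)
#' are rejected here, at load time, never during scanning.
#'
#' @param path Path to the lexicon CSV. Lines starting with `#` are comments;
#'   a leading `# <name> v<version>` comment line is recorded as the lexicon
#'   version.
#' @return A data frame of class `csa_lexicon` with compiled match patterns,
#'   carrying a `version` attribute.
#' @seealso [default_lexicon()], [scan_note()]
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  version <- if (startsWith(first, "#")) sub("^#\\s*", "", first) else "unversioned"
  lex <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_lexicon(lex)
  # surfaces are normalized like note text; the {AGE} token must survive folding
  lex$surface <- gsub("{age}", "{AGE}", normalize_texts(lex$surface), fixed = TRUE)
  lex$is_template <- grepl("{AGE}", lex$surface, fixed = TRUE)
  lex$regex <- vapply(lex$surface, compile_surface, character(1))
  lex$pclass <- match(lex$polarity, c("exclude", "indeterminate", "include")) - 1L
  attr(lex, "version") <- version
  class(lex) <- c("csa_lexicon", "data.frame")
  lex
}

#' Default shipped CSA lexicon
#'
#' Every phrase with a documented role in the detection strategy (core
#' inclusion phrases, age-slot templates, negation and possible-history
#' exclusions, indeterminate historical mentions) plus systematic
#' inflectional variants. The file is versioned and user-extensible; see
#' [read_lexicon()] for the format.
#'
#' @return A `csa_lexicon` data frame.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "csa_lexicon.csv", package = "csascreenr"))
}

validate_lexicon <- function(lex) {
  required <- c("pattern_id", "surface", "polarity")
  missing <- setdiff(required, names(lex))
  if (length(missing)) {
    stop("lexicon lacks column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(lex) == 0L) stop("lexicon is empty", call. = FALSE)
  if (anyDuplicated(lex$pattern_id)) {
    stop("duplicate pattern_id in lexicon: ",
         paste(unique(lex$pattern_id[duplicated(lex$pattern_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(lex$surface) | !nzchar(trimws(lex$surface)))) {
    stop("lexicon contains empty surface(s)", call. = FALSE)
  }
  bad_pol <- setdiff(unique(lex$polarity), c("include", "exclude", "indeterminate"))
  if (length(bad_pol)) {
    stop("invalid polarity value(s): ", paste(bad_pol, collapse = ", "), call. = FALSE)
  }
  # braces are only legal as part of the {AGE} slot token
  stripped <- gsub("{AGE}", "", lex$surface, fixed = TRUE)
  if (any(grepl("[{}]", stripped))) {
    stop("malformed age-slot template in surface(s): ",
         paste(lex$pattern_id[grepl("[{}]", stripped)], collapse = ", "),
         call. = FALSE)
  }
  invisible(lex)
}

# A 1-2 digit age, optionally a range ("6-9", "6 to 9"); endpoints captured
# together and parsed out later. ‐/– are the hyphen/dash variants
# common in pasted clinical text.
age_slot_regex <- "([0-9]{1,2}(?: ?(?:-|\u2010|\u2013|to|and) ?[0-9]{1,2})?)"

escape_regex <- function(x) gsub("([\\\\.^$|()\\[\\]{}*+?])", "\\\\\\1", x, perl = TRUE)

# Compile a normalized surface into a PCRE pattern anchored at word-ish
# boundaries so e.g. "csa" never fires inside another token.
compile_surface <- function(surface) {
  n_slots <- lengths(regmatches(surface, gregexpr("{AGE}", surface, fixed = TRUE)))
  parts <- strsplit(surface, "{AGE}", fixed = TRUE)[[1L]]
  if (length(parts) < n_slots + 1L) {
    parts <- c(parts, rep("", n_slots + 1L - length(parts)))
  }
  body <- paste(escape_regex(parts), collapse = age_slot_regex)
  paste0("(?<![a-z0-9])", body, "(?![a-z0-9])")
}

#' @export
print.csa_lexicon <- function(x, ...) {
  cat("CSA phrase lexicon (", attr(x, "version"), ")\n", sep = "")
  tab <- table(x$polarity)
  cat("  ", nrow(x), " patterns: ",
      paste(names(tab), unname(tab), sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}
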