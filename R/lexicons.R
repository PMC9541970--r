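# Rule resources: ICD code sets, term lexicons, scoping configuration.

# Short function words that may occur inside lexicon phrases. Stop-class
# removal must never delete these when they are part of an active lexicon
# phrase ("assault BY husband", "problems WITH spouse OR partner", ...).
.function_words <- c(
  "a", "an", "the", "and", "or", "but", "so", "as", "at", "by", "for",
  "from", "in", "into", "of", "off", "on", "onto", "out", "over", "per",
  "to", "under", "until", "up", "upon", "with", "within", "against",
  "between", "during", "after", "before", "near", "since", "toward",
  "towards"
)

#' Normalize a diagnosis code string
#'
#' Uppercases and strips the dot separator, so `"995.81"` and `"99581"`
#' compare equal. EHR exports vary in dot usage; all membership tests in the
#' package run on this normalized form.
#'
#' @param code character vector of raw code strings.
#' @return character vector of normalized codes.
#' @export
#' @examples
#' normalize_code(c("T74.11xa", "995.81"))
normalize_code <- function(code) {
  toupper(gsub(".", "", as.character(code), fixed = TRUE))
}

#' Construct an IPV diagnosis-code set
#'
#' @param icd9_codes,icd10_codes character vectors of codes (dot and case
#'   insensitive; normalized on construction).
#' @return an object of class `ipv_code_set` with elements `icd9` and
#'   `icd10` (normalized, unique, sorted in input order).
#' @seealso [load_default_codes()] for the packaged default set.
#' @export
code_set <- function(icd9_codes = character(), icd10_codes = character()) {
  icd9 <- unique(normalize_code(icd9_codes))
  icd10 <- unique(normalize_code(icd10_codes))
  if (any(!nzchar(c(icd9, icd10)))) {
    stop("code set contains an empty code string", call. = FALSE)
  }
  if (length(intersect(icd9, icd10))) {
    stop("codes present in both ICD-9 and ICD-10 sets: ",
         paste(intersect(icd9, icd10), collapse = ", "), call. = FALSE)
  }
  structure(list(icd9 = icd9, icd10 = icd10), class = "ipv_code_set")
}

#' Load the packaged default IPV code set
#'
#' Reads the shipped two-column TSV of IPV-related ICD-9 and ICD-10 codes
#' (adult physical/sexual/emotional abuse, perpetrator, and
#' asphyxiation/strangulation codes). One ICD-9 code (995.83) is listed in
#' the source coding table under two diagnosis names and is stored once.
#'
#' @param path optional path to an alternative two-column TSV
#'   (`code<TAB>revision`, revision one of `icd9`/`icd10`, `#` comments).
#' @return an [code_set()] object.
#' @export
#' @examples
#' codes <- load_default_codes()
#' code_member(codes, "t7411xa")
load_default_codes <- function(path = NULL) {
  if (is.null(path)) path <- ipv_extdata("icd_codes.tsv")
  if (!file.exists(path)) {
    stop("code resource not found: ", path, call. = FALSE)
  }
  tab <- tryCatch(
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) {
      stop("failed to read code resource ", path, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (!all(c("code", "revision") %in% names(tab))) {
    stop("code resource ", path, " must have columns 'code' and 'revision'",
         call. = FALSE)
  }
  rev <- tolower(tab$revision)
  if (!all(rev %in% c("icd9", "icd10"))) {
    stop("code resource ", path, " has unknown revision tags", call. = FALSE)
  }
  code_set(icd9_codes = tab$code[rev == "icd9"],
           icd10_codes = tab$code[rev == "icd10"])
}

#' Test membership of a code in a code set
#'
#' Invariant to case and dot usage. With `revision = NULL` both revisions
#' are searched.
#'
#' @param codeset an [code_set()] object.
#' @param code character vector of raw codes.
#' @param revision `NULL`, `"icd9"`, or `"icd10"`.
#' @return logical vector.
#' @export
code_member <- function(codeset, code, revision = NULL) {
  stopifnot(inherits(codeset, "ipv_code_set"))
  norm <- normalize_code(code)
  pool <- if (is.null(revision)) {
    c(codeset$icd9, codeset$icd10)
  } else {
    codeset[[match.arg(revision, c("icd9", "icd10"))]]
  }
  norm %in% pool
}

#' @export
print.ipv_code_set <- function(x, ...) {
  cat("<ipv_code_set> ", length(x$icd9), " ICD-9 codes, ",
      length(x$icd10), " ICD-10 codes\n", sep = "")
  invisible(x)
}

# --- term lexicons ----------------------------------------------------------

# Tokenize a lexicon phrase into lowercase word tokens (no removal: every
# phrase word must survive to be matchable).
phrase_tokens <- function(phrase) {
  tk <- tokenize(phrase)
  tk$norm[tk$kind != "punct"]
}

#' Construct a term lexicon
#'
#' A tiered, ordered list of phrases held in normalized token form. Phrases
#' are lowercased, tokenized, and stemmed with the same canonicalization
#' applied to note text, so matching happens in a shared key space
#' ("battered" and "batter", "strangle" and "strangled" coincide).
#'
#' @param phrases character vector of phrases (one or more words each).
#' @param tier `"situational"` or `"extended"`.
#' @param source_label provenance string recorded on the object.
#' @return object of class `ipv_lexicon`: `phrases` (raw), `tokens` (list of
#'   lowercase token vectors), `keys` (list of stemmed key vectors), `tier`,
#'   `source_label`.
#' @export
term_lexicon <- function(phrases, tier = c("situational", "extended"),
                         source_label = "user") {
  tier <- match.arg(tier)
  phrases <- as.character(phrases)
  if (any(is.na(phrases)) || any(!nzchar(trimws(phrases)))) {
    stop("lexicon phrases must be non-empty strings", call. = FALSE)
  }
  tokens <- lapply(tolower(trimws(phrases)), phrase_tokens)
  if (any(lengths(tokens) == 0L)) {
    stop("every lexicon phrase must contain at least one word token",
         call. = FALSE)
  }
  keys <- lapply(tokens, stem_keys)
  key_str <- vapply(keys, paste, "", collapse = " ")
  if (anyDuplicated(key_str)) {
    stop("duplicate phrase within tier: ",
         paste(unique(phrases[duplicated(key_str)]), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(tier = tier, phrases = phrases, tokens = tokens, keys = keys,
         source_label = source_label),
    class = "ipv_lexicon"
  )
}

#' @export
length.ipv_lexicon <- function(x) length(x$phrases)

#' @export
print.ipv_lexicon <- function(x, ...) {
  cat("<ipv_lexicon> tier=", x$tier, ", ", length(x), " phrases (",
      x$source_label, ")\n", sep = "")
  invisible(x)
}

#' Load a packaged default term lexicon
#'
#' The default situational tier holds exactly 23 phrases derived from the
#' IPV literature, risk-assessment instruments, and clinician expertise
#' ("domestic violence", "assault by husband", ...); the default extended
#' tier holds exactly 49 additional mechanism-specific phrases mined from
#' confirmed IPV encounters ("strangle by partner", "attack by gf", ...).
#' One phrase, "violence against women", belongs to both tiers.
#'
#' @param tier `"situational"` or `"extended"`.
#' @return an [term_lexicon()] object.
#' @export
#' @examples
#' length(load_default_lexicon("situational")) # 23
#' length(load_default_lexicon("extended"))    # 49
load_default_lexicon <- function(tier = c("situational", "extended")) {
  tier <- match.arg(tier)
  file <- switch(tier,
                 situational = "terms_situational.txt",
                 extended = "terms_extended.txt")
  read_lexicon(ipv_extdata(file), tier = tier,
               source_label = paste0("packaged default (", tier, ")"))
}

#' Read a lexicon from a plain-text file
#'
#' One phrase per line, UTF-8, `#` comments and blank lines ignored.
#'
#' @inheritParams term_lexicon
#' @param path file path.
#' @return an [term_lexicon()] object.
#' @export
read_lexicon <- function(path, tier = c("situational", "extended"),
                         source_label = path) {
  if (!file.exists(path)) {
    stop("lexicon resource not found: ", path, call. = FALSE)
  }
  phrases <- read_resource_lines(path)
  if (!length(phrases)) {
    stop("lexicon resource is empty: ", path, call. = FALSE)
  }
  term_lexicon(phrases, tier = match.arg(tier), source_label = source_label)
}

#' Write a lexicon to a plain-text file (one phrase per line)
#'
#' @param lexicon an [term_lexicon()] object.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "ipv_lexicon"))
  writeLines(lexicon$phrases, path, useBytes = TRUE)
  invisible(path)
}

#' Union of two term lexicons
#'
#' Phrase union with duplicates (same normalized key sequence) removed,
#' keeping first-seen order. The result is recorded as tier `"extended"`:
#' it is the lexicon the extended-approach classifier runs, i.e. "any of the
#' situational or extended situational terms".
#'
#' @param a,b [term_lexicon()] objects (either may be empty via
#'   `empty_lexicon()`).
#' @return an `ipv_lexicon` of the unique union.
#' @export
combined_lexicon <- function(a, b) {
  stopifnot(inherits(a, "ipv_lexicon"), inherits(b, "ipv_lexicon"))
  phrases <- c(a$phrases, b$phrases)
  keys <- c(a$keys, b$keys)
  key_str <- vapply(keys, paste, "", collapse = " ")
  keep <- !duplicated(key_str)
  if (!any(keep)) return(empty_lexicon("extended"))
  term_lexicon(phrases[keep], tier = "extended",
               source_label = paste0("union(", a$source_label, ", ",
                                     b$source_label, ")"))
}

#' An empty lexicon (identity element for [combined_lexicon()])
#' @param tier tier recorded on the empty object.
#' @return an `ipv_lexicon` with zero phrases.
#' @export
empty_lexicon <- function(tier = c("situational", "extended")) {
  structure(
    list(tier = match.arg(tier), phrases = character(), tokens = list(),
         keys = list(), source_label = "empty"),
    class = "ipv_lexicon"
  )
}

#' Function words occurring inside lexicon phrases
#'
#' Returns every short function word ("by", "of", "or", "with", "against",
#' ...) found inside any phrase of the lexicon. These words must be
#' protected from stop-class removal during normalization, otherwise phrases
#' such as "assault by husband" could never match.
#'
#' @param lexicon an [term_lexicon()] object.
#' @return character vector (possibly empty) of protected function words.
#' @export
#' @examples
#' "by" %in% protected_function_words(load_default_lexicon("situational"))
protected_function_words <- function(lexicon) {
  stopifnot(inherits(lexicon, "ipv_lexicon"))
  intersect(unique(as.character(unlist(lexicon$tokens))), .function_words)
}

# --- scoping configuration --------------------------------------------------

#' Construct a scoping configuration
#'
#' Cue and terminator sets for NegEx-style negation scoping and for
#' history-of-IPV scoping. History cues are matched longest-first so that
#' e.g. "h/o of" is not shadowed by "h/o".
#'
#' @param negation_cues character vector of single-word negation cues.
#' @param termination_tokens character vector of words and single
#'   punctuation marks that end a scope.
#' @param history_cues character vector of history cue phrases (1-2 words).
#' @param faithful_table3 flag recorded on the object (see
#'   [load_scoping_config()]).
#' @return object of class `ipv_scoping`.
#' @export
scoping_config <- function(negation_cues, termination_tokens, history_cues,
                           faithful_table3 = FALSE) {
  negation_cues <- tolower(as.character(negation_cues))
  termination_tokens <- tolower(as.character(termination_tokens))
  history_cues <- tolower(as.character(history_cues))
  if (length(intersect(negation_cues, termination_tokens))) {
    stop("negation cues and termination tokens must be disjoint: ",
         paste(intersect(negation_cues, termination_tokens), collapse = ", "),
         call. = FALSE)
  }
  bad <- !grepl("^([a-z][a-z/]*|[^[:alnum:][:space:]])$", termination_tokens)
  if (any(bad)) {
    stop("termination tokens must be lowercase words or single punctuation ",
         "marks: ", paste(termination_tokens[bad], collapse = ", "),
         call. = FALSE)
  }
  cue_tokens <- lapply(history_cues, function(p) {
    tk <- strsplit(trimws(p), "[[:space:]]+")[[1]]
    if (!length(tk)) stop("empty history cue", call. = FALSE)
    tk
  })
  ord <- order(-lengths(cue_tokens), seq_along(cue_tokens))
  structure(
    list(negation_cues = unique(negation_cues),
         termination_tokens = unique(termination_tokens),
         history_cues = history_cues[ord],
         history_cue_tokens = cue_tokens[ord],
         faithful_table3 = isTRUE(faithful_table3)),
    class = "ipv_scoping"
  )
}

#' Load the packaged default scoping configuration
#'
#' The default mode excludes `"and"` from the termination tokens: the
#' reference behaviour for this ruleset negates across "and" ("... denies
#' drug, alcohol use and_neg intimate_neg partner_neg violence_neg"), even
#' though the published token table lists "and" as a terminator.
#' `faithful_table3 = TRUE` restores the verbatim table.
#'
#' @param faithful_table3 logical; keep `"and"` as a termination token.
#' @param path optional path to an alternative YAML config (keys
#'   `scoping$negation_cues`, `scoping$termination_tokens`,
#'   `scoping$history_cues`).
#' @return an [scoping_config()] object.
#' @export
load_scoping_config <- function(faithful_table3 = FALSE, path = NULL) {
  if (is.null(path)) path <- ipv_extdata("config.yaml")
  if (!file.exists(path)) {
    stop("scoping resource not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)$scoping
  if (is.null(cfg)) {
    stop("config ", path, " lacks a 'scoping' section", call. = FALSE)
  }
  term <- unlist(cfg$termination_tokens)
  if (!isTRUE(faithful_table3)) term <- setdiff(term, "and")
  scoping_config(
    negation_cues = unlist(cfg$negation_cues),
    termination_tokens = term,
    history_cues = unlist(cfg$history_cues),
    faithful_table3 = faithful_table3
  )
}

#' @export
print.ipv_scoping <- function(x, ...) {
  cat("<ipv_scoping> ", length(x$negation_cues), " negation cues, ",
      length(x$termination_tokens), " terminators, ",
      length(x$history_cues), " history cues",
      if (x$faithful_table3) " (faithful table mode)", "\n", sep = "")
  invisible(x)
}

# All word tokens used by a scoping config (for normalization protection).
scoping_protected_tokens <- function(scoping) {
  words <- c(scoping$negation_cues,
             grep("^[a-z]", scoping$termination_tokens, value = TRUE),
             unlist(scoping$history_cue_tokens))
  unique(words)
}
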