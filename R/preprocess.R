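# Tokenization and text normalization.
#
# Pipeline order is fixed: strip_template_blocks -> tokenize ->
# normalize_tokens -> mark_negation -> mark_history -> strip_punctuation ->
# match_terms. Punctuation must survive normalization because "." / "?" / "but"
# serve as scope terminators; it is removed only after history detection.

# Words, numbers, and slash-joined clinical abbreviations ("h/o", "h/x")
# become single tokens; every other non-space character is a punct token.
.token_rx <- "[A-Za-z0-9]+(?:/[A-Za-z0-9]+)*|[^A-Za-z0-9[:space:]]"

new_token_seq <- function(surface, note_id = NA_character_) {
  n <- length(surface)
  norm <- tolower(surface)
  kind <- rep("word", n)
  kind[grepl("^[0-9]+$", surface)] <- "number"
  kind[!grepl("[A-Za-z0-9]", surface)] <- "punct"
  structure(
    list(surface = surface, norm = norm, key = norm, kind = kind,
         removed = logical(n), negated = logical(n), in_history = logical(n),
         note_id = note_id),
    class = "ipv_tokens"
  )
}

#' Tokenize note text
#'
#' Splits text into word, number, and punctuation tokens; whitespace is
#' collapsed and discarded; original order is preserved. Slash-joined
#' clinical abbreviations ("h/o", "h/x") are kept as single word tokens so
#' the history cues of the scoping table can match.
#'
#' @param text a single string (possibly empty).
#' @param note_id optional identifier carried on the sequence.
#' @return an object of class `ipv_tokens`: parallel vectors `surface`,
#'   `norm` (lowercased surface), `key` (canonical matching form, filled by
#'   [normalize_tokens()]), `kind`, and the flags `removed`, `negated`,
#'   `in_history`.
#' @export
#' @examples
#' tokenize("assault by husband.")$surface
tokenize <- function(text, note_id = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(new_token_seq(character(), note_id))
  m <- gregexpr(.token_rx, text, perl = TRUE)
  new_token_seq(regmatches(text, m)[[1]], note_id)
}

#' @export
length.ipv_tokens <- function(x) length(x$surface)

#' @export
print.ipv_tokens <- function(x, ...) {
  cat("<ipv_tokens> ", length(x), " tokens (", sum(!x$removed),
      " surviving)\n", sep = "")
  if (length(x)) cat(" ", render_annotated(x), "\n", sep = "")
  invisible(x)
}

#' Canonical matching keys for word tokens
#'
#' Light rule-based stemming shared by note text and lexicon phrases: strips
#' one of the suffixes "ing"/"ed"/"s" (requiring a stem of at least three
#' characters, and not stripping "s" after "ss"), then a final "e" from
#' words longer than three characters. Both sides of a match pass through
#' the same function, so "assaulted"/"assault", "battered"/"batter",
#' "strangled"/"strangle" (-> "strangl") land on identical keys.
#'
#' @param words character vector of lowercase words.
#' @param suffixes ordered character vector of suffixes to try (first match
#'   wins).
#' @return character vector of keys.
#' @export
stem_keys <- function(words, suffixes = c("ing", "ed", "s")) {
  w <- words
  n <- nchar(w)
  done <- logical(length(w))
  for (suf in suffixes) {
    k <- nchar(suf)
    hit <- !done & n >= (3L + k) & endsWith(w, suf)
    if (suf == "s") hit <- hit & !endsWith(w, "ss")
    if (any(hit)) {
      w[hit] <- substr(w[hit], 1L, n[hit] - k)
      n[hit] <- n[hit] - k
      done <- done | hit
    }
  }
  efinal <- n > 3L & endsWith(w, "e")
  w[efinal] <- substr(w[efinal], 1L, n[efinal] - 1L)
  w
}

#' Construct a normalization configuration
#'
#' @param temporal_stopwords,preposition_stopwords,pronoun_stopwords
#'   stop-class word sets removed during normalization.
#' @param protected_words words never removed regardless of other rules
#'   (function words inside active lexicon phrases plus scoping cue /
#'   terminator words; see [default_pipeline_config()]).
#' @param min_word_length word tokens shorter than this are removed
#'   (default 2: "words with fewer than two characters").
#' @param stemming_suffixes passed to [stem_keys()].
#' @param template_patterns glob line patterns for
#'   [strip_template_blocks()].
#' @return object of class `ipv_norm_config`.
#' @export
normalization_config <- function(temporal_stopwords = character(),
                                 preposition_stopwords = character(),
                                 pronoun_stopwords = character(),
                                 protected_words = character(),
                                 min_word_length = 2L,
                                 stemming_suffixes = c("ing", "ed", "s"),
                                 template_patterns = character()) {
  min_word_length <- as.integer(min_word_length)
  if (is.na(min_word_length) || min_word_length < 1L) {
    stop("min_word_length must be >= 1", call. = FALSE)
  }
  structure(
    list(temporal_stopwords = tolower(temporal_stopwords),
         preposition_stopwords = tolower(preposition_stopwords),
         pronoun_stopwords = tolower(pronoun_stopwords),
         protected_words = tolower(protected_words),
         min_word_length = min_word_length,
         stemming_suffixes = stemming_suffixes,
         template_patterns = template_patterns),
    class = "ipv_norm_config"
  )
}

#' Load the packaged default normalization configuration
#'
#' Stop-class word lists (temporal, preposition, pronoun) and template
#' patterns ship as editable plain-text resources. `protected_words` is
#' empty here; [default_pipeline_config()] fills it from the active lexicons
#' and scoping config.
#'
#' @param path optional alternative YAML config (key `normalization`).
#' @param template_path optional alternative template-pattern file (one glob
#'   pattern per line).
#' @return an [normalization_config()] object.
#' @export
load_normalization_config <- function(path = NULL, template_path = NULL) {
  if (is.null(path)) path <- ipv_extdata("config.yaml")
  if (is.null(template_path)) template_path <- ipv_extdata("template_patterns.txt")
  cfg <- yaml::read_yaml(path)$normalization
  if (is.null(cfg)) {
    stop("config ", path, " lacks a 'normalization' section", call. = FALSE)
  }
  normalization_config(
    temporal_stopwords = unlist(cfg$temporal_stopwords),
    preposition_stopwords = unlist(cfg$preposition_stopwords),
    pronoun_stopwords = unlist(cfg$pronoun_stopwords),
    min_word_length = cfg$min_word_length %||% 2L,
    stemming_suffixes = unlist(cfg$stemming_suffixes) %||% c("ing", "ed", "s"),
    template_patterns = read_resource_lines(template_path)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Compile one template glob pattern to a regex; errors name the pattern.
template_pattern_rx <- function(pattern) {
  if (length(pattern) != 1L || is.na(pattern) || !nzchar(trimws(pattern))) {
    stop("invalid template pattern: ",
         if (length(pattern) == 1L) deparse(pattern) else "<not a string>",
         call. = FALSE)
  }
  glob2rx(trimws(pattern))
}

#' Remove auto-populated template lines from note text
#'
#' Lines matching any configured glob pattern (case-insensitive, after
#' trimming) are dropped before tokenization. Auto-populated screening
#' question blocks are removed whether completed or blank, so a pattern
#' should end in `*` to also catch filled answers.
#'
#' @param text note text (single string; lines separated by newlines).
#' @param patterns character vector of glob patterns (`*`, `?` wildcards).
#' @return the text with matching lines removed.
#' @export
#' @examples
#' strip_template_blocks("do you feel safe at home? no\nseen for laceration",
#'                       "do you feel safe at home*")
strip_template_blocks <- function(text, patterns) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text) || !length(patterns)) return(text)
  rx <- vapply(patterns, template_pattern_rx, "")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  trimmed <- trimws(lines)
  drop <- logical(length(lines))
  for (r in rx) {
    drop <- drop | grepl(r, trimmed, ignore.case = TRUE)
  }
  paste(lines[!drop], collapse = "\n")
}

#' Normalize a token sequence
#'
#' Applies the general and task-specific text normalization: lowercases all
#' tokens; marks as removed every number token, every word shorter than
#' `min_word_length`, and every temporal / preposition / pronoun stopword
#' not present in `protected_words`; computes stemmed matching keys
#' ([stem_keys()]) for surviving words. Punctuation tokens are retained:
#' they are needed later as scope terminators.
#'
#' Idempotent: all decisions are recomputed from the original surfaces.
#'
#' @param seq an [tokenize()]d `ipv_tokens` object.
#' @param cfg an [normalization_config()].
#' @return the annotated `ipv_tokens` object.
#' @export
#' @examples
#' cfg <- default_pipeline_config()$normalization
#' s <- normalize_tokens(tokenize("assaulted last night by her husband"), cfg)
#' s$key[!s$removed]
normalize_tokens <- function(seq, cfg) {
  stopifnot(inherits(seq, "ipv_tokens"), inherits(cfg, "ipv_norm_config"))
  n <- length(seq)
  if (!n) return(seq)
  norm <- tolower(seq$surface)
  seq$norm <- norm
  removed <- logical(n)
  word <- seq$kind == "word"
  removed[seq$kind == "number"] <- TRUE
  stopset <- c(cfg$temporal_stopwords, cfg$preposition_stopwords,
               cfg$pronoun_stopwords)
  protected <- norm %in% cfg$protected_words
  removed[word & !protected &
            (nchar(norm) < cfg$min_word_length | norm %in% stopset)] <- TRUE
  seq$removed <- removed
  key <- norm
  key[word] <- stem_keys(norm[word], cfg$stemming_suffixes)
  seq$key <- key
  seq
}

#' Remove punctuation tokens
#'
#' Marks punctuation tokens as removed. Run after negation and history
#' marking (punctuation serves as scope terminators until then); word
#' annotations are untouched.
#'
#' @param seq an `ipv_tokens` object with scoping already applied.
#' @return the `ipv_tokens` object with punct tokens removed.
#' @export
strip_punctuation <- function(seq) {
  stopifnot(inherits(seq, "ipv_tokens"))
  seq$removed[seq$kind == "punct"] <- TRUE
  seq
}
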