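# Encounter classification: lexicon phrase matching over annotated tokens,
# ICD code matching over structured fields, and the three approaches.

#' Bundle the rule resources for classification
#'
#' Loads the packaged code set, both term lexicons (plus their union for the
#' extended approach), the scoping configuration, and the normalization
#' configuration with its protected-word set filled in from the active
#' lexicons and the scoping tokens.
#'
#' @param faithful_table3 passed to [load_scoping_config()].
#' @param situational,extended optional replacement [term_lexicon()]s.
#' @param strip_templates logical; remove auto-populated screening-template
#'   lines before tokenization (default TRUE).
#' @return object of class `ipv_resources` with elements `codes`,
#'   `situational`, `extended`, `combined`, `scoping`, `normalization`.
#' @export
#' @examples
#' res <- ipv_resources()
#' length(res$combined) # 71 unique phrases
ipv_resources <- function(faithful_table3 = FALSE,
                          situational = load_default_lexicon("situational"),
                          extended = load_default_lexicon("extended"),
                          strip_templates = TRUE) {
  scoping <- load_scoping_config(faithful_table3)
  combined <- combined_lexicon(situational, extended)
  norm <- load_normalization_config()
  norm$protected_words <- unique(c(
    protected_function_words(combined),
    scoping_protected_tokens(scoping)
  ))
  if (!strip_templates) norm$template_patterns <- character()
  structure(
    list(codes = load_default_codes(), situational = situational,
         extended = extended, combined = combined, scoping = scoping,
         normalization = norm),
    class = "ipv_resources"
  )
}

#' Pipeline configuration pieces with protection wired in
#'
#' Convenience accessor returning the scoping and normalization configs of a
#' default [ipv_resources()] bundle.
#'
#' @param resources an `ipv_resources` bundle (default: packaged defaults).
#' @return list with elements `scoping` and `normalization`.
#' @export
default_pipeline_config <- function(resources = ipv_resources()) {
  list(scoping = resources$scoping, normalization = resources$normalization)
}

#' @export
print.ipv_resources <- function(x, ...) {
  cat("<ipv_resources>\n")
  cat("  codes:       ", length(x$codes$icd9), " ICD-9 + ",
      length(x$codes$icd10), " ICD-10\n", sep = "")
  cat("  lexicons:    ", length(x$situational), " situational + ",
      length(x$extended), " extended (", length(x$combined),
      " combined)\n", sep = "")
  cat("  scoping:     ", length(x$scoping$negation_cues), " cues / ",
      length(x$scoping$termination_tokens), " terminators / ",
      length(x$scoping$history_cues), " history cues\n", sep = "")
  invisible(x)
}

#' Run the full note-annotation pipeline on raw text
#'
#' Template-line stripping, tokenization, normalization, negation marking,
#' history marking, and (optionally) punctuation removal, in that fixed
#' order. Punctuation removal happens after history detection because
#' punctuation terminates scopes.
#'
#' @param text raw note text.
#' @param resources an [ipv_resources()] bundle.
#' @param keep_punctuation keep punctuation tokens (useful with
#'   [render_annotated()]); matching requires them stripped.
#' @param note_id identifier carried on the sequence.
#' @return an annotated `ipv_tokens` object.
#' @export
#' @examples
#' res <- ipv_resources()
#' render_annotated(annotate_note("pt denies domestic violence.", res,
#'                                keep_punctuation = TRUE))
annotate_note <- function(text, resources = ipv_resources(),
                          keep_punctuation = FALSE,
                          note_id = NA_character_) {
  stopifnot(inherits(resources, "ipv_resources"))
  text <- strip_template_blocks(text, resources$normalization$template_patterns)
  seq <- tokenize(text, note_id = note_id)
  seq <- normalize_tokens(seq, resources$normalization)
  seq <- mark_negation(seq, resources$scoping)
  seq <- mark_history(seq, resources$scoping)
  if (!keep_punctuation) seq <- strip_punctuation(seq)
  seq
}

#' Match lexicon phrases against an annotated token sequence
#'
#' Finds every contiguous occurrence, over the surviving (non-removed,
#' non-punctuation) tokens, of any lexicon phrase all of whose tokens are
#' unflagged (neither negated nor in a history scope). Matching is on the
#' stemmed keys; overlapping matches are all reported.
#'
#' @param seq a fully preprocessed and scoped `ipv_tokens` object.
#' @param lexicon an [term_lexicon()].
#' @return data frame with columns `phrase`, `tier`, `note_id`, `start`,
#'   `end` (token positions in the original sequence).
#' @export
match_terms <- function(seq, lexicon) {
  stopifnot(inherits(seq, "ipv_tokens"), inherits(lexicon, "ipv_lexicon"))
  alive <- which(!seq$removed & seq$kind != "punct")
  empty <- data.frame(phrase = character(), tier = character(),
                      note_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (!length(alive) || !length(lexicon)) return(empty)
  keys <- seq$key[alive]
  ok <- !seq$negated[alive] & !seq$in_history[alive]
  m <- length(keys)
  hits <- list()
  for (p in seq_along(lexicon$keys)) {
    kp <- lexicon$keys[[p]]
    L <- length(kp)
    starts <- which(keys == kp[1L])
    starts <- starts[starts + L - 1L <= m]
    for (s in starts) {
      span <- s:(s + L - 1L)
      if (all(keys[span] == kp) && all(ok[span])) {
        hits[[length(hits) + 1L]] <- data.frame(
          phrase = lexicon$phrases[p], tier = lexicon$tier,
          note_id = seq$note_id %||% NA_character_,
          start = alive[s], end = alive[s + L - 1L],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(hits)) return(empty)
  do.call(rbind, hits)
}

#' Match diagnosis codes against a code set
#'
#' Codes are normalized (uppercase, dot stripped) and tested against the
#' revision set named by their tag, or against both sets when no tag is
#' supplied. Unparseable code strings are skipped with a warning.
#'
#' @param codes character vector of raw code strings.
#' @param codeset an [code_set()].
#' @param revisions optional character vector of tags (`"icd9"`/`"icd10"`,
#'   `"9"`/`"10"` accepted), recycled along `codes`.
#' @return character vector of the matched, normalized codes.
#' @export
#' @examples
#' match_icd(c("T76.21XA", "I10"), load_default_codes())
match_icd <- function(codes, codeset, revisions = NULL) {
  stopifnot(inherits(codeset, "ipv_code_set"))
  codes <- as.character(codes)
  if (!length(codes)) return(character())
  norm <- normalize_code(codes)
  parseable <- !is.na(norm) & grepl("^[A-Z0-9]+$", norm)
  if (any(!parseable)) {
    warning("skipping unparseable diagnosis code(s): ",
            paste(unique(codes[!parseable]), collapse = ", "), call. = FALSE)
    norm <- norm[parseable]
    if (!is.null(revisions)) revisions <- revisions[parseable]
  }
  if (is.null(revisions)) {
    return(norm[norm %in% c(codeset$icd9, codeset$icd10)])
  }
  rev <- tolower(as.character(revisions))
  rev[rev %in% c("9", "icd-9")] <- "icd9"
  rev[rev %in% c("10", "icd-10")] <- "icd10"
  hit <- (rev == "icd9" & norm %in% codeset$icd9) |
    (rev == "icd10" & norm %in% codeset$icd10) |
    (!rev %in% c("icd9", "icd10") &
       norm %in% c(codeset$icd9, codeset$icd10))
  norm[hit]
}

#' Construct an encounter record
#'
#' @param encounter_id,patient_id identifiers.
#' @param visit_date visit date (`Date` or `"YYYY-MM-DD"` string).
#' @param diagnosis_codes data frame with columns `code` and `revision`
#'   (may have zero rows).
#' @param notes data frame with columns `note_id`, `author_role`
#'   (`physician_app`, `nursing`, `social_work`, or `other`), `text`.
#'   The chief-complaint field, when present, is simply one more note with
#'   `author_role = "other"`.
#' @return object of class `ipv_encounter`.
#' @export
encounter <- function(encounter_id, patient_id, visit_date,
                      diagnosis_codes = NULL, notes = NULL) {
  if (is.null(diagnosis_codes) || !NROW(diagnosis_codes)) {
    diagnosis_codes <- data.frame(code = character(), revision = character(),
                                  stringsAsFactors = FALSE)
  }
  if (is.null(notes) || !NROW(notes)) {
    notes <- data.frame(note_id = character(), author_role = character(),
                        text = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("code", "revision") %in% names(diagnosis_codes)),
            all(c("note_id", "author_role", "text") %in% names(notes)))
  if (anyDuplicated(notes$note_id)) {
    stop("note_id values must be unique within an encounter ",
         encounter_id, call. = FALSE)
  }
  visit_date <- as.Date(visit_date)
  if (is.na(visit_date)) stop("unparseable visit_date for encounter ",
                              encounter_id, call. = FALSE)
  structure(
    list(encounter_id = as.character(encounter_id),
         patient_id = as.character(patient_id),
         visit_date = visit_date,
         diagnosis_codes = diagnosis_codes,
         notes = notes),
    class = "ipv_encounter"
  )
}

#' Classify a single encounter
#'
#' * `approach = "icd"`: positive iff at least one diagnosis code is in the
#'   IPV code set.
#' * `approach = "situational"`: positive iff any note yields a situational
#'   term match after preprocessing and scope suppression.
#' * `approach = "extended"`: as situational, but against the union of the
#'   situational and extended lexicons.
#'
#' @param enc an [encounter()].
#' @param approach `"icd"`, `"situational"`, or `"extended"`.
#' @param resources an [ipv_resources()] bundle.
#' @return object of class `ipv_result`: `encounter_id`, `approach`,
#'   `label` (logical, true iff evidence non-empty), and `evidence` (matched
#'   codes, or a data frame of term matches).
#' @export
classify_encounter <- function(enc, approach = c("icd", "situational",
                                                 "extended"),
                               resources = ipv_resources()) {
  stopifnot(inherits(enc, "ipv_encounter"),
            inherits(resources, "ipv_resources"))
  approach <- match.arg(approach)
  if (approach == "icd") {
    matched <- match_icd(enc$diagnosis_codes$code, resources$codes,
                         revisions = enc$diagnosis_codes$revision)
    evidence <- matched
    label <- length(matched) > 0L
  } else {
    lex <- if (approach == "situational") resources$situational
           else resources$combined
    hits <- list()
    for (i in seq_len(nrow(enc$notes))) {
      txt <- enc$notes$text[i]
      if (is.na(txt) || !nzchar(txt)) next
      seq <- annotate_note(txt, resources,
                           note_id = enc$notes$note_id[i])
      h <- match_terms(seq, lex)
      if (nrow(h)) hits[[length(hits) + 1L]] <- h
    }
    evidence <- if (length(hits)) do.call(rbind, hits) else
      data.frame(phrase = character(), tier = character(),
                 note_id = character(), start = integer(), end = integer(),
                 stringsAsFactors = FALSE)
    label <- nrow(evidence) > 0L
  }
  structure(
    list(encounter_id = enc$encounter_id, approach = approach,
         label = label, evidence = evidence),
    class = "ipv_result"
  )
}

#' Classify a corpus of encounters
#'
#' @param encounters list of [encounter()] objects (unique `encounter_id`s;
#'   duplicates are a hard error naming the id).
#' @param approach passed to [classify_encounter()].
#' @param resources an [ipv_resources()] bundle.
#' @param progress print a dot every 200 encounters.
#' @return list with `results` (data frame: `encounter_id`, `patient_id`,
#'   `visit_date`, `approach`, `label`, `n_evidence`, `evidence` summary
#'   string) and `summary` (`n_encounters`, `n_positive`,
#'   `n_patients_positive`).
#' @export
classify_corpus <- function(encounters, approach = c("icd", "situational",
                                                     "extended"),
                            resources = ipv_resources(), progress = FALSE) {
  approach <- match.arg(approach)
  ids <- vapply(encounters, function(e) e$encounter_id, "")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate encounter_id in corpus: ", dup[1L], call. = FALSE)
  }
  n <- length(encounters)
  label <- logical(n)
  n_ev <- integer(n)
  ev_str <- character(n)
  pid <- character(n)
  vdate <- character(n)
  for (i in seq_len(n)) {
    enc <- encounters[[i]]
    r <- classify_encounter(enc, approach, resources)
    label[i] <- r$label
    if (approach == "icd") {
      n_ev[i] <- length(r$evidence)
      ev_str[i] <- paste(r$evidence, collapse = ";")
    } else {
      n_ev[i] <- nrow(r$evidence)
      ev_str[i] <- paste(unique(paste0(r$evidence$phrase, "@",
                                       r$evidence$note_id)), collapse = ";")
    }
    pid[i] <- enc$patient_id
    vdate[i] <- format(enc$visit_date)
    if (progress && i %% 200L == 0L) cat(".")
  }
  if (progress && n >= 200L) cat("\n")
  results <- data.frame(
    encounter_id = ids, patient_id = pid, visit_date = vdate,
    approach = rep(approach, n), label = label, n_evidence = n_ev,
    evidence = ev_str, stringsAsFactors = FALSE
  )
  summary <- structure(
    list(approach = approach, n_encounters = n, n_positive = sum(label),
         n_patients_positive = length(unique(pid[label]))),
    class = "ipv_corpus_summary"
  )
  list(results = results, summary = summary)
}

#' @export
print.ipv_corpus_summary <- function(x, ...) {
  cat("IPV classification summary (approach: ", x$approach, ")\n", sep = "")
  cat("  encounters:          ", x$n_encounters, "\n", sep = "")
  cat("  positive encounters: ", x$n_positive, "\n", sep = "")
  cat("  positive patients:   ", x$n_patients_positive, "\n", sep = "")
  invisible(x)
}

#' @export
print.ipv_result <- function(x, ...) {
  cat("<ipv_result> ", x$encounter_id, " [", x$approach, "] label=",
      x$label, "\n", sep = "")
  invisible(x)
}
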