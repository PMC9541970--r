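# Synthetic labelled corpus generator.
#
# Emulates the text phenomena the detector must handle: in-lexicon IPV
# phrases wrapped in temporal/possessive filler, negated mentions, history
# mentions, auto-populated screening-template blocks, distractor notes, and
# under-coded ICD fields. Every positive phrasing is machine-recoverable by
# construction (fillers inserted inside phrases are stop-class words the
# normalizer strips), which is what makes closed-loop testing possible.

.verb_heads <- c("assault", "attack", "strike", "strangle")

#' Generator parameters
#'
#' @param n_encounters number of encounters (>= 1).
#' @param prevalence fraction of truth-positive encounters in `[0, 1]`;
#'   allocation is exact (`round(prevalence * n)`), then shuffled.
#' @param negated_mention_rate probability a negative encounter contains a
#'   negated IPV mention ("patient denies domestic violence.").
#' @param history_mention_rate probability a negative encounter contains a
#'   history-of-IPV mention ("hx of ipv, resolved.").
#' @param template_block_rate probability an encounter carries an
#'   auto-populated screening-question block (completed or blank).
#' @param distractor_rate probability a negative encounter contains a
#'   distractor sentence (e.g. "domestic dispute between mother and child",
#'   "ipv vaccine administered") — deliberate false-positive bait.
#' @param icd_coding_rate probability a truth-positive encounter also
#'   carries an IPV diagnosis code; the default 0.013 reflects how rarely
#'   note-identified encounters are also ICD-coded.
#' @param notes_per_encounter integer range `c(min, max)` of notes per
#'   encounter.
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return object of class `ipv_synth_params`.
#' @export
synth_params <- function(n_encounters = 1000L, prevalence = 0.1,
                         negated_mention_rate = 0.15,
                         history_mention_rate = 0.10,
                         template_block_rate = 0.10,
                         distractor_rate = 0.05,
                         icd_coding_rate = 0.013,
                         notes_per_encounter = c(1L, 3L),
                         seed = 1L) {
  n_encounters <- as.integer(n_encounters)
  if (is.na(n_encounters) || n_encounters < 1L) {
    stop("n_encounters must be a positive integer", call. = FALSE)
  }
  fr <- c(prevalence = prevalence,
          negated_mention_rate = negated_mention_rate,
          history_mention_rate = history_mention_rate,
          template_block_rate = template_block_rate,
          distractor_rate = distractor_rate,
          icd_coding_rate = icd_coding_rate)
  bad <- is.na(fr) | fr < 0 | fr > 1
  if (any(bad)) {
    stop("rates must be fractions in [0, 1]: ",
         paste(names(fr)[bad], collapse = ", "), call. = FALSE)
  }
  notes_per_encounter <- as.integer(notes_per_encounter)
  if (length(notes_per_encounter) == 1L) {
    notes_per_encounter <- rep(notes_per_encounter, 2L)
  }
  if (any(is.na(notes_per_encounter)) || notes_per_encounter[1L] < 1L ||
      notes_per_encounter[2L] < notes_per_encounter[1L]) {
    stop("notes_per_encounter must be an increasing positive range",
         call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  structure(
    c(as.list(fr),
      list(n_encounters = n_encounters,
           notes_per_encounter = notes_per_encounter, seed = seed)),
    class = "ipv_synth_params"
  )
}

#' @export
print.ipv_synth_params <- function(x, ...) {
  cat("<ipv_synth_params> n=", x$n_encounters, ", prevalence=",
      x$prevalence, ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

load_synth_bank <- function() {
  yaml::read_yaml(ipv_extdata("synth_bank.yaml"))
}

#' Realize a lexicon phrase as note text
#'
#' * `"plain"`: the phrase verbatim.
#' * `"inflected"`: the head verb (assault/attack/strike/strangle) is
#'   regularly inflected ("assault" -> "assaulted", "strangle" ->
#'   "strangled"); phrases without a verb head are returned unchanged.
#' * `"temporal_possessive"`: temporal and possessive filler that the
#'   normalizer strips is inserted inside the phrase ("assault by husband"
#'   -> "assault last night by her husband"); phrases without a "by" slot
#'   get the temporal filler appended.
#'
#' Styles combine: `c("inflected", "temporal_possessive")` yields
#' "assaulted last night by her husband".
#'
#' @param phrase a phrase from an active lexicon.
#' @param style character vector drawn from
#'   `c("plain", "inflected", "temporal_possessive")`.
#' @param temporal,possessive filler strings (must be stop-class words).
#' @return the realized string; guaranteed to normalize back to the phrase.
#' @export
#' @examples
#' phrase_realizer("assault by husband",
#'                 c("inflected", "temporal_possessive"))
phrase_realizer <- function(phrase, style = "plain",
                            temporal = "last night", possessive = "her") {
  ok <- c("plain", "inflected", "temporal_possessive")
  if (!length(style) || !all(style %in% ok)) {
    stop("style must be drawn from: ", paste(ok, collapse = ", "),
         call. = FALSE)
  }
  tokens <- strsplit(trimws(phrase), "[[:space:]]+")[[1]]
  if ("inflected" %in% style && tokens[1L] %in% .verb_heads) {
    head <- tokens[1L]
    tokens[1L] <- if (endsWith(head, "e")) paste0(head, "d")
                  else paste0(head, "ed")
  }
  if ("temporal_possessive" %in% style) {
    if (length(tokens) >= 3L && tokens[2L] == "by") {
      tokens <- c(tokens[1L], strsplit(temporal, " ")[[1L]], "by",
                  possessive, tokens[-(1:2)])
    } else {
      tokens <- c(tokens, strsplit(temporal, " ")[[1L]])
    }
  }
  paste(tokens, collapse = " ")
}

# One benign sentence (no IPV vocabulary).
benign_sentence <- function(bank) sample(bank$benign_sentences, 1L)

synth_note <- function(note_id, role, text) {
  data.frame(note_id = note_id, author_role = role, text = text,
             stringsAsFactors = FALSE)
}

sample_code <- function(pool, date) {
  rev <- if (date < as.Date("2015-10-01")) "icd9" else "icd10"
  cand <- Filter(function(x) x$revision == rev, pool)
  pick <- cand[[sample.int(length(cand), 1L)]]
  data.frame(code = pick$code, revision = pick$revision,
             stringsAsFactors = FALSE)
}

#' Generate a labelled synthetic encounter corpus
#'
#' Exactly `round(prevalence * n)` encounters are truth-positive; each
#' embeds a uniformly chosen phrase from the active combined lexicon,
#' realized in one of the [phrase_realizer()] styles and surrounded by
#' benign clinical filler. Negative encounters may contain negated
#' mentions, history mentions, screening-template blocks, or distractor
#' sentences at the configured rates. Truth-positive encounters carry an
#' IPV diagnosis code with probability `icd_coding_rate` (ICD-9 before
#' October 2015, ICD-10 after, matching the visit date); all encounters
#' carry benign codes.
#'
#' @param params an [synth_params()] object.
#' @param resources an [ipv_resources()] bundle supplying the active
#'   lexicons.
#' @return list with `encounters` (list of [encounter()]) and `truth`
#'   (data frame: `encounter_id`, `patient_id`, `is_ipv`, `phenomena`
#'   comma-joined tag set, `phrase`).
#' @export
#' @examples
#' corpus <- generate_corpus(synth_params(n_encounters = 20, seed = 7))
#' sum(corpus$truth$is_ipv)
generate_corpus <- function(params, resources = ipv_resources()) {
  stopifnot(inherits(params, "ipv_synth_params"),
            inherits(resources, "ipv_resources"))
  bank <- load_synth_bank()
  phrases <- resources$combined$phrases
  if (!length(phrases)) stop("active lexicon is empty", call. = FALSE)
  n <- params$n_encounters
  n_pos <- round(params$prevalence * n)
  roles <- c("physician_app", "nursing", "social_work", "other")
  styles <- list("plain", "inflected", "temporal_possessive",
                 c("inflected", "temporal_possessive"))
  date0 <- as.Date("2012-01-01")
  date_span <- as.integer(as.Date("2020-08-31") - date0) + 1L

  with_seed(params$seed, {
    is_pos <- c(rep(TRUE, n_pos), rep(FALSE, n - n_pos))[sample.int(n)]
    n_pat <- max(1L, round(0.85 * n))
    pid <- sprintf("P%05d", sample.int(n_pat, n, replace = TRUE))
    dates <- date0 + (sample.int(date_span, n, replace = TRUE) - 1L)
    encounters <- vector("list", n)
    truth_phen <- character(n)
    truth_phrase <- rep(NA_character_, n)

    for (i in seq_len(n)) {
      eid <- sprintf("E%06d", i)
      rng <- params$notes_per_encounter
      n_notes <- if (rng[1L] == rng[2L]) rng[1L] else
        sample(seq(rng[1L], rng[2L]), 1L)
      note_texts <- vapply(seq_len(n_notes), function(k) {
        paste0(benign_sentence(bank), ". ", benign_sentence(bank), ".")
      }, "")
      phen <- character()
      codes <- sample_code(bank$benign_codes, dates[i])

      if (is_pos[i]) {
        phrase <- sample(phrases, 1L)
        realized <- phrase_realizer(
          phrase, styles[[sample.int(length(styles), 1L)]],
          temporal = sample(bank$temporal_fillers, 1L),
          possessive = sample(bank$possessives, 1L)
        )
        sentence <- trimws(paste(sample(bank$positive_prefixes, 1L),
                                 realized,
                                 sample(bank$positive_suffixes, 1L)))
        slot <- sample.int(n_notes, 1L)
        note_texts[slot] <- paste0(sentence, ". ", benign_sentence(bank), ".")
        phen <- "positive_phrase"
        truth_phrase[i] <- phrase
        if (runif(1L) < params$icd_coding_rate) {
          codes <- rbind(codes, sample_code(bank$ipv_codes, dates[i]))
          phen <- c(phen, "icd_coded")
        }
      } else {
        if (runif(1L) < params$negated_mention_rate) {
          slot <- sample.int(n_notes, 1L)
          note_texts[slot] <- paste(note_texts[slot],
                                    sample(bank$negated_sentences, 1L))
          phen <- c(phen, "negated")
        }
        if (runif(1L) < params$history_mention_rate) {
          slot <- sample.int(n_notes, 1L)
          note_texts[slot] <- paste(note_texts[slot],
                                    sample(bank$history_sentences, 1L))
          phen <- c(phen, "history")
        }
        if (runif(1L) < params$distractor_rate) {
          slot <- sample.int(n_notes, 1L)
          note_texts[slot] <- paste0(note_texts[slot], " ",
                                     sample(bank$distractor_sentences, 1L),
                                     ".")
          phen <- c(phen, "distractor")
        }
      }
      if (runif(1L) < params$template_block_rate) {
        block <- bank$template_blocks[[
          sample.int(length(bank$template_blocks), 1L)]]
        line <- sample(unlist(block$lines), 1L)
        slot <- sample.int(n_notes, 1L)
        note_texts[slot] <- paste(note_texts[slot], line, sep = "\n")
        phen <- c(phen, "template")
      }

      notes <- do.call(rbind, lapply(seq_len(n_notes), function(k) {
        synth_note(sprintf("%s-N%02d", eid, k), sample(roles, 1L),
                   note_texts[k])
      }))
      encounters[[i]] <- encounter(eid, pid[i], dates[i],
                                   diagnosis_codes = codes, notes = notes)
      truth_phen[i] <- paste(phen, collapse = ",")
    }

    truth <- data.frame(
      encounter_id = vapply(encounters, function(e) e$encounter_id, ""),
      patient_id = pid,
      is_ipv = is_pos,
      phenomena = truth_phen,
      phrase = truth_phrase,
      stringsAsFactors = FALSE
    )
    list(encounters = encounters, truth = truth)
  })
}
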