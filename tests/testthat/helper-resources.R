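# Shared fixtures, built in code. The resource bundle is loaded once per
# test run; tests that need modified resources construct their own.

.res <- ipv_resources()
.res_faithful <- ipv_resources(faithful_table3 = TRUE)

# Build a token sequence directly from lowercase token strings (words and
# single-character punctuation), bypassing tokenize(), for scoping tests.
make_seq <- function(tokens, removed = NULL) {
  seq <- ipvdetect::tokenize(paste(tokens, collapse = " "))
  if (!is.null(removed)) seq$removed <- removed
  seq
}

# Brute-force negation oracle: a word token j is negated iff there exists a
# surviving cue token c < j with no surviving terminator strictly between
# c and j (checked pairwise, independent of the scanning implementation).
oracle_negation <- function(seq, cfg) {
  n <- length(seq)
  flags <- logical(n)
  if (!n) return(flags)
  alive <- !seq$removed
  cue <- which(alive & seq$kind == "word" & seq$norm %in% cfg$negation_cues)
  term <- which(alive & seq$norm %in% cfg$termination_tokens)
  for (j in seq_len(n)) {
    # a token that is itself a terminator ends the scope before it is reached
    if (!alive[j] || seq$kind[j] != "word" || j %in% term) next
    for (c in cue) {
      if (c < j && !any(term > c & term < j)) flags[j] <- TRUE
    }
  }
  flags
}

# Brute-force history oracle: longest-first cue scan done independently on
# the surviving word norms, then pairwise "no terminator between" check.
oracle_history <- function(seq, cfg) {
  n <- length(seq)
  flags <- logical(n)
  alive_w <- which(!seq$removed & seq$kind == "word")
  if (!length(alive_w)) return(flags)
  norms <- seq$norm[alive_w]
  punct_alive <- which(!seq$removed & seq$kind == "punct")
  term <- which(!seq$removed & seq$norm %in% cfg$termination_tokens)
  cue_ends <- integer()
  i <- 1L
  while (i <= length(alive_w)) {
    hit <- 0L
    for (cue in cfg$history_cue_tokens) {
      L <- length(cue)
      if (i + L - 1L <= length(norms) &&
          identical(norms[i:(i + L - 1L)], cue) &&
          !any(punct_alive > alive_w[i] & punct_alive < alive_w[i + L - 1L])) {
        hit <- L
        break
      }
    }
    if (hit) {
      cue_ends <- c(cue_ends, alive_w[i + hit - 1L])
      i <- i + hit
    } else {
      i <- i + 1L
    }
  }
  for (j in seq_len(n)) {
    if (seq$removed[j] || seq$kind[j] != "word") next
    for (ce in cue_ends) {
      if (ce < j && !any(term > ce & term < j) && !(j %in% term)) {
        flags[j] <- TRUE
      }
    }
  }
  flags
}

# Random token sequence over a small alphabet mixing cues, terminators,
# history cue pieces, punctuation, and ordinary words.
random_scope_seq <- function(max_len = 30L) {
  vocab <- c("denies", "no", "not", "pain", "assault", "alcohol", "use",
             "but", "and", "reports", "history", "of", "hx", "h/o", "ho",
             "ipv", "violence", ".", "?", ",", ";", "word")
  n <- sample.int(max_len, 1L)
  make_seq(sample(vocab, n, replace = TRUE))
}

# A hand-built encounter with a single note.
note_encounter <- function(text, id = "E1", patient = "P1",
                           date = "2019-06-01", codes = NULL) {
  encounter(id, patient, date, diagnosis_codes = codes,
            notes = data.frame(note_id = paste0(id, "-N1"),
                               author_role = "other", text = text,
                               stringsAsFactors = FALSE))
}
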