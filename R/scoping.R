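# Negation and history scoping (simplified NegEx).
#
# A cue opens a scope that runs to the next termination token or to the end
# of the sequence; every surviving word token inside the scope is flagged.
# Scopes from multiple cues may overlap (flags are a union); there are no
# backward scopes and no pseudo-negation phrases.

# Indices of surviving terminator tokens (words or punctuation).
terminator_positions <- function(seq, cfg) {
  which(!seq$removed & seq$norm %in% cfg$termination_tokens)
}

flag_scope <- function(seq, field, from, to) {
  if (to < from) return(seq)
  idx <- from:to
  idx <- idx[!seq$removed[idx] & seq$kind[idx] == "word"]
  seq[[field]][idx] <- TRUE
  seq
}

#' Mark negated tokens
#'
#' For each surviving negation cue ("denies", "no", "without", ...), every
#' surviving word token strictly after the cue and before the next
#' termination token (or the end of the sequence) is flagged
#' `negated = TRUE`. The cue itself is never flagged by its own scope.
#' Deterministic and insensitive to cue processing order.
#'
#' @param seq a normalized `ipv_tokens` object (punctuation still present).
#' @param cfg an [scoping_config()].
#' @return the `ipv_tokens` object with `negated` flags set.
#' @export
#' @examples
#' cfg <- load_scoping_config()
#' s <- annotate_note("patient denies domestic violence.")
#' s$negated[!s$removed]
mark_negation <- function(seq, cfg) {
  stopifnot(inherits(seq, "ipv_tokens"), inherits(cfg, "ipv_scoping"))
  n <- length(seq)
  if (!n) return(seq)
  cues <- which(!seq$removed & seq$kind == "word" &
                  seq$norm %in% cfg$negation_cues)
  if (!length(cues)) return(seq)
  terms <- terminator_positions(seq, cfg)
  for (cue in cues) {
    nxt <- terms[terms > cue]
    end <- if (length(nxt)) nxt[1L] - 1L else n
    seq <- flag_scope(seq, "negated", cue + 1L, end)
  }
  seq
}

#' Mark history-of-IPV tokens
#'
#' History cue phrases ("history of", "hx of", "h/o", ...) are matched
#' longest-first over the surviving word tokens; every surviving word token
#' after a matched cue, up to the next termination token (or sequence end),
#' is flagged `in_history = TRUE`. The history scope reuses the negation
#' termination set, so "history of ipv ... but not currently" ends at
#' "but". Negation and history flags are independent.
#'
#' @inheritParams mark_negation
#' @return the `ipv_tokens` object with `in_history` flags set.
#' @export
mark_history <- function(seq, cfg) {
  stopifnot(inherits(seq, "ipv_tokens"), inherits(cfg, "ipv_scoping"))
  n <- length(seq)
  if (!n) return(seq)
  alive <- which(!seq$removed & seq$kind == "word")
  if (!length(alive)) return(seq)
  norms <- seq$norm[alive]
  punct_alive <- !seq$removed & seq$kind == "punct"
  terms <- terminator_positions(seq, cfg)
  m <- length(alive)
  i <- 1L
  while (i <= m) {
    matched <- 0L
    for (cue in cfg$history_cue_tokens) {
      L <- length(cue)
      if (i + L - 1L <= m && all(norms[i:(i + L - 1L)] == cue)) {
        # a surviving punctuation token inside the cue span breaks the match
        span <- alive[i]:alive[i + L - 1L]
        if (!any(punct_alive[span])) {
          matched <- L
          break
        }
      }
    }
    if (matched > 0L) {
      cue_end <- alive[i + matched - 1L]
      nxt <- terms[terms > cue_end]
      end <- if (length(nxt)) nxt[1L] - 1L else n
      seq <- flag_scope(seq, "in_history", cue_end + 1L, end)
      i <- i + matched
    } else {
      i <- i + 1L
    }
  }
  seq
}

#' Render an annotated sequence as a debug string
#'
#' Surviving tokens are joined with spaces; punctuation re-attaches to the
#' preceding token. Negated words get a `_neg` suffix and history words a
#' `_hx` suffix (in that order when both flags are set). The rendering uses
#' lowercased surfaces, not stemmed keys, matching the reference dialect
#' ("patient denies drug_neg, alcohol_neg use_neg ...").
#'
#' @param seq an `ipv_tokens` object.
#' @return a single string.
#' @export
#' @examples
#' render_annotated(annotate_note("patient denies domestic violence."))
render_annotated <- function(seq) {
  stopifnot(inherits(seq, "ipv_tokens"))
  out <- character()
  for (i in seq_len(length(seq))) {
    if (seq$removed[i]) next
    if (seq$kind[i] == "punct") {
      if (length(out)) {
        out[length(out)] <- paste0(out[length(out)], seq$norm[i])
      } else {
        out <- seq$norm[i]
      }
    } else {
      s <- seq$norm[i]
      if (seq$negated[i]) s <- paste0(s, "_neg")
      if (seq$in_history[i]) s <- paste0(s, "_hx")
      out <- c(out, s)
    }
  }
  paste(out, collapse = " ")
}
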