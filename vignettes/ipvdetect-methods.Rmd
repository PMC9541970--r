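---
title: "Methods: rule-based IPV phenotyping of ED notes"
author: "ipvdetect authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based IPV phenotyping of ED notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipvdetect)
```

## The problem and the model

Intimate partner violence (IPV) is systematically under-captured in
structured emergency-department (ED) data: clinicians document the
circumstances of a visit in free text far more often than they assign an
IPV diagnosis code, and IPV-related codes are sometimes applied to non-IPV
encounters (e.g. elder abuse). `ipvdetect` therefore implements a purely
rule-based, note-level phenotype with three nested evidence tiers:

* **ICD tier** — set membership of the encounter's diagnosis codes in a
  fixed IPV code set (7 unique ICD-9 codes and 9 ICD-10 codes covering
  adult physical/sexual/emotional abuse, perpetrator, and
  asphyxiation/strangulation). Codes are compared uppercased with the dot
  stripped, since EHR exports vary in dot usage. Revision tags on codes,
  when present, select the revision set; the visit date is deliberately
  *not* used to gate revisions, because revision tags travel with the code
  while date-based switching assumes a clean cut-over.
* **Situational tier** — 23 phrases describing IPV situations, matched in
  any note of the encounter.
* **Extended tier** — the union of the situational phrases with 49
  mechanism-specific phrases (strangle/strike/attack/assault "by
  <partner>", plus abbreviations "ipv"/"dv" and lethality terms), 71
  unique phrases. One phrase ("violence against women") belongs to both
  tiers and is deduplicated on union, which is also why
  situational-positive always implies extended-positive (tier
  monotonicity).

An encounter is positive under a tier iff at least one note contains at
least one phrase occurrence whose tokens are all unsuppressed. There is no
scoring or ranking: the phenotype is binary, and the evidence (matched
phrases/codes with note ids and token spans) is retained for audit.

## The text pipeline

The stage order is fixed and matters:

```
strip_template_blocks -> tokenize -> normalize_tokens -> mark_negation
  -> mark_history -> strip_punctuation -> match_terms
```

Punctuation must survive normalization because "." and "?" terminate
negation/history scopes; it is stripped only after history marking, which
mirrors the convention that punctuation removal is the *last*
pre-processing step before matching.

**Tokenization.** Words, numbers, and single punctuation characters become
separate tokens; whitespace is discarded. Slash-joined clinical
abbreviations ("h/o", "h/x") are kept as single word tokens — without
this, the slashed history cues could never match. Token order is
preserved, and each token carries its surface, lowercased `norm`, stemmed
`key`, kind, and the flags `removed` / `negated` / `in_history`.

**Normalization.** Lowercasing; removal of number tokens, words shorter
than two characters, and three configurable stop classes (temporal words
such as "last night ... ago", prepositions, pronouns). Two protections
override removal: (a) function words occurring inside any active lexicon
phrase ("by", "of", "or", "with", "against", ...), computed by
`protected_function_words()`; (b) every word used by the scoping
configuration (cues, word terminators, history-cue tokens), so "of" (in
"history of"), "no", "pt", "per", "without" always survive. The stop-word
lists ship as an editable YAML resource; they are a package choice, since
the rule set itself only names the stop *classes*.

**Stemming.** The reference reduction "assaulted last night by her
husband" → "assault by husband" requires undoing inflection without a full
stemmer. We use a deliberately minimal rule: strip one of the suffixes
`ing`/`ed`/`s` (requiring a residual stem of ≥ 3 characters, never
stripping `s` after `ss`), then strip a final `e` from words longer than
three characters. Crucially the *same* function canonicalizes note tokens
and lexicon phrases, so "strangled" and "strangle" meet at the key
"strangl" and "battered"/"batter" at "batter". The price is occasional
key collisions of unrelated words (e.g. "here" → "her"); none involve
lexicon keys, and irregular inflections ("struck") are not handled — a
known limitation shared with the original rule set, which is also defeated
by misspellings.

**Negation and history scoping.** A simplified NegEx: each surviving cue
token opens a scope that runs to the next surviving termination token or
to the end of the sequence; every surviving word token strictly inside is
flagged. Scopes union; nothing before a cue is ever flagged; there are no
backward scopes or pseudo-negation phrases. History scoping is the same
mechanism driven by cue *phrases* matched longest-first ("h/o of" before
"h/o"), and it reuses the negation terminator set — the worked example
"history of ipv during previous pregnancy **but** not currently" then ends
its scope at "but" exactly as intended. Negation and history flags are
independent: a cue inside a history scope still negates.

Two deliberate deviations from the verbatim scoping table, both
reversible:

* `"and"` is listed as a termination token, yet the canonical worked
  example negates *through* "and" ("... use_neg and_neg intimate_neg
  partner_neg violence_neg"). The default configuration therefore drops
  "and" from the terminators so the operational demonstration reproduces;
  `load_scoping_config(faithful_table3 = TRUE)` (or
  `ipv_resources(faithful_table3 = TRUE)`) restores the verbatim table.
* The ambiguous one-letter-ish history cues ("ho") stay enabled for
  fidelity but can be removed via `scoping_config()`.

**Template stripping.** Auto-populated IPV screening-question lines are a
false-positive source whether answered or blank ("do you feel safe at
home? no" contains no negated *phrase* — the question text itself is the
hazard). Any note line matching a configured glob pattern is dropped
before tokenization; patterns ship as an editable one-per-line resource
and should end in `*` to catch filled answers.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_word_length` | 2 | words with fewer characters are removed |
| `stemming_suffixes` | `ing, ed, s` | tried in order, first match wins |
| `faithful_table3` | `FALSE` | keep "and" as a scope terminator |
| `strip_templates` | `TRUE` | remove screening-template lines |
| stop-word lists | packaged YAML | temporal / preposition / pronoun classes |
| template patterns | packaged file | glob line patterns |

Matching is whole-token only. Lowercase "ipv" therefore also matches
inactivated-polio-vaccine mentions; this is retained by default for
fidelity and is documented (and demonstrated by the generator's
distractors) as a known false-positive source, alongside "domestic
dispute" used for non-partner family conflict.

## The synthetic corpus generator

`generate_corpus()` emulates exactly the phenomena the rules must handle,
with ground truth: positives embed a uniformly chosen lexicon phrase
realized by `phrase_realizer()` (verbatim, verb-inflected, and/or wrapped
in temporal/possessive filler the normalizer strips); negatives may carry
negated mentions, history mentions, auto-populated screening blocks, or
distractor sentences at configured rates; truth-positive encounters carry
an IPV diagnosis code with probability `icd_coding_rate` (ICD-9 before
October 2015, ICD-10 after, matching the visit date); all encounters carry
benign codes and benign clinical filler. Positive allocation is exact
(`round(prevalence * n)`, then shuffled) so tests can assert counts
without tolerance, and generation is deterministic given the seed.

Defaults: `n_encounters = 1000`, `prevalence = 0.1` — the desk-scale study
condition used throughout the test suite — with
`negated_mention_rate = 0.15`, `history_mention_rate = 0.10`,
`template_block_rate = 0.10`, `distractor_rate = 0.05` chosen once as
plausible ED-note rates (the source rule set reports the phenomena but not
their rates), and `icd_coding_rate = 0.013`, the observed fraction of
note-identified IPV encounters that also carried an IPV code (96 of
7,399). Visit dates are uniform over January 2012–August 2020 and ~85% as
many patients as encounters are simulated so some patients recur.

What passing closed-loop tests shows — and does not. Every positive
phrasing is machine-recoverable *by construction*: the fillers inserted
inside phrases are precisely stop-class words. Recovering precision and
recall of 1.0 on such a corpus validates the internal consistency of
normalizer, scoping, and matcher (any regression in any stage breaks it);
it says nothing about recall on real notes, where patients and clinicians
use vocabulary outside the 71 phrases, misspell, or inflect irregularly.
The generator makes no attempt at clinically realistic narrative beyond
the phenomena the detector must handle.

## Evaluation utilities

`confusion()` has two coverage modes because that is how such phenotypes
are actually validated: `"review"` mode scores truth that exists only for
(a sample of) predicted positives — precision is defined, recall is
explicitly `NA` (unflagged charts were never reviewed); `"full"` mode
requires complete truth and yields both. `review_tally()` recomputes
precision directly from printed review counts (e.g. 16 confirmed of 199
reviewed → 8.0%; 1,790 of 1,798 → 99.56%, which rounds to the reported
99.5% only at coarser precision — the report prints the full value and
leaves rounding to the caller). `sample_for_review()` draws
`round(fraction * n)` positives, optionally stratified by visit year with
each year's allocation within one encounter of exact proportionality
(floor + largest-remainder). `compare_approaches()` produces the
A-only/B-only/shared encounter and distinct-patient counts used to compare
tiers.

## Numerical and design choices

* Token positions are 1-based (R convention); order is what matters.
* `normalize_tokens()` recomputes every decision from token surfaces, so
  it is idempotent; flags set later are never recomputed by earlier
  stages (the stage order is a contract).
* Stop-class removal happens *before* scoping; scoping then runs on
  surviving words plus punctuation. The protected-word mechanism is what
  keeps this consistent (cue words are never removed).
* Empty text, empty corpora, cue-at-end-of-sequence, and encounters with
  no codes and no notes are all defined (empty sequence, zero summary,
  empty scope, negative under every approach).
* Duplicate encounter ids are a hard error naming the id; duplicate note
  ids within an encounter likewise.
* The ICD-9 set stores 7 unique codes although the source table prints 8
  rows (one code is listed under two diagnosis names); membership is a
  set, so the duplicate collapses. Perpetrator codes (E967.0/E967.9) are
  standalone members, not conditioned on co-occurring abuse codes.

## Problem sizes used in the test suite

The packaged tests run the scope oracle comparison on 10,000 random
sequences of up to 30 tokens, the closed-loop recovery on five seeds of
1,000 encounters at 10% prevalence (distractors and templates off), the
suppression check on 300 all-negated encounters, and tier monotonicity on
a 500-encounter corpus with all phenomena enabled. These sizes were chosen
as the smallest corpora at which every phenomenon occurs many times per
run.

## Known limitations

* Vocabulary-bound recall: anything phrased outside the lexicons is
  missed; no spelling correction; no irregular-verb handling.
* Whole-token abbreviation collisions ("ipv", "dv", "so", "ex") can
  false-positive; an exclusion-context mechanism is deliberately not
  enabled by default.
* History suppression trades recall for specificity: prior IPV is a risk
  factor for current IPV, and suppressing `_hx` spans can discard true
  current cases described in historical framing.
* No machine-learned extension (transformers, active learning) is in
  scope; the package is the auditable rule baseline such models would be
  compared against.
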