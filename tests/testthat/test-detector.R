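test_that("match_terms finds unflagged phrase occurrences only", {
  s <- annotate_note("assault by husband", .res)
  m <- match_terms(s, .res$situational)
  expect_identical(m$phrase, "assault by husband")

  suppressed <- annotate_note("patient denies domestic violence.", .res)
  expect_identical(nrow(match_terms(suppressed, .res$combined)), 0L)

  ext <- annotate_note("attack by gf", .res)
  expect_identical(match_terms(ext, .res$combined)$phrase, "attack by gf")
  expect_identical(nrow(match_terms(ext, .res$situational)), 0L)
})

test_that("overlapping and nested phrase matches are all reported", {
  s <- annotate_note("pt battered woman, given domestic violence resources",
                     .res)
  got <- match_terms(s, .res$combined)$phrase
  expect_true(all(c("battered", "battered woman", "domestic violence",
                    "domestic violence resources") %in% got))
})

test_that("phrase matching spans removed filler tokens", {
  s <- annotate_note("assaulted repeatedly last night by her husband", .res)
  # "repeatedly" survives between phrase tokens, so no contiguous match
  expect_identical(nrow(match_terms(s, .res$situational)), 0L)
  s2 <- annotate_note("assaulted last night by her husband", .res)
  expect_identical(match_terms(s2, .res$situational)$phrase,
                   "assault by husband")
})

test_that("match_icd normalizes, respects revision tags, and warns", {
  codes <- .res$codes
  expect_identical(match_icd("T76.21XA", codes), "T7621XA")
  expect_identical(match_icd("I10", codes), character(0))
  expect_identical(match_icd("995.81", codes, revisions = "icd9"), "99581")
  expect_identical(match_icd(c("995.81", "T74.11XA"), codes,
                             revisions = c("icd9", "icd10")),
                   c("99581", "T7411XA"))
  expect_warning(got <- match_icd(c("??", "T74.11XA"), codes),
                 "unparseable")
  expect_identical(got, "T7411XA")
})

test_that("classify_encounter implements the three approaches", {
  res <- .res
  enc <- note_encounter("pt strangle by partner per roommate")
  expect_false(classify_encounter(enc, "situational", res)$label)
  r3 <- classify_encounter(enc, "extended", res)
  expect_true(r3$label)
  expect_identical(r3$evidence$phrase, "strangle by partner")

  coded <- encounter("E2", "P2", "2016-03-01",
                     diagnosis_codes = data.frame(code = "T74.11XA",
                                                  revision = "icd10"))
  expect_true(classify_encounter(coded, "icd", res)$label)
  expect_false(classify_encounter(coded, "extended", res)$label)

  empty <- encounter("E3", "P3", "2014-01-01")
  for (a in c("icd", "situational", "extended")) {
    r <- classify_encounter(empty, a, res)
    expect_false(r$label)
    expect_identical(NROW(r$evidence), 0L)
  }
  expect_error(classify_encounter(enc, "bogus", res))
})

test_that("label is true iff evidence is non-empty", {
  encs <- list(note_encounter("assault by spouse", "A"),
               note_encounter("denies assault by spouse.", "B"),
               note_encounter("routine visit", "C"))
  for (e in encs) {
    r <- classify_encounter(e, "extended", .res)
    expect_identical(r$label, NROW(r$evidence) > 0L)
  }
})

test_that("classify_corpus counts encounters and distinct patients", {
  encs <- list(
    note_encounter("assault by husband", id = "E1", patient = "P1"),
    note_encounter("attack by bf", id = "E2", patient = "P1"),
    note_encounter("routine visit", id = "E3", patient = "P2")
  )
  out <- classify_corpus(encs, "extended", .res)
  expect_identical(out$summary$n_encounters, 3L)
  expect_identical(out$summary$n_positive, 2L)
  expect_identical(out$summary$n_patients_positive, 1L)

  empty <- classify_corpus(list(), "extended", .res)
  expect_identical(empty$summary$n_encounters, 0L)
  expect_identical(empty$summary$n_positive, 0L)
  expect_identical(empty$summary$n_patients_positive, 0L)

  dup <- c(encs, list(note_encounter("x", id = "E1", patient = "P9")))
  expect_error(classify_corpus(dup, "extended", .res), "E1")
})

test_that("adding phrases to a lexicon never loses a positive", {
  base <- .res
  extra <- ipv_resources(
    situational = load_default_lexicon("situational"),
    extended = combined_lexicon(
      load_default_lexicon("extended"),
      term_lexicon("choked by partner", tier = "extended",
                   source_label = "extra"))
  )
  texts <- c("assault by husband", "attack by gf", "choked by partner",
             "routine visit")
  for (txt in texts) {
    enc <- note_encounter(txt)
    before <- classify_encounter(enc, "extended", base)$label
    after <- classify_encounter(enc, "extended", extra)$label
    expect_true(!before || after)
  }
})

test_that("classification is deterministic across runs", {
  enc <- note_encounter("pt reports assault by husband. denies etoh.")
  r1 <- classify_encounter(enc, "extended", .res)
  r2 <- classify_encounter(enc, "extended", .res)
  expect_identical(r1, r2)
})

test_that("the ipv abbreviation hazard is documented behaviour", {
  # whole-token matching: "ipv" matches even in a vaccine context by
  # default (fidelity to the rule set); partial tokens never match
  vac <- note_encounter("ipv vaccine administered")
  expect_true(classify_encounter(vac, "extended", .res)$label)
  part <- note_encounter("hipvac device placed")
  expect_false(classify_encounter(part, "extended", .res)$label)
})

test_that("screening-template lines cannot produce matches", {
  enc <- note_encounter("seen for ankle sprain\ndomestic violence screen: negative")
  expect_false(classify_encounter(enc, "extended", .res)$label)
  raw <- ipv_resources(strip_templates = FALSE)
  expect_true(classify_encounter(enc, "extended", raw)$label)
})
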