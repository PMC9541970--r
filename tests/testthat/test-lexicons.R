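test_that("default code set matches the published coding table", {
  codes <- load_default_codes()
  expect_length(codes$icd9, 7)   # 8 listed rows, 995.83 listed twice
  expect_length(codes$icd10, 9)
  expect_true(code_member(codes, "T74.11XA"))
  expect_true(code_member(codes, "t7411xa"))     # case/dot invariance
  expect_true(code_member(codes, "995.81"))
  expect_true(code_member(codes, "99581", revision = "icd9"))
  expect_false(code_member(codes, "I10"))
  expect_false(code_member(codes, "995.81", revision = "icd10"))
  # perpetrator codes are standalone members like all others
  expect_true(all(code_member(codes, c("E967.0", "E967.9"))))
  # 995.8 and 995.83 are distinct codes, not prefixes of one another
  expect_true(all(c("9958", "99583") %in% codes$icd9))
})

test_that("code set construction rejects empty and cross-revision codes", {
  expect_error(code_set("", "T7411XA"), "empty")
  expect_error(code_set("9958", "99.58"), "both")
})

test_that("default lexicons have the published sizes and phrases", {
  sit <- load_default_lexicon("situational")
  ext <- load_default_lexicon("extended")
  expect_length(sit, 23)
  expect_length(ext, 49)
  expect_true("assault by husband" %in% sit$phrases)
  expect_true("attack by gf" %in% ext$phrases)
  # one phrase is deliberately shared between the tiers
  expect_true("violence against women" %in% sit$phrases)
  expect_true("violence against women" %in% ext$phrases)
  expect_error(load_default_lexicon("bogus"))
})

test_that("lexicon phrases are tokenized lowercase with >= 1 token", {
  lex <- term_lexicon(c("Domestic Violence", "IPV"), tier = "extended")
  expect_identical(lex$tokens[[1]], c("domestic", "violence"))
  expect_identical(lex$tokens[[2]], "ipv")
  expect_true(all(lengths(lex$tokens) >= 1))
  expect_error(term_lexicon(c("a b", "a b"), tier = "situational"),
               "duplicate")
  expect_error(term_lexicon("", tier = "situational"))
})

test_that("combined lexicon is a deduplicated union with identities", {
  sit <- load_default_lexicon("situational")
  ext <- load_default_lexicon("extended")
  comb <- combined_lexicon(sit, ext)
  expect_length(comb, 71)  # 23 + 49 - shared "violence against women"
  expect_identical(comb$tier, "extended")
  expect_identical(combined_lexicon(sit, sit)$phrases, sit$phrases)
  expect_identical(combined_lexicon(empty_lexicon(), sit)$phrases,
                   sit$phrases)
})

test_that("lexicons round-trip through their plain-text format", {
  for (tier in c("situational", "extended")) {
    lex <- load_default_lexicon(tier)
    tmp <- withr::local_tempfile(fileext = ".txt")
    write_lexicon(lex, tmp)
    back <- read_lexicon(tmp, tier = tier)
    expect_identical(back$phrases, lex$phrases)
    expect_identical(back$keys, lex$keys)
  }
})

test_that("protected function words come from inside lexicon phrases", {
  sit <- load_default_lexicon("situational")
  pw <- protected_function_words(sit)
  expect_true(all(c("by", "with", "or", "and", "to", "against") %in% pw))
  expect_identical(protected_function_words(empty_lexicon()), character(0))
  expect_identical(
    protected_function_words(term_lexicon("femicide", tier = "extended")),
    character(0)
  )
})

test_that("scoping config honours the faithful-table switch on 'and'", {
  dflt <- load_scoping_config()
  faith <- load_scoping_config(faithful_table3 = TRUE)
  expect_true(all(c("denies", "denied", "deny", "no", "non", "not",
                    "without", "unable") %in% dflt$negation_cues))
  expect_true(all(c(".", "but") %in% dflt$termination_tokens))
  expect_false("and" %in% dflt$termination_tokens)
  expect_true("and" %in% faith$termination_tokens)
})

test_that("scoping config invariants hold on load", {
  cfg <- load_scoping_config(faithful_table3 = TRUE)
  expect_length(intersect(cfg$negation_cues, cfg$termination_tokens), 0)
  # each terminator is a single punctuation mark or a lowercase word
  expect_true(all(grepl("^([a-z][a-z/]*|[^[:alnum:][:space:]])$",
                        cfg$termination_tokens)))
  # history cues ordered longest-first so "h/o of" is not shadowed by "h/o"
  lens <- lengths(cfg$history_cue_tokens)
  expect_true(all(diff(lens) <= 0))
  expect_lt(match("h/o of", cfg$history_cues), match("h/o", cfg$history_cues))
  expect_error(scoping_config("no", c("no", "."), "hx"), "disjoint")
  expect_error(scoping_config("denies", c(".", "AND"), "hx"), NA)
})
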