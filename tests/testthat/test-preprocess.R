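cfg <- .res$normalization

surviving_keys <- function(text) {
  s <- normalize_tokens(tokenize(text), cfg)
  s$key[!s$removed & s$kind != "punct"]
}

test_that("tokenize splits words, numbers, and punctuation in order", {
  expect_identical(tokenize("assault by husband.")$surface,
                   c("assault", "by", "husband", "."))
  expect_length(tokenize(""), 0)
  expect_identical(tokenize("drug, alcohol use")$surface,
                   c("drug", ",", "alcohol", "use"))
  tk <- tokenize("h/o of ipv?")
  expect_identical(tk$surface, c("h/o", "of", "ipv", "?"))
  expect_identical(tk$kind, c("word", "word", "word", "punct"))
  expect_identical(tokenize("45 yo")$kind, c("number", "word"))
})

test_that("tokenize preserves the non-whitespace character multiset", {
  texts <- c("Pt c/o pain; denies DV (per spouse). Vitals: 120/80!",
             "assaulted  last   night\tby her husband?",
             "a-b c_d e.f 42x")
  for (txt in texts) {
    got <- paste(tokenize(txt)$surface, collapse = "")
    want <- gsub("[[:space:]]", "", txt)
    expect_identical(sort(strsplit(got, "")[[1]]),
                     sort(strsplit(want, "")[[1]]))
  }
})

test_that("normalization reproduces the reference reductions", {
  expect_identical(surviving_keys("assaulted last night by her husband"),
                   c("assault", "by", "husband"))
  expect_identical(surviving_keys("ASSAULT BY HUSBAND"),
                   c("assault", "by", "husband"))
  # "a"/"f" short, "45"/"2" numbers, "days"/"ago" temporal, "her" pronoun,
  # "by" protected
  expect_identical(surviving_keys("a 45 yo f assaulted 2 days ago by her husband"),
                   c("yo", "assault", "by", "husband"))
})

test_that("punctuation survives normalization but numbers do not", {
  s <- normalize_tokens(tokenize("denies abuse 2 days ago."), cfg)
  expect_false(s$removed[s$surface == "."])
  expect_true(s$removed[s$surface == "2"])
})

test_that("normalize is idempotent and never removes protected words", {
  texts <- c("assaulted last night by her husband.",
             "Patient denies drug, alcohol use and intimate partner violence.",
             "hx of ipv during previous pregnancy but not currently",
             "referral to partnership against domestic violence")
  for (txt in texts) {
    once <- normalize_tokens(tokenize(txt), cfg)
    twice <- normalize_tokens(once, cfg)
    expect_identical(twice$key, once$key)
    expect_identical(twice$removed, once$removed)
    prot <- once$norm %in% cfg$protected_words & once$kind == "word"
    expect_false(any(once$removed & prot))
  }
})

test_that("light stemming canonicalizes inflections onto lexicon keys", {
  expect_identical(stem_keys(c("assaulted", "strangled", "strangle",
                               "battered", "attacks", "abuses", "attacking")),
                   c("assault", "strangl", "strangl", "batter", "attack",
                     "abus", "attack"))
  # too short to stem; "ss" endings keep their s
  expect_identical(stem_keys(c("dv", "ipv", "so", "ex", "miss")),
                   c("dv", "ipv", "so", "ex", "miss"))
})

test_that("template blocks are stripped whether completed or blank", {
  pat <- "do you feel safe at home*"
  note <- paste("seen for wrist injury",
                "do you feel safe at home? ___",
                "plan: splint", sep = "\n")
  expect_identical(strip_template_blocks(note, pat),
                   "seen for wrist injury\nplan: splint")
  filled <- "do you feel safe at home? no"
  expect_identical(strip_template_blocks(filled, pat), "")
  untouched <- "no template lines here"
  expect_identical(strip_template_blocks(untouched, pat), untouched)
  expect_error(strip_template_blocks(note, c(pat, "")),
               "invalid template pattern")
})

test_that("strip_punctuation removes punct and keeps word annotations", {
  s <- annotate_note("patient denies assault, by husband.", .res,
                     keep_punctuation = TRUE)
  negged <- s$norm[s$negated]
  s2 <- strip_punctuation(s)
  expect_true(all(s2$removed[s2$kind == "punct"]))
  expect_identical(s2$norm[s2$negated], negged)
  s3 <- make_seq(c("assault", "by", "husband"))
  expect_identical(strip_punctuation(s3)$removed, s3$removed)
})

test_that("min_word_length is configurable and validated", {
  c3 <- normalization_config(min_word_length = 3)
  expect_identical({
    s <- normalize_tokens(tokenize("dv at home"), c3)
    s$key[!s$removed]
  }, "hom")  # "dv"/"at" below length 3; "home" keeps only its stemmed key
  expect_error(normalization_config(min_word_length = 0), "min_word_length")
})
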