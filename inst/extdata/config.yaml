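# Default scoping + normalization configuration.
#
# `scoping` holds the verbatim cue/terminator/history sets. Note that "and"
# is listed as a termination token here, but the default loader drops it so
# that negation scopes carry across "and" (see load_scoping_config(); pass
# faithful_table3 = TRUE to keep the verbatim set).
scoping:
  negation_cues:
    - denies
    - denied
    - deny
    - "no"
    - non
    - "not"
    - without
    - unable
  termination_tokens:
    - "?"
    - "."
    - "-"
    - ";"
    - ":"
    - "+"
    - "and"
    - but
    - complains
    - did
    - except
    - has
    - per
    - pt
    - reports
    - secondary
    - states
  history_cues:
    - history of
    - hx of
    - h/x of
    - ho of
    - h/o of
    - hx
    - h/x
    - h/o
    - ho
normalization:
  min_word_length: 2
  stemming_suffixes: [ing, ed, s]
  # time indications stripped before matching ("assaulted last night by her
  # husband" must reduce to "assault by husband")
  temporal_stopwords:
    - last
    - night
    - tonight
    - yesterday
    - today
    - morning
    - evening
    - afternoon
    - ago
    - day
    - days
    - week
    - weeks
    - month
    - months
    - year
    - years
    - am
    - pm
    - prior
    - previous
    - previously
    - recent
    - recently
    - current
    - currently
    - earlier
  # prepositions stripped unless protected by an active lexicon or scoping
  # config ("by", "against", "of", "per", ... are protected downstream).
  # "without" is deliberately absent: it is a negation cue.
  preposition_stopwords:
    - about
    - above
    - across
    - after
    - against
    - along
    - around
    - at
    - before
    - behind
    - below
    - beneath
    - beside
    - between
    - by
    - during
    - for
    - from
    - in
    - inside
    - into
    - near
    - of
    - off
    - on
    - onto
    - out
    - outside
    - over
    - past
    - since
    - through
    - to
    - toward
    - towards
    - under
    - until
    - up
    - upon
    - with
    - within
  pronoun_stopwords:
    - i
    - me
    - my
    - mine
    - myself
    - you
    - your
    - yours
    - yourself
    - he
    - him
    - his
    - himself
    - she
    - her
    - hers
    - herself
    - it
    - its
    - itself
    - we
    - us
    - our
    - ours
    - ourselves
    - they
    - them
    - their
    - theirs
    - themselves
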