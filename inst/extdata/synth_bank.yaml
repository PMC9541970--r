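# Template bank for the synthetic corpus generator. Entirely invented
# (synthetic); no real patient text. Every positive realization is
# machine-recoverable by construction: fillers inserted inside lexicon
# phrases are limited to temporal/possessive stop-class words that the
# normalizer strips.
positive_prefixes:
  - "pt reports"
  - "patient states she was"
  - "patient presenting after"
  - "per ems,"
  - "triage note:"
  - "sw consulted, pt discloses"
positive_suffixes:
  - "this evening at home"
  - "earlier today"
  - ""
  - "while at home"
temporal_fillers:
  - "last night"
  - "yesterday"
  - "earlier today"
  - "2 days ago"
possessives:
  - her
  - his
  - their
benign_sentences:
  - "presented with chest pain radiating to the left arm"
  - "ankle sprain sustained while playing basketball"
  - "denies fever, chills, or nausea"
  - "medications reviewed and reconciled"
  - "ct head negative for acute findings"
  - "discharged home in stable condition"
  - "follow up with primary care in one week"
  - "pmh notable for asthma and hypertension"
  - "laceration repaired with 4 sutures, wound care reviewed"
  - "pt ambulating without difficulty"
negated_sentences:
  - "patient denies domestic violence."
  - "denies intimate partner violence or abuse at home."
  - "pt denied assault by partner."
  - "no concern for domestic abuse at this time."
history_sentences:
  - "reports hx of domestic violence in a previous relationship."
  - "history of ipv during previous pregnancy but not currently."
  - "h/o of spouse abuse, resolved."
  - "hx of intimate partner violence, none recent."
distractor_sentences:
  - "domestic dispute between mother and child reported by neighbor"
  - "ipv vaccine administered per immunization schedule"
  - "discussed workplace violence prevention resources"
template_blocks:
  - pattern: "do you feel safe at home*"
    lines:
      - "do you feel safe at home? ___"
      - "do you feel safe at home? no"
  - pattern: "domestic violence screen*"
    lines:
      - "domestic violence screen: not completed"
      - "domestic violence screen: negative"
  - pattern: "ipv screening:*"
    lines:
      - "ipv screening: declined"
      - "ipv screening: ___"
benign_codes:
  - code: "I10"
    revision: icd10
  - code: "J45.909"
    revision: icd10
  - code: "S93.401A"
    revision: icd10
  - code: "R51.9"
    revision: icd10
  - code: "401.9"
    revision: icd9
  - code: "493.90"
    revision: icd9
  - code: "845.00"
    revision: icd9
ipv_codes:
  - code: "995.83"
    revision: icd9
  - code: "995.82"
    revision: icd9
  - code: "995.81"
    revision: icd9
  - code: "995.8"
    revision: icd9
  - code: "E967.0"
    revision: icd9
  - code: "E967.9"
    revision: icd9
  - code: "994.7"
    revision: icd9
  - code: "T76.21XA"
    revision: icd10
  - code: "T76.51XA"
    revision: icd10
  - code: "T76.11XA"
    revision: icd10
  - code: "T74.11XA"
    revision: icd10
  - code: "T74.21XA"
    revision: icd10
  - code: "T74.51XA"
    revision: icd10
  - code: "T71.9XXA"
    revision: icd10
  - code: "T71.163A"
    revision: icd10
  - code: "T71.193A"
    revision: icd10
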