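# Auto-populated screening-question line patterns, one per line.
# Any note line matching one of these glob patterns ("*" = any run of
# characters, "?" = any single character) is removed before tokenization,
# whether the question was answered or left blank.
do you feel safe at home*
have you been hit, kicked, punched, or otherwise hurt by someone*
are you in a relationship with someone who threatens or hurts you*
ipv screening:*
domestic violence screen*
abuse screening completed*
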