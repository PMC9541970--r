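# IPV-related diagnosis codes, one per line: code <TAB> revision
# 995.83 is listed under two diagnosis names (adult sexual abuse / adult rape)
# in the source coding table; membership is a set, so it is stored once.
code	revision
995.83	icd9
995.82	icd9
995.81	icd9
995.8	icd9
E967.0	icd9
E967.9	icd9
994.7	icd9
T76.21XA	icd10
T76.51XA	icd10
T76.11XA	icd10
T74.11XA	icd10
T74.21XA	icd10
T74.51XA	icd10
T71.9XXA	icd10
T71.163A	icd10
T71.193A	icd10
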