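# abbreviation<TAB>expansion (whole-token, case-insensitive)
cont	continue
dc	discontinue
d/c	discontinue
d/ced	discontinued
d/cd	discontinued
d/c'd	discontinued
info	information
pt	patient
pts	patients
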