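# indicator lemma<TAB>class (C|D|S|U)[<TAB>weak]
# Indicators are matched on lemmas, so inflected forms ("started", "taking",
# "d/ced" after abbreviation expansion) hit these entries.
# "weak" marks attributive intake verbs that adopt the class of a governing
# indicator immediately before them ("stop taking", "recommend taking").
continue	C
take	C	weak
use	C	weak
increase	C
decrease	C
maintain	C
remain	C
start	S
restart	S
initiate	S
begin	S
add	S
resume	S
try	S	weak
discontinue	D
stop	D
hold	D
off	D
quit	D
cease	D
withhold	D
recommend	U
advise	U
suggest	U
consider	U
avoid	U
inquire	U
discuss	U
counsel	U
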