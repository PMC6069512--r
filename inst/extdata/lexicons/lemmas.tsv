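# inflected form<TAB>lemma : exception dictionary consulted before the
# suffix-stripping rules of the surrogate lexical normalizer.
took	take
taken	take
takes	take
held	hold
holds	hold
began	begin
begun	begin
withheld	withhold
left	leave
felt	feel
said	say
saw	see
went	go
got	get
gotten	get
made	make
found	find
told	tell
kept	keep
wrote	write
written	write
denies	deny
denied	deny
denying	deny
declining	decline
stopped	stop
stopping	stop
quitting	quit
women	woman
men	man
feet	foot
teeth	tooth
better	good
worse	bad
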