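# known lemmas used by the suffix stripper's e-restoration step: after
# stripping -ed/-ing, if <stem>e is listed here (or is an indicator, negator
# or dictionary lemma) the stripper restores the final e.
advise
agree
arrange
arrive
balance
bruise
capsule
cause
challenge
change
charge
close
complete
continue
decline
decrease
describe
dose
encourage
examine
experience
improve
increase
indicate
inquire
initiate
involve
manage
measure
medicine
migraine
note
notice
nurse
practice
prepare
provide
purchase
receive
reduce
release
remove
require
resume
schedule
sense
settle
side
source
store
tolerate
use
take
write
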