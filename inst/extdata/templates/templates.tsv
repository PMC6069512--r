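# class<TAB>id<TAB>source<TAB>form<TAB>indicators<TAB>template
# Template bank for the synthetic clinical-sentence generator.
# Placeholders: {sup} target supplement mention, {ind} status indicator
# (inflected per `form`), {gap} variable-length filler controlling the
# indicator-mention token distance. Words between {ind} and {sup} other
# than {gap} are stop-word glue or fixed content counted into the
# distance. source=printed marks templates abstracted from published
# example sentences; source=synthetic marks paraphrase variants.
C	c01	printed	base	continue	{ind} {gap} {sup} to reduce inflammation.
C	c02	printed	past	increase	she has {ind} her {gap} {sup} and this has eliminated her symptoms.
C	c03	printed	gerund	take,use	she is also {ind} a {gap} {sup} and tylenol as needed for pain.
C	c04	printed	base	increase,continue	{ind} {gap} {sup} to 200 mg per day for high triglycerides.
C	c05	printed	past	continue	he was also {ind} on {gap} {sup} to protect against mouth sores.
C	c06	synthetic	base	continue	pt will {ind} {gap} {sup} at home.
C	c07	synthetic	base	continue,increase	she plans to {ind} her {gap} {sup} daily.
C	c08	synthetic	gerund	take,use	he is {ind} {gap} {sup} every morning.
C	c09	synthetic	past	continue	his {sup} {gap} was {ind} at the same dose.
C	c10	synthetic	third	remain,continue	patient {ind} on {gap} {sup} for now.
D	d01	printed	base	stop,discontinue	{ind} {gap} {sup} supplement.
D	d02	printed	base	discontinue,stop	she is to {ind} her {gap} {sup}.
D	d03	printed	gerund	hold	you are already {ind} the {gap} {sup} and aspirin.
D	d04	printed	past	discontinue,stop	the {sup} {gap} was {ind} on admission.
D	d05	printed	base	stop	pt did {ind} {gap} {sup} oct 2013.
D	d06	synthetic	base	stop,discontinue,hold	please {ind} {gap} {sup} before surgery.
D	d07	synthetic	past	stop,quit,discontinue	he {ind} his {gap} {sup} last month.
D	d08	synthetic	base	off	patient is now {ind} {gap} {sup}.
D	d09	synthetic	base	hold,withhold	we will {ind} {gap} {sup} for now.
D	d10	synthetic	past	discontinue,cease	her {sup} {gap} was {ind} at discharge.
S	s01	printed	past	start	{ind} {gap} {sup} 1 week ago for cold.
S	s02	printed	base	add	{ind} a supplement with {sup}.
S	s03	printed	base	begin,start	i have asked him to {ind} {gap} {sup} three capsules per day.
S	s04	printed	base	start,begin	patient is to {ind} taking {sup} tonight to help her sleep.
S	s05	synthetic	base	start,begin	she will {ind} {gap} {sup} tonight.
S	s06	synthetic	past	start,add,restart	he {ind} {gap} {sup} two weeks ago.
S	s07	synthetic	past	start,initiate	pt has recently {ind} {gap} {sup} for energy.
S	s08	synthetic	past	add,start	{sup} {gap} was {ind} last week.
S	s09	synthetic	base	resume,restart	she would like to {ind} her {gap} {sup} after the procedure.
U	u01	printed	base	recommend	i did {ind} taking over the counter {gap} {sup}, either 500 or 1000 mg per day.
U	u02	printed	past	advise	she was {ind} to take {gap} {sup} daily.
U	u03	printed	base	avoid	{ind} use of {gap} {sup} on methadone as it can affect systemic level.
U	u04	printed	past	suggest	also {ind} that she could consider trying otc {gap} {sup}.
U	u05	printed	base	recommend	{ind} over the counter {gap} {sup} 3 mg once daily.
U	u06	printed	gerund	inquire	pt {ind} about {gap} {sup}.
U	u07	printed	base	avoid	{ind} grapefruit and {gap} {sup} before surgery.
U	u08	synthetic	past	discuss	{ind} risks and benefits of {gap} {sup} with patient.
U	u09	synthetic	past	counsel	patient was {ind} regarding {gap} {sup} today.
U	u10	synthetic	none	-	patient has questions about {sup}.
U	u11	synthetic	none	-	{sup} listed on home medication list.
U	u12	synthetic	none	-	pt brought in a bottle of {sup} from home.
U	u13	synthetic	none	-	wife gives him {sup} occasionally.
U	u14	synthetic	none	-	pt curious about {sup} benefits.
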