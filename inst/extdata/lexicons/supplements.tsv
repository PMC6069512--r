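# canonical<TAB>comma-separated variants (canonical itself is always a variant)
# 25 commonly used dietary supplements with lexical variants (misspellings,
# brand/compound forms). Editable data, not code.
alfalfa	alfalfa tabs,alfafa
biotin	biotine
black cohosh	black kohosh,blackcohosh
coenzyme q10	coq10,co q10,coenzyme q 10,ubiquinone
cranberry	cranberries,cranberry extract
dandelion	dandelion root,dandilion
echinacea	echinecea,echinacia
fish oil	fishoil,fish oils,omega 3 fish oil
flax seed	flaxseed,flax seed oil
folic acid	folate,folic
garlic	garlic tablets,garlic pills
ginger	ginger root,ginger tea
ginkgo	ginko,gingko,ginkoba,ginkgo biloba
ginseng	ginsing,ginseng extract
glucosamine	glucosamin,glucosamine chondroitin
glutamine	l-glutamine,glutamin
kava kava	kava,kavakava
lecithin	lecitin,lecithin granules
melatonin	melatonine,melatonin supplement
milk thistle	milkthistle,milk thisle
saw palmetto	saw palmeto,sawpalmetto
st john's wort	st. john's wort,st johns wort,saint john's wort,st john wort
turmeric	tumeric,turmeric curcumin
valerian	valerian root,valarian
vitamin e	vit e,vitamin e supplement
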