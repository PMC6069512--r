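#' Golden example sentences
#'
#' A small validation set of published clinical example sentences with
#' their known use-status classes, one target supplement each: the
#' canonical demonstrations of each class (continue/increase/take for C,
#' stop/discontinue/hold for D, start/add/begin for S,
#' recommend/avoid/suggest/inquire for U), plus negated and
#' multi-indicator constructions. The rule engine at its default
#' configuration classifies all of them correctly, which pins down the
#' resolution policy (nearest indicator, negation remap, weak-verb
#' governing).
#'
#' @return a `sup_corpus` with the known class in `label`
#' @examples
#' g <- golden_sentences()
#' pred <- classify_corpus(g)
#' mean(pred == g$label)
#' @export
golden_sentences <- function() {
  rows <- list(
    ## class demonstrations, three per class
    c("Continue fish oil to reduce inflammation.", "fish oil", "C"),
    c("She has increased her alfalfa tabs and this has eliminated her symptoms and chest tightness.", "alfalfa", "C"),
    c("She is also taking a Vitamin E supplement and Tylenol as needed for pain.", "vitamin e", "C"),
    c("Stop Vitamin E supplement.", "vitamin e", "D"),
    c("She is to discontinue her St. John's Wort.", "st john's wort", "D"),
    c("You are already holding the fish oil and aspirin.", "fish oil", "D"),
    c("Started echinacea 1 week ago for cold.", "echinacea", "S"),
    c("Add supplements with ginger.", "ginger", "S"),
    c("I have asked him to begin using fish oil 3 capsules a per day, and he is agreeable to this.", "fish oil", "S"),
    c("I did recommend taking over-the-counter fish oil, either 500 or 1000 mg per day.", "fish oil", "U"),
    c("Avoid use of st. john's wort on methadone as it can affect systemic level.", "st john's wort", "U"),
    c("Also suggested that she could consider trying otc Ginkgo biloba.", "ginkgo", "U"),
    ## further published examples
    c("She has started ginkgo for memory issue", "ginkgo", "S"),
    c("Stop taking ginger before surgery", "ginger", "D"),
    c("The patient has discontinued taking ginseng two months ago", "ginseng", "D"),
    c("The Ginkgo biloba was discontinued on admission", "ginkgo", "D"),
    c("Pt did stop ginseng Oct 2013", "ginseng", "D"),
    c("Increase fish oil to 200 mg per day for high triglycerides", "fish oil", "C"),
    c("He was also continued on glutamine and Peridex to protect against mouth sores", "glutamine", "C"),
    c("Continued joint pain, has added glucosamine and started exercise regimen last week", "glucosamine", "S"),
    c("Patient is to start taking melatonin tonight to help her sleep", "melatonin", "S"),
    c("She was advised to take NSAID's PRN and Vitamin E daily", "vitamin e", "U"),
    c("Recommend over the counter biotin 3 mg once daily", "biotin", "U"),
    c("Pt inquiring about milk thistle", "milk thistle", "U"),
    c("Avoid grapefruit, ginseng, and St. John's wort", "ginseng", "U"),
    ## negation and competing-indicator constructions
    c("He never stopped taking the saw palmetto.", "saw palmetto", "C"),
    c("Still off estrogen and started black cohosh because of nightsweats", "black cohosh", "S"))
  sup_corpus(id = sprintf("g%02d", seq_along(rows)),
             text = vapply(rows, `[`, character(1), 1L),
             supplement = vapply(rows, `[`, character(1), 2L),
             label = vapply(rows, `[`, character(1), 3L))
}
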