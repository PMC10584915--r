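Package: presnfold
Title: Comparative Pre-snRNA Secondary Structure and Sm-Site Opening Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the conserved secondary structure that
    spliceosomal pre-snRNAs form around the Sm protein binding site, and the
    constrained-refolding pathway that opens it.  The package predicts
    suboptimal secondary structures with a built-in band-limited enumerator
    under a reduced nearest-neighbour energy model, compares structures with
    Zhang-Shasha ordered tree edit distances, selects evolutionarily
    conserved best-representative structures across species, models the
    two-step pathway from the primary folded transcript via a folding
    intermediate to a final structure with a single-stranded Sm site,
    converts SHAPE reactivities into folding constraints with windowed
    differential-reactivity significance calls, and generates synthetic
    homologous pre-snRNA gene families with planted near-Sm-site structures
    for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
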