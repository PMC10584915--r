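#!/usr/bin/env Rscript
# SHAPE-reactivity-guided folding and differential-reactivity windows on a
# synthetic probing experiment: a planted template is "probed" in a closed
# (NSS folded) and an open (Sm site exposed) state, reactivities are turned
# into hard folding constraints, and the windowed Z-factor / standard-score
# rule calls the region that changed.

suppressPackageStartupMessages(library(presnfold))
dir.create("results", showWarnings = FALSE)
set.seed(5)

tpl <- make_nss_template(seed = 5)
n <- nchar(tpl$structure$sequence)
sm_pos <- tpl$sm[1]:tpl$sm[2]

# emulate reactivities: unpaired nucleotides are flexible (high reactivity)
emulate <- function(pt) {
  r <- ifelse(is.na(pt), rnorm(n, 1.0, 0.15), abs(rnorm(n, 0.08, 0.05)))
  reactivity_profile(pmax(r, 0), rep(0.05, n), tpl$structure$sequence)
}
closed <- emulate(tpl$structure$pair_table)
open_pt <- tpl$structure$pair_table
open_pt[c(tpl$nss_pairs)] <- NA # NSS unwound in the open state
open <- emulate(open_pt)
write_reactivity_tsv(closed, "results/reactivity_closed.tsv")
write_reactivity_tsv(open, "results/reactivity_open.tsv")

# hard constraints from the closed-state profile reproduce the planted fold
cs <- reactivity_to_constraints(closed, unpaired_threshold = 0.4)
refold <- mfe(tpl$structure$sequence, constraint = cs$symbols)
cat("Planted structure:                 ", tpl$structure$dotbracket, "\n")
cat("SHAPE-constrained MFE (closed):    ", refold$dotbracket, "\n")
cat("Constraint string:                 ", cs$symbols, "\n\n")

dw <- delta_windows(closed, open)
cat("Differential windows (3-of-5 nucleotides with Z-factor > 0 and\n")
cat("|standard score| >= 1):\n")
print(dw$significant_regions)
cat("\nNSS strand positions:", min(tpl$nss_pairs), "-", max(tpl$nss_pairs),
    "; Sm site:", tpl$sm[1], "-", tpl$sm[2], "\n")
cat("The called region falls inside the unwound NSS, as expected for an\n")
cat("ex vivo (protein-free) vs in vivo (Sm-bound, NSS opened) comparison.\n")
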