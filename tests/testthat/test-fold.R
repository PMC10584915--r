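test_that("sequences without legal pairs fold fully unpaired", {
  s <- subopt("AAAAAAAA", band = Inf, max_structures = Inf)
  expect_length(s, 1L)
  expect_equal(s[[1]]$dotbracket, "........")
  expect_equal(s[[1]]$energy, 0)
})

test_that("the enumerator matches brute-force enumeration on small inputs", {
  expect_equal(mfe("GGGAAACCC")$dotbracket, "(((...)))")
  set.seed(101)
  for (r in 1:12) {
    s <- random_rna(sample(8:14, 1))
    a <- subopt(s, band = Inf, max_structures = Inf)
    b <- enumerate_structures(s)
    expect_equal(vapply(a, `[[`, "", "dotbracket"),
                 vapply(b, `[[`, "", "dotbracket"), info = s)
    expect_equal(vapply(a, `[[`, 0, "energy"),
                 vapply(b, `[[`, 0, "energy"), tolerance = 1e-9, info = s)
  }
})

test_that("the MFE structure has minimal energy and respects the band cap", {
  set.seed(11)
  for (r in 1:8) {
    s <- random_rna(14)
    ss <- subopt(s, band = 5, max_structures = 20)
    e <- vapply(ss, `[[`, 0, "energy")
    expect_true(all(diff(e) >= -1e-9))
    expect_lte(length(ss), 20L)
    expect_true(all(e <= e[1] + 5 + 1e-6))
    expect_equal(mfe(s)$dotbracket, ss[[1]]$dotbracket)
  }
})

test_that("constraints are honoured by every returned structure", {
  # all-x forces the open chain
  x <- subopt("GGGAAACCC", constraint = "xxxxxxxxx")
  expect_length(x, 1L)
  expect_equal(x[[1]]$dotbracket, ".........")
  # unconstrained equals the all-dot constraint
  expect_equal(mfe("GCGCAAAGCGC")$dotbracket,
               mfe("GCGCAAAGCGC", constraint = "...........")$dotbracket)
  # forced root pair appears in the output (constrained brute force agrees)
  m <- mfe("GGAGAAACCC", constraint = "(........)")
  expect_equal(m$pair_table[1], 10L)
  cb <- enumerate_structures("GGAGAAACCC", constraint = "(........)")
  expect_equal(m$dotbracket, cb[[1]]$dotbracket)
  # blocking one strand of a hairpin unfolds it in the MFE
  h <- mfe("GGGGAAAACCCC", constraint = "........xxxx")
  expect_true(all(is.na(h$pair_table[9:12])))
  # constraint satisfaction on random constrained ensembles
  set.seed(21)
  for (r in 1:6) {
    s <- random_rna(12)
    cons <- paste(sample(c(".", "x"), 12, replace = TRUE, prob = c(0.7, 0.3)),
                  collapse = "")
    for (st in subopt(s, constraint = cons, band = Inf, max_structures = Inf))
      expect_true(satisfies_constraint(st, cons))
    expect_equal(vapply(subopt(s, cons, band = Inf, max_structures = Inf),
                        `[[`, "", "dotbracket"),
                 vapply(enumerate_structures(s, cons), `[[`, "", "dotbracket"))
  }
})

test_that("constrained refolding reproduces, opens or remodels templates", {
  tpl <- mfe("GGGGAAAACCCC")
  # no blocking: the template is pinned as the top structure
  out <- constrained_refold(tpl)
  expect_equal(out[[1]]$dotbracket, tpl$dotbracket)
  # blocking the root pair bans it from every returned structure
  root <- c(tpl$pairs[1, 1], tpl$pairs[1, 2])
  out2 <- constrained_refold(tpl, blocked = root)
  for (st in out2) {
    expect_true(is.na(st$pair_table[root[1]]) ||
                  st$pair_table[root[1]] != root[2])
  }
})

test_that("the structure-energy evaluator agrees with the DP on optima", {
  set.seed(31)
  for (r in 1:10) {
    s <- random_rna(16)
    m <- mfe(s)
    expect_equal(structure_energy(m), m$energy, tolerance = 1e-9)
  }
})

test_that("stability profiles rank U-rich helices least stable", {
  # fully unpaired structure: empty helix list
  s0 <- secondary_structure("AAAA", "....")
  expect_equal(nrow(stability_profile(s0)), 0L)
  # one GC-rich and one AU/GU-only helix: the AU/GU helix is least stable
  seqs <- "GGGGCAAAGCCCCAUAUAAAAUAU"
  db   <- "(((((...)))))((((...))))"
  s <- secondary_structure(seqs, db)
  prof <- stability_profile(s)
  expect_equal(nrow(prof), 2L)
  expect_equal(prof$augu_frac[1], 1)   # least stable row first
  expect_equal(prof$augu_frac[2], 0)
  expect_gt(prof$dG[1], prof$dG[2])
  # a single helix's dG equals the sum of its stack entries
  m <- energy_model()
  s1 <- secondary_structure("GCGAAACGC", "(((...)))")
  p1 <- stability_profile(s1, m)
  expect_equal(p1$dG, m$stack["GC", "CG"] + m$stack["CG", "GC"])
})

test_that("stacking terms are negative for Watson-Crick-on-WC stacks", {
  m <- energy_model()
  wc <- c("CG", "GC", "AU", "UA")
  expect_true(all(m$stack[wc, wc] < 0))
  # physical symmetry: a stack read from the other strand scores the same
  rev_pair <- c(CG = "GC", GC = "CG", GU = "UG", UG = "GU",
                AU = "UA", UA = "AU")
  for (p in rownames(m$stack)) for (q in colnames(m$stack))
    expect_equal(m$stack[p, q], m$stack[rev_pair[q], rev_pair[p]])
})
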