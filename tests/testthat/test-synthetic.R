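test_that("planted templates have the promised geometry and MFE fold", {
  tpl <- make_nss_template(stem_len = 7, loop_len = 6, sm_overlap = 3,
                           seed = 17)
  sm_pos <- tpl$sm[1]:tpl$sm[2]
  # exactly 3 Sm positions are paired in the planted structure
  expect_equal(sum(!is.na(tpl$structure$pair_table[sm_pos])), 3L)
  expect_equal(nrow(tpl$nss_pairs), 7L)
  # sm_overlap = 0 leaves the Sm site fully in the loop, unpaired
  tpl0 <- make_nss_template(sm_overlap = 0, loop_len = 8, seed = 17)
  expect_true(all(is.na(tpl0$structure$pair_table[tpl0$sm[1]:tpl0$sm[2]])))
  # the generated structure is the model MFE (validity by construction)
  for (s in c(1, 2, 3)) {
    t2 <- make_nss_template(seed = s)
    expect_equal(mfe(t2$structure$sequence)$dotbracket,
                 t2$structure$dotbracket)
    # NSS pairs are all A-U or G-U
    bases <- strsplit(t2$structure$sequence, "")[[1]]
    pp <- paste0(bases[t2$nss_pairs[, 1]], bases[t2$nss_pairs[, 2]])
    expect_true(all(pp %in% c("AU", "UA", "GU", "UG")))
  }
})

test_that("homolog mutation respects divergence, compensation and the Sm site", {
  tpl <- make_nss_template(seed = 23)
  sq <- tpl$structure$sequence
  # divergence 0: identical sequence
  expect_equal(mutate_homolog(sq, tpl$structure, 0, 0.9, sm = tpl$sm,
                              seed = 1), sq)
  # Sm interval is never touched
  sm_pos <- tpl$sm[1]:tpl$sm[2]
  for (s in 1:20) {
    m <- mutate_homolog(sq, tpl$structure, 0.3, 0.5, sm = tpl$sm, seed = s)
    expect_equal(substr(m, tpl$sm[1], tpl$sm[2]),
                 substr(sq, tpl$sm[1], tpl$sm[2]))
  }
  # compensatory_prob 1: the planted structure stays legal for every mutant
  for (s in 1:20) {
    m <- mutate_homolog(sq, tpl$structure, 0.2, 1, sm = tpl$sm, seed = s)
    expect_no_error(secondary_structure(m, tpl$structure$dotbracket))
  }
  # Monte-Carlo substitution count ~ divergence * mutable sites
  div <- 0.1
  mutable <- nchar(sq) - length(sm_pos)
  nsub <- vapply(1:400, function(s) {
    m <- mutate_homolog(sq, tpl$structure, div, 0, sm = tpl$sm, seed = s)
    sum(strsplit(m, "")[[1]] != strsplit(sq, "")[[1]])
  }, 0)
  expected <- div * mutable
  tol <- 4 * sqrt(div * (1 - div) * mutable / 400) # binomial SE of the mean
  expect_lt(abs(mean(nsub) - expected), tol)
})

test_that("families are deterministic and decoy accounting is exact", {
  cfg <- sim_config(seed = 31)
  f1 <- make_family(cfg)
  f2 <- make_family(cfg)
  p1 <- withr::local_tempfile(fileext = ".fa")
  p2 <- withr::local_tempfile(fileext = ".fa")
  write_variant_fasta(f1$variant_set, p1)
  write_variant_fasta(f2$variant_set, p2)
  expect_identical(readLines(p1), readLines(p2)) # byte-identical under seed

  # zero decoy rates: the filter removes nothing
  f0 <- make_family(sim_config(decoy_fragment_rate = 0, decoy_smless_rate = 0,
                               seed = 32))
  r0 <- filter_variants(f0$variant_set)
  expect_equal(r0$report$short + r0$report$no_sm, 0L)
  expect_equal(r0$variant_set, f0$variant_set)

  # injected decoys are removed and counted exactly, nothing else is
  fhi <- make_family(sim_config(decoy_fragment_rate = 1, decoy_smless_rate = 1,
                                seed = 33))
  n_frag <- sum(vapply(fhi$decoys, function(d) "frag" %in% d, TRUE))
  n_smless <- sum(vapply(fhi$decoys, function(d) "smless" %in% d, TRUE))
  rhi <- filter_variants(fhi$variant_set)
  expect_equal(rhi$report$short, n_frag)
  expect_equal(rhi$report$no_sm, n_smless)
  kept_ids <- unlist(lapply(rhi$variant_set$per_species, function(rs)
    vapply(rs, `[[`, "", "id")))
  expect_false(any(kept_ids %in% c("frag", "smless")))
  n_true <- sum(lengths(fhi$variant_set$per_species)) - n_frag - n_smless
  expect_equal(sum(lengths(rhi$variant_set$per_species)), n_true)
})

test_that("scrambled families have distinct per-species structures", {
  fam <- make_scrambled_family(sim_config(n_species = 4, seed = 34))
  expect_gt(length(unique(fam$ground_truth)), 1L)
})
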