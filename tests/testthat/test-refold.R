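test_that("NSS detection picks the helix with maximal Sm overlap", {
  # planted template: the NSS helix encloses the whole Sm site span
  tpl <- make_nss_template(seed = 2)
  nss <- detect_nss(tpl$structure, tpl$sm)
  expect_s3_class(nss, "nss_region")
  expect_equal(nss$sm_overlap, unname(tpl$sm[2] - tpl$sm[1] + 1L))
  expect_equal(unname(nss$helix_pairs), unname(tpl$nss_pairs))

  # Sm region and window helix-free: no NSS
  seqs <- paste0("GGGGC", "AAA", "GCCCC", strrep("C", 12), "AUUUUUG",
                 strrep("C", 5))
  db <- paste0("(((((", "...", ")))))", strrep(".", 24))
  s <- secondary_structure(seqs, db)
  sm <- unname(find_sm_site(seqs))
  expect_null(detect_nss(s, sm, window = 5))

  # two candidate helices with overlaps 4 vs 1: the 4-overlap helix wins
  n <- 40L
  pairs <- list(c(5L, 15L), c(6L, 14L), c(18L, 30L), c(19L, 29L), c(20L, 28L))
  bases <- rep("A", n)
  pt <- rep(NA_integer_, n)
  for (p in pairs) {
    bases[p[1]] <- "G"; bases[p[2]] <- "C"
    pt[p[1]] <- p[2]; pt[p[2]] <- p[1]
  }
  s2 <- secondary_structure(paste(bases, collapse = ""),
                            pairtable_to_dotbracket(pt))
  nss2 <- detect_nss(s2, sm = c(15L, 21L), window = 10)
  expect_equal(unname(nss2$helix_pairs[1, ]), c(18L, 30L))
  expect_equal(nss2$sm_overlap, 4L)
})

test_that("an unpaired Sm site gives the k = 0 pathway", {
  tpl <- make_nss_template(sm_overlap = 0, loop_len = 8, seed = 4)
  expect_true(all(is.na(tpl$structure$pair_table[tpl$sm[1]:tpl$sm[2]])))
  pw <- fold_pathway(tpl$structure, sm = tpl$sm)
  expect_equal(pw$k_blocked, 0L)
  expect_equal(pw$intermediate$dotbracket, tpl$structure$dotbracket)
  expect_sm_open(pw$intermediate, tpl$sm)
  expect_sm_open(pw$final, tpl$sm)
})

test_that("minimal blocking opens the Sm site; more blocking keeps it open", {
  tpl <- make_nss_template(seed = 5)
  sm <- tpl$sm
  pw <- fold_pathway(tpl$structure, sm = sm)
  k <- pw$k_blocked
  expect_gte(k, 1L)
  expect_sm_open(pw$intermediate, sm)
  expect_sm_open(pw$final, sm)
  nss <- detect_nss(tpl$structure, sm)
  hp <- nss$helix_pairs
  refold_top <- function(kk) {
    blocked <- as.vector(t(hp[seq_len(kk), , drop = FALSE]))
    constrained_refold(tpl$structure, blocked = blocked,
                       exclude_pairs = hp)[[1]]
  }
  # minimality: k-1 leaves at least one Sm position paired
  top_km1 <- if (k > 1L) refold_top(k - 1L) else tpl$structure
  expect_true(any(!is.na(top_km1$pair_table[sm[1]:sm[2]])))
  # monotonicity: k+1 and k+2 give the same opening effect
  for (kk in (k + 1L):min(k + 2L, nrow(hp)))
    expect_sm_open(refold_top(kk), sm)
})

test_that("refolding unwinds more of the NSS than just the blocked pairs", {
  tpl <- make_nss_template(seed = 6)
  pw <- fold_pathway(tpl$structure, sm = tpl$sm)
  nss_pos <- c(tpl$nss_pairs[, 1], tpl$nss_pairs[, 2])
  blocked_n <- 2L * pw$k_blocked
  opened <- sum(is.na(pw$intermediate$pair_table[nss_pos]) &
                  !is.na(tpl$structure$pair_table[nss_pos]))
  expect_gt(opened, blocked_n) # the whole stub unfolds, not only blocked nts
})

test_that("forcing the Sm motif single-stranded is a no-op when satisfied", {
  tpl <- make_nss_template(seed = 7)
  pw <- fold_pathway(tpl$structure, sm = tpl$sm)
  # the intermediate already has Sm + 3 downstream nucleotides unpaired
  expect_equal(pw$final$dotbracket, pw$intermediate$dotbracket)
})

test_that("downstream blocking matters only when downstream nts are paired", {
  seqs <- paste0("CC", "AUUUUUG", "AUA", "CCCCC", "UAU")
  db <- paste0("..", ".......", "(((", ".....", ")))")
  inter <- secondary_structure(seqs, db)
  sm <- c(3L, 9L)
  r0 <- force_sm_single(inter, sm, downstream_n = 0)
  r3 <- force_sm_single(inter, sm, downstream_n = 3)
  expect_equal(r0$final$dotbracket, db)          # template reproduced
  expect_true(all(is.na(r3$final$pair_table[10:12])))
  expect_false(identical(r3$final$dotbracket, db))
})

test_that("the cross-species pathway keeps the Sm site open at both steps", {
  cfg <- sim_config(divergence = 0, copy_divergence = 0,
                    decoy_fragment_rate = 0,
                    decoy_smless_rate = 0, n_species = 3, seed = 8)
  fam <- make_family(cfg)
  pw <- pathway(fam$variant_set)
  expect_length(pw$failed, 0L)
  inter_dbs <- vapply(pw$per_species, function(r) r$intermediate$dotbracket, "")
  final_dbs <- vapply(pw$per_species, function(r) r$final$dotbracket, "")
  expect_equal(length(unique(inter_dbs)), 1L) # identical inputs, identical paths
  expect_equal(length(unique(final_dbs)), 1L)
  for (r in pw$per_species) {
    expect_sm_open(r$intermediate, r$sm)
    expect_sm_open(r$final, r$sm)
  }
  expect_equal(pw$intermediate_set$conservation, 0)
  expect_equal(pw$final_set$conservation, 0)
})
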