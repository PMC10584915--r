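test_that("FASTA variant sets parse, normalize and round-trip", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">hs|U2|v1", "ggGATTTc", ">mm|U2|v1", "GGGAUUUC"), path)
  vs <- read_variant_fasta(path)
  expect_s3_class(vs, "variant_set")
  expect_equal(vs$rna_name, "U2")
  expect_equal(length(vs$per_species), 2L)
  expect_equal(vs$per_species$hs[[1]]$sequence, "GGGAUUUC") # T->U, uppercase

  out <- withr::local_tempfile(fileext = ".fa")
  write_variant_fasta(vs, out)
  back <- read_variant_fasta(out)
  expect_equal(back, vs)

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">justonefield", "ACGU"), bad)
  expect_error(read_variant_fasta(bad), "malformed FASTA header")
  mixed <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">hs|U2|v1", "ACGU", ">hs|U4|v1", "ACGU"), mixed)
  expect_error(read_variant_fasta(mixed), "mixes RNAs")
})

test_that("variant filtering applies the length, Sm-site and 70K rules", {
  full <- "GGCGCCAUAACGGCGCCCCAUUUUUGACCCCC" # 32 nt, has Sm site
  frag <- substr(full, 1, 19)                # 59% of average, no Sm either
  smless <- gsub("AUUUUUG", "ACCAGCA", full)
  recs <- c(lapply(1:10, function(k) rec(paste0("v", k), "hs", "U2", full)),
            lapply(1:3, function(k) rec(paste0("f", k), "hs", "U2", frag)),
            lapply(1:2, function(k) rec(paste0("s", k), "hs", "U2", smless)))
  vs <- variant_set("U2", list(hs = recs))
  res <- filter_variants(vs)
  expect_equal(length(res$variant_set$per_species$hs), 10L)
  expect_equal(res$report$short, 3L)
  expect_equal(res$report$no_sm, 2L)

  # all identical records are all retained; filtering is idempotent
  vs2 <- variant_set("U2", list(hs = lapply(1:4, function(k)
    rec(paste0("v", k), "hs", "U2", full))))
  res2 <- filter_variants(vs2)
  expect_equal(length(res2$variant_set$per_species$hs), 4L)
  res3 <- filter_variants(res2$variant_set)
  expect_equal(res3$variant_set, res2$variant_set)

  # U1-70K motif requirement removes motif-less records
  with70k <- paste0(full, "GCAGGGCG")
  recs4 <- list(rec("a", "hs", "U1", with70k),
                rec("b", "hs", "U1", paste0(full, "CCCCCCCC")))
  vs4 <- variant_set("U1", list(hs = recs4))
  res4 <- filter_variants(vs4, require_u1_70k = TRUE,
                          u1_70k_pattern = "GCAGGGCG")
  expect_equal(length(res4$variant_set$per_species$hs), 1L)
  expect_equal(res4$variant_set$per_species$hs[[1]]$id, "a")
  expect_equal(res4$report$no_70k, 1L)
})

test_that("3' extension appends genomic context by configured lengths", {
  r <- rec("v1", "hs", "U2", "GG")
  out <- extend_3prime(r, "AUC", ext_len = 3)
  expect_equal(out$sequence, "GGAUC")
  expect_equal(extend_3prime(r, "AUC", ext_len = 0)$sequence, "GG")
  # default length comes from the per-RNA table (U2 -> 21)
  ctx <- strrep("A", 30)
  out2 <- extend_3prime(rec("v1", "hs", "U2", "GG"), ctx)
  expect_equal(nchar(out2$sequence), 2L + 21L)
  expect_equal(unname(ext_len_defaults()), c(49L, 21L, 7L, 48L))
  expect_error(extend_3prime(r, "AU", ext_len = 3), "shorter than ext_len")
})

test_that("Sm-site detection finds the 3'-most U-rich site", {
  toy <- paste0(strrep("C", 49), "AUUUUUG", strrep("C", 10))
  expect_equal(unname(find_sm_site(toy)), c(50L, 56L))
  expect_null(find_sm_site("GGGCGCGCGCCC"))
  two <- paste0(strrep("C", 9), "AUUUUUG", strrep("C", 64), "AUUUUUG", "CC")
  expect_equal(unname(find_sm_site(two))[1], 81L)
  # 5'-padding shifts the interval by exactly the pad length
  pad <- strrep("G", 13)
  expect_equal(unname(find_sm_site(paste0(pad, toy))),
               unname(find_sm_site(toy)) + 13L)
  # greedy U-run extension with G within 3 nt
  expect_equal(unname(find_sm_site("CCAUUUUUUUCAGCC")), c(3L, 13L))
  # explicit IUPAC pattern
  expect_equal(unname(find_sm_site("CCGAUUUUUGCC", pattern = "RAUUUUUG"))[1], 3L)
})

test_that("dot-bracket parsing, constraints and Vienna files behave", {
  s <- secondary_structure("GGGAAACCC", "(((...)))")
  expect_equal(s$pair_table[1], 9L)
  expect_equal(pairtable_to_dotbracket(s$pair_table), "(((...)))")
  expect_error(secondary_structure("GGGAAACCC", "(((...))"), "lengths differ")
  expect_error(secondary_structure("GGAAAAACC", "(((...)))"), "illegal base pair")
  expect_error(secondary_structure("GCGAACGCA", "((.(...))"), "unbalanced")
  expect_error(secondary_structure("GGGGACCCC", "(((....)))"[1]), "lengths differ")
  expect_error(secondary_structure("GAAAC", "(...)"[1], min_hairpin = 4), "hairpin")

  expect_error(constraint_spec("((x.."), "unbalanced")
  expect_no_error(constraint_spec("(x)..", "GACAA"))
  cs <- constraint_spec(".x(...).", "GGGAAACC")
  expect_true(cs$prohibit[2])
  expect_equal(cs$forced[3], 7L)

  vpath <- withr::local_tempfile(fileext = ".dbn")
  write_vienna(list(toy = s), vpath)
  back <- read_vienna(vpath)
  expect_equal(back$toy$dotbracket, "(((...)))")
  writeLines(c(">e", "GGGAAACCC", "(((...))) (-3.40)"), vpath)
  withE <- read_vienna(vpath)
  expect_equal(withE$e$energy, -3.4)
})
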