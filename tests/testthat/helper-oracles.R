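# Shared oracles and fixture builders.

# all dot-bracket strings of length n with hairpin loops >= 3 (shapes only)
all_dotbrackets <- local({
  memo <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (n == 0) return("")
    res <- paste0(".", all_dotbrackets(n - 1))
    if (n >= 5) {
      for (j in 5:n)
        for (inner in all_dotbrackets(j - 2))
          res <- c(res, paste0("(", inner, ")", all_dotbrackets(n - j)))
    }
    memo[[key]] <<- res
    res
  }
})

# exhaustive minimal-cost Tai mapping (independent of the Zhang-Shasha DP)
ted_bruteforce <- function(a, b) {
  ta <- if (inherits(a, "structure_tree")) a else structure_tree(a)
  tb <- if (inherits(b, "structure_tree")) b else structure_tree(b)
  presnfold:::tai_bruteforce_cpp(ta$pre_labels, ta$pre_parent,
                                 tb$pre_labels, tb$pre_parent)
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")

# a three-species FASTA fixture written to a temp file
write_toy_fasta <- function(path, rna = "U2") {
  lines <- c(">hs|U2|v1", "GGGCGCAAAGCGCCCAUUUUUGAA",
             ">mm|U2|v1", "GGGCGCAAAGCGCCCAUUUUUGAA",
             ">dr|U2|v1", "GGGCGCAAAGCGCCUAUUUUUGAA")
  writeLines(lines, path)
  path
}

# plain record constructor
rec <- function(id, species, rna, sequence)
  list(id = id, species = species, rna_name = rna, sequence = sequence)

expect_sm_open <- function(s, sm) {
  expect_true(all(is.na(s$pair_table[sm[1]:sm[2]])))
}
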