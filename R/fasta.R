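#' Read a FASTA file of snRNA gene variants into a variant set
#'
#' Headers must follow a `species<delim>rna<delim>id` convention (default
#' delimiter `|`), e.g. `>hs|U2|v1`.  T is converted to U and lowercase is
#' uppercased.  All records must belong to a single RNA.
#'
#' @param path FASTA path.
#' @param delim header field delimiter (default `"|"`).
#' @return a `variant_set`: list with `rna_name` and `per_species`, a named
#'   list (species) of lists of records; each record has `id`, `species`,
#'   `rna_name`, `sequence`.
#' @export
read_variant_fasta <- function(path, delim = "|") {
  xs <- Biostrings::readBStringSet(path)
  if (length(xs) == 0L) stop("empty FASTA file: ", path)
  recs <- lapply(seq_along(xs), function(k) {
    header <- names(xs)[k]
    fields <- strsplit(header, delim, fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("malformed FASTA header (expected species", delim, "rna", delim,
           "id): '", header, "' (record ", k, ")")
    list(id = fields[3], species = fields[1], rna_name = fields[2],
         sequence = normalize_rna(as.character(xs[[k]])))
  })
  rna <- unique(vapply(recs, `[[`, "", "rna_name"))
  if (length(rna) != 1L)
    stop("FASTA mixes RNAs (", paste(rna, collapse = ", "),
         "); one variant set holds a single RNA")
  species <- vapply(recs, `[[`, "", "species")
  per_species <- split(recs, factor(species, levels = unique(species)))
  ids <- vapply(recs, `[[`, "", "id")
  key <- paste(species, ids)
  if (anyDuplicated(key))
    stop("duplicate (species, id) in FASTA: ", key[duplicated(key)][1])
  variant_set(rna, per_species)
}

#' Construct a variant set
#'
#' @param rna_name RNA name (e.g. "U2").
#' @param per_species named list: species -> list of records (each with
#'   `id`, `species`, `rna_name`, `sequence`).
#' @return a `variant_set`.
#' @export
variant_set <- function(rna_name, per_species) {
  if (!length(per_species)) stop("species list must be non-empty")
  if (is.null(names(per_species)) || any(!nzchar(names(per_species))))
    stop("per_species must be a named list")
  for (sp in names(per_species))
    for (r in per_species[[sp]])
      if (!identical(r$rna_name, rna_name))
        stop("record ", r$id, " has rna_name ", r$rna_name,
             " but the set is ", rna_name)
  structure(list(rna_name = rna_name, per_species = per_species),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", x$rna_name, "-", length(x$per_species), "species, ",
      sum(lengths(x$per_species)), "variants\n")
  invisible(x)
}

#' Write a variant set to FASTA
#'
#' @param vs a `variant_set`.
#' @param path output path.
#' @param delim header delimiter.
#' @export
write_variant_fasta <- function(vs, path, delim = "|") {
  recs <- unlist(vs$per_species, recursive = FALSE, use.names = FALSE)
  seqs <- Biostrings::BStringSet(vapply(recs, `[[`, "", "sequence"))
  names(seqs) <- vapply(recs, function(r)
    paste(r$species, r$rna_name, r$id, sep = delim), "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Filter gene variants the way incomplete database copies are removed
#'
#' Removes gene fragments shorter than `min_len_frac` of the average variant
#' length (the average is taken over all input records of the RNA, pooled
#' across species, before any removal), then variants lacking a complete Sm
#' site, and optionally -- for U1 -- variants lacking the U1-70K binding
#' motif.
#'
#' @param vs a `variant_set`.
#' @param min_len_frac length threshold as a fraction of the average (0.75).
#' @param sm_pattern Sm-site pattern passed to [find_sm_site()]; `NULL` uses
#'   the default U-rich rule.
#' @param require_u1_70k also require the U1-70K motif (for U1 sets).
#' @param u1_70k_pattern IUPAC motif for the U1-70K binding site; required
#'   when `require_u1_70k` is `TRUE`.
#' @return list with `variant_set` (filtered) and `report` (counts of
#'   removals per rule plus dropped species).
#' @export
filter_variants <- function(vs, min_len_frac = 0.75, sm_pattern = NULL,
                            require_u1_70k = FALSE, u1_70k_pattern = NULL) {
  stopifnot(inherits(vs, "variant_set"))
  if (require_u1_70k && is.null(u1_70k_pattern))
    stop("u1_70k_pattern must be supplied when require_u1_70k is TRUE")
  all_len <- unlist(lapply(vs$per_species, function(rs)
    vapply(rs, function(r) nchar(r$sequence), 0)))
  if (!length(all_len)) stop("variant set has no records")
  avg <- mean(all_len)
  n_short <- 0L; n_no_sm <- 0L; n_no_70k <- 0L
  dropped_species <- character(0)
  kept <- list()
  for (sp in names(vs$per_species)) {
    keep <- list()
    for (r in vs$per_species[[sp]]) {
      if (nchar(r$sequence) < min_len_frac * avg) {
        n_short <- n_short + 1L
        next
      }
      if (is.null(find_sm_site(r$sequence, pattern = sm_pattern))) {
        n_no_sm <- n_no_sm + 1L
        next
      }
      if (require_u1_70k &&
          !length(iupac_matches(r$sequence, u1_70k_pattern))) {
        n_no_70k <- n_no_70k + 1L
        next
      }
      keep[[length(keep) + 1L]] <- r
    }
    if (length(keep)) kept[[sp]] <- keep else dropped_species <- c(dropped_species, sp)
  }
  if (length(dropped_species))
    warning("species dropped (no variants left): ",
            paste(dropped_species, collapse = ", "))
  if (!length(kept)) stop("no variants survived filtering")
  list(variant_set = variant_set(vs$rna_name, kept),
       report = list(short = n_short, no_sm = n_no_sm, no_70k = n_no_70k,
                     average_length = avg, dropped_species = dropped_species))
}

#' Default 3' extension lengths per RNA
#'
#' Lengths of the 3' extra sequence found in human pre-snRNAs, used to build
#' precursor sequences from mature sequences plus genomic context.
#'
#' @return named integer vector.
#' @export
ext_len_defaults <- function() c(U1 = 49L, U2 = 21L, U4 = 7L, U5 = 48L)

#' Extend a mature snRNA record 3'-ward into its genomic context
#'
#' @param rec a record (list with `sequence`, `rna_name`, ...) or a plain
#'   sequence string.
#' @param genomic_context sense-strand sequence beginning at the nucleotide
#'   immediately 3' of the mature end.
#' @param ext_len number of nucleotides to append; `NULL` looks the RNA up
#'   in [ext_len_defaults()].
#' @return the record (or string) with the extended sequence.
#' @export
extend_3prime <- function(rec, genomic_context, ext_len = NULL) {
  plain <- is.character(rec)
  seqstr <- if (plain) normalize_rna(rec) else rec$sequence
  if (is.null(ext_len)) {
    rna <- if (plain) NULL else rec$rna_name
    defaults <- ext_len_defaults()
    if (is.null(rna) || !rna %in% names(defaults))
      stop("ext_len not given and no default for RNA '", rna, "'")
    ext_len <- defaults[[rna]]
  }
  ext_len <- as.integer(ext_len)
  if (ext_len < 0L) stop("ext_len must be >= 0")
  if (ext_len == 0L) return(rec)
  ctx <- normalize_rna(genomic_context)
  if (nchar(ctx) < ext_len)
    stop("genomic context (", nchar(ctx), " nt) shorter than ext_len (",
         ext_len, ")")
  ext <- paste0(seqstr, substr(ctx, 1L, ext_len))
  if (plain) ext else { rec$sequence <- ext; rec }
}

iupac_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", U = "U", T = "U",
           R = "[AG]", Y = "[CU]", S = "[GC]", W = "[AU]",
           K = "[GU]", M = "[AC]", B = "[CGU]", D = "[AGU]",
           H = "[ACU]", V = "[ACG]", N = "[ACGU]")
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(map))
  if (length(bad)) stop("invalid IUPAC characters: ", paste(bad, collapse = " "))
  paste0(map[chars], collapse = "")
}

# start positions of all IUPAC motif matches (1-based)
iupac_matches <- function(sequence, pattern) {
  re <- iupac_regex(pattern)
  m <- gregexpr(paste0("(?=", re, ")"), normalize_rna(sequence), perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Locate the Sm site in a sequence
#'
#' The Sm site is the conserved single-stranded U-rich stretch near the
#' snRNA 3' end.  With `pattern = NULL` the default rule is used: an `A`
#' followed by a run of at least four `U`s extended greedily, with a `G`
#' required within three nucleotides after the run; the reported interval
#' runs from the `A` through that `G`.  Alternatively an explicit IUPAC
#' motif can be supplied.  When several matches exist the 3'-most is
#' returned (Sm sites sit near the 3' end).
#'
#' @param sequence RNA string.
#' @param pattern optional IUPAC motif overriding the default rule.
#' @return integer vector `c(start, end)`, 1-based inclusive, or `NULL` if
#'   absent.
#' @export
find_sm_site <- function(sequence, pattern = NULL) {
  s <- normalize_rna(sequence)
  if (!is.null(pattern)) {
    starts <- iupac_matches(s, pattern)
    if (!length(starts)) return(NULL)
    st <- max(starts)
    return(c(start = st, end = st + nchar(pattern) - 1L))
  }
  m <- gregexpr("AU{4,}", s, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  best <- NULL
  for (q in seq_along(m)) {
    st <- as.integer(m[q])
    run_end <- st + attr(m, "match.length")[q] - 1L
    tail_start <- run_end + 1L
    tail_end <- min(nchar(s), run_end + 3L)
    if (tail_start > nchar(s)) next
    tail <- substr(s, tail_start, tail_end)
    g <- regexpr("G", tail, fixed = TRUE)
    if (g > 0L) best <- c(start = st, end = run_end + as.integer(g))
  }
  best
}
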