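#' Generate a toy pre-snRNA template with a planted NSS
#'
#' Builds a short pre-snRNA-like sequence containing, 5' to 3': an
#' optional stable G/C flanking hairpin, a U-rich Sm site, and a planted
#' Near Sm-site Structure (NSS) -- an A-U/G-U-paired stem whose loop holds
#' the Sm 5' portion and whose 3' arm starts with the Sm 3' portion -- plus
#' a low-complexity 3' extension.  Unstructured linkers and the tail are
#' C-rich so the planted fold is the model's MFE structure, which is
#' verified at generation (the draw is retried if an alternative fold
#' wins).
#'
#' @param stem_len NSS stem length in pairs (>= 2; default 9).
#' @param loop_len NSS loop length (>= Sm-in-loop part; default 6).
#' @param sm_overlap number of Sm-site nucleotides drawn into the NSS stem
#'   (default 3).
#' @param gc_flanks include the stable G/C hairpin 5' of the Sm site
#'   (default TRUE).
#' @param ext_len 3' extension length (default 8).
#' @param seed RNG seed.
#' @param model energy model used for the MFE check.
#' @param max_tries redraw attempts before giving up.
#' @return list with `structure` (a `secondary_structure`, the planted MFE
#'   fold), `sm` (interval), `nss_pairs` (two-column matrix, root first).
#' @export
make_nss_template <- function(stem_len = 9L, loop_len = 6L, sm_overlap = 3L,
                              gc_flanks = TRUE, ext_len = 8L, seed = NULL,
                              model = energy_model(), max_tries = 40L) {
  stem_len <- as.integer(stem_len); loop_len <- as.integer(loop_len)
  sm_overlap <- as.integer(sm_overlap)
  sm_seq <- c("A", "U", "U", "U", "U", "U", "G")
  if (stem_len < 2L) stop("stem_len must be >= 2")
  if (sm_overlap < 0L || sm_overlap > length(sm_seq))
    stop("sm_overlap must be between 0 and ", length(sm_seq))
  if (sm_overlap > stem_len) stop("sm_overlap cannot exceed stem_len")
  in_loop <- length(sm_seq) - sm_overlap
  pad <- loop_len - in_loop
  if (pad < 0L) stop("loop_len too small to hold the Sm 5' portion (need >= ",
                     in_loop, ")")
  if (loop_len < 3L) stop("loop_len must be >= 3")
  if (pad == 0L && sm_overlap > 0L && sm_overlap < length(sm_seq))
    stop("loop_len must exceed the Sm 5' portion by at least 1 ",
         "(a flush A-U loop closure would extend the stem)")
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      arm3_extra <- sample(c("U", "A"), stem_len - sm_overlap, replace = TRUE,
                           prob = c(0.75, 0.25))
      sm_tail <- if (sm_overlap > 0L)
        sm_seq[(in_loop + 1L):length(sm_seq)] else character(0)
      arm3 <- c(sm_tail, arm3_extra)
      partner <- function(b) switch(b,
        U = sample(c("A", "G"), 1, prob = c(0.7, 0.3)),
        A = "U", G = "U", C = "G")
      arm5 <- rev(vapply(arm3, partner, ""))
      h1_5 <- sample(c("G", "C"), 6, replace = TRUE)
      h1 <- c(h1_5, rep("C", 3), rev(chartr("GC", "CG", h1_5)))
      parts <- list()
      if (gc_flanks) parts$h1 <- h1
      parts$spacer <- c("C", "C")
      parts$arm5 <- arm5
      # the C pad goes 5' of the Sm loop portion so the loop-closing bases
      # cannot pair and silently extend the stem; with the whole Sm site in
      # the loop the pad moves 3' of it for the same reason (C against A)
      parts$loop <- if (sm_overlap > 0L)
        c(rep("C", pad), sm_seq[seq_len(in_loop)])
      else c(sm_seq, rep("C", pad))
      parts$arm3 <- arm3
      parts$tail <- rep("C", ext_len)
      seqc <- unlist(parts, use.names = FALSE)
      n <- length(seqc)
      off <- function(name) { # start offset of a part
        before <- 0L
        for (nm in names(parts)) {
          if (nm == name) return(before)
          before <- before + length(parts[[nm]])
        }
        stop("unknown part")
      }
      pt <- rep(NA_integer_, n)
      if (gc_flanks) {
        o <- off("h1")
        for (k in 1:6) { pt[o + k] <- o + 16L - k; pt[o + 16L - k] <- o + k }
      }
      o5 <- off("arm5"); o3 <- off("arm3")
      nss_pairs <- matrix(0L, nrow = stem_len, ncol = 2)
      for (k in seq_len(stem_len)) {
        i <- o5 + k; j <- o3 + stem_len + 1L - k
        pt[i] <- j; pt[j] <- i
        nss_pairs[k, ] <- c(i, j)
      }
      sm_start <- off("loop") + (if (sm_overlap > 0L) pad else 0L) + 1L
      sm <- c(start = sm_start, end = sm_start + length(sm_seq) - 1L)
      seqstr <- paste(seqc, collapse = "")
      planted <- secondary_structure(seqstr, pairtable_to_dotbracket(pt))
      planted$energy <- structure_energy(planted, model)
      pred <- mfe(seqstr, model = model)
      if (identical(pred$dotbracket, planted$dotbracket)) {
        planted$energy <- pred$energy
        return(list(structure = planted, sm = sm, nss_pairs = nss_pairs))
      }
    }
    stop("could not generate a template whose planted fold is the MFE ",
         "structure in ", max_tries, " tries")
  })
}

#' Mutate a homologous gene variant from a template
#'
#' Each position outside the Sm interval is substituted with probability
#' `divergence`.  Substitutions at paired positions are compensated with
#' probability `compensatory_prob`: the partner is changed so a legal pair
#' (A-U/G-C/G-U, either orientation) is preserved.  When the partner lies
#' inside the protected Sm interval the substitution itself is redrawn to
#' a base that keeps the pair legal instead.  The Sm interval is never
#' touched.
#'
#' @param sequence template RNA string.
#' @param struct template `secondary_structure` (pairing pattern).
#' @param divergence per-site substitution probability.
#' @param compensatory_prob probability a paired-site substitution is
#'   compensated.
#' @param sm protected Sm interval `c(start, end)`; `NULL` protects
#'   nothing.
#' @param seed RNG seed.
#' @return mutated sequence string.
#' @export
mutate_homolog <- function(sequence, struct, divergence, compensatory_prob,
                           sm = NULL, seed = NULL) {
  bases <- c("A", "C", "G", "U")
  legal_partner <- list(A = "U", C = "G", G = c("C", "U"), U = c("A", "G"))
  s <- strsplit(normalize_rna(sequence), "")[[1]]
  pt <- struct$pair_table
  if (length(pt) != length(s)) stop("structure does not fit the sequence")
  protected <- if (is.null(sm)) integer(0) else sm[1]:sm[2]
  with_seed(seed, {
    for (i in seq_along(s)) {
      if (i %in% protected) next
      if (stats::runif(1) >= divergence) next
      new <- sample(setdiff(bases, s[i]), 1)
      j <- pt[i]
      if (!is.na(j) && stats::runif(1) < compensatory_prob) {
        if (j %in% protected) {
          # cannot touch the partner: redraw the substitution itself
          ok <- legal_partner[[s[j]]]
          cand <- setdiff(ok, s[i])
          if (!length(cand)) next
          s[i] <- if (length(cand) == 1L) cand else sample(cand, 1)
        } else {
          s[i] <- new
          ok <- legal_partner[[new]]
          s[j] <- if (length(ok) == 1L) ok else sample(ok, 1)
        }
      } else {
        s[i] <- new
      }
    }
    paste(s, collapse = "")
  })
}

#' Simulation configuration for synthetic pre-snRNA families
#'
#' Defaults emulate the study conditions used throughout the validation
#' experiments: six species, two to four gene variants per species, 5%
#' per-site divergence with 90% compensatory substitutions in helices, and
#' a 10% chance each of a short gene fragment and of an Sm-less decoy per
#' species.
#'
#' @param n_species number of species.
#' @param variants_per_species range `c(min, max)` of variants per species.
#' @param divergence per-site substitution probability of a species lineage
#'   relative to the family template.
#' @param copy_divergence per-site substitution probability of an individual
#'   gene copy relative to its species sequence (gene copies within one
#'   genome are nearly identical; default 0.01).
#' @param compensatory_prob compensation probability for paired sites.
#' @param decoy_fragment_rate per-species probability of one short-fragment
#'   decoy.
#' @param decoy_smless_rate per-species probability of one Sm-less decoy.
#' @param stem_len,loop_len,sm_overlap,gc_flanks,ext_len template geometry
#'   (see [make_nss_template()]).
#' @param rna_name label for the simulated RNA.
#' @param seed RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species = 6L, variants_per_species = c(2L, 4L),
                       divergence = 0.05, copy_divergence = 0.01,
                       compensatory_prob = 0.9,
                       decoy_fragment_rate = 0.1, decoy_smless_rate = 0.1,
                       stem_len = 9L, loop_len = 6L, sm_overlap = 3L,
                       gc_flanks = TRUE, ext_len = 8L,
                       rna_name = "simU", seed = 1L) {
  stopifnot(n_species >= 1, divergence >= 0, divergence <= 1,
            compensatory_prob >= 0, compensatory_prob <= 1,
            decoy_fragment_rate >= 0, decoy_fragment_rate <= 1,
            decoy_smless_rate >= 0, decoy_smless_rate <= 1)
  structure(list(n_species = as.integer(n_species),
                 variants_per_species = as.integer(variants_per_species),
                 divergence = divergence,
                 copy_divergence = copy_divergence,
                 compensatory_prob = compensatory_prob,
                 decoy_fragment_rate = decoy_fragment_rate,
                 decoy_smless_rate = decoy_smless_rate,
                 stem_len = as.integer(stem_len),
                 loop_len = as.integer(loop_len),
                 sm_overlap = as.integer(sm_overlap),
                 gc_flanks = isTRUE(gc_flanks),
                 ext_len = as.integer(ext_len),
                 rna_name = rna_name, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a family of homologous pre-snRNA gene variants
#'
#' Draws one planted-NSS template, derives one species sequence per
#' "species" by mutating the template at `divergence`, then emits the
#' species' gene-copy variants by mutating the species sequence at the much
#' smaller `copy_divergence` (database gene copies within one genome are
#' nearly identical).  At the configured rates each species additionally
#' receives decoys: a gene fragment truncated to 60% of the template length
#' and an Sm-less variant with a scrambled Sm site.  Deterministic under
#' the seed.
#'
#' @param cfg a [sim_config()].
#' @return a `simulated_family`: list with `variant_set`, `template` (the
#'   planted `secondary_structure`), `sm`, `nss_pairs`, `ground_truth`
#'   (per-species planted dot-bracket), and `decoys` (bookkeeping of
#'   injected decoy ids per species).
#' @export
make_family <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    tpl <- make_nss_template(stem_len = cfg$stem_len, loop_len = cfg$loop_len,
                             sm_overlap = cfg$sm_overlap,
                             gc_flanks = cfg$gc_flanks, ext_len = cfg$ext_len)
    species <- sprintf("sp%02d", seq_len(cfg$n_species))
    per_species <- list()
    decoys <- list()
    for (sp in species) {
      species_seq <- mutate_homolog(tpl$structure$sequence, tpl$structure,
                                    cfg$divergence, cfg$compensatory_prob,
                                    sm = tpl$sm)
      nv <- if (cfg$variants_per_species[1] == cfg$variants_per_species[2])
        cfg$variants_per_species[1]
      else sample(cfg$variants_per_species[1]:cfg$variants_per_species[2], 1)
      recs <- list()
      for (v in seq_len(nv)) {
        mseq <- mutate_homolog(species_seq, tpl$structure,
                               cfg$copy_divergence, cfg$compensatory_prob,
                               sm = tpl$sm)
        recs[[length(recs) + 1L]] <-
          list(id = paste0("v", v), species = sp, rna_name = cfg$rna_name,
               sequence = mseq)
      }
      dk <- character(0)
      if (stats::runif(1) < cfg$decoy_fragment_rate) {
        mseq <- mutate_homolog(species_seq, tpl$structure,
                               cfg$copy_divergence, cfg$compensatory_prob,
                               sm = tpl$sm)
        frag <- substr(mseq, 1L, floor(0.6 * nchar(mseq)))
        recs[[length(recs) + 1L]] <-
          list(id = "frag", species = sp, rna_name = cfg$rna_name,
               sequence = frag)
        dk <- c(dk, "frag")
      }
      if (stats::runif(1) < cfg$decoy_smless_rate) {
        mseq <- mutate_homolog(species_seq, tpl$structure,
                               cfg$copy_divergence, cfg$compensatory_prob,
                               sm = tpl$sm)
        s <- strsplit(mseq, "")[[1]]
        s[tpl$sm[1]:tpl$sm[2]] <- c("A", "C", "C", "A", "G", "C", "A")
        mseq <- paste(s, collapse = "")
        guard <- 0L
        while (!is.null(hit <- find_sm_site(mseq)) && guard < 50L) {
          s <- strsplit(mseq, "")[[1]]
          us <- which(s[hit[1]:hit[2]] == "U") + hit[1] - 1L
          s[us[1]] <- "C"
          mseq <- paste(s, collapse = "")
          guard <- guard + 1L
        }
        recs[[length(recs) + 1L]] <-
          list(id = "smless", species = sp, rna_name = cfg$rna_name,
               sequence = mseq)
        dk <- c(dk, "smless")
      }
      per_species[[sp]] <- recs
      decoys[[sp]] <- dk
    }
    gt <- stats::setNames(rep(tpl$structure$dotbracket, length(species)),
                          species)
    structure(list(variant_set = variant_set(cfg$rna_name, per_species),
                   template = tpl$structure, sm = tpl$sm,
                   nss_pairs = tpl$nss_pairs, ground_truth = gt,
                   decoys = decoys, config = cfg),
              class = "simulated_family")
  })
}

#' Simulate a structurally unrelated ("scrambled") family
#'
#' Negative control for conservation scoring: every species receives its
#' own independently drawn template with randomized geometry (stem, loop,
#' spacer and extension lengths), so there is no shared structure to
#' recover -- the analogue of clades without a conserved precursor fold.
#' Variant counts, divergence and decoy rates follow the configuration.
#'
#' @param cfg a [sim_config()].
#' @return a `simulated_family` (with per-species `ground_truth` differing
#'   across species).
#' @export
make_scrambled_family <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    species <- sprintf("sp%02d", seq_len(cfg$n_species))
    per_species <- list()
    gt <- character(0)
    sms <- list()
    for (sp in species) {
      # stems below ~8 A-U/G-U pairs rarely beat the open fold, so the
      # randomized geometry stays in the viable range
      tpl <- make_nss_template(stem_len = sample(8:12, 1),
                               loop_len = sample(6:9, 1),
                               sm_overlap = cfg$sm_overlap,
                               gc_flanks = sample(c(TRUE, FALSE), 1),
                               ext_len = sample(4:12, 1))
      nv <- if (cfg$variants_per_species[1] == cfg$variants_per_species[2])
        cfg$variants_per_species[1]
      else sample(cfg$variants_per_species[1]:cfg$variants_per_species[2], 1)
      recs <- list()
      for (v in seq_len(nv)) {
        mseq <- mutate_homolog(tpl$structure$sequence, tpl$structure,
                               cfg$copy_divergence, cfg$compensatory_prob,
                               sm = tpl$sm)
        recs[[length(recs) + 1L]] <-
          list(id = paste0("v", v), species = sp, rna_name = cfg$rna_name,
               sequence = mseq)
      }
      per_species[[sp]] <- recs
      gt[sp] <- tpl$structure$dotbracket
      sms[[sp]] <- tpl$sm
    }
    structure(list(variant_set = variant_set(cfg$rna_name, per_species),
                   template = NULL, sm = sms, nss_pairs = NULL,
                   ground_truth = gt, decoys = list(), config = cfg),
              class = "simulated_family")
  })
}
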