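#' Reduced nearest-neighbour energy model
#'
#' The built-in folding engine scores structures with a reduced
#' nearest-neighbour model: sequence-dependent stacking energies for
#' adjacent base pairs, length-dependent hairpin/bulge/internal-loop
#' penalties with Jacobson-Stockmayer extrapolation, and a linear multiloop
#' penalty.  Stacking terms for Watson-Crick-on-Watson-Crick stacks are all
#' negative; A-U and G-U containing stacks are markedly weaker than G-C
#' stacks, which is what makes U-rich helices the least stable elements of
#' a fold.  Dangles, coaxial stacking and tetraloop bonuses are outside the
#' model.
#'
#' @param min_hairpin minimum hairpin loop length (default 3).
#' @param max_interior largest total unpaired size of a bulge/internal loop
#'   considered by the engine (default 30).
#' @param ml_close,ml_branch,ml_unpaired multiloop closing, per-branch and
#'   per-unpaired-nucleotide penalties (kcal/mol).
#' @return a list of model tables consumed by the folding functions.
#' @export
energy_model <- function(min_hairpin = 3L, max_interior = 30L,
                         ml_close = 3.4, ml_branch = 0.4, ml_unpaired = 0.0) {
  # pair order: CG GC GU UG AU UA; rows = outer pair, cols = inner pair
  M <- matrix(c(
    -3.3, -3.4, -2.1, -1.4, -2.1, -2.1,
    -3.4, -3.3, -2.5, -1.5, -2.2, -2.4,
    -1.4, -1.5, -0.5,  0.3, -0.6, -1.0,
    -2.1, -2.5, -0.5, -0.5, -1.4, -1.3,
    -2.1, -2.4, -1.3, -1.0, -0.9, -1.3,
    -2.1, -2.2, -1.4, -0.6, -1.1, -0.9), nrow = 6, byrow = TRUE)
  rev_idx <- c(2L, 1L, 4L, 3L, 6L, 5L) # CG<->GC, GU<->UG, AU<->UA
  # a stack read 5'->3' on the other strand is the same physical motif
  sym <- matrix(0, 6, 6)
  for (p in 1:6) for (q in 1:6) sym[p, q] <- M[rev_idx[q], rev_idx[p]]
  stack <- (M + sym) / 2
  dimnames(stack) <- list(c("CG","GC","GU","UG","AU","UA"),
                          c("CG","GC","GU","UG","AU","UA"))
  rt <- 0.0019872 * 310.15
  js <- function(base, ref, L) base + 1.75 * rt * log(L / ref)
  hairpin <- numeric(500)
  hstart <- c(5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4) # loop lengths 3..9
  hairpin[1:2] <- 1e9
  hairpin[3:9] <- hstart
  hairpin[10:500] <- js(6.4, 9, 10:500)
  bulge <- numeric(60)
  bulge[1:6] <- c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4)
  bulge[7:60] <- js(4.4, 6, 7:60)
  internal <- numeric(60)
  internal[1] <- 1e9 # internal loops have >=1 nt on each side
  internal[2:6] <- 0.8 + 0.4 * (2:6)
  internal[7:60] <- js(3.2, 6, 7:60)
  list(stack = stack, hairpin = hairpin, bulge = bulge, internal = internal,
       asym_coef = 0.5, asym_max = 2.0,
       ml_close = ml_close, ml_branch = ml_branch, ml_unpaired = ml_unpaired,
       min_hairpin = as.integer(min_hairpin),
       max_interior = as.integer(max_interior))
}

seq_to_codes <- function(sequence) {
  s <- normalize_rna(sequence)
  match(strsplit(s, "")[[1]], c("A", "C", "G", "U")) - 1L
}

#' Predict suboptimal secondary structures (built-in enumerator)
#'
#' Band-limited exhaustive enumeration under the reduced nearest-neighbour
#' model: all structures within `band` kcal/mol of the minimum free energy
#' are generated and the `max_structures` lowest-energy ones returned,
#' sorted by energy with lexicographic dot-bracket tie-breaking (so reruns
#' are bit-identical).  Hard constraints are honoured: `x` positions never
#' pair and forced `(`/`)` pairs are present in every returned structure.
#'
#' @param sequence RNA string.
#' @param constraint `NULL`, a constraint string, or a [constraint_spec()].
#' @param max_structures maximum number of structures (default 20).
#' @param band energy band above the MFE in kcal/mol (default 5); `Inf`
#'   enumerates the complete structure space (only sensible for short
#'   sequences).
#' @param model energy model from [energy_model()].
#' @return list of `secondary_structure`, energy-sorted; empty (with a
#'   warning) when the constraint is unsatisfiable.
#' @export
subopt <- function(sequence, constraint = NULL, max_structures = 20,
                   band = 5, model = energy_model()) {
  if (max_structures < 1) stop("max_structures must be >= 1")
  s <- normalize_rna(sequence)
  n <- nchar(s)
  cs <- as_constraint(constraint, n, s)
  res <- fold_subopt_cpp(seq_to_codes(s),
                         ifelse(is.na(cs$forced), -1L, cs$forced - 1L),
                         cs$prohibit,
                         band, as.numeric(max_structures), model)
  if (!res$satisfiable) {
    warning("constraint is unsatisfiable; returning no structures")
    return(list())
  }
  out <- vector("list", length(res$dotbracket))
  for (k in seq_along(out))
    out[[k]] <- secondary_structure(s, res$dotbracket[k], energy = res$energy[k])
  bad <- !vapply(out, satisfies_constraint, logical(1), constraint = cs)
  if (any(bad)) stop("internal error: enumerator violated the constraint")
  out
}

#' Minimum free energy structure
#'
#' First structure of [subopt()]; with a `template` structure its pairs are
#' forced wherever the sequence still permits them, so the template serves
#' as a structural scaffold for e.g. mutant prediction.
#'
#' @inheritParams subopt
#' @param template optional `secondary_structure` whose pairs are applied as
#'   forced-pair constraints where the sequence allows.
#' @return a single `secondary_structure`.
#' @export
mfe <- function(sequence, constraint = NULL, template = NULL,
                model = energy_model()) {
  if (!is.null(template)) {
    if (!is.null(constraint))
      stop("give either a constraint or a template, not both")
    constraint <- template_constraint(template, normalize_rna(sequence))
  }
  out <- subopt(sequence, constraint, max_structures = 1, band = 0,
                model = model)
  if (!length(out)) stop("no structure satisfies the constraint")
  out[[1]]
}

# constraint string forcing the template's pairs where `sequence` (which may
# carry mutations) still forms a legal pair; other positions unconstrained
template_constraint <- function(template, sequence, blocked = integer(0),
                                exclude_pairs = NULL) {
  n <- nchar(sequence)
  if (length(template) != n)
    stop("template and sequence lengths differ")
  bases <- strsplit(sequence, "")[[1]]
  sym <- rep(".", n)
  sym[blocked] <- "x"
  drop <- character(0)
  if (!is.null(exclude_pairs) && nrow(exclude_pairs))
    drop <- paste(exclude_pairs[, 1], exclude_pairs[, 2])
  pr <- template$pairs
  if (nrow(pr)) for (q in seq_len(nrow(pr))) {
    i <- pr[q, 1]; j <- pr[q, 2]
    if (i %in% blocked || j %in% blocked) next          # blocked wins
    if (paste(i, j) %in% drop) next
    if (!paste0(bases[i], bases[j]) %in%
        c("AU", "UA", "GC", "CG", "GU", "UG")) next     # mutation broke it
    sym[i] <- "("; sym[j] <- ")"
  }
  paste(sym, collapse = "")
}

#' Constrained refolding around blocked nucleotides
#'
#' Rebuilds the ensemble of a folded transcript when a set of nucleotides is
#' blocked from base-pairing (mimicking protein binding or helicase action).
#' The constraint combines the template structure with the blocked set:
#' blocked positions become `x`, template pairs with both ends unblocked are
#' forced (pairs touching a blocked position are dropped -- blocking wins),
#' everything else is free.  Pairs listed in `exclude_pairs` (e.g. the
#' helix being opened) are not forced either, leaving the folding engine
#' free to unwind or retain them on energetic grounds.
#'
#' @param template a `secondary_structure` (the fold being remodelled).
#' @param blocked integer vector of 1-based positions prohibited from
#'   pairing.
#' @param exclude_pairs optional two-column matrix of template pairs to
#'   leave unconstrained rather than forced.
#' @inheritParams subopt
#' @return list of `secondary_structure` as from [subopt()].
#' @export
constrained_refold <- function(template, blocked = integer(0),
                               exclude_pairs = NULL, max_structures = 20,
                               band = 5, model = energy_model()) {
  stopifnot(inherits(template, "secondary_structure"))
  n <- length(template)
  blocked <- as.integer(blocked)
  if (length(blocked) && (min(blocked) < 1L || max(blocked) > n))
    stop("blocked positions outside the sequence")
  cons <- template_constraint(template, template$sequence, blocked = blocked,
                              exclude_pairs = exclude_pairs)
  subopt(template$sequence, cons, max_structures = max_structures,
         band = band, model = model)
}

#' Free energy of a given structure under the model
#'
#' Evaluated by loop decomposition, independently of the folding DP.
#'
#' @param s a `secondary_structure`.
#' @param model energy model.
#' @return energy in kcal/mol.
#' @export
structure_energy <- function(s, model = energy_model()) {
  stopifnot(inherits(s, "secondary_structure"))
  pt <- ifelse(is.na(s$pair_table), -1L, s$pair_table - 1L)
  eval_energy_cpp(seq_to_codes(s$sequence), pt, model)
}

#' Exhaustively enumerate all structures of a short sequence
#'
#' Generates every pseudoknot-free structure over the allowed pair set with
#' the model's minimum hairpin size, honours constraints, scores each with
#' [structure_energy()], and sorts by (energy, dot-bracket).  Complexity is
#' exponential; intended for oracle checks on short sequences.
#'
#' @inheritParams subopt
#' @param max_len guard: refuse sequences longer than this (default 20).
#' @return list of `secondary_structure`.
#' @export
enumerate_structures <- function(sequence, constraint = NULL,
                                 model = energy_model(), max_len = 20L) {
  s <- normalize_rna(sequence)
  n <- nchar(s)
  if (n > max_len) stop("sequence longer than max_len = ", max_len)
  cs <- as_constraint(constraint, n, s)
  bases <- strsplit(s, "")[[1]]
  ok_pair <- function(i, j) {
    if (j - i - 1 < model$min_hairpin) return(FALSE)
    if (cs$prohibit[i] || cs$prohibit[j]) return(FALSE)
    if (!is.na(cs$forced[i]) && cs$forced[i] != j) return(FALSE)
    if (!is.na(cs$forced[j]) && cs$forced[j] != i) return(FALSE)
    fp <- which(!is.na(cs$forced) & cs$forced > seq_len(n))
    for (a in fp) {
      b <- cs$forced[a]
      if ((i < a && a < j && j < b) || (a < i && i < b && b < j)) return(FALSE)
    }
    paste0(bases[i], bases[j]) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  # enumerate pair sets over [i..j]
  memo <- new.env(parent = emptyenv())
  gen <- function(i, j) {
    if (i > j) return(list(list()))
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    res <- list()
    # position i unpaired (if allowed)
    if (is.na(cs$forced[i]))
      res <- gen(i + 1L, j)
    # position i paired with k
    if (j - i >= model$min_hairpin + 1L) {
      for (k in (i + model$min_hairpin + 1L):j) {
        if (!ok_pair(i, k)) next
        inner <- gen(i + 1L, k - 1L)
        outer <- gen(k + 1L, j)
        for (a in inner) for (b in outer)
          res[[length(res) + 1L]] <- c(list(c(i, k)), a, b)
      }
    }
    memo[[key]] <- res
    res
  }
  sets <- gen(1L, n)
  out <- lapply(sets, function(ps) {
    pt <- rep(NA_integer_, n)
    for (p in ps) { pt[p[1]] <- p[2]; pt[p[2]] <- p[1] }
    st <- secondary_structure(s, pairtable_to_dotbracket(pt))
    st$energy <- structure_energy(st, model)
    st
  })
  e <- vapply(out, `[[`, 0, "energy")
  db <- vapply(out, `[[`, "", "dotbracket")
  # micro-kcal rounding + byte order: the engine's exact sort convention
  out[order(round(e, 6), db, method = "radix")]
}

#' Helix-level thermodynamic stability profile
#'
#' Decomposes a structure into helices (maximal runs of directly stacked
#' pairs; any bulge or internal loop ends a helix), sums each helix's
#' stacking contributions under the model, and reports the fraction of A-U
#' plus G-U pairs.  Helices are returned least stable first (largest
#' stacking free energy), mirroring the observation that the U-rich helix
#' around the Sm site is thermodynamically the weakest part of the
#' precursor fold.
#'
#' @param s a `secondary_structure`.
#' @param model energy model.
#' @return data.frame with one row per helix: `outer_i`, `outer_j` (root
#'   pair), `n_pairs`, `dG` (sum of stack terms, kcal/mol), `augu_frac`;
#'   ordered by decreasing `dG` (least stable first).  Zero rows for a
#'   fully unpaired structure.
#' @export
stability_profile <- function(s, model = energy_model()) {
  stopifnot(inherits(s, "secondary_structure"))
  helices <- decompose_helices(s)
  if (!length(helices))
    return(data.frame(outer_i = integer(0), outer_j = integer(0),
                      n_pairs = integer(0), dG = numeric(0),
                      augu_frac = numeric(0)))
  bases <- strsplit(s$sequence, "")[[1]]
  ptype <- function(i, j)
    match(paste0(bases[i], bases[j]), c("CG", "GC", "GU", "UG", "AU", "UA"))
  rows <- lapply(helices, function(h) {
    np <- nrow(h)
    dG <- 0
    if (np > 1) for (q in seq_len(np - 1))
      dG <- dG + model$stack[ptype(h[q, 1], h[q, 2]),
                             ptype(h[q + 1, 1], h[q + 1, 2])]
    augu <- mean(paste0(bases[h[, 1]], bases[h[, 2]]) %in%
                   c("AU", "UA", "GU", "UG"))
    data.frame(outer_i = h[1, 1], outer_j = h[1, 2], n_pairs = np,
               dG = dG, augu_frac = augu)
  })
  out <- do.call(rbind, rows)
  out[order(-out$dG, out$outer_i), , drop = FALSE]
}

# helices as list of two-column matrices of pairs, outermost first
decompose_helices <- function(s) {
  pr <- s$pairs
  if (!nrow(pr)) return(list())
  pr <- pr[order(pr[, 1]), , drop = FALSE]
  pt <- s$pair_table
  helices <- list()
  used <- rep(FALSE, nrow(pr))
  rownames(pr) <- NULL
  key <- paste(pr[, 1], pr[, 2])
  for (q in seq_len(nrow(pr))) {
    if (used[q]) next
    i <- pr[q, 1]; j <- pr[q, 2]
    run <- matrix(c(i, j), ncol = 2)
    used[q] <- TRUE
    while (!is.na(pt[run[nrow(run), 1] + 1L]) &&
           pt[run[nrow(run), 1] + 1L] == run[nrow(run), 2] - 1L) {
      i2 <- run[nrow(run), 1] + 1L; j2 <- run[nrow(run), 2] - 1L
      run <- rbind(run, c(i2, j2))
      used[key == paste(i2, j2)] <- TRUE
    }
    helices[[length(helices) + 1L]] <- run
  }
  helices
}
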