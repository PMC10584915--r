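#' Fold every variant of a variant set into a candidate pool
#'
#' For each sequence variant of each species, up to `max_structures`
#' suboptimal structures are predicted; every structure carries its
#' (species, variant, rank) provenance.  The pool is the raw material for
#' the best-representative and homolog-matching stages.
#'
#' @param vs a `variant_set`.
#' @param constraint optional constraint string applied to every variant
#'   (all variants must share one length for that; usually `NULL`).
#' @inheritParams subopt
#' @return a `candidate_pool`: list with `rna_name` and `per_species`, a
#'   named list of flat structure lists; each structure gains `species`,
#'   `variant`, `rank` fields.
#' @export
candidate_pool <- function(vs, constraint = NULL, max_structures = 20,
                           band = 5, model = energy_model()) {
  stopifnot(inherits(vs, "variant_set"))
  per_species <- lapply(names(vs$per_species), function(sp) {
    out <- list()
    for (r in vs$per_species[[sp]]) {
      ss <- subopt(r$sequence, constraint = constraint,
                   max_structures = max_structures, band = band,
                   model = model)
      for (k in seq_along(ss)) {
        st <- ss[[k]]
        st$species <- sp; st$variant <- r$id; st$rank <- k
        out[[length(out) + 1L]] <- st
      }
    }
    out
  })
  names(per_species) <- names(vs$per_species)
  structure(list(rna_name = vs$rna_name, per_species = per_species),
            class = "candidate_pool")
}

# raw tree edit distance matrix over a flat structure list, cached by
# unique dot-bracket
pool_distances <- function(structures) {
  distance_matrix(structures, normalize = FALSE)
}

#' Best representative structure of one species
#'
#' Among all suboptimal structures of all variants of a species, the best
#' representative is the candidate with the minimal average (over variants)
#' of the distance to its best match within each variant's ensemble --
#' i.e. the structure most consistently reproduced across the species'
#' gene copies.  The candidate's own variant contributes a zero term.
#' Ties break by lower free energy, then lexicographic dot-bracket.
#'
#' @param structures flat list of `secondary_structure` for one species,
#'   each carrying a `variant` field (as built by [candidate_pool()]).
#' @param denom averaging denominator: `"variants"` divides by the number
#'   of variants m_i (default), `"count"` leaves the plain sum.  The argmin
#'   is identical either way.
#' @return the winning `secondary_structure`, with `score` (the average
#'   best-match distance) attached.
#' @export
best_representative <- function(structures, denom = c("variants", "count")) {
  denom <- match.arg(denom)
  if (!length(structures)) stop("empty candidate pool for species")
  variants <- vapply(structures, `[[`, "", "variant")
  d <- pool_distances(structures)
  uv <- unique(variants)
  scores <- vapply(seq_along(structures), function(l) {
    s <- sum(vapply(uv, function(v) min(d[l, variants == v]), 0))
    if (denom == "variants") s / length(uv) else s
  }, 0)
  e <- vapply(structures, `[[`, 0, "energy")
  db <- vapply(structures, `[[`, "", "dotbracket")
  best <- order(scores, e, db, method = "radix")[1]
  out <- structures[[best]]
  out$score <- scores[best]
  out
}

#' Match a template structure across the other species
#'
#' For each species other than the template's own, the structure with the
#' minimal tree edit distance to the template is selected from that
#' species' pool of suboptimal structures; the template's own pool is never
#' searched (it would trivially return the template itself).
#'
#' @param template a `secondary_structure` with a `species` field.
#' @param pool a `candidate_pool`.
#' @return named list: species -> matched `secondary_structure` (the
#'   template species maps to the template itself).
#' @export
match_homologs <- function(template, pool) {
  stopifnot(inherits(pool, "candidate_pool"))
  if (is.null(template$species)) stop("template lacks species provenance")
  tt <- structure_tree(template)
  out <- list()
  for (sp in names(pool$per_species)) {
    if (identical(sp, template$species)) {
      out[[sp]] <- template
      next
    }
    cands <- pool$per_species[[sp]]
    if (!length(cands)) {
      warning("species ", sp, " has an empty pool; skipped")
      next
    }
    dv <- vapply(cands, function(s) tree_edit_distance(tt, structure_tree(s)), 0)
    e <- vapply(cands, `[[`, 0, "energy")
    db <- vapply(cands, `[[`, "", "dotbracket")
    out[[sp]] <- cands[[order(dv, e, db, method = "radix")[1]]]
  }
  out
}

# sum of pairwise raw tree edit distances of a homolog set
mutual_score <- function(members) {
  d <- pool_distances(members)
  sum(d[upper.tri(d)])
}

#' Representative set constructor
#'
#' @param members named list species -> `secondary_structure`.
#' @param template_species species whose best representative anchored the
#'   set.
#' @param norm normalization convention for the conservation score.
#' @return a `representative_set` with `per_species`, `template_species`,
#'   `mutual_score` (sum of pairwise raw distances) and `conservation`
#'   (mean pairwise normalized distance; 0 for identical structures).
#' @export
representative_set <- function(members, template_species, norm = "mean") {
  ms <- mutual_score(members)
  dn <- distance_matrix(members, normalize = TRUE, norm = norm)
  conservation <- mean(dn[upper.tri(dn)])
  structure(list(per_species = members, template_species = template_species,
                 mutual_score = ms, conservation = conservation),
            class = "representative_set")
}

#' @export
print.representative_set <- function(x, ...) {
  cat("representative_set:", length(x$per_species), "species; template",
      x$template_species, "\n  mutual_score =", x$mutual_score,
      " conservation =", signif(x$conservation, 4), "\n")
  invisible(x)
}

#' Select the most mutually related homolog set
#'
#' Given one template-anchored homolog set per species, returns the set
#' with minimal mutual tree edit distance (the sum over all ordered pairs
#' within the set).  Ties break deterministically by template-species
#' order.
#'
#' @param sets list of `representative_set`.
#' @return the winning `representative_set`.
#' @export
select_most_related_set <- function(sets) {
  if (!length(sets)) stop("no sets given")
  scores <- vapply(sets, `[[`, 0, "mutual_score")
  sets[[which.min(scores)]] # which.min takes the first (lowest index) tie
}

#' Cross-species consensus: best representative structures
#'
#' Runs the full consensus workflow on a filtered variant set: fold every
#' variant into suboptimal ensembles, pick one best representative per
#' species, anchor one homolog set on each species' representative, and
#' return the most mutually related set together with its conservation
#' score (mean pairwise normalized tree edit distance; lower means more
#' conserved).
#'
#' @param vs a `variant_set` (already filtered).
#' @inheritParams candidate_pool
#' @param norm normalization convention for the conservation score.
#' @return a `representative_set`; the candidate `pool` is attached as an
#'   attribute for downstream pathway modelling.
#' @export
run_consensus <- function(vs, constraint = NULL, max_structures = 20,
                          band = 5, model = energy_model(), norm = "mean") {
  stopifnot(inherits(vs, "variant_set"))
  if (length(vs$per_species) < 2L)
    stop("conservation is undefined for fewer than 2 species")
  pool <- candidate_pool(vs, constraint = constraint,
                         max_structures = max_structures, band = band,
                         model = model)
  reps <- lapply(pool$per_species, best_representative)
  sets <- lapply(names(reps), function(sp) {
    members <- match_homologs(reps[[sp]], pool)
    representative_set(members, template_species = sp, norm = norm)
  })
  chosen <- select_most_related_set(sets)
  attr(chosen, "pool") <- pool
  attr(chosen, "species_representatives") <- reps
  chosen
}
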