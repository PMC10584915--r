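#' Detect the Near Sm-site Structure (NSS)
#'
#' The NSS is the compact helix formed around -- and partly including --
#' the Sm site in the precursor fold.  Among the helices of a structure,
#' candidates are those with a paired position inside the Sm interval
#' extended by `window` nucleotides on each side, or whose enclosed region
#' contains Sm nucleotides.  The helix with the largest overlap with the
#' Sm interval wins; ties go to the helix whose root is closest to the Sm
#' 5' end.
#'
#' @param s a `secondary_structure`.
#' @param sm integer `c(start, end)`, 1-based inclusive Sm-site interval.
#' @param window search window on each side of the Sm interval (default 10).
#' @return an `nss_region` (list with `helix_pairs` ordered root to loop,
#'   `span`, `sm_overlap`) or `NULL` if the region is helix-free.
#' @export
detect_nss <- function(s, sm, window = 10L) {
  stopifnot(inherits(s, "secondary_structure"), length(sm) == 2L)
  n <- length(s)
  if (sm[1] < 1L || sm[2] > n || sm[1] > sm[2])
    stop("Sm interval outside the sequence")
  helices <- decompose_helices(s)
  if (!length(helices)) return(NULL)
  sm_pos <- sm[1]:sm[2]
  win <- max(1L, sm[1] - window):min(n, sm[2] + window)
  cand <- list()
  for (h in helices) {
    paired <- c(h[, 1], h[, 2])
    span <- h[1, 1]:h[1, 2]
    if (any(paired %in% win) || any(sm_pos %in% span)) {
      cand[[length(cand) + 1L]] <-
        list(helix_pairs = h, span = c(h[1, 1], h[1, 2]),
             sm_overlap = sum(sm_pos %in% span))
    }
  }
  if (!length(cand)) return(NULL)
  ov <- vapply(cand, `[[`, 0L, "sm_overlap")
  if (max(ov) == 0L) return(NULL)
  best <- which(ov == max(ov))
  if (length(best) > 1L) {
    rootdist <- vapply(cand[best], function(x) abs(x$helix_pairs[1, 1] - sm[1]), 0)
    best <- best[which.min(rootdist)]
  } else best <- best[1]
  # Mutations can interrupt the NSS stem with a bulge or small internal
  # loop; the region is the whole nested run of pairs around the Sm site,
  # so extend the winning helix root-ward and loop-ward through directly
  # nested neighbours (a multiloop branch point stops the walk).
  hp <- extend_helix_run(cand[[best]]$helix_pairs, s$pair_table)
  sm_pos2 <- sm[1]:sm[2]
  span <- hp[1, 1]:hp[1, 2]
  structure(list(helix_pairs = hp, span = c(hp[1, 1], hp[1, 2]),
                 sm_overlap = sum(sm_pos2 %in% span)),
            class = "nss_region")
}

# grow a helix (two-column pair matrix, root first) outward and inward along
# the nested line: a neighbouring pair is absorbed when only unpaired bases
# separate it from the current run
extend_helix_run <- function(hp, pt) {
  n <- length(pt)
  paired_between <- function(a, b) { # any paired position in (a, b)?
    if (b - a < 2L) return(FALSE)
    any(!is.na(pt[(a + 1L):(b - 1L)]))
  }
  repeat { # root-ward
    i0 <- hp[1, 1]; j0 <- hp[1, 2]
    a <- i0 - 1L
    while (a >= 1L && is.na(pt[a])) a <- a - 1L
    if (a < 1L) break
    b <- pt[a]
    if (b < j0 || paired_between(j0, b)) break # not directly enclosing
    hp <- rbind(c(a, b), hp)
  }
  repeat { # loop-ward
    i1 <- hp[nrow(hp), 1]; j1 <- hp[nrow(hp), 2]
    a <- i1 + 1L
    while (a <= n && is.na(pt[a])) a <- a + 1L
    if (a >= j1) break
    b <- pt[a]
    if (is.na(b) || b > j1 || b < a || paired_between(b, j1)) break
    hp <- rbind(hp, c(a, b))
    # continue down that helix's stack
    while (!is.na(pt[hp[nrow(hp), 1] + 1L]) &&
           pt[hp[nrow(hp), 1] + 1L] == hp[nrow(hp), 2] - 1L)
      hp <- rbind(hp, c(hp[nrow(hp), 1] + 1L, hp[nrow(hp), 2] - 1L))
  }
  hp
}

#' Minimal root-ward blocking that opens the Sm site
#'
#' Starting from the primary folded transcript, blocks the k outermost
#' pairs of the NSS helix (both positions of each pair are prohibited from
#' pairing, mimicking strand separation by the SMN complex helicase) and
#' refolds under a constraint that keeps the rest of the template fold
#' fixed while leaving the remaining NSS pairs free to unwind.  Returns
#' the smallest k for which the top-ranked refolded structure has a fully
#' single-stranded Sm site; blocking more pairs toward the loop keeps the
#' site open.
#'
#' @param primary a `secondary_structure` (the primary folded transcript).
#' @param nss an `nss_region` from [detect_nss()].
#' @param sm Sm interval, `c(start, end)` 1-based inclusive.
#' @inheritParams subopt
#' @return list with `k` (number of blocked pairs), `intermediate` (the
#'   top-ranked open structure), `suboptimals` (the constrained ensemble at
#'   that k), `blocked` (positions), `constraint` (string used).
#' @export
min_block_open <- function(primary, nss, sm, max_structures = 20, band = 5,
                           model = energy_model()) {
  stopifnot(inherits(primary, "secondary_structure"),
            inherits(nss, "nss_region"))
  sm_pos <- sm[1]:sm[2]
  hp <- nss$helix_pairs
  for (k in 0:nrow(hp)) {
    blocked <- if (k == 0L) integer(0) else as.vector(t(hp[seq_len(k), , drop = FALSE]))
    if (k == 0L && all(is.na(primary$pair_table[sm_pos])))
      return(list(k = 0L, intermediate = primary,
                  suboptimals = list(primary), blocked = integer(0),
                  constraint = strrep(".", length(primary))))
    if (k == 0L) next
    ss <- constrained_refold(primary, blocked = blocked, exclude_pairs = hp,
                             max_structures = max_structures, band = band,
                             model = model)
    if (!length(ss)) next
    top <- ss[[1]]
    if (all(is.na(top$pair_table[sm_pos]))) {
      cons <- template_constraint(primary, primary$sequence,
                                  blocked = blocked, exclude_pairs = hp)
      return(list(k = k, intermediate = top, suboptimals = ss,
                  blocked = blocked, constraint = cons))
    }
  }
  residual <- sm_pos[!is.na(primary$pair_table[sm_pos])]
  stop("no blocking of up to ", nrow(hp), " NSS pairs opens the Sm site; ",
       "residual paired Sm positions: ", paste(residual, collapse = ", "))
}

#' Force the Sm motif single-stranded (final structure)
#'
#' Prohibits pairing of the Sm nucleotides plus `downstream_n` following
#' positions (mimicking bound Sm proteins), keeps the intermediate's pairs
#' as a template where still legal, and returns the constrained ensemble;
#' the top-ranked structure is the final structure.
#'
#' @param intermediate a `secondary_structure` (folding intermediate).
#' @param sm Sm interval, `c(start, end)` 1-based inclusive.
#' @param downstream_n additional downstream nucleotides kept
#'   single-stranded (default 3).
#' @inheritParams subopt
#' @return list with `final` (top structure), `suboptimals`, `blocked`,
#'   `constraint`.
#' @export
force_sm_single <- function(intermediate, sm, downstream_n = 3L,
                            max_structures = 20, band = 5,
                            model = energy_model()) {
  stopifnot(inherits(intermediate, "secondary_structure"))
  n <- length(intermediate)
  blocked <- sm[1]:min(n, sm[2] + downstream_n)
  ss <- constrained_refold(intermediate, blocked = blocked,
                           max_structures = max_structures, band = band,
                           model = model)
  if (!length(ss)) stop("Sm-single-stranded constraint unsatisfiable")
  cons <- template_constraint(intermediate, intermediate$sequence,
                              blocked = blocked)
  list(final = ss[[1]], suboptimals = ss, blocked = blocked,
       constraint = cons)
}

#' Two-step restructuring pathway for one molecule
#'
#' Convenience wrapper running [detect_nss()], [min_block_open()] and
#' [force_sm_single()] on a single primary folded transcript.
#'
#' @param primary a `secondary_structure`.
#' @param sm Sm interval; `NULL` locates it with [find_sm_site()].
#' @param window NSS detection window.
#' @param downstream_n downstream nucleotides blocked in the final step.
#' @inheritParams subopt
#' @return a `pathway_result`: `primary`, `intermediate`, `final`,
#'   `k_blocked`, `sm`, `step1_constraint`, `step2_constraint`, plus the
#'   constrained ensembles of both steps.
#' @export
fold_pathway <- function(primary, sm = NULL, window = 10L, downstream_n = 3L,
                         max_structures = 20, band = 5,
                         model = energy_model()) {
  if (is.null(sm)) {
    sm <- find_sm_site(primary$sequence)
    if (is.null(sm)) stop("no Sm site found in the sequence")
  }
  sm_pos <- sm[1]:sm[2]
  nss <- detect_nss(primary, sm, window = window)
  if (is.null(nss)) {
    # Sm region unstructured: the primary already is the open intermediate
    step1 <- list(k = 0L, intermediate = primary, suboptimals = list(primary),
                  blocked = integer(0),
                  constraint = strrep(".", length(primary)))
  } else {
    step1 <- min_block_open(primary, nss, sm, max_structures = max_structures,
                            band = band, model = model)
  }
  step2 <- force_sm_single(step1$intermediate, sm,
                           downstream_n = downstream_n,
                           max_structures = max_structures, band = band,
                           model = model)
  stopifnot(all(is.na(step1$intermediate$pair_table[sm_pos])),
            all(is.na(step2$final$pair_table[sm_pos])))
  structure(list(primary = primary, intermediate = step1$intermediate,
                 final = step2$final, k_blocked = step1$k, sm = sm,
                 nss = nss,
                 step1_constraint = step1$constraint,
                 step2_constraint = step2$constraint,
                 step1_suboptimals = step1$suboptimals,
                 step2_suboptimals = step2$suboptimals),
            class = "pathway_result")
}

#' @export
print.pathway_result <- function(x, ...) {
  cat("pathway_result: k_blocked =", x$k_blocked, "\n")
  cat("  primary:      ", x$primary$dotbracket, "\n")
  cat("  intermediate: ", x$intermediate$dotbracket, "\n")
  cat("  final:        ", x$final$dotbracket, "\n")
  invisible(x)
}

#' Cross-species restructuring pathway with consensus at each step
#'
#' Runs the consensus stage on a variant set (or reuses a supplied
#' [run_consensus()] result), then models the two-step opening pathway for
#' each species' primary folded transcript, and re-applies the
#' template-matching and most-related-set selection to the pools of
#' Sm-open constrained suboptimal structures to pick the cross-species
#' folding-intermediate and final-structure sets.
#'
#' @param vs a `variant_set`.
#' @param consensus optional precomputed `representative_set` from
#'   [run_consensus()] (with its pool attribute).
#' @inheritParams fold_pathway
#' @param norm normalization for conservation scores.
#' @return list with `per_species` (named list of `pathway_result`),
#'   `primary_set`, `intermediate_set`, `final_set`
#'   (`representative_set`s), and `failed` (species excluded, with
#'   reasons).
#' @export
pathway <- function(vs, consensus = NULL, window = 10L, downstream_n = 3L,
                    max_structures = 20, band = 5, model = energy_model(),
                    norm = "mean") {
  if (is.null(consensus))
    consensus <- run_consensus(vs, max_structures = max_structures,
                               band = band, model = model, norm = norm)
  per_species <- list()
  failed <- list()
  for (sp in names(consensus$per_species)) {
    primary <- consensus$per_species[[sp]]
    pr <- tryCatch(
      fold_pathway(primary, window = window, downstream_n = downstream_n,
                   max_structures = max_structures, band = band,
                   model = model),
      error = function(e) e)
    if (inherits(pr, "error")) failed[[sp]] <- conditionMessage(pr)
    else per_species[[sp]] <- pr
  }
  if (length(failed))
    warning("species excluded from pathway consensus: ",
            paste(names(failed), collapse = ", "))
  if (length(per_species) < 2L)
    stop("fewer than 2 species completed the pathway")

  stage_consensus <- function(stage_subopt, stage_top) {
    pools <- lapply(names(per_species), function(sp) {
      res <- per_species[[sp]]
      sm_pos <- res$sm[1]:res$sm[2]
      open <- Filter(function(s) all(is.na(s$pair_table[sm_pos])),
                     res[[stage_subopt]])
      lapply(seq_along(open), function(k) {
        st <- open[[k]]; st$species <- sp; st$variant <- "pathway"
        st$rank <- k; st
      })
    })
    names(pools) <- names(per_species)
    pool <- structure(list(rna_name = vs$rna_name, per_species = pools),
                      class = "candidate_pool")
    sets <- lapply(names(per_species), function(sp) {
      tmpl <- per_species[[sp]][[stage_top]]
      tmpl$species <- sp
      members <- match_homologs(tmpl, pool)
      representative_set(members, template_species = sp, norm = norm)
    })
    select_most_related_set(sets)
  }

  list(per_species = per_species,
       primary_set = consensus,
       intermediate_set = stage_consensus("step1_suboptimals", "intermediate"),
       final_set = stage_consensus("step2_suboptimals", "final"),
       failed = failed)
}
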