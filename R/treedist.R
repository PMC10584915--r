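#' Convert a secondary structure to an ordered labeled tree
#'
#' The "full" representation gives one internal `P` node per base pair and
#' one `U` leaf per unpaired base under a virtual root `R`, with children in
#' 5'-to-3' order -- the representation classically used for tree edit
#' distances between plain dot-bracket strings.  The "coarse"
#' representation collapses structural elements: `S` per helix (maximal
#' stack), with a loop child (`H` hairpin, `B` bulge, `I` internal, `M`
#' multiloop) whose children are the inner helices; external unpaired bases
#' are ignored.
#'
#' @param s a `secondary_structure` or dot-bracket string.
#' @param representation `"full"` or `"coarse"`.
#' @return a `structure_tree`: postorder `labels` (integer-coded),
#'   `lml` (leftmost-leaf index per node, 1-based postorder), `n_nodes`,
#'   `size` (sequence length), `representation`, plus preorder `pre_labels`
#'   and `pre_parent` used by exhaustive mapping searches.
#' @export
structure_tree <- function(s, representation = c("full", "coarse")) {
  representation <- match.arg(representation)
  if (is.character(s)) {
    db <- s
    pt <- dotbracket_to_pairtable(db)
  } else {
    stopifnot(inherits(s, "secondary_structure"))
    db <- s$dotbracket
    pt <- s$pair_table
  }
  nested <- if (representation == "full") full_tree(pt) else coarse_tree(pt)
  post <- postorder_arrays(nested)
  pre <- preorder_arrays(nested)
  structure(list(labels = post$labels, lml = post$lml,
                 n_nodes = length(post$labels), size = length(pt),
                 representation = representation,
                 label_names = post$names,
                 pre_labels = pre$labels, pre_parent = pre$parent),
            class = "structure_tree")
}

#' @export
print.structure_tree <- function(x, ...) {
  cat("structure_tree (", x$representation, "): ", x$n_nodes, " nodes\n",
      sep = "")
  invisible(x)
}

# label codes: R=0, P=1, U=2 (full); R=0, S=3, H=4, B=5, I=6, M=7 (coarse)
TREE_LABELS <- c(R = 0L, P = 1L, U = 2L, S = 3L, H = 4L, B = 5L, I = 6L, M = 7L)

# nested list representation: list(label=, children=list(...))
full_tree <- function(pt) {
  build <- function(i, j) {
    kids <- list()
    k <- i
    while (k <= j) {
      if (is.na(pt[k])) {
        kids[[length(kids) + 1L]] <- list(label = TREE_LABELS[["U"]],
                                          children = list())
        k <- k + 1L
      } else {
        inner <- build(k + 1L, pt[k] - 1L)
        kids[[length(kids) + 1L]] <- list(label = TREE_LABELS[["P"]],
                                          children = inner$children)
        k <- pt[k] + 1L
      }
    }
    list(label = NA, children = kids)
  }
  top <- build(1L, length(pt))
  list(label = TREE_LABELS[["R"]], children = top$children)
}

coarse_tree <- function(pt) {
  # helix starting at pair (i, pt[i]): follow direct stacking
  helix_inner <- function(i) {
    j <- pt[i]
    while (!is.na(pt[i + 1L]) && pt[i + 1L] == j - 1L) {
      i <- i + 1L; j <- j - 1L
    }
    c(i, j)
  }
  build_helix <- function(i) {
    inner <- helix_inner(i)
    a <- inner[1] + 1L; b <- inner[2] - 1L
    kids <- list(); starts <- integer(0); unp <- 0L
    k <- a
    while (k <= b) {
      if (is.na(pt[k])) { unp <- unp + 1L; k <- k + 1L }
      else {
        kids[[length(kids) + 1L]] <- build_helix(k)
        starts <- c(starts, k)
        k <- pt[k] + 1L
      }
    }
    loop_label <-
      if (!length(kids)) "H"
      else if (length(kids) >= 2L) "M"
      else {
        left <- starts[1] - a
        right <- b - pt[starts[1]]
        if (left > 0L && right > 0L) "I" else "B"
      }
    loop <- list(label = TREE_LABELS[[loop_label]], children = kids)
    list(label = TREE_LABELS[["S"]], children = list(loop))
  }
  kids <- list()
  k <- 1L
  n <- length(pt)
  while (k <= n) {
    if (is.na(pt[k])) k <- k + 1L
    else { kids[[length(kids) + 1L]] <- build_helix(k); k <- pt[k] + 1L }
  }
  list(label = TREE_LABELS[["R"]], children = kids)
}

postorder_arrays <- function(tree) {
  labels <- integer(0); lml <- integer(0); nms <- character(0)
  walk <- function(node) {
    first_leaf <- NA_integer_
    for (ch in node$children) {
      f <- walk(ch)
      if (is.na(first_leaf)) first_leaf <- f
    }
    labels[[length(labels) + 1L]] <<- node$label
    idx <- length(labels)
    if (is.na(first_leaf)) first_leaf <- idx
    lml[[idx]] <<- first_leaf
    first_leaf
  }
  walk(tree)
  list(labels = labels, lml = lml,
       names = names(TREE_LABELS)[match(labels, TREE_LABELS)])
}

preorder_arrays <- function(tree) {
  labels <- integer(0); parent <- integer(0)
  walk <- function(node, par) {
    labels[[length(labels) + 1L]] <<- node$label
    idx <- length(labels)
    parent[[idx]] <<- par
    for (ch in node$children) walk(ch, idx - 1L) # 0-based parent for C++
  }
  walk(tree, -1L)
  list(labels = labels, parent = parent)
}

#' Tree edit distance between two structure trees
#'
#' Minimal cost of node insertions, deletions and relabelings transforming
#' one ordered labeled tree into the other (Zhang-Shasha dynamic program),
#' with unit costs and free relabeling of identical labels.  Zero iff the
#' trees are identical.
#'
#' @param a,b `structure_tree` objects (same representation), or
#'   `secondary_structure`/dot-bracket inputs which are converted with the
#'   default representation.
#' @return non-negative distance.
#' @export
tree_edit_distance <- function(a, b) {
  if (!inherits(a, "structure_tree")) a <- structure_tree(a)
  if (!inherits(b, "structure_tree")) b <- structure_tree(b)
  if (!identical(a$representation, b$representation))
    stop("trees use different representations: ", a$representation,
         " vs ", b$representation)
  zs_tree_dist_cpp(a$labels, a$lml, b$labels, b$lml)
}

#' Length-normalized structural distance
#'
#' Tree edit distances grow with molecule size; for cross-RNA comparison
#' they are normalized to sequence length.  The default denominator is the
#' arithmetic mean of the two lengths.
#'
#' @param d raw tree edit distance.
#' @param len_a,len_b sequence lengths.
#' @param norm denominator convention: `"mean"`, `"max"` or `"min"`.
#' @return normalized distance (dimensionless fraction).
#' @export
normalized_distance <- function(d, len_a, len_b,
                                norm = c("mean", "max", "min")) {
  norm <- match.arg(norm)
  if (len_a <= 0 || len_b <= 0) stop("sequence lengths must be positive")
  denom <- switch(norm, mean = (len_a + len_b) / 2,
                  max = max(len_a, len_b), min = min(len_a, len_b))
  d / denom
}

#' Pairwise tree edit distance matrix
#'
#' @param structures list of `secondary_structure` (or dot-bracket strings).
#' @param normalize divide each entry by the mean of the two sequence
#'   lengths (see [normalized_distance()]).
#' @param representation tree representation.
#' @param norm normalization denominator convention.
#' @return symmetric matrix with zero diagonal; labels from names or
#'   indices.
#' @export
distance_matrix <- function(structures, normalize = FALSE,
                            representation = "full", norm = "mean") {
  if (!length(structures)) stop("empty structure list")
  dbs <- vapply(structures, function(s)
    if (is.character(s)) s else s$dotbracket, "")
  lens <- nchar(dbs)
  uniq <- unique(dbs)
  trees <- lapply(uniq, structure_tree, representation = representation)
  du <- zs_dist_matrix_cpp(lapply(trees, `[[`, "labels"),
                           lapply(trees, `[[`, "lml"))
  idx <- match(dbs, uniq)
  d <- du[idx, idx, drop = FALSE]
  if (normalize) {
    denom <- switch(norm,
                    mean = outer(lens, lens, function(a, b) (a + b) / 2),
                    max = outer(lens, lens, pmax),
                    min = outer(lens, lens, pmin))
    d <- d / denom
  }
  labs <- names(structures)
  if (is.null(labs)) labs <- as.character(seq_along(structures))
  dimnames(d) <- list(labs, labs)
  d
}
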