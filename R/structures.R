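#' Secondary structure objects
#'
#' A `secondary_structure` couples an RNA sequence with a pseudoknot-free
#' dot-bracket string.  The pair table is derived from the dot-bracket and
#' validated: brackets must balance, every pair must be one of
#' A-U/G-C/G-U (either orientation), and hairpin loops must enclose at least
#' `min_hairpin` unpaired nucleotides.
#'
#' @param sequence RNA string over A/C/G/U (T is converted to U, case folded).
#' @param dotbracket string over `(`, `)`, `.` of the same length.
#' @param energy optional free energy in kcal/mol.
#' @param min_hairpin minimum hairpin loop size (default 3).
#' @return an object of class `secondary_structure` with elements
#'   `sequence`, `dotbracket`, `pairs` (two-column matrix of 1-based pair
#'   indices, i < j), `pair_table` (partner index per position, `NA` if
#'   unpaired) and `energy`.
#' @export
secondary_structure <- function(sequence, dotbracket, energy = NULL,
                                min_hairpin = 3L) {
  sequence <- normalize_rna(sequence)
  if (!is.character(dotbracket) || length(dotbracket) != 1L)
    stop("dotbracket must be a single string")
  if (nchar(dotbracket) != nchar(sequence))
    stop("sequence and dotbracket lengths differ (",
         nchar(sequence), " vs ", nchar(dotbracket), ")")
  pt <- dotbracket_to_pairtable(dotbracket)
  n <- nchar(sequence)
  bases <- strsplit(sequence, "")[[1]]
  idx <- which(!is.na(pt) & pt > seq_len(n))
  if (length(idx)) {
    a <- bases[idx]; b <- bases[pt[idx]]
    legal <- paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
    if (!all(legal))
      stop("illegal base pair(s) at positions ",
           paste(idx[!legal], collapse = ", "))
    hp <- pt[idx] - idx - 1L
    inner <- vapply(seq_along(idx), function(q) {
      span <- (idx[q] + 1L):(pt[idx[q]] - 1L)
      all(is.na(pt[span]))
    }, logical(1))
    if (any(inner & hp < min_hairpin))
      stop("hairpin loop shorter than ", min_hairpin, " nucleotides")
  }
  structure(list(sequence = sequence,
                 dotbracket = dotbracket,
                 pairs = cbind(i = idx, j = pt[idx]),
                 pair_table = pt,
                 energy = if (is.null(energy)) NA_real_ else as.numeric(energy)),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, sep = "")
  if (!is.na(x$energy)) cat(sprintf(" (%.2f)", x$energy))
  cat("\n")
  invisible(x)
}

#' @export
length.secondary_structure <- function(x) nchar(x$sequence)

# uppercase, T->U, validate alphabet
normalize_rna <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  s <- chartr("t", "u", toupper(sequence))
  s <- chartr("T", "U", s)
  if (grepl("[^ACGU]", s))
    stop("sequence contains characters outside A/C/G/U after normalization")
  s
}

#' Convert dot-bracket to a pair table
#'
#' @param dotbracket dot-bracket string.
#' @return integer vector of partner positions (1-based), `NA` where unpaired.
#' @export
dotbracket_to_pairtable <- function(dotbracket) {
  chars <- strsplit(dotbracket, "")[[1]]
  bad <- setdiff(unique(chars), c("(", ")", "."))
  if (length(bad)) stop("invalid dot-bracket characters: ",
                        paste(bad, collapse = " "))
  pt <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket: unmatched ')' at ", k)
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- k
      pt[k] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unmatched '(' at ",
                          stack[length(stack)])
  pt
}

#' Convert a pair table to dot-bracket
#'
#' @param pair_table integer vector of partner positions, `NA` if unpaired.
#' @return dot-bracket string.
#' @export
pairtable_to_dotbracket <- function(pair_table) {
  out <- rep(".", length(pair_table))
  paired <- which(!is.na(pair_table))
  out[paired[pair_table[paired] > paired]] <- "("
  out[paired[pair_table[paired] < paired]] <- ")"
  paste(out, collapse = "")
}

#' Folding constraint strings
#'
#' A constraint uses `.` (unconstrained), `x` (prohibited from pairing) and
#' matched `(`/`)` (forced pair).  Forced pairs must be nested, must not
#' touch an `x` position, and -- when a sequence is supplied -- must be
#' complementary under the allowed pair set.
#'
#' @param symbols constraint string.
#' @param sequence optional RNA sequence to validate forced pairs against.
#' @return object of class `constraint_spec` with `symbols`, `prohibit`
#'   (logical), `forced` (partner index or `NA`).
#' @export
constraint_spec <- function(symbols, sequence = NULL) {
  chars <- strsplit(symbols, "")[[1]]
  bad <- setdiff(unique(chars), c("(", ")", ".", "x"))
  if (length(bad)) stop("invalid constraint characters: ",
                        paste(bad, collapse = " "))
  db <- gsub("x", ".", symbols)
  pt <- dotbracket_to_pairtable(db)
  if (any(!is.na(pt) & chars == "x"))
    stop("position cannot be both forced and prohibited")
  if (!is.null(sequence)) {
    sequence <- normalize_rna(sequence)
    if (nchar(sequence) != length(chars))
      stop("constraint and sequence lengths differ")
    bases <- strsplit(sequence, "")[[1]]
    idx <- which(!is.na(pt) & pt > seq_along(pt))
    if (length(idx)) {
      legal <- paste0(bases[idx], bases[pt[idx]]) %in%
        c("AU", "UA", "GC", "CG", "GU", "UG")
      if (!all(legal))
        stop("forced pair(s) not complementary at positions ",
             paste(idx[!legal], collapse = ", "))
    }
  }
  structure(list(symbols = symbols,
                 prohibit = chars == "x",
                 forced = pt),
            class = "constraint_spec")
}

#' @export
print.constraint_spec <- function(x, ...) {
  cat(x$symbols, "\n")
  invisible(x)
}

# accept either a constraint_spec, a string, or NULL
as_constraint <- function(constraint, n, sequence = NULL) {
  if (is.null(constraint))
    return(constraint_spec(strrep(".", n)))
  if (is.character(constraint))
    constraint <- constraint_spec(constraint, sequence)
  if (!inherits(constraint, "constraint_spec"))
    stop("constraint must be NULL, a string, or a constraint_spec")
  if (length(constraint$prohibit) != n)
    stop("constraint length (", length(constraint$prohibit),
         ") does not match sequence length (", n, ")")
  constraint
}

#' Does a structure satisfy a constraint?
#'
#' @param s a `secondary_structure`.
#' @param constraint a `constraint_spec` or constraint string.
#' @return `TRUE`/`FALSE`.
#' @export
satisfies_constraint <- function(s, constraint) {
  cs <- as_constraint(constraint, length(s))
  pt <- s$pair_table
  if (any(cs$prohibit & !is.na(pt))) return(FALSE)
  f <- which(!is.na(cs$forced))
  all(!is.na(pt[f]) & pt[f] == cs$forced[f])
}

#' Read a Vienna-style dot-bracket file
#'
#' Records are `>header` / sequence / structure lines; the structure line may
#' carry a trailing energy in parentheses, e.g. `((...)) (-3.40)`.
#'
#' @param path file path.
#' @return list of `secondary_structure` objects, named by header.
#' @export
read_vienna <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no '>' headers found in ", path)
  out <- list()
  for (h in seq_along(heads)) {
    i <- heads[h]
    stop_at <- if (h < length(heads)) heads[h + 1] - 1L else length(lines)
    if (stop_at < i + 2L) stop("record '", lines[i], "' lacks structure line")
    seqline <- trimws(lines[i + 1L])
    structline <- trimws(lines[i + 2L])
    energy <- NA_real_
    em <- regmatches(structline, regexpr("\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", structline))
    if (length(em) && grepl("[.0-9]", em)) {
      # only treat as energy when it follows whitespace after the structure
      if (grepl("[.)]\\s+\\(\\s*-?[0-9.]+\\s*\\)\\s*$", structline)) {
        energy <- as.numeric(gsub("[()\\s]", "", em, perl = TRUE))
        structline <- trimws(sub("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", "", structline))
      }
    }
    name <- sub("^>\\s*", "", lines[i])
    out[[name]] <- secondary_structure(seqline, structline, energy = energy)
  }
  out
}

#' Write structures to a Vienna-style dot-bracket file
#'
#' @param structures list of `secondary_structure` (named, names become
#'   headers).
#' @param path output path.
#' @export
write_vienna <- function(structures, path) {
  if (inherits(structures, "secondary_structure"))
    structures <- list(structure_1 = structures)
  nm <- names(structures)
  if (is.null(nm)) nm <- paste0("structure_", seq_along(structures))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(structures)) {
    s <- structures[[k]]
    line <- s$dotbracket
    if (!is.na(s$energy)) line <- sprintf("%s (%.2f)", line, s$energy)
    writeLines(c(paste0(">", nm[k]), s$sequence, line), con)
  }
  invisible(path)
}

# seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
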