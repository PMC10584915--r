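#' SHAPE reactivity profile
#'
#' Per-nucleotide 2'-OH reactivities with standard errors; missing values
#' (`NA`) propagate through all downstream computations.
#'
#' @param reactivity numeric vector (NA = no data).
#' @param stderr numeric vector of standard errors, same length.
#' @param sequence RNA string of the same length.
#' @return a `reactivity_profile`.
#' @export
reactivity_profile <- function(reactivity, stderr = NULL, sequence) {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  if (length(reactivity) != n)
    stop("reactivity length differs from sequence length")
  if (is.null(stderr)) stderr <- rep(NA_real_, n)
  if (length(stderr) != n)
    stop("stderr length differs from sequence length")
  structure(list(reactivity = as.numeric(reactivity),
                 stderr = as.numeric(stderr), sequence = sequence),
            class = "reactivity_profile")
}

#' Read a reactivity TSV (position, sequence, reactivity, stderr)
#'
#' Columns follow the common SHAPE-MaP profile layout; `-999` is treated as
#' missing.
#'
#' @param path TSV path.
#' @return a `reactivity_profile`.
#' @export
read_reactivity_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "sequence", "reactivity", "stderr")
  if (!all(need %in% names(d)))
    stop("reactivity TSV needs columns: ", paste(need, collapse = ", "))
  d <- d[order(d$position), ]
  r <- d$reactivity; e <- d$stderr
  r[r <= -998] <- NA; e[e <= -998] <- NA
  reactivity_profile(r, e, paste(d$sequence, collapse = ""))
}

#' Write a reactivity profile as TSV
#'
#' @param p a `reactivity_profile`.
#' @param path output path.
#' @export
write_reactivity_tsv <- function(p, path) {
  d <- data.frame(position = seq_len(nchar(p$sequence)),
                  sequence = strsplit(p$sequence, "")[[1]],
                  reactivity = ifelse(is.na(p$reactivity), -999, p$reactivity),
                  stderr = ifelse(is.na(p$stderr), -999, p$stderr))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert reactivities into hard folding constraints
#'
#' Highly reactive nucleotides are flexible, hence single-stranded:
#' positions with reactivity at or above the threshold are prohibited from
#' pairing (`x`); missing positions stay unconstrained.  Raising the
#' threshold never adds a constraint.
#'
#' @param p a `reactivity_profile`.
#' @param unpaired_threshold reactivity above which a position is called
#'   unpaired (default 0.4, the usual hard-constraint convention).
#' @return a `constraint_spec`.
#' @export
reactivity_to_constraints <- function(p, unpaired_threshold = 0.4) {
  stopifnot(inherits(p, "reactivity_profile"))
  sym <- rep(".", length(p$reactivity))
  hit <- !is.na(p$reactivity) & p$reactivity >= unpaired_threshold
  sym[hit] <- "x"
  if (all(is.na(p$reactivity)))
    warning("profile has no data; constraint is empty")
  constraint_spec(paste(sym, collapse = ""))
}

smooth_win <- function(x, w) {
  n <- length(x)
  half <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    win <- x[max(1L, i - half):min(n, i + half)]
    if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }, 0)
}

#' Windowed differential-reactivity significance calls
#'
#' Implements the standard differential-SHAPE decision rule for comparing
#' two reactivity profiles (e.g. ex vivo vs in vivo): reactivities and
#' errors are smoothed with a centered window, the per-nucleotide
#' difference is scored by (i) a Z-factor, `1 - 1.96 (se_a + se_b) / |diff|`,
#' requiring separation beyond measurement error, and (ii) a standard score
#' of the difference against its own distribution.  Nucleotides passing
#' both (Z-factor > 0, |standard score| >= 1) are significant when at
#' least `min_hits` of any `window` consecutive nucleotides pass; passing
#' nucleotides inside qualifying windows are merged into regions.
#'
#' @param a,b `reactivity_profile`s of equal length.
#' @param window region window size (default 5).
#' @param min_hits required passing nucleotides per window (default 3).
#' @param smooth smoothing window for reactivities and errors (default 3).
#' @param z_crit multiplier for the error term (default 1.96).
#' @param ss_min standard-score threshold (default 1).
#' @return list with `diff` (smoothed difference), `z_factor`,
#'   `std_score`, `pass` (logical per nucleotide), and
#'   `significant_regions` (two-column matrix of 1-based intervals).
#' @export
delta_windows <- function(a, b, window = 5L, min_hits = 3L, smooth = 3L,
                          z_crit = 1.96, ss_min = 1) {
  stopifnot(inherits(a, "reactivity_profile"),
            inherits(b, "reactivity_profile"))
  n <- length(a$reactivity)
  if (length(b$reactivity) != n) stop("profiles have different lengths")
  ra <- smooth_win(a$reactivity, smooth)
  rb <- smooth_win(b$reactivity, smooth)
  ea <- smooth_win(a$stderr, smooth)
  eb <- smooth_win(b$stderr, smooth)
  d <- ra - rb
  zf <- 1 - z_crit * (ea + eb) / abs(d)
  ss <- (d - mean(d, na.rm = TRUE)) / stats::sd(d, na.rm = TRUE)
  pass <- !is.na(zf) & !is.na(ss) & zf > 0 & abs(ss) >= ss_min
  flagged <- rep(FALSE, n)
  if (n >= window) {
    for (i in seq_len(n - window + 1L)) {
      w <- i:(i + window - 1L)
      if (sum(pass[w]) >= min_hits) flagged[w][pass[w]] <- TRUE
    }
  } else if (sum(pass) >= min_hits) flagged[pass] <- TRUE
  regions <- runs_to_intervals(flagged)
  list(diff = d, z_factor = zf, std_score = ss, pass = pass,
       significant_regions = regions)
}

runs_to_intervals <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}
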