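#' Mean pairwise similarity of a distance matrix
#'
#' The conservation statistic reported per RNA and clade: the mean of the
#' upper-triangle pairwise (normalized) distances.  Lower values mean
#' higher structural similarity.
#'
#' @param dm symmetric distance matrix (at least 2 labels).
#' @return mean pairwise distance.
#' @export
mean_pairwise_similarity <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 2L) stop("need at least 2 structures")
  mean(dm[upper.tri(dm)])
}

#' Pooled two-sample two-tailed t-test
#'
#' Equal-variance (pooled) two-sample t statistic with
#' `df = n_a + n_b - 2` and a two-tailed p-value from the t distribution --
#' the test used to compare per-clade mean structural distances.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return list with `t_statistic`, `degrees_of_freedom`, `p_value`.
#' @export
two_sample_ttest <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("both samples need at least 2 values")
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  if (sp2 == 0) {
    if (mean(a) == mean(b))
      return(list(t_statistic = 0, degrees_of_freedom = df, p_value = 1))
    stop("zero pooled variance with unequal means")
  }
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t_statistic = t, degrees_of_freedom = df,
       p_value = 2 * stats::pt(-abs(t), df))
}

#' Box-plot summary with 1.5 IQR fences
#'
#' Quartiles use midpoint interpolation (R quantile type 5, the convention
#' of common numeric environments); whiskers extend to the most extreme
#' points within 1.5 interquartile ranges of the box, and points outside
#' the fences are flagged as outliers.
#'
#' @param values numeric vector (length >= 1).
#' @return list with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @export
boxplot_summary <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("need at least one value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 5, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- values[values >= lo & values <= hi]
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(values[values < lo | values > hi]))
}

#' Published per-clade mean structural distances
#'
#' The per-RNA mean pairwise normalized tree edit distances of best
#' representative structures, as printed for the major spliceosomal snRNAs
#' (metazoa vs protists vs fungi, each kingdom with two alternative species
#' samplings) and the metazoan minor snRNAs.  Shipped as plain TSV under
#' `inst/extdata`.
#'
#' @return list with two data.frames: `major` (columns `rna`, `metazoa`,
#'   `protists_broad`, `protists_model`, `fungi_broad`, `fungi_model`) and
#'   `minor` (columns `rna`, `metazoa_minor`).
#' @export
snrna_similarity_tables <- function() {
  major <- utils::read.delim(system.file("extdata", "similarity_major.tsv",
                                         package = "presnfold"),
                             stringsAsFactors = FALSE)
  minor <- utils::read.delim(system.file("extdata", "similarity_minor.tsv",
                                         package = "presnfold"),
                             stringsAsFactors = FALSE)
  list(major = major, minor = minor)
}

#' Clade comparisons of the published similarity tables
#'
#' Recomputes the pooled two-sample two-tailed t-tests comparing the
#' metazoan major-snRNA mean distances against each alternative protist and
#' fungi sampling, and against the metazoan minor snRNAs.
#'
#' @return data.frame with `comparison`, `t_statistic`, `df`, `p_value`.
#' @export
clade_comparisons <- function() {
  tabs <- snrna_similarity_tables()
  met <- tabs$major$metazoa
  cmp <- list(
    metazoa_vs_protists_broad = tabs$major$protists_broad,
    metazoa_vs_protists_model = tabs$major$protists_model,
    metazoa_vs_fungi_broad = tabs$major$fungi_broad,
    metazoa_vs_fungi_model = tabs$major$fungi_model,
    metazoa_major_vs_minor = tabs$minor$metazoa_minor)
  rows <- lapply(names(cmp), function(nm) {
    tt <- two_sample_ttest(met, cmp[[nm]])
    data.frame(comparison = nm, t_statistic = tt$t_statistic,
               df = tt$degrees_of_freedom, p_value = tt$p_value)
  })
  do.call(rbind, rows)
}
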