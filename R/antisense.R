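#' Pair each antisense TSS with its cognate sense transcript
#'
#' For every aTSS, looks up the overlapped gene and takes the maximum
#' average coverage over that gene's sense (leaderless/leadered) TSSs; a
#' gene without a detected sense TSS gets sense coverage 0 and
#' `sense_detected = FALSE`.
#'
#' @param classified output of [classify_tss()] with `average_coverage`.
#' @return data.frame `tss_id`, `gene`, `antisense_coverage`,
#'   `sense_coverage`, `sense_detected`; one row per aTSS.
#' @export
pair_sense_antisense <- function(classified) {
  a <- classified[classified$primary_class == "antisense", , drop = FALSE]
  if (any(is.na(a$associated_gene))) {
    stop("antisense TSS without an overlapped gene", call. = FALSE)
  }
  pc <- classified[classified$primary_class %in% c("leaderless", "leadered"), ,
                   drop = FALSE]
  sense_cov <- vapply(a$associated_gene, function(g) {
    cov <- pc$average_coverage[pc$associated_gene == g]
    if (length(cov)) max(cov) else 0
  }, numeric(1))
  data.frame(tss_id = a$tss_id, gene = a$associated_gene,
             antisense_coverage = a$average_coverage,
             sense_coverage = sense_cov,
             sense_detected = sense_cov > 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sense/antisense reciprocity statistics
#'
#' Reports the fraction of antisense transcripts whose cognate sense
#' transcript was not detected, the Spearman rank correlation over pairs
#' with both coverages positive (`NA` when fewer than two such pairs), and
#' an axis-concentration statistic: the fraction of pairs in which the
#' weaker of the two coverages is below a tenth of the stronger (points
#' lying near one of the scatterplot axes).
#'
#' @param pairs output of [pair_sense_antisense()].
#' @param axis_ratio cut-off of the min/max coverage ratio.
#' @return list `fraction_sense_undetected`, `spearman`,
#'   `axis_concentration`, `n_pairs`, `n_both_expressed`.
#' @export
reciprocity_stats <- function(pairs, axis_ratio = 0.1) {
  stopifnot(nrow(pairs) >= 2)
  undet <- mean(!pairs$sense_detected)
  both <- pairs$sense_coverage > 0 & pairs$antisense_coverage > 0
  rho <- if (sum(both) >= 2) {
    stats::cor(pairs$sense_coverage[both], pairs$antisense_coverage[both],
               method = "spearman")
  } else NA_real_
  hi <- pmax(pairs$sense_coverage, pairs$antisense_coverage)
  lo <- pmin(pairs$sense_coverage, pairs$antisense_coverage)
  axis_frac <- mean(ifelse(hi > 0, lo / hi, 0) < axis_ratio)
  list(fraction_sense_undetected = undet, spearman = rho,
       axis_concentration = axis_frac, n_pairs = nrow(pairs),
       n_both_expressed = sum(both))
}

#' Overlap of internal/antisense TSSs with a gene category
#'
#' Counts iTSSs and aTSSs whose overlapped gene belongs to the given
#' annotation category (e.g. transposase genes), and separately the iTSSs
#' positioned in the 3'-most fraction of the gene (3'-end overlap).
#'
#' @param classified output of [classify_tss()].
#' @param genome a `genome_model`.
#' @param category feature category to count against.
#' @param three_prime_frac gene tail fraction counted as 3'-end overlap.
#' @return list `internal_overlapping`, `internal_three_prime`,
#'   `antisense_overlapping`.
#' @export
category_overlap <- function(classified, genome, category = "transposase",
                             three_prime_frac = 0.2) {
  f <- genome$features
  if (!any(f$category == category)) {
    warning("no features of category '", category, "' in the annotation")
    return(list(internal_overlapping = 0L, internal_three_prime = 0L,
                antisense_overlapping = 0L))
  }
  cat_ids <- f$feature_id[f$category == category]
  it <- classified[classified$primary_class == "internal" &
                     classified$associated_gene %in% cat_ids, , drop = FALSE]
  at <- classified[classified$primary_class == "antisense" &
                     classified$associated_gene %in% cat_ids, , drop = FALSE]
  n3 <- 0L
  if (nrow(it)) {
    j <- match(it$associated_gene, f$feature_id)
    len <- f$end[j] - f$start[j] + 1
    off <- ifelse(f$strand[j] == "+", it$position - f$start[j],
                  f$end[j] - it$position)
    n3 <- sum(off / len >= 1 - three_prime_frac)
  }
  list(internal_overlapping = nrow(it), internal_three_prime = as.integer(n3),
       antisense_overlapping = nrow(at))
}
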