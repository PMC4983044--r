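#' Oriented feature sequences
#'
#' Extracts each feature's sequence on its own strand (5'->3'), e.g. the
#' CDS beginning with the start codon.
#'
#' @param genome a `genome_model`.
#' @param feature_ids features to extract (default: all).
#' @return named character vector of sequences.
#' @export
feature_sequences <- function(genome, feature_ids = NULL) {
  f <- genome$features
  if (!is.null(feature_ids)) f <- f[f$feature_id %in% feature_ids, , drop = FALSE]
  out <- character(nrow(f))
  for (repl in unique(f$replicon)) {
    x <- genome$seq[[repl]]
    sel <- which(f$replicon == repl)
    v <- as.character(Biostrings::Views(x, start = f$start[sel],
                                        end = f$end[sel]))
    minus <- f$strand[sel] == "-"
    if (any(minus)) {
      v[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(v[minus])))
    }
    out[sel] <- v
  }
  names(out) <- f$feature_id
  out
}

#' 5'-UTR length histograms
#'
#' Tabulates (a) the number of protein-coding TSSs with 0..`max_ext`
#' nucleotides between TSS and start codon (the leaderless extension
#' spectrum) and (b) leadered 5'-UTR lengths in 10-nt groups covering
#' 6..250 nt (first group truncated at 6).
#'
#' @param classified output of [classify_tss()].
#' @param max_ext largest extension tabulated individually.
#' @param max_utr largest 5'-UTR length.
#' @param bin group width of the leadered histogram.
#' @return list `extension_counts` (named 0..max_ext) and `leader_bins`
#'   (named "6-15", "16-25", ...).
#' @export
utr_histograms <- function(classified, max_ext = 20, max_utr = 250, bin = 10) {
  pc <- classified[classified$primary_class %in% c("leaderless", "leadered"), ,
                   drop = FALSE]
  ext <- table(factor(pc$utr_length, levels = 0:max_ext))
  extension_counts <- setNames(as.integer(ext), names(ext))

  lead <- classified$utr_length[classified$primary_class == "leadered"]
  breaks <- seq(6, max_utr + bin, by = bin)   # 6,16,26,...; last bin truncated
  idx <- findInterval(lead, breaks)
  lab_hi <- pmin(breaks[-1] - 1, max_utr)
  labels <- paste0(breaks[-length(breaks)], "-", lab_hi)
  tab <- table(factor(idx, levels = seq_along(labels)))
  leader_bins <- setNames(as.integer(tab), labels)
  list(extension_counts = extension_counts, leader_bins = leader_bins)
}

#' Top and bottom expression deciles
#'
#' Orders TSSs by `average_coverage` (ties broken by coverage then
#' position, so the split is deterministic) and takes the lowest and
#' highest `floor(N/10)` as the bottom and top deciles, with per-class
#' counts inside each.
#'
#' @param classified output of [classify_tss()] with `average_coverage`.
#' @param classes restrict to these primary classes first (default: all).
#' @return list of class `expression_deciles`: `k` (decile size), `top`,
#'   `bottom` (row subsets), `top_classes`, `bottom_classes` (counts).
#' @export
expression_deciles <- function(classified, classes = NULL) {
  x <- classified
  if (!is.null(classes)) {
    x <- x[x$primary_class %in% classes, , drop = FALSE]
  }
  n <- nrow(x)
  if (n < 20) warning("fewer than 20 TSSs; deciles may overlap")
  k <- floor(n / 10)
  o <- order(x$average_coverage, x$position)
  bottom <- x[o[seq_len(k)], , drop = FALSE]
  top <- x[o[seq.int(n - k + 1, n)], , drop = FALSE]
  lev <- sort(unique(x$primary_class))
  structure(list(
    k = k,
    top = top, bottom = bottom,
    top_classes = table(factor(top$primary_class, levels = lev)),
    bottom_classes = table(factor(bottom$primary_class, levels = lev))),
    class = "expression_deciles")
}

#' Start codons of leaderless transcripts
#'
#' Reads the three genome bases at each leaderless TSS's associated gene
#' start, tallies counts and mean average coverage per start codon (ATG,
#' GTG, TTG, other), and tabulates the 0-5 nt leaderless extension
#' spectrum separately for GTG-start genes.
#'
#' @param classified output of [classify_tss()] with `average_coverage`.
#' @param genome a `genome_model`.
#' @return list `by_codon` (data.frame codon/count/mean_coverage) and
#'   `gtg_extension` (named counts 0..5).
#' @export
start_codon_summary <- function(classified, genome) {
  ll <- classified[classified$primary_class == "leaderless", , drop = FALSE]
  seqs <- feature_sequences(genome, unique(ll$associated_gene))
  codon <- substr(seqs[ll$associated_gene], 1, 3)
  grp <- ifelse(codon %in% c("ATG", "GTG", "TTG"), codon, "other")
  grp <- factor(grp, levels = c("ATG", "GTG", "TTG", "other"))
  by_codon <- data.frame(
    codon = levels(grp),
    count = as.integer(table(grp)),
    mean_coverage = vapply(levels(grp), function(g) {
      if (any(grp == g)) mean(ll$average_coverage[grp == g]) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE)
  gtg_ext <- table(factor(ll$utr_length[grp == "GTG"], levels = 0:5))
  list(by_codon = by_codon,
       gtg_extension = setNames(as.integer(gtg_ext), names(gtg_ext)))
}

#' A/T fraction at the three codon positions
#'
#' Over all codons of all sequences, the fraction with A or T at codon
#' positions 1, 2 and 3, plus the overall A/T fraction for comparison.
#' Trailing bases of sequences whose length is not a codon multiple are
#' ignored with a warning.
#'
#' @param cds_sequences character vector of coding sequences (5'->3').
#' @return list `at_by_position` (length 3), `at_overall`, `n_codons`.
#' @export
codon_position_composition <- function(cds_sequences) {
  extra <- nchar(cds_sequences) %% 3
  if (any(extra != 0)) {
    warning(sum(extra != 0),
            " sequence(s) not a codon multiple; trailing bases ignored")
    cds_sequences <- substr(cds_sequences, 1,
                            nchar(cds_sequences) - extra)
  }
  chars <- strsplit(paste(cds_sequences, collapse = ""), "")[[1]]
  pos <- rep_len(1:3, length(chars))
  is_at <- chars %in% c("A", "T")
  at_by_position <- vapply(1:3, function(p) mean(is_at[pos == p]), numeric(1))
  list(at_by_position = at_by_position,
       at_overall = mean(is_at),
       n_codons = length(chars) / 3)
}

#' Base-frequency matrix after the start codon
#'
#' Per-position base frequencies over the first `length` nucleotides
#' following the start codon (i.e. starting at the second codon) of a gene
#' set; genes too short are excluded and counted.  Suitable as input for
#' [logo_matrix()]-style relative-entropy display against the genome
#' background.
#'
#' @param cds_sequences coding sequences including the start codon.
#' @param length number of positions after the start codon.
#' @return list `freq` (4 x `length` matrix, columns sum to 1),
#'   `n_included`, `n_excluded`.
#' @export
post_start_matrix <- function(cds_sequences, length = 97) {
  ok <- nchar(cds_sequences) >= 3 + length
  sub <- substr(cds_sequences[ok], 4, 3 + length)
  m <- matrix(unlist(strsplit(sub, "")), nrow = base::length(sub), byrow = TRUE)
  freq <- vapply(seq_len(length), function(j) {
    tabulate(match(m[, j], BASES), 4) / nrow(m)
  }, numeric(4))
  rownames(freq) <- BASES
  list(freq = freq, n_included = sum(ok), n_excluded = sum(!ok))
}
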