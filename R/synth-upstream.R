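#' Simulate a set of upstream 71-mers with a planted promoter
#'
#' Generates random GC-rich 71-mers and plants the basal-promoter
#' consensus (BRE followed by TATA box) into a fraction of them, with the
#' TATA 3' edge `tata_offset` nt (plus uniform jitter) upstream of the
#' last base.  Used to study promoter-motif recovery in isolation from the
#' full genome simulation.
#'
#' @param n number of sequences.
#' @param frac_planted fraction carrying the consensus.
#' @param consensus planted string over ACGT.
#' @param tata_offset distance from the consensus 3' edge to the 71-mer
#'   3' end.
#' @param jitter maximum uniform jitter (nt) on `tata_offset`.
#' @param gc background G+C fraction.
#' @param width sequence length.
#' @param seed RNG seed.
#' @return list with `seqs` (character vector) and `planted` (logical).
#' @export
simulate_upstream_seqs <- function(n, frac_planted = 0.8,
                                   consensus = "CGAAATTAT",
                                   tata_offset = 24, jitter = 2,
                                   gc = 0.67, width = 71, seed = 1) {
  set.seed(seed)
  motif <- strsplit(consensus, "")[[1]]
  k <- length(motif)
  planted <- runif(n) < frac_planted
  seqs <- vapply(seq_len(n), function(i) {
    x <- random_bases(width, gc)
    if (planted[i]) {
      off <- tata_offset + sample(seq(-jitter, jitter), 1)
      end <- width - off
      x[(end - k + 1):end] <- motif
    }
    paste(x, collapse = "")
  }, character(1))
  list(seqs = seqs, planted = planted)
}
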