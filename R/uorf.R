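STOP_CODONS <- c("TAA", "TAG", "TGA")

# EMBOSS pKa values
PKA_POSITIVE <- c(Nterm = 8.6, H = 6.5, K = 10.8, R = 12.5)
PKA_NEGATIVE <- c(Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1, Y = 10.1)

# average residue masses (Da); a peptide adds one water
RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

check_peptide <- function(peptide) {
  aa <- strsplit(peptide, "")[[1]]
  if (length(aa) == 0) stop("empty peptide", call. = FALSE)
  bad <- setdiff(unique(aa), names(RESIDUE_MASS))
  if (length(bad)) {
    stop("non-standard residue(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  aa
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch charge over the N-terminus, C-terminus and the
#' ionizable side chains (D, E, C, Y, H, K, R) with the EMBOSS pKa set.
#'
#' @param peptide amino-acid string (20 standard residues).
#' @param pH pH value(s).
#' @return net charge (vectorized over `pH`).
#' @export
peptide_charge <- function(peptide, pH) {
  aa <- check_peptide(peptide)
  counts_pos <- c(Nterm = 1, H = sum(aa == "H"), K = sum(aa == "K"),
                  R = sum(aa == "R"))
  counts_neg <- c(Cterm = 1, C = sum(aa == "C"), D = sum(aa == "D"),
                  E = sum(aa == "E"), Y = sum(aa == "Y"))
  z <- numeric(length(pH))
  for (g in names(counts_pos)) {
    z <- z + counts_pos[[g]] / (1 + 10^(pH - PKA_POSITIVE[[g]]))
  }
  for (g in names(counts_neg)) {
    z <- z - counts_neg[[g]] / (1 + 10^(PKA_NEGATIVE[[g]] - pH))
  }
  z
}

#' Isoelectric point of a peptide
#'
#' The pH at which [peptide_charge()] crosses zero, found by bisection on
#' \[0, 14\] to the requested tolerance.  The charge function is strictly
#' decreasing in pH, so the root is unique.
#'
#' @param peptide amino-acid string.
#' @param tol bisection tolerance (pH units).
#' @return the pI.
#' @export
peptide_pi <- function(peptide, tol = 1e-3) {
  check_peptide(peptide)
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (peptide_charge(peptide, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Average molecular weight of a peptide
#'
#' Sum of average residue masses plus one water (18.02 Da).
#'
#' @param peptide amino-acid string.
#' @return mass in Da.
#' @export
peptide_mw <- function(peptide) {
  aa <- check_peptide(peptide)
  sum(RESIDUE_MASS[aa]) + WATER_MASS
}

translate_orf <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAString(nt)))
}

#' Find upstream ORFs in a 5'-UTR sequence
#'
#' Scans all three frames of the UTR (given 5'->3' on the mRNA strand) for
#' start-codon..in-frame-stop ORFs fully contained in the UTR whose
#' peptide (excluding the stop) has at least `min_len` residues.
#' Overlapping ORFs are all reported.  Each record carries the peptide,
#' its length, isoelectric point and average molecular weight.
#'
#' @param utr_sequence the UTR sequence (character).
#' @param min_len minimum peptide length in amino acids.
#' @param start_codons allowed start codons (ATG by default; add GTG to
#'   scan for non-canonical starts).
#' @return data.frame `start_offset` (0-based within the UTR), `frame`,
#'   `length_aa`, `peptide`, `pi`, `mw`, sorted by start offset.
#' @export
find_uorfs <- function(utr_sequence, min_len = 15, start_codons = "ATG") {
  L <- nchar(utr_sequence)
  out <- list()
  if (L >= 6) {
    codon_at <- function(i) substr(utr_sequence, i, i + 2)
    starts <- which(vapply(seq_len(L - 2), function(i) {
      codon_at(i) %in% start_codons
    }, logical(1)))
    for (s in starts) {
      t <- s + 3
      while (t + 2 <= L && !(codon_at(t) %in% STOP_CODONS)) t <- t + 3
      if (t + 2 > L) next                       # no in-frame stop inside UTR
      len_aa <- (t - s) / 3
      if (len_aa < min_len) next
      pep <- translate_orf(substr(utr_sequence, s, t - 1))
      out[[length(out) + 1L]] <- data.frame(
        start_offset = s - 1L, frame = (s - 1L) %% 3L,
        length_aa = len_aa, peptide = pep,
        pi = peptide_pi(pep), mw = peptide_mw(pep),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start_offset = integer(), frame = integer(),
                      length_aa = integer(), peptide = character(),
                      pi = numeric(), mw = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start_offset), , drop = FALSE]
}

#' 5'-UTR sequence of a leadered TSS
#'
#' @param genome a `genome_model`.
#' @param tss one classified TSS row (class `leadered`).
#' @return the UTR (TSS up to the base before the start codon) on the
#'   mRNA strand.
#' @export
utr_sequence <- function(genome, tss) {
  stopifnot(tss$primary_class == "leadered")
  f <- genome$features
  j <- match(tss$associated_gene, f$feature_id)
  x <- genome$seq[[tss$replicon]]
  if (tss$strand == "+") {
    as.character(Biostrings::subseq(x, tss$position, f$start[j] - 1))
  } else {
    as.character(Biostrings::reverseComplement(
      Biostrings::subseq(x, f$end[j] + 1, tss$position)))
  }
}

#' Scan long 5'-UTRs for upstream ORFs
#'
#' Applies [find_uorfs()] to every leadered TSS whose UTR length lies in
#' `[min_utr, max_utr]` (the very-long-leader set).
#'
#' @param classified output of [classify_tss()].
#' @param genome a `genome_model`.
#' @param min_utr,max_utr UTR length window (nt).
#' @param min_len minimum peptide length (aa).
#' @param start_codons see [find_uorfs()].
#' @return data.frame of uORF records with `tss_id` and `gene` prepended;
#'   attribute `n_utr_scanned`.
#' @export
scan_long_utr_uorfs <- function(classified, genome, min_utr = 150,
                                max_utr = 250, min_len = 15,
                                start_codons = "ATG") {
  long <- classified[classified$primary_class == "leadered" &
                       classified$utr_length >= min_utr &
                       classified$utr_length <= max_utr, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(long))) {
    u <- utr_sequence(genome, long[i, , drop = FALSE])
    rec <- find_uorfs(u, min_len, start_codons)
    if (nrow(rec)) {
      rec <- cbind(tss_id = long$tss_id[i], gene = long$associated_gene[i],
                   rec, stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- rec
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(tss_id = character(), gene = character(),
               start_offset = integer(), frame = integer(),
               length_aa = integer(), peptide = character(),
               pi = numeric(), mw = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_utr_scanned") <- nrow(long)
  res
}

#' Count TSSs of small protein genes
#'
#' Counts protein-coding TSSs (leaderless or leadered) whose associated
#' gene encodes at most `max_len` amino acids (CDS length / 3 minus the
#' stop).
#'
#' @param classified output of [classify_tss()].
#' @param genome a `genome_model`.
#' @param max_len largest protein length counted as small (aa).
#' @return integer count.
#' @export
count_small_protein_tss <- function(classified, genome, max_len = 100) {
  pc <- classified[classified$primary_class %in% c("leaderless", "leadered"), ,
                   drop = FALSE]
  f <- genome$features
  j <- match(pc$associated_gene, f$feature_id)
  aa <- (f$end[j] - f$start[j] + 1) / 3 - 1
  sum(aa <= max_len)
}

#' Concatenate intergenic regions with a stop-codon linker
#'
#' Sorts the regions by length, joins neighbours with the 12-mer linker
#' `TTAATTAATTAA` (which contains a stop codon in all six reading frames)
#' and splits the concatenation into chunks of roughly 2-3 kb, never
#' splitting inside a region.  A chunk exceeds the upper bound only when a
#' single region does.
#'
#' @param regions character vector of sequences.
#' @param chunk_range target chunk size range (nt).
#' @param linker the linker sequence.
#' @return character vector of chunks.
#' @export
concat_intergenic <- function(regions, chunk_range = c(2000, 3000),
                              linker = "TTAATTAATTAA") {
  stopifnot(length(regions) > 0)
  regions <- regions[order(nchar(regions))]
  chunks <- character(0)
  cur <- ""
  for (r in regions) {
    cand <- if (nzchar(cur)) paste0(cur, linker, r) else r
    if (nzchar(cur) && nchar(cand) > chunk_range[2]) {
      chunks <- c(chunks, cur)
      cur <- r
    } else {
      cur <- cand
    }
  }
  if (nzchar(cur)) chunks <- c(chunks, cur)
  chunks
}

#' Intergenic region sequences of a genome
#'
#' Regions not overlapping any annotated feature, per replicon, on the
#' forward strand.
#'
#' @param genome a `genome_model`.
#' @param min_width smallest region reported.
#' @return character vector of sequences.
#' @export
intergenic_regions <- function(genome, min_width = 1) {
  out <- character(0)
  for (repl in names(genome$seq)) {
    L <- replicon_length(genome, repl)
    f <- genome$features[genome$features$replicon == repl, , drop = FALSE]
    occ <- IRanges::reduce(IRanges::IRanges(f$start, f$end))
    gaps <- IRanges::gaps(occ, start = 1, end = L)
    gaps <- gaps[IRanges::width(gaps) >= min_width]
    if (length(gaps)) {
      out <- c(out, as.character(Biostrings::Views(
        genome$seq[[repl]], start = IRanges::start(gaps),
        end = IRanges::end(gaps))))
    }
  }
  out
}
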