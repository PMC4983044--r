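#!/usr/bin/env Rscript
# Stage 6: uORFs in long 5'-UTRs, small-protein TSSs and the intergenic
# concatenation utility.
#
# Scans every leadered transcript with a 150-250 nt UTR for contained
# ATG...stop ORFs of >= 15 codons and reports peptide length, isoelectric
# point and average molecular weight; counts TSSs of genes encoding <= 100
# amino acids; and demonstrates the stop-codon-linker concatenation of the
# intergenic regions into 2-3 kb chunks.

suppressPackageStartupMessages(library(haloTSS))

fx <- read_fixture("results/fixture")
cl <- read_tsv("results/tss_classified.tsv")

uorfs <- scan_long_utr_uorfs(cl, fx$genome)
message(attr(uorfs, "n_utr_scanned"), " transcripts with 150-250 nt UTRs; ",
        nrow(uorfs), " uORFs found")
if (nrow(uorfs)) {
  message("peptides: ", paste(uorfs$length_aa, "aa, pI",
                              round(uorfs$pi, 2), collapse = "; "))
}
write_tsv(uorfs, "results/uorfs.tsv")

n_small <- count_small_protein_tss(cl, fx$genome)
message(n_small, " TSSs belong to small-protein genes (<= 100 aa), i.e. ",
        percent(n_small,
                sum(cl$primary_class %in% c("leaderless", "leadered"))),
        " % of protein-coding TSSs")

regions <- intergenic_regions(fx$genome, min_width = 50)
chunks <- concat_intergenic(regions)
message(length(regions), " intergenic regions concatenated into ",
        length(chunks), " chunks of ",
        min(nchar(chunks)), "-", max(nchar(chunks)), " nt")
write_tsv(data.frame(chunk = seq_along(chunks), length = nchar(chunks)),
          "results/intergenic_chunks.tsv")
message("wrote results/uorfs.tsv, intergenic_chunks.tsv")
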