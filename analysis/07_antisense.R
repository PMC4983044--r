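#!/usr/bin/env Rscript
# Stage 7: sense/antisense reciprocity and intragenic TSS positions.
#
# Pairs every antisense TSS with its host gene's strongest sense
# transcript, quantifies how often the sense partner is undetected and how
# reciprocal the two coverages are, locates iTSSs/aTSSs within their genes
# in ten equal sections, and counts transposase-gene overlaps.

suppressPackageStartupMessages(library(haloTSS))

fx <- read_fixture("results/fixture")
cl <- read_tsv("results/tss_classified.tsv")

pairs <- pair_sense_antisense(cl)
st <- reciprocity_stats(pairs)
message(st$n_pairs, " sense/antisense pairs; sense undetected for ",
        round(100 * st$fraction_sense_undetected), " %")
message("Spearman over co-expressed pairs (n = ", st$n_both_expressed,
        "): ", round(st$spearman, 3))
message("fraction of pairs near a scatter axis: ",
        round(st$axis_concentration, 3))
write_tsv(pairs, "results/sense_antisense_pairs.tsv")

it <- decile_distribution(cl, fx$genome, "internal")
at <- decile_distribution(cl, fx$genome, "antisense")
write_tsv(data.frame(section = 1:10, internal = it, antisense = at),
          "results/intragenic_deciles.tsv")
message("iTSS sections: ", paste(it, collapse = " "))
message("aTSS sections: ", paste(at, collapse = " "))

ov <- category_overlap(cl, fx$genome, "transposase")
message(ov$internal_overlapping, " iTSSs overlap transposase genes (",
        ov$internal_three_prime, " in the 3'-most 20 %); ",
        ov$antisense_overlapping, " aTSSs overlap transposase genes")
write_tsv(data.frame(count = unlist(ov)), "results/transposase_overlap.tsv")
message("wrote pairs, decile and overlap tables")
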