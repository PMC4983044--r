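#!/usr/bin/env Rscript
# Stage 3: classify the consensus TSSs against the annotation.
#
# Applies the distance rules (leaderless 0-5 nt, known-RNA -3..250 nt,
# overlap -> internal/antisense, leadered 6-250 nt, else intergenic),
# flags internal/antisense TSSs with downstream genes, finds genes with
# alternative TSSs and writes the per-replicon classification summary.

suppressPackageStartupMessages(library(haloTSS))

fx <- read_fixture("results/fixture")
cons <- read_tsv("results/tss_consensus.tsv")

cl <- classify_tss(cons, fx$genome)
cl <- add_downstream_flags(cl, fx$genome)

message("classes:")
print(table(cl$primary_class))
flagged <- !is.na(cl$downstream_gene)
message(sum(flagged & cl$primary_class == "internal"),
        " internal and ", sum(flagged & cl$primary_class == "antisense"),
        " antisense TSSs have a gene 1-250 nt downstream")

multi <- find_multi_tss(cl)
message(nrow(multi), " genes carry more than one TSS (",
        sum(multi$combination == "leaderless+leadered"),
        " with a leaderless and a leadered transcript)")

st <- summarize_tss(cl)
check_summary_invariants(st)
print(st)

write_tsv(cl, "results/tss_classified.tsv")
write_tsv(multi, "results/multi_tss_genes.tsv")
write_tsv(st, "results/summary_table.tsv")
message("wrote results/tss_classified.tsv, multi_tss_genes.tsv, summary_table.tsv")
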