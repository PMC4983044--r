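#!/usr/bin/env Rscript
# Stage 5: 5'-UTR lengths, expression deciles, start codons and coding
# composition.
#
# Tabulates the leaderless extension spectrum (0-20 nt) and the leadered
# UTR histogram (10-nt groups over 6-250 nt), compares leaderless vs
# leadered membership in the top and bottom expression deciles, summarizes
# start-codon usage of leaderless transcripts, and computes A/T codon-
# position composition plus the post-start-codon base-frequency matrices.

suppressPackageStartupMessages(library(haloTSS))

fx <- read_fixture("results/fixture")
cl <- read_tsv("results/tss_classified.tsv")

h <- utr_histograms(cl)
message("leaderless (0-5 nt): ", sum(h$extension_counts[as.character(0:5)]),
        "; leadered (6-250 nt): ", sum(h$leader_bins))
write_tsv(data.frame(extension = names(h$extension_counts),
                     count = h$extension_counts),
          "results/utr_extension_hist.tsv")
write_tsv(data.frame(bin = names(h$leader_bins), count = h$leader_bins),
          "results/utr_leader_hist.tsv")

dec <- expression_deciles(cl, classes = c("leaderless", "leadered"))
message("top decile: ", paste(names(dec$top_classes), dec$top_classes,
                              sep = "=", collapse = " "))
message("bottom decile: ", paste(names(dec$bottom_classes),
                                 dec$bottom_classes, sep = "=",
                                 collapse = " "))
write_tsv(data.frame(class = names(dec$top_classes),
                     top = as.integer(dec$top_classes),
                     bottom = as.integer(dec$bottom_classes)),
          "results/deciles_protein_coding.tsv")

sc <- start_codon_summary(cl, fx$genome)
print(sc$by_codon)
write_tsv(sc$by_codon, "results/start_codons.tsv")
write_tsv(data.frame(extension = names(sc$gtg_extension),
                     count = sc$gtg_extension),
          "results/gtg_extension_hist.tsv")

# composition over the two gene sets
seqs <- feature_sequences(fx$genome)
for (class in c("leaderless", "leadered")) {
  genes <- unique(cl$associated_gene[cl$primary_class == class])
  cds <- seqs[genes]
  cc <- codon_position_composition(cds)
  message(class, " genes: A/T at codon positions 1/2/3 = ",
          paste(round(cc$at_by_position, 3), collapse = "/"),
          " (overall ", round(cc$at_overall, 3), ")")
  m <- post_start_matrix(cds)
  write_tsv(data.frame(base = rownames(m$freq), m$freq, check.names = FALSE),
            paste0("results/post_start_freq_", class, ".tsv"))
}
message("wrote UTR, decile, start-codon and composition tables")
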