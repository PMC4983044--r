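#!/usr/bin/env Rscript
# Stage 8: final report.
#
# Re-checks the partition identities of the classification summary,
# recomputes the in-text percentages from the published per-replicon count
# table shipped with the package (the worked-example arithmetic), and
# compares the synthetic study's class proportions with them.

suppressPackageStartupMessages(library(haloTSS))

st <- read_tsv("results/summary_table.tsv")
class(st) <- c("summary_table", "data.frame")
check_summary_invariants(st)
g <- function(x) st$total[st$class == x]
message("synthetic study: ", g("all"), " TSSs; leaderless ",
        percent(g("leaderless"), g("protein_coding")),
        " % of protein-coding, novel ", percent(g("novel"), g("all")),
        " % of all")

counts <- class_counts_example()
tot <- setNames(rowSums(counts[, -1]), counts$class)
published <- data.frame(
  quantity = c("leaderless of protein-coding", "leadered of protein-coding",
               "novel of all", "intergenic of novel", "antisense of novel",
               "internal of novel", "genes with two TSSs",
               "GTG-start leaderless", "iTSS with downstream gene",
               "aTSS with downstream gene", "small-protein TSSs"),
  value = c(percent(tot[["leaderless"]], tot[["protein_coding"]]),
            percent(tot[["leadered"]], tot[["protein_coding"]]),
            percent(tot[["novel"]], tot[["all"]]),
            percent(tot[["intergenic_novel"]], tot[["novel"]]),
            percent(tot[["antisense"]], tot[["novel"]]),
            percent(tot[["internal"]], tot[["novel"]]),
            percent(139, tot[["protein_coding"]], 1),
            percent(118, tot[["leaderless"]]),
            percent(144, tot[["internal"]]),
            percent(50, tot[["antisense"]]),
            percent(291, tot[["protein_coding"]])))
print(published)
write_tsv(published, "results/published_percentages.tsv")
message("wrote results/published_percentages.tsv")
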