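#!/usr/bin/env Rscript
# Stage 2: call TSSs from the +/-TEX coverage tracks.
#
# Normalizes all libraries to the shallowest, calls per-replicate
# candidates (height >= 5, two-fold step, TEX enrichment >= 2.5 with one
# pseudocount), merges candidates closer than 10 nt and forms the
# replicate consensus.  Reports how recovery compares with the planted
# truth and writes results/tss_consensus.tsv.

suppressPackageStartupMessages(library(haloTSS))

fx <- read_fixture("results/fixture")
cons <- call_tss_consensus(fx$coverage)
cons$tss_id <- sprintf("TSS%05d", seq_len(nrow(cons)))

message(nrow(cons), " consensus TSSs")
message("support: >=1: ", sum(cons$support >= 1),
        "  >=2: ", sum(cons$support >= 2),
        "  =3: ", sum(cons$support == 3))

hit <- vapply(seq_len(nrow(fx$truth)), function(i) {
  any(cons$strand == fx$truth$strand[i] &
        abs(cons$position - fx$truth$position[i]) < 10)
}, logical(1))
message("recall of planted TSSs: ", round(mean(hit), 3))

repro <- cons[cons$support >= 2, ]
dec <- vapply(seq_len(nrow(fx$decoys)), function(i) {
  any(repro$strand == fx$decoys$strand[i] &
        abs(repro$position - fx$decoys$position[i]) < 10)
}, logical(1))
message("processed decoys in the reproducible (>=2 replicate) set: ",
        sum(dec), " of ", nrow(fx$decoys))

write_tsv(cons, "results/tss_consensus.tsv")
message("wrote results/tss_consensus.tsv")
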