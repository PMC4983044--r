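#!/usr/bin/env Rscript
# Stage 1: generate the synthetic dRNA-Seq study.
#
# Builds the GC-rich genome with its planted primary transcriptome (truth
# TSSs of all six classes, basal promoters, TEX-neutral processed decoys)
# and simulates three replicate +/-TEX 5'-end coverage libraries.  Writes
# the fixture (FASTA, GFF3, wiggle, TSV) under results/fixture/.

suppressPackageStartupMessages(library(haloTSS))

seed <- 1
cfg <- synth_config(seed = seed)
sim <- generate_genome(cfg)
cov <- simulate_all_coverage(sim)

message("genome: ", replicon_length(sim$genome), " bp, GC ",
        round(gc_fraction(sim$genome), 3))
message("truth TSSs by class:")
print(table(sim$truth$true_class))
message(nrow(sim$decoys), " processed 5'-end decoys planted")

files <- write_fixture(sim, cov, "results/fixture")
message("wrote ", length(files), " fixture files to results/fixture/")
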