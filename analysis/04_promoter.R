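#!/usr/bin/env Rscript
# Stage 4: basal-promoter model.
#
# Extracts the 71-mer upstream of every TSS, refines a 28-base PWM by
# iterative positional re-alignment at the exact p = 0.001 score
# threshold, classifies each TSS's promoter as stringent / relaxed / none
# (p <= 0.001 / p <= 0.01), and writes the PWM, the promoter calls and the
# relative-entropy logo matrix.

suppressPackageStartupMessages(library(haloTSS))

fx <- read_fixture("results/fixture")
cl <- read_tsv("results/tss_classified.tsv")

ups <- extract_upstream(fx$genome, cl)
q <- genome_background(fx$genome)
message("background composition: ",
        paste(names(q), round(q, 3), sep = "=", collapse = " "))

ref <- refine_pwm(ups, q)
print(ref)
message("p = 0.001 score threshold at convergence: ", round(ref$threshold, 3))

calls <- classify_promoters(ref$pwm, ups)
message("stringent score cutoff: ", round(attr(calls, "t_stringent"), 3),
        "; relaxed cutoff: ", round(attr(calls, "t_relaxed"), 3))
print(table(calls$promoter_class))

logo <- logo_matrix(substr(ups$seq[ref$positives], ref$offsets,
                           ref$offsets + 27), q)
message("total information content of the motif: ",
        round(sum(logo$information), 2), " bits")

pwm <- ref$pwm
write_tsv(data.frame(base = rownames(pwm$counts), pwm$counts,
                     check.names = FALSE), "results/promoter_pwm_counts.tsv")
write_tsv(data.frame(base = rownames(pwm$log_odds), pwm$log_odds,
                     check.names = FALSE), "results/promoter_pwm_logodds.tsv")
write_tsv(calls, "results/promoter_calls.tsv")
write_tsv(data.frame(base = rownames(logo$contributions), logo$contributions,
                     check.names = FALSE), "results/promoter_logo.tsv")
message("wrote results/promoter_{pwm_counts,pwm_logodds,calls,logo}.tsv")
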