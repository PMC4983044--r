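# haloTSS

Primary-transcriptome analysis from differential RNA-Seq (dRNA-Seq) for
GC-rich prokaryotes, written for the haloarchaeal case: leaderless-dominant
translation, BRE+TATA basal promoters, and a large complement of internal
and antisense transcripts.

dRNA-Seq compares two libraries from the same RNA: one treated with a
5'-monophosphate-dependent terminator exonuclease (TEX), which destroys
processed transcripts but spares 5'-triphosphate primary transcripts, and
one untreated. haloTSS turns strand-specific 5'-end coverage of such
library pairs into an annotated TSS catalogue:

* **TSS calling** — per-replicate candidates require a minimum normalized
  +TEX height, a ≥2-fold step over the upstream neighbour, and a TEX
  enrichment factor `plus/(minus + 1) ≥ 2.5`; candidates closer than
  10 nt merge, and a replicate consensus records support and mean +TEX
  coverage.
* **Classification** — each TSS becomes *leaderless* (gene start 0–5 nt
  downstream), *known RNA* (−3…250 nt), *internal*/*antisense* (inside an
  annotated gene, same/opposite strand), *leadered* (6–250 nt) or
  *intergenic novel*, with downstream-gene flags, multi-TSS genes, and
  intragenic decile positions.
* **Promoter model** — 71-mers upstream of all TSSs; a 28-base PWM
  (log₂-odds against the strand-symmetric genomic background) refined by
  iterative positional re-alignment at an exact p = 0.001 score threshold
  computed by dynamic programming; promoters classified stringent
  (p ≤ 0.001), relaxed (p ≤ 0.01) or none; relative-entropy logo
  matrices.
* **Downstream analyses** — 5'-UTR length spectra, expression deciles,
  start-codon usage, post-start-codon composition, uORF detection in long
  UTRs with peptide pI (bisection on the EMBOSS charge model) and average
  molecular weight, small-protein TSS counts, sense/antisense reciprocity,
  transposase overlaps, and the stop-codon-linker concatenation of
  intergenic regions.
* **Synthetic data** — a generator that plants a full truth transcriptome
  (all six TSS classes, promoters, TEX-neutral processed decoys,
  anti-correlated sense/antisense expression) in a 67 % GC genome, so the
  entire chain is testable without sequencing data.

## Worked example

```r
library(haloTSS)
cfg <- synth_config(seed = 1)          # the default synthetic study
run <- run_pipeline(cfg)
run$summary[, c("class", "total", "percent")]
#>               class total percent
#> 1               all   525      NA
#> 2           forward   258      49
#> 3           reverse   267      51
#> 4    protein_coding   235      45
#> 5        leaderless   183      78
#> 6          leadered    52      22
#> 7         known_rna    11       2
#> 8             novel   279      53
#> 9  intergenic_novel    40      14
#> 10        antisense   124      44
#> 11         internal   115      41
```

525 consensus TSSs are called from the three simulated ±TEX replicate
pairs; 78 % of protein-coding transcripts are leaderless (the planted
haloarchaeal proportion plus the leaderless sense companions of antisense
units), and novel transcripts (intergenic + antisense + internal) make up
53 % of the catalogue. The partition identities (forward + reverse = all,
leaderless + leadered = protein-coding, …) hold exactly.

```r
run$promoter$refinement
#> pwm_refinement: 186/525 positives after 4 iteration(s) (converged); peak offset 26
#>   consensus: AAACTAGAAATCCGAAATTATATGCAAT
```

The refinement converges in 4 iterations and its consensus contains the
planted BRE+TATA element `CGAAATTAT` exactly (positions 13–21 of the
28-mer). Reciprocity of sense and antisense transcription:

```r
unlist(run$analyses$reciprocity[1:3])
#> fraction_sense_undetected         spearman  axis_concentration
#>                 0.57            -0.86                0.73
```

57 % of antisense TSSs have no detected sense partner (0.6 planted), and
co-expressed pairs are strongly rank-anti-correlated (Spearman −0.86
against a planted −0.8): most points of the sense-vs-antisense scatter lie
on one of the axes.

## The analysis workflow

The numbered drivers under `analysis/` run the study end to end and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # genome + truth + ±TEX coverage
Rscript analysis/02_call_tss.R          # normalized calling + consensus
Rscript analysis/03_classify.R          # classes, flags, summary table
Rscript analysis/04_promoter.R          # PWM refinement + promoter calls
Rscript analysis/05_utr_start_codons.R  # UTR spectra, deciles, codons
Rscript analysis/06_uorf_smallproteins.R
Rscript analysis/07_antisense.R         # reciprocity + decile positions
Rscript analysis/08_report.R            # identities + worked percentages
```

Each script states what it found (recall of the planted TSSs, decoy
rejections, promoter recovery, …) and leaves TSV tables behind.

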