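---
title: "Calling and classifying primary transcription start sites from dRNA-Seq"
author: "haloTSS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and classifying primary transcription start sites from dRNA-Seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haloTSS)
```

## The problem

Differential RNA-Seq (dRNA-Seq) discriminates primary transcript 5' ends
from processed ones by sequencing two libraries from the same RNA: one
treated with a 5'-monophosphate-dependent terminator exonuclease (TEX),
which degrades processed transcripts but spares 5'-triphosphate primary
transcripts, and one untreated. A genuine transcription start site (TSS)
shows a sharp accumulation of read 5' ends that is *enriched* in the +TEX
library; a processed site shows similar 5'-end counts in both libraries.

In halophilic archaea the resulting primary-transcriptome map has a
characteristic structure: most protein-coding transcripts are
*leaderless* (0–5 nt between TSS and start codon), basal promoters
consist of a BRE element (consensus `CGAAA`) directly 5' of a TATA box
(consensus `TTWT`), and a large share of TSSs lie inside or antisense to
annotated genes. haloTSS implements the complete analysis chain for such
data — TSS calling, classification, promoter-motif refinement, and the
downstream UTR, start-codon, uORF, small-protein and sense/antisense
analyses — together with a synthetic-data generator so that every stage
is testable without access to raw sequencing data.

## TSS calling

Coverage tracks hold strand-specific *read-start* counts per base (the
number of reads whose 5' end maps at each position), not read-body
coverage: it is the 5'-end signal that defines a TSS, and read bodies add
no information to the calling decision. Tracks are normalized to the
shallowest library by `min(mapped_reads)/mapped_reads`, preserving
within-library ratios.

A position is a TSS candidate in one replicate when, on normalized
tracks:

* the +TEX height reaches `min_height` (default 5 normalized read
  starts),
* the height steps up at least `step_factor`-fold (default 2.0) over the
  neighbouring position upstream in transcription direction — a TSS is a
  sharp 5' boundary, not a plateau, so replicon edge positions, which
  have no upstream context, are never callable,
* the TEX enrichment factor `plus / (minus + 1)` is at least 2.5
  (inclusive). The single pseudocount keeps the ratio defined when the
  untreated library has no reads at the position.

The enrichment cutoff of 2.5 is the biologically meaningful parameter;
`min_height` and `step_factor` are exposed tuning knobs of this caller.
Candidates closer than 10 nt on the same strand (single-linkage over
successive gaps) are one TSS, represented by the highest-+TEX member with
ties broken to the most upstream position. The same <10 nt rule
identifies TSSs across replicates; the consensus records which replicates
detected and TEX-enriched each TSS and the mean +TEX height over
detecting replicates (`average_coverage`).

Two conventions follow from a noise analysis of the count model rather
than from the calling rules themselves. Recall of planted TSSs is
measured on the full consensus (detected in at least one replicate),
mirroring how a pooled multi-replicate TSS catalogue is used downstream.
The absence of calls at processed sites, however, is asserted on the
*reproducible* consensus (detected in at least two replicates): at a
TEX-neutral site the enrichment ratio is a ratio of two same-mean counts,
and a single library crossing 2.5-fold by chance is an expected event at
the scale of hundreds of processed sites, while the same fluctuation in
two independent replicates within 10 nt is not. Replication, not the
threshold, is what separates primary from processed 5' ends at
borderline coverage.

## Classification

Every TSS receives exactly one class by precedence, with distances
measured in transcription direction on 1-based inclusive coordinates
(d = 0 is the start-codon first base):

1. **leaderless** — a same-strand protein-coding gene start 0–5 nt
   downstream. Sense association wins even when the TSS lies inside
   another gene, the situation of overlapping gene pairs.
2. **known RNA** — a same-strand known-RNA 5' end between −3
   (a small retraction, for RNAs annotated slightly too long) and
   +250 nt.
3. **internal / antisense** — a TSS inside an annotated gene, on the
   same or opposite strand; same-strand overlap is preferred when genes
   on both strands contain the TSS. Internal and antisense TSSs may
   still have a gene start 1–250 nt downstream; these are flagged
   separately as likely promoters for the downstream gene.
4. **leadered** — a same-strand protein-coding gene start 6–250 nt
   downstream.
5. **intergenic novel** — everything else.

Placing the overlap rule above the leadered rule is a deliberate design
choice: an internal TSS near the 3' end of one gene that drives the next
gene is an internal TSS *with a downstream-gene flag*, not a leadered
transcript of the downstream gene. The alternative order would make such
sub-operonic promoters unrepresentable. The leaderless rule stays on top
because a TSS on (or within 5 nt of) a start codon is evidence of a
sense transcript regardless of gene overlap. Within each rule the
nearest eligible gene wins, which makes the assignment total and
deterministic.

Intragenic positions of internal and antisense TSSs are summarized by
dividing each overlapped gene into 10 equal sections along its own
5'→3' direction (`section = floor(10*offset/length) + 1`, clamped
to 10).

## The promoter model

Each TSS contributes a 71-base sequence on its own strand whose last
base is the first transcribed base; TSSs within 70 nt of a replicon edge
or with ambiguous bases are skipped and counted. The background base
composition is taken from the complete genome, strand-symmetrized
(q~A~ = q~T~, q~C~ = q~G~) — not from the 71-mer collection, which is
promoter-biased by construction.

A 28-base position weight matrix is built from aligned windows with a
pseudocount of 0.5 per base per column (avoiding infinite log-odds) and
log~2~ odds against the genomic background. Match significance uses the
exact score distribution of a random background window, computed by
dynamic programming over columns with scores discretized downwards to a
granularity of 0.001. The returned threshold is the upper p-quantile of
that distribution: the largest discretized score t with
P(score ≥ t) ≥ p. For a 28-column matrix the distribution atoms are
minute, so the quantile and the strict-tail formulations coincide in
practice; the quantile form is also well defined for toy matrices with
large atoms, where a strict-tail threshold can be unattainable.

Scanning evaluates all 44 window offsets of a 71-mer on the given strand
only (archaeal basal promoters are strand-specific) and reports the
best-scoring window at or above the threshold, ties to the smallest
offset.

### Iterative positional refinement

The TATA box sits at a roughly, but not exactly, fixed distance from the
TSS, so aligning windows by TSS position blurs the motif. Refinement
alternates between model and alignment:

1. Build the PWM from the currently aligned positive windows. The
   initial alignment uses a fixed window whose 3' edge is 18 nt upstream
   of the TSS, wide enough to cover the BRE+TATA region at typical
   archaeal spacing (TATA 3' edge ~22–26 nt upstream).
2. Compute the p = 0.001 score threshold for the current PWM.
3. Scan all 71-mers; keep hits whose match offset lies within ±4 nt of
   the modal (peak) offset, re-aligned at their match offsets. The
   *modal* offset is used rather than the mean: the offset distribution
   is a sharp peak over a uniform background of chance hits, and the
   mode is insensitive to that background.
4. Repeat until the positive set and all offsets are identical between
   successive iterations (complete convergence), a previously seen state
   recurs (an oscillation, reported as non-converged), or an iteration
   cap of 200 is reached. Fewer than two positives at any point is a
   degenerate-motif error.

The refined PWM then classifies every TSS: **stringent** when the best
match reaches the p ≤ 0.001 threshold, **relaxed** when it reaches only
p ≤ 0.01, **none** otherwise. The corresponding numeric score cutoffs
are dataset-dependent outputs, reported alongside the calls, not
constants of the method. For display, aligned windows are summarized as
per-column Kullback–Leibler information with signed per-base
contributions (negative when a base is rarer than background, matching
inverted letters in a structure logo).

## Downstream analyses

* **UTR spectra** — counts of protein-coding TSSs with 0–20 nt between
  TSS and start codon, and leadered UTR lengths in 10-nt groups over
  6–250 nt (first group truncated at 6).
* **Expression deciles** — TSSs ordered by `average_coverage`; the
  bottom and top `floor(N/10)` form the deciles, with ties broken by
  coverage then position so the split is reproducible. Per-class counts
  inside each decile compare, e.g., leaderless vs leadered membership.
* **Start codons** — the three genome bases at each leaderless gene
  start, tallied as ATG/GTG/TTG/other (never silently dropped), with
  mean coverage per codon and the 0–5 nt extension spectrum of GTG
  starts.
* **Coding composition** — A/T fractions at the three codon positions,
  and 4×97 base-frequency matrices over the 97 nt following the start
  codon (the figure-ready window starting at codon two) for leaderless
  vs leadered gene sets.
* **uORFs** — all three frames of each 150–250 nt UTR are scanned for
  ATG…in-frame-stop ORFs fully contained in the UTR with at least 15
  encoded residues; GTG starts are an option, off by default, since
  canonical uORF calls are ATG-initiated. Each peptide gets its
  isoelectric point — the unique root of the Henderson–Hasselbalch net
  charge with the EMBOSS pKa set, found by bisection on pH 0–14 to
  10^-3^ — and its average molecular weight (residue masses plus one
  water).
* **Small proteins** — protein-coding TSSs whose gene encodes at most
  100 amino acids (CDS length/3 − 1).
* **Sense/antisense reciprocity** — each antisense TSS is paired with
  the *maximum* average coverage over its host gene's sense TSSs (the
  strongest sense promoter is the relevant partner). Reported are the
  fraction of pairs with no detected sense transcript, the Spearman
  correlation over co-expressed pairs, and an axis-concentration
  statistic (fraction of pairs whose weaker coverage is under a tenth of
  the stronger — points lying on a scatterplot axis).
* **Transposase overlap** — internal/antisense TSSs overlapping
  transposase-category genes, with "3'-end overlap" quantified as the
  3'-most 20 % of the gene; the fraction is a parameter since no
  standard cutoff exists.
* **Intergenic concatenation** — intergenic regions sorted by length and
  joined with the 12-mer linker `TTAATTAATTAA`, which contains a stop
  codon in all six reading frames, then split into ~2–3 kb chunks
  without ever splitting a region (a chunk exceeds 3 kb only when a
  single region does). This prepares translated-search input for
  missing-gene discovery.

Percentages in summary tables are rounded half-up (0 decimals for table
cells, 1 for small in-text values), and the classification summary
satisfies exact partition identities (forward + reverse = all;
leaderless + leadered = protein-coding; intergenic + antisense +
internal = novel; protein-coding + known + novel = all) on every run.

## The synthetic study

`synth_config()` defines the conditions the generator emulates; its
defaults are fixed study conditions, not tuning knobs:

* a single ~2.5 Mb replicon at 67 % GC (the haloarchaeal genome
  composition), sized to at least 10× the annotated span;
* a one-tenth-scale transcriptome with haloarchaeal class proportions —
  130 leaderless, 52 leadered, 11 known-RNA, 40 intergenic, 115
  internal and 124 antisense truth units — yielding ≈520 truth TSSs
  including the sense companions of antisense units;
* leaderless extensions of 0–5 nt with 80 % exactly 0; leadered UTRs
  6–250 nt with mean ≈30 nt (short leaders dominate);
* start codons ATG/GTG/TTG at 82/12/6 %, GTG-start leaderless genes at
  half the expression of the rest, and leaderless genes at four-fold the
  expression of leadered ones — the planted expression effects the
  decile and start-codon analyses must recover;
* per-TSS expected read-start counts drawn log-normally with median 150
  and log-sd 0.8, matching average 5'-end coverages of order 10²–10³
  reported for haloarchaeal dRNA-Seq;
* the consensus `CGAAA`+`TTAT` planted upstream of 34 % of truth TSSs,
  TATA 3' edge 24 ± 2 nt upstream of the TSS;
* +TEX read-start rates 5-fold the −TEX rates at primary TSSs; one
  TEX-neutral processed decoy per expressed gene at half the primary
  rate; Poisson background of 0.02 read starts per base;
* negative-binomial count noise with size 100 around the expected
  rates. The log-normal expression distribution carries the biological
  spread between genes; the negative binomial models residual technical
  noise around a gene's fixed rate, and near-Poisson noise at this scale
  is what makes a 2.5-fold enrichment test meaningful at all — under
  strong per-observation overdispersion, same-mean ratios exceed 2.5
  routinely and no threshold separates primary from processed sites;
* library depths log-normal with log-sd 0.05 (near-equimolar pooling);
* sense/antisense expression coupled through a Gaussian copula with
  target Spearman −0.8, with 60 % of antisense hosts lacking a detected
  sense transcript;
* a single master seed; per-replicate streams derive from it
  deterministically, and the same configuration reproduces every file
  byte for byte.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: read-level errors and mapping
ambiguity, operonic structure and polycistronic read-through, 5'-end
softness of real TSSs (truth positions are exact; real TSSs wobble over
1–3 nt), sequence-dependent library biases, rRNA contamination, and
genome-scale gene density (units are spaced so that classification
windows never interact except where planted). The classifier's exact
recovery on synthetic data validates the rule arithmetic, not its
behaviour in dense gene neighbourhoods, which the toy-genome unit tests
probe instead.

## Problem sizes and runtime

The shipped analyses and tests use the one-tenth-scale study (≈520
TSSs, ≈2.5 Mb genome, three replicates), 500 upstream 71-mers for
promoter-recovery runs, brute-force enumeration up to width-5 PWMs, and
100 random peptides for the pI oracle. These sizes keep a complete run
in the low tens of seconds while leaving every estimate's sampling error
well inside the tolerances asserted.

## Known limitations

* The caller reports exact peak positions; it does not model multi-base
  TSS clusters beyond the 10-nt merge rule.
* Known-RNA association uses the annotated 5' end only; processed RNA
  families (e.g. crRNAs) are out of scope.
* The refinement's initial window anchor (3' edge 18 nt upstream) is a
  reasoned default for archaeal spacing; motifs at unusual distances
  require setting `init_offset`.
* Average coverage aggregates replicates by mean over detecting
  replicates; no variance-stabilized expression measure is attempted.
* pI uses the EMBOSS pKa set; other scales shift absolute values by up
  to ~0.5 pH units, though orderings are stable.
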