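#' Configuration for the synthetic dRNA-Seq study
#'
#' Defines the conditions the synthetic genome, truth TSS set and coverage
#' tracks are generated under.  Defaults emulate a GC-rich haloarchaeal
#' chromosome: 67 % GC, leaderless-dominant protein-coding gene starts,
#' planted BRE+TATA basal promoters upstream of a third of the TSSs,
#' five-fold TEX enrichment of primary 5' ends, and sense/antisense
#' expression that is negatively associated.  Class counts default to a
#' one-tenth-scale transcriptome with the class proportions typical of a
#' haloarchaeon (leaderless : leadered roughly 72 : 28 among protein-coding
#' TSSs; antisense and internal TSSs each comparable in number to the
#' protein-coding set).
#'
#' @param genome_length replicon length in bases, or `NULL` to size the
#'   genome automatically as `max(layout, 10 * total annotated span)`.
#' @param gc_content genomic G+C fraction.
#' @param n_genes named integer vector with elements `leaderless`,
#'   `leadered`, `known_rna`, `intergenic_novel`, `internal`, `antisense`:
#'   number of truth units per class.
#' @param promoter_fraction_stringent fraction of truth TSSs that receive a
#'   planted basal-promoter consensus upstream.
#' @param planted_bre,planted_tata BRE and TATA-box consensus planted for
#'   promoter-positive TSSs (concatenated, BRE immediately 5' of the TATA).
#' @param tata_offset distance (nt) from the TATA-box 3' edge to the TSS.
#' @param tata_jitter maximum uniform jitter (nt) applied to `tata_offset`.
#' @param tex_enrichment ratio of +TEX to -TEX expected read-start rate at
#'   primary 5' ends.
#' @param expression_meanlog,expression_sdlog log-normal parameters of the
#'   per-TSS expected read-start count (the scale matches average 5'-end
#'   coverages of order 100 seen in haloarchaeal dRNA-Seq).
#' @param leaderless_expr_mult expression multiplier for leaderless genes
#'   (highly expressed genes tend to be leaderless).
#' @param gtg_expr_mult expression multiplier for GTG-start leaderless genes.
#' @param start_codon_probs named probabilities for ATG/GTG/TTG gene starts.
#' @param leaderless_ext_probs probabilities of 0..5 extra nucleotides
#'   between a leaderless TSS and the start codon (most start exactly on it).
#' @param utr_mean mean of the (shifted, capped) exponential 5'-UTR length
#'   distribution for leadered genes; lengths lie in 6..250 nt.
#' @param cds_length_range CDS length range in nt (rounded to codons).
#' @param rna_length_range length range for known-RNA features.
#' @param transposase_frac probability that an internal/antisense host
#'   gene is annotated as a transposase (category overlap analyses).
#' @param antisense_rho target Spearman correlation between sense and
#'   antisense expression of a gene (negative: reciprocal expression).
#' @param sense_undetected_frac fraction of antisense units whose host gene
#'   has no detectable sense transcript.
#' @param nb_size negative-binomial size (inverse dispersion) of read-start
#'   counts around their expected rate; counts model residual technical
#'   noise, the biological spread being carried by the log-normal expression
#'   distribution.
#' @param background_rate expected spurious read starts per base per library.
#' @param processed_rate processed (TEX-neutral) 5'-end rate as a fraction
#'   of the parent gene's primary rate.
#' @param depth_sdlog log-normal spread of per-library sequencing depth
#'   (libraries pooled near-equimolar).
#' @param mapped_reads_base nominal mapped-read total per library.
#' @param n_replicates number of replicate library pairs.
#' @param seed master seed; all per-replicate streams derive from it.
#' @return object of class `synth_config` (a validated list).
#' @export
synth_config <- function(genome_length = NULL,
                         gc_content = 0.67,
                         n_genes = c(leaderless = 130, leadered = 52,
                                     known_rna = 11, intergenic_novel = 40,
                                     internal = 115, antisense = 124),
                         promoter_fraction_stringent = 0.34,
                         planted_bre = "CGAAA",
                         planted_tata = "TTAT",
                         tata_offset = 24,
                         tata_jitter = 2,
                         tex_enrichment = 5,
                         expression_meanlog = log(150),
                         expression_sdlog = 0.8,
                         leaderless_expr_mult = 4,
                         gtg_expr_mult = 0.5,
                         start_codon_probs = c(ATG = 0.82, GTG = 0.12, TTG = 0.06),
                         leaderless_ext_probs = c(0.8, 0.04, 0.04, 0.04, 0.04, 0.04),
                         utr_mean = 30,
                         cds_length_range = c(150, 1200),
                         rna_length_range = c(80, 400),
                         transposase_frac = 0.1,
                         antisense_rho = -0.8,
                         sense_undetected_frac = 0.6,
                         nb_size = 100,
                         background_rate = 0.02,
                         processed_rate = 0.5,
                         depth_sdlog = 0.05,
                         mapped_reads_base = 2e6,
                         n_replicates = 3,
                         seed = 1) {
  cfg <- list(
    genome_length = genome_length, gc_content = gc_content,
    n_genes = n_genes,
    promoter_fraction_stringent = promoter_fraction_stringent,
    planted_bre = planted_bre, planted_tata = planted_tata,
    tata_offset = tata_offset, tata_jitter = tata_jitter,
    tex_enrichment = tex_enrichment,
    expression_meanlog = expression_meanlog,
    expression_sdlog = expression_sdlog,
    leaderless_expr_mult = leaderless_expr_mult,
    gtg_expr_mult = gtg_expr_mult,
    start_codon_probs = start_codon_probs,
    leaderless_ext_probs = leaderless_ext_probs,
    utr_mean = utr_mean,
    cds_length_range = cds_length_range,
    rna_length_range = rna_length_range,
    transposase_frac = transposase_frac,
    antisense_rho = antisense_rho,
    sense_undetected_frac = sense_undetected_frac,
    nb_size = nb_size, background_rate = background_rate,
    processed_rate = processed_rate,
    depth_sdlog = depth_sdlog, mapped_reads_base = mapped_reads_base,
    n_replicates = n_replicates, seed = seed
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  fr <- c(cfg$gc_content, cfg$promoter_fraction_stringent,
          cfg$sense_undetected_frac, cfg$transposase_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  need <- c("leaderless", "leadered", "known_rna", "intergenic_novel",
            "internal", "antisense")
  if (!all(need %in% names(cfg$n_genes))) {
    stop("n_genes must name all classes: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(cfg$n_genes < 0)) stop("n_genes must be non-negative", call. = FALSE)
  consensus <- paste0(cfg$planted_bre, cfg$planted_tata)
  if (!grepl("^[ACGT]+$", consensus)) {
    stop("planted consensus must be over {A,C,G,T}", call. = FALSE)
  }
  # the planted element (plus jitter slack) must fit the 28-base promoter
  # window used downstream
  if (nchar(consensus) + 2 * cfg$tata_jitter > 28) {
    stop("planted consensus does not fit inside the 28-base promoter window",
         call. = FALSE)
  }
  if (cfg$tex_enrichment <= 0) stop("tex_enrichment must be > 0", call. = FALSE)
  if (abs(sum(cfg$start_codon_probs) - 1) > 1e-8 ||
      abs(sum(cfg$leaderless_ext_probs) - 1) > 1e-8) {
    stop("codon/extension probabilities must sum to 1", call. = FALSE)
  }
  if (cfg$antisense_rho < -1 || cfg$antisense_rho > 1) {
    stop("antisense_rho must lie in [-1, 1]", call. = FALSE)
  }
  if (cfg$n_replicates < 1) stop("need at least one replicate", call. = FALSE)
  if (cfg$seed %% 1 != 0) stop("seed must be an integer", call. = FALSE)
  invisible(cfg)
}
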