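#' Generate a synthetic genome with a planted primary transcriptome
#'
#' Builds a random GC-rich replicon, plants annotated features (protein-coding
#' genes, known RNAs, a configurable fraction of transposase-category host
#' genes) and a truth set of TSSs of
#' all six classes: leaderless and leadered protein-coding starts, known-RNA
#' starts, intergenic novel TSSs, internal (iTSS) and antisense (aTSS)
#' starts.  A configurable fraction of truth TSSs gets the basal-promoter
#' consensus (BRE then TATA box) planted upstream, with the TATA 3' edge at
#' the configured spacing from the TSS.  Each expressed gene additionally
#' receives one processed (TEX-neutral) 5'-end decoy inside its body.
#'
#' All randomness is governed by `config$seed`; the same config yields a
#' byte-identical genome and truth set.
#'
#' @param config a [synth_config()] object.
#' @return a list of class `synth_genome` with elements `genome` (a
#'   `genome_model`: DNAStringSet plus feature table), `truth` (truth TSS
#'   table), `decoys` (processed 5'-end table) and `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  replicon <- "synth_chr"

  classes <- rep(names(ng), times = ng)
  classes <- sample(classes)          # shuffle unit order along the genome
  n_units <- length(classes)

  # feature widths per unit (0 = no feature, intergenic TSS only)
  rand_cds_len <- function(n) {
    w <- round(runif(n, config$cds_length_range[1], config$cds_length_range[2]))
    pmax(150, 3 * round(w / 3))
  }
  widths <- integer(n_units)
  has_cds <- classes %in% c("leaderless", "leadered", "internal", "antisense")
  widths[has_cds] <- rand_cds_len(sum(has_cds))
  is_rna <- classes == "known_rna"
  widths[is_rna] <- round(runif(sum(is_rna), config$rna_length_range[1],
                                config$rna_length_range[2]))

  span <- sum(widths)
  pad <- 600                           # room for UTRs/promoters + >250 nt gaps
  layout_min <- sum(widths + pad) + 2000
  L <- config$genome_length %||% max(layout_min, ceiling(10 * span))
  if (L < layout_min) {
    stop("annotation does not fit in genome_length (need >= ", layout_min,
         " bases)", call. = FALSE)
  }
  if (L < 10 * span) {
    stop("genome_length must be at least 10x the total annotated span",
         call. = FALSE)
  }
  gap <- floor((L - span - 2000) / (n_units + 1L))

  genome <- random_bases(L, config$gc_content)

  motif <- strsplit(paste0(config$planted_bre, config$planted_tata), "")[[1]]
  k <- length(motif)
  stops <- c("TAA", "TAG", "TGA")
  rho <- config$antisense_rho
  copula_r <- 2 * sin(pi * rho / 6)    # Pearson r giving Spearman rho

  feats <- list(); truth <- list(); decoys <- list()
  new_expr <- function(n = 1) {
    rlnorm(n, config$expression_meanlog, config$expression_sdlog)
  }
  plant_promoter <- function(pos, strand) {
    off <- config$tata_offset +
      sample(seq(-config$tata_jitter, config$tata_jitter), 1)
    if (strand == "+") {
      idx <- (pos - off - k + 1):(pos - off)
      genome[idx] <<- motif
    } else {
      idx <- (pos + off):(pos + off + k - 1)
      genome[idx] <<- revcomp_chars(motif)
    }
    invisible(off)
  }
  stamp_cds <- function(fstart, fend, strand) {
    w <- fend - fstart + 1
    codon <- sample(names(config$start_codon_probs), 1,
                    prob = config$start_codon_probs)
    cds <- c(strsplit(codon, "")[[1]],
             random_bases(w - 6, config$gc_content),
             strsplit(sample(stops, 1), "")[[1]])
    genome[fstart:fend] <<- if (strand == "+") cds else revcomp_chars(cds)
    codon
  }

  cursor <- 1000
  gene_i <- 0; tss_i <- 0
  add_tss <- function(pos, strand, class, expr, gene_id = NA_character_,
                      utr = NA_integer_, codon = NA_character_,
                      companion = FALSE) {
    tss_i <<- tss_i + 1
    planted <- runif(1) < config$promoter_fraction_stringent
    if (planted) plant_promoter(pos, strand)
    truth[[tss_i]] <<- data.frame(
      tss_id = sprintf("TSS%04d", tss_i), replicon = replicon,
      position = as.integer(pos), strand = strand, true_class = class,
      expression_level = expr, has_planted_promoter = planted,
      gene_id = gene_id, utr_length = utr, start_codon = codon,
      companion = companion, stringsAsFactors = FALSE)
    invisible(tss_i)
  }
  add_feature <- function(fstart, fend, strand, category) {
    gene_i <<- gene_i + 1
    id <- sprintf("G%04d", gene_i)
    feats[[gene_i]] <<- data.frame(
      feature_id = id, replicon = replicon, start = as.integer(fstart),
      end = as.integer(fend),
      strand = strand, category = category, stringsAsFactors = FALSE)
    id
  }
  add_decoy <- function(fstart, fend, strand, expr) {
    off <- round(runif(1, 0.3, 0.9) * (fend - fstart))
    decoys[[length(decoys) + 1L]] <<- data.frame(
      replicon = replicon, position = as.integer(fstart + off), strand = strand,
      rate = config$processed_rate * expr, stringsAsFactors = FALSE)
  }

  for (i in seq_len(n_units)) {
    cls <- classes[i]
    w <- widths[i]
    strand <- sample(c("+", "-"), 1)
    fstart <- cursor + gap
    fend <- fstart + max(w, 1) - 1
    cursor <- fend

    if (cls == "intergenic_novel") {
      add_tss(fstart, strand, "intergenic_novel", new_expr())
      next
    }

    five_prime <- if (strand == "+") fstart else fend
    dir_sign <- if (strand == "+") 1L else -1L

    if (cls == "known_rna") {
      id <- add_feature(fstart, fend, strand, "known_rna")
      expr <- new_expr()
      add_tss(five_prime, strand, "known_rna", expr, gene_id = id, utr = 0L)
      add_decoy(fstart, fend, strand, expr)
      next
    }

    codon <- stamp_cds(fstart, fend, strand)
    host_cat <- if (cls %in% c("internal", "antisense") &&
                    runif(1) < config$transposase_frac) "transposase" else "CDS"
    id <- add_feature(fstart, fend, strand, host_cat)

    if (cls == "leaderless") {
      d <- sample(0:5, 1, prob = config$leaderless_ext_probs)
      expr <- new_expr() * config$leaderless_expr_mult
      if (codon == "GTG") expr <- expr * config$gtg_expr_mult
      add_tss(five_prime - dir_sign * d, strand, "leaderless", expr,
              gene_id = id, utr = d, codon = codon)
      add_decoy(fstart, fend, strand, expr)
    } else if (cls == "leadered") {
      u <- min(250L, 6L + as.integer(floor(stats::rexp(1, 1 / config$utr_mean))))
      expr <- new_expr()
      add_tss(five_prime - dir_sign * u, strand, "leadered", expr,
              gene_id = id, utr = u, codon = codon)
      add_decoy(fstart, fend, strand, expr)
    } else if (cls == "internal") {
      off <- round(runif(1, 0.2, 0.9) * (w - 1))
      add_tss(five_prime + dir_sign * off, strand, "internal", new_expr(),
              gene_id = id)
    } else if (cls == "antisense") {
      z <- rnorm(2)
      z2 <- copula_r * z[1] + sqrt(1 - copula_r^2) * z[2]
      a_expr <- qlnorm(pnorm(z[1]), config$expression_meanlog,
                       config$expression_sdlog)
      off <- round(runif(1, 0.2, 0.9) * (w - 1))
      anti_strand <- if (strand == "+") "-" else "+"
      add_tss(fstart + off, anti_strand, "antisense", a_expr, gene_id = id)
      if (runif(1) >= config$sense_undetected_frac) {
        s_expr <- qlnorm(pnorm(z2), config$expression_meanlog,
                         config$expression_sdlog) * config$leaderless_expr_mult
        if (codon == "GTG") s_expr <- s_expr * config$gtg_expr_mult
        d <- sample(0:5, 1, prob = config$leaderless_ext_probs)
        add_tss(five_prime - dir_sign * d, strand, "leaderless", s_expr,
                gene_id = id, utr = d, codon = codon, companion = TRUE)
        add_decoy(fstart, fend, strand, s_expr)
      }
    }
  }

  features <- do.call(rbind, feats)
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$position), , drop = FALSE]
  rownames(truth) <- NULL
  decoys <- if (length(decoys)) do.call(rbind, decoys) else
    data.frame(replicon = character(), position = integer(),
               strand = character(), rate = numeric())
  rownames(decoys) <- NULL

  seq <- Biostrings::DNAStringSet(paste(genome, collapse = ""))
  names(seq) <- replicon
  gm <- genome_model(seq, features)
  structure(list(genome = gm, truth = truth, decoys = decoys, config = config),
            class = "synth_genome")
}

#' Genome model: sequence plus annotated features
#'
#' Lightweight container pairing a replicon sequence set with a feature
#' table.  Features carry 1-based inclusive GFF3-style coordinates and a
#' `category` attribute (`CDS`, `known_rna` or `transposase`).
#'
#' @param seq named [Biostrings::DNAStringSet].
#' @param features data.frame with columns `feature_id`, `replicon`,
#'   `start`, `end`, `strand`, `category`.
#' @return object of class `genome_model`.
#' @export
genome_model <- function(seq, features) {
  stopifnot(methods::is(seq, "DNAStringSet"), !is.null(names(seq)))
  need <- c("feature_id", "replicon", "start", "end", "strand", "category")
  if (!all(need %in% names(features))) {
    stop("features must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  stopifnot_strand(features$strand)
  if (!all(features$replicon %in% names(seq))) {
    stop("feature replicon not present in sequence set", call. = FALSE)
  }
  structure(list(seq = seq, features = features), class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$seq), "replicon(s),",
      sum(Biostrings::width(x$seq)), "bases,",
      nrow(x$features), "features\n")
  invisible(x)
}

#' Genome length of a replicon
#' @param gm a `genome_model`
#' @param replicon replicon name (default: first)
#' @return integer length
#' @export
replicon_length <- function(gm, replicon = names(gm$seq)[1]) {
  unname(Biostrings::width(gm$seq)[match(replicon, names(gm$seq))])
}

#' G+C fraction of a genome
#' @param gm a `genome_model`
#' @return fraction of G+C over all replicons
#' @export
gc_fraction <- function(gm) {
  f <- Biostrings::alphabetFrequency(gm$seq, baseOnly = TRUE)
  tot <- sum(f[, c("A", "C", "G", "T")])
  sum(f[, c("G", "C")]) / tot
}
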