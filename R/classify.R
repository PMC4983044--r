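PROTEIN_CATEGORIES <- c("CDS", "transposase")
TSS_CLASSES <- c("leaderless", "leadered", "known_rna", "intergenic_novel",
                 "internal", "antisense")

# distance from a TSS to a feature 5' start, measured in transcription
# direction of the feature: positive = gene start downstream of the TSS
tss_gene_distance <- function(pos, f_start, f_end, f_strand) {
  ifelse(f_strand == "+", f_start - pos, pos - f_end)
}

#' Classify TSSs against a genome annotation
#'
#' Each TSS gets exactly one primary class by precedence: (1) a same-strand
#' protein-coding gene start 0-5 nt downstream makes it `leaderless` (sense
#' association wins even inside another gene, as for overlapping gene
#' pairs); (2) a same-strand known-RNA 5' end between -3 (retraction by 3)
#' and +250 nt, `known_rna`; (3) a TSS lying within an annotated gene is
#' `internal` (same strand) or `antisense` (opposite strand), same-strand
#' overlap preferred -- internal and antisense TSSs may therefore have
#' further gene starts 1-250 nt downstream, which [flag_downstream_gene()]
#' reports; (4) a same-strand protein-coding gene start 6-250 nt
#' downstream, `leadered`; (5) all remaining TSSs are `intergenic_novel`.
#' Within a rule the nearest eligible gene wins.  Distances are measured in
#' transcription direction on 1-based inclusive coordinates; d = 0 puts the
#' TSS on the start-codon first base.
#'
#' @param tss TSS record data.frame (needs `replicon`, `position`,
#'   `strand`; other columns are carried through).
#' @param genome a `genome_model`.
#' @param max_utr largest 5'-UTR length considered gene-associated (nt).
#' @param leaderless_max largest leaderless extension (nt).
#' @param rna_retraction allowed upstream retraction for known-RNA starts.
#' @return the input with columns `primary_class`, `associated_gene` and
#'   `utr_length` appended.
#' @export
classify_tss <- function(tss, genome, max_utr = 250, leaderless_max = 5,
                         rna_retraction = 3) {
  feats <- genome$features
  n <- nrow(tss)
  cls <- character(n); gene <- rep(NA_character_, n)
  utr <- rep(NA_integer_, n)
  if (any(tss$position < 1) ||
      any(tss$position > vapply(tss$replicon, function(r)
        replicon_length(genome, r), numeric(1)))) {
    stop("TSS outside replicon", call. = FALSE)
  }

  for (i in seq_len(n)) {
    pos <- tss$position[i]; s <- tss$strand[i]; repl <- tss$replicon[i]
    f <- feats[feats$replicon == repl, , drop = FALSE]
    same <- f$strand == s

    pc <- same & f$category %in% PROTEIN_CATEGORIES
    d_pc <- tss_gene_distance(pos, f$start, f$end, f$strand)
    hit <- pc & d_pc >= 0 & d_pc <= leaderless_max
    if (any(hit)) {
      j <- which(hit)[which.min(d_pc[hit])]
      cls[i] <- "leaderless"; gene[i] <- f$feature_id[j]
      utr[i] <- d_pc[j]
      next
    }
    rna <- same & f$category == "known_rna"
    hit <- rna & d_pc >= -rna_retraction & d_pc <= max_utr
    if (any(hit)) {
      j <- which(hit)[which.min(abs(d_pc[hit]))]
      cls[i] <- "known_rna"; gene[i] <- f$feature_id[j]
      next
    }
    inside <- f$start <= pos & f$end >= pos
    if (any(inside & same)) {
      j <- which(inside & same)
      j <- j[which.max(f$start[j])]     # innermost same-strand gene
      cls[i] <- "internal"; gene[i] <- f$feature_id[j]
      next
    }
    if (any(inside)) {
      j <- which(inside)
      j <- j[which.max(f$start[j])]
      cls[i] <- "antisense"; gene[i] <- f$feature_id[j]
      next
    }
    hit <- pc & d_pc > leaderless_max & d_pc <= max_utr
    if (any(hit)) {
      j <- which(hit)[which.min(d_pc[hit])]
      cls[i] <- "leadered"; gene[i] <- f$feature_id[j]
      utr[i] <- d_pc[j]
      next
    }
    cls[i] <- "intergenic_novel"
  }
  tss$primary_class <- cls
  tss$associated_gene <- gene
  tss$utr_length <- utr
  tss
}

#' Genes associated with more than one TSS
#'
#' Groups leaderless/leadered TSSs by their associated protein-coding gene
#' and reports genes with two or more TSSs together with the class
#' combination (e.g. `"leaderless+leadered"`, `"2xleadered"`).
#'
#' @param classified output of [classify_tss()].
#' @return data.frame with `gene`, `n_tss`, `combination`, `utr_lengths`.
#' @export
find_multi_tss <- function(classified) {
  pc <- classified[classified$primary_class %in% c("leaderless", "leadered"), ,
                   drop = FALSE]
  if (nrow(pc) == 0) {
    return(data.frame(gene = character(), n_tss = integer(),
                      combination = character(), utr_lengths = character(),
                      stringsAsFactors = FALSE))
  }
  by_gene <- split(pc, pc$associated_gene)
  by_gene <- by_gene[vapply(by_gene, nrow, integer(1)) >= 2]
  if (!length(by_gene)) {
    return(data.frame(gene = character(), n_tss = integer(),
                      combination = character(), utr_lengths = character(),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(names(by_gene), function(g) {
    x <- by_gene[[g]]
    tab <- table(factor(x$primary_class, levels = c("leaderless", "leadered")))
    tab <- tab[tab > 0]
    parts <- ifelse(tab == 1, names(tab), paste0(tab, "x", names(tab)))
    data.frame(gene = g, n_tss = nrow(x),
               combination = paste(parts, collapse = "+"),
               utr_lengths = paste(sort(x$utr_length), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$gene), , drop = FALSE]
}

#' Flag an internal/antisense TSS with a downstream gene
#'
#' An iTSS or aTSS is flagged when the nearest annotated gene start on the
#' TSS strand lies 1-250 nt downstream; such TSSs likely drive the
#' downstream gene (sub-operonic promoters, or promoters just upstream of
#' the sense gene for aTSSs).
#'
#' @param tss one row of a classified TSS table (class `internal` or
#'   `antisense`).
#' @param genome a `genome_model`.
#' @param max_dist largest qualifying distance (nt).
#' @return list with `flagged`, `gene`, `distance`.
#' @export
flag_downstream_gene <- function(tss, genome, max_dist = 250) {
  if (!tss$primary_class %in% c("internal", "antisense")) {
    stop("flag_downstream_gene: class must be internal or antisense",
         call. = FALSE)
  }
  f <- genome$features
  f <- f[f$replicon == tss$replicon & f$strand == tss$strand, , drop = FALSE]
  d <- tss_gene_distance(tss$position, f$start, f$end, f$strand)
  hit <- d >= 1 & d <= max_dist
  if (!any(hit)) return(list(flagged = FALSE, gene = NA_character_,
                             distance = NA_integer_))
  j <- which(hit)[which.min(d[hit])]
  list(flagged = TRUE, gene = f$feature_id[j], distance = d[j])
}

#' Add downstream-gene flags for all internal/antisense TSSs
#'
#' @param classified output of [classify_tss()].
#' @param genome a `genome_model`.
#' @param max_dist see [flag_downstream_gene()].
#' @return `classified` with `downstream_gene` and `downstream_distance`
#'   columns.
#' @export
add_downstream_flags <- function(classified, genome, max_dist = 250) {
  classified$downstream_gene <- NA_character_
  classified$downstream_distance <- NA_integer_
  idx <- which(classified$primary_class %in% c("internal", "antisense"))
  for (i in idx) {
    fl <- flag_downstream_gene(classified[i, , drop = FALSE], genome, max_dist)
    if (fl$flagged) {
      classified$downstream_gene[i] <- fl$gene
      classified$downstream_distance[i] <- fl$distance
    }
  }
  classified
}

#' Intragenic decile distribution of internal or antisense TSSs
#'
#' Each overlapped gene is divided into 10 equal sections along its own
#' 5'->3' direction; the section of each TSS is
#' `floor(10 * offset / length) + 1`, clamped to 10.  Counts over sections
#' sum to the number of TSSs considered.
#'
#' @param classified output of [classify_tss()].
#' @param genome a `genome_model`.
#' @param which `"internal"` or `"antisense"`.
#' @return integer vector of length 10 (named "1".."10").
#' @export
decile_distribution <- function(classified, genome,
                                which = c("internal", "antisense")) {
  which <- match.arg(which)
  sub <- classified[classified$primary_class == which, , drop = FALSE]
  counts <- setNames(integer(10), as.character(1:10))
  if (nrow(sub) == 0) return(counts)
  f <- genome$features
  j <- match(sub$associated_gene, f$feature_id)
  stopifnot(!anyNA(j))
  len <- f$end[j] - f$start[j] + 1
  off <- ifelse(f$strand[j] == "+", sub$position - f$start[j],
                f$end[j] - sub$position)
  stopifnot(all(off >= 0), all(off < len))
  sec <- pmin(floor(10 * off / len) + 1, 10)
  tab <- table(factor(sec, levels = 1:10))
  counts[] <- as.integer(tab)
  counts
}
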