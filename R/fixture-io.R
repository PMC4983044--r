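#' Write a synthetic fixture to disk
#'
#' Writes the genome (FASTA), annotation (GFF3 with a `category` attribute),
#' one wiggle file per library/strand/replicate (variableStep, raw counts),
#' the per-library mapped-read totals (TSV) and the truth/decoy tables
#' (TSV).  [read_fixture()] reconstructs the in-memory objects.
#'
#' @param sim a `synth_genome` from [generate_genome()].
#' @param coverage per-replicate coverage list from [simulate_all_coverage()].
#' @param outdir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_fixture <- function(sim, coverage, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  add <- function(f) files <<- c(files, f)

  fa <- file.path(outdir, "genome.fasta")
  Biostrings::writeXStringSet(sim$genome$seq, fa)
  add(fa)

  gff <- file.path(outdir, "annotation.gff3")
  write_annotation_gff3(sim$genome$features, gff)
  add(gff)

  mr <- list()
  for (r in seq_along(coverage)) {
    for (lib in names(coverage[[r]])) {
      for (s in names(coverage[[r]][[lib]])) {
        tr <- coverage[[r]][[lib]][[s]]
        wf <- file.path(outdir, sprintf("rep%d_%s_%s.wig", r, lib, s))
        write_wiggle(tr, wf)
        add(wf)
      }
      mr[[length(mr) + 1L]] <- data.frame(
        replicate = r, library = lib,
        mapped_reads = coverage[[r]][[lib]]$fwd$mapped_reads)
    }
  }
  mrf <- file.path(outdir, "mapped_reads.tsv")
  write_tsv(do.call(rbind, mr), mrf); add(mrf)

  tf <- file.path(outdir, "truth.tsv")
  write_tsv(sim$truth, tf); add(tf)
  df <- file.path(outdir, "decoys.tsv")
  write_tsv(sim$decoys, df); add(df)
  invisible(files)
}

#' Read a fixture directory back into memory
#'
#' @param outdir directory written by [write_fixture()].
#' @return list with `genome` (a `genome_model`), `truth`, `decoys` and
#'   `coverage` (nested per-replicate track list, raw counts).
#' @export
read_fixture <- function(outdir) {
  seq <- Biostrings::readDNAStringSet(file.path(outdir, "genome.fasta"))
  names(seq) <- sub("\\s.*$", "", names(seq))
  features <- read_annotation_gff3(file.path(outdir, "annotation.gff3"))
  gm <- genome_model(seq, features)
  L <- replicon_length(gm)

  mapped <- read_tsv(file.path(outdir, "mapped_reads.tsv"))
  reps <- sort(unique(mapped$replicate))
  coverage <- lapply(reps, function(r) {
    out <- list()
    for (lib in c("minus_tex", "plus_tex")) {
      m <- mapped$mapped_reads[mapped$replicate == r & mapped$library == lib]
      out[[lib]] <- list(
        fwd = read_wiggle(file.path(outdir, sprintf("rep%d_%s_fwd.wig", r, lib)),
                          L, "+", lib, r, m),
        rev = read_wiggle(file.path(outdir, sprintf("rep%d_%s_rev.wig", r, lib)),
                          L, "-", lib, r, m))
    }
    out
  })
  truth <- read_tsv(file.path(outdir, "truth.tsv"))
  decoys <- read_tsv(file.path(outdir, "decoys.tsv"))
  list(genome = gm, truth = truth, decoys = decoys, coverage = coverage)
}

#' Write a coverage track as a variableStep wiggle file
#'
#' Only non-zero positions are written; values are non-negative.  An
#' all-zero track is written as a single zero entry so the file stays a
#' valid wiggle.
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @export
write_wiggle <- function(track, path) {
  pos <- which(track$values != 0)
  if (length(pos) == 0) pos <- 1L
  gr <- GenomicRanges::GRanges(track$replicon,
                               IRanges::IRanges(pos, width = 1),
                               score = track$values[pos])
  rtracklayer::export.wig(gr, path)
  invisible(path)
}

#' Read a wiggle file into a dense coverage track
#'
#' @param path wiggle file.
#' @param length replicon length (bases).
#' @param strand,library,replicate,mapped_reads track metadata (wiggle does
#'   not encode them; the fixture encodes strand and library in the file
#'   name and depth in `mapped_reads.tsv`).
#' @return a [coverage_track()].
#' @export
read_wiggle <- function(path, length, strand, library, replicate,
                        mapped_reads) {
  if (!file.exists(path)) {
    stop("coverage file not found: ", path, call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "wig")
  v <- numeric(length)
  repl <- "synth_chr"
  if (base::length(gr)) {
    v[GenomicRanges::start(gr)] <- S4Vectors::mcols(gr)$score
    repl <- as.character(GenomicRanges::seqnames(gr))[1]
  }
  coverage_track(v, strand, library, replicate, mapped_reads,
                 replicon = repl)
}

#' Write an annotation table as GFF3
#'
#' @param features feature data.frame (`feature_id`, `replicon`, `start`,
#'   `end`, `strand`, `category`).
#' @param path output path.
#' @export
write_annotation_gff3 <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    features$replicon,
    IRanges::IRanges(features$start, features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- features$feature_id
  S4Vectors::mcols(gr)$category <- features$category
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read a GFF3 annotation into a feature table
#'
#' Features must carry `ID` and `category` attributes; `category`
#' distinguishes protein-coding genes (`CDS`), stable RNAs/sRNAs
#' (`known_rna`) and transposase genes (`transposase`).
#'
#' @param path GFF3 file.
#' @return feature data.frame.
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  data.frame(
    feature_id = as.character(mc$ID),
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    category = as.character(mc$category),
    stringsAsFactors = FALSE)
}

#' Write/read a plain tab-separated table
#'
#' Thin wrappers used for all tabular outputs (no quoting, no row names).
#'
#' @param df data.frame to write.
#' @param path file path.
#' @return the path ([write_tsv()]) or a data.frame ([read_tsv()]).
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
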