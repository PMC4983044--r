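#' Coverage track of 5'-end read starts
#'
#' One strand of one library: per-base counts of reads whose 5' end maps at
#' each position.  This is the quantity TSS calling operates on (not full
#' read-body coverage).
#'
#' @param values non-negative numeric vector, one entry per base.
#' @param strand `"+"` or `"-"`.
#' @param library `"minus_tex"` or `"plus_tex"`.
#' @param replicate replicate index (1-based).
#' @param mapped_reads total aligned reads of the library (both strands).
#' @param replicon replicon identifier.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(values, strand, library, replicate, mapped_reads,
                           replicon = "synth_chr") {
  stopifnot_strand(strand)
  if (any(values < 0)) stop("coverage values must be >= 0", call. = FALSE)
  if (!library %in% c("minus_tex", "plus_tex")) {
    stop("library must be 'minus_tex' or 'plus_tex'", call. = FALSE)
  }
  structure(list(replicon = replicon, strand = strand,
                 values = as.numeric(values), library = library,
                 replicate = as.integer(replicate),
                 mapped_reads = mapped_reads),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track %s(%s) rep%d: %d bases, %d read starts, %g mapped\n",
              x$library, x$strand, x$replicate, length(x$values),
              round(sum(x$values)), x$mapped_reads))
  invisible(x)
}

#' Normalize coverage tracks to the shallowest library
#'
#' Scales every track by `min(mapped_reads) / mapped_reads(track)`, so all
#' libraries are expressed on the depth scale of the least-deep one.  The
#' minimum-depth library is unchanged and within-library value ratios are
#' preserved.
#'
#' @param tracks list of [coverage_track()] objects (all libraries, both
#'   strands).
#' @return list of tracks with scaled values; each carries a `norm_factor`
#'   attribute.
#' @export
normalize_coverage <- function(tracks) {
  stopifnot(length(tracks) > 0)
  mapped <- vapply(tracks, function(t) t$mapped_reads, numeric(1))
  if (any(mapped <= 0)) {
    stop("normalization error: library with zero mapped reads", call. = FALSE)
  }
  m <- min(mapped)
  lapply(tracks, function(t) {
    f <- m / t$mapped_reads
    t$values <- t$values * f
    t$norm_factor <- f
    t
  })
}

#' Flatten nested per-replicate coverage into a list of tracks
#'
#' @param coverage list (one element per replicate) of
#'   `list(minus_tex = list(fwd, rev), plus_tex = list(fwd, rev))`.
#' @return flat list of `coverage_track` objects.
#' @export
flatten_coverage <- function(coverage) {
  out <- list()
  for (rep_cov in coverage) {
    for (lib in names(rep_cov)) {
      for (s in names(rep_cov[[lib]])) {
        out[[length(out) + 1L]] <- rep_cov[[lib]][[s]]
      }
    }
  }
  out
}

#' Simulate plus/minus-TEX 5'-end coverage for one replicate
#'
#' Read-start counts at every truth TSS are drawn from a negative binomial
#' around the TSS's expected rate; the +TEX library rate is
#' `tex_enrichment`-fold the -TEX rate (primary 5' ends survive the
#' exonuclease).  Processed 5'-end decoys get equal rates in both libraries.
#' Every base additionally receives Poisson background read starts.
#' Per-library sequencing depth varies log-normally around the nominal
#' depth; raw counts scale with depth and `mapped_reads` records it.
#'
#' The replicate stream is derived deterministically from the master seed.
#'
#' @param genome a `genome_model` (defines replicon length).
#' @param truth truth TSS table from [generate_genome()].
#' @param config the [synth_config()] used.
#' @param replicate replicate index (1-based).
#' @param decoys processed 5'-end table (optional).
#' @return `list(minus_tex = list(fwd, rev), plus_tex = list(fwd, rev))` of
#'   [coverage_track()] objects.
#' @export
simulate_coverage <- function(genome, truth, config, replicate, decoys = NULL) {
  L <- replicon_length(genome)
  if (any(truth$position < 1 | truth$position > L)) {
    stop("truth TSS outside genome", call. = FALSE)
  }
  set.seed(config$seed + 7919L * as.integer(replicate))
  depth <- c(minus_tex = rlnorm(1, 0, config$depth_sdlog),
             plus_tex = rlnorm(1, 0, config$depth_sdlog))
  mapped <- round(config$mapped_reads_base * depth)

  mk_values <- function(lib, strand) {
    rate_mult <- if (lib == "plus_tex") config$tex_enrichment else 1
    v <- as.numeric(rpois(L, config$background_rate * depth[[lib]]))
    sel <- truth$strand == strand
    if (any(sel)) {
      mu <- truth$expression_level[sel] * rate_mult * depth[[lib]]
      v[truth$position[sel]] <- v[truth$position[sel]] +
        rnbinom(sum(sel), mu = mu, size = config$nb_size)
    }
    if (!is.null(decoys) && nrow(decoys)) {
      dsel <- decoys$strand == strand
      if (any(dsel)) {
        mu <- decoys$rate[dsel] * depth[[lib]]   # TEX-neutral: same both libs
        v[decoys$position[dsel]] <- v[decoys$position[dsel]] +
          rnbinom(sum(dsel), mu = mu, size = config$nb_size)
      }
    }
    v
  }

  out <- list()
  for (lib in c("minus_tex", "plus_tex")) {
    out[[lib]] <- list(
      fwd = coverage_track(mk_values(lib, "+"), "+", lib, replicate,
                           mapped[[lib]]),
      rev = coverage_track(mk_values(lib, "-"), "-", lib, replicate,
                           mapped[[lib]])
    )
  }
  out
}

#' Simulate coverage for all replicates
#'
#' @param sim a `synth_genome` object.
#' @return list with one [simulate_coverage()] result per replicate.
#' @export
simulate_all_coverage <- function(sim) {
  lapply(seq_len(sim$config$n_replicates), function(r) {
    simulate_coverage(sim$genome, sim$truth, sim$config, r, sim$decoys)
  })
}
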