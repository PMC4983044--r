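#' Call TSS candidates from a +/-TEX track pair
#'
#' A position is a candidate when, on normalized tracks, (a) the +TEX
#' 5'-end height reaches `min_height`, (b) the height steps up at least
#' `step_factor`-fold relative to the previous position in transcription
#' direction, and (c) the TEX enrichment factor
#' `plus / (minus + pseudocount)` reaches `min_enrichment` (inclusive).
#' Condition (c) is what distinguishes a primary 5' end (5'-PPP, spared by
#' the exonuclease) from a processed one.
#'
#' @param minus,plus -TEX and +TEX [coverage_track()]s of the same replicon
#'   and strand, already normalized (see [normalize_coverage()]).
#' @param min_height minimum normalized +TEX height.
#' @param step_factor minimum fold step over the upstream neighbour.
#' @param min_enrichment minimum +TEX/-TEX enrichment factor.
#' @param pseudocount added to the -TEX height before the ratio, so
#'   enrichment is defined when the -TEX library has no reads.
#' @param keep_unenriched if `TRUE`, positions passing (a) and (b) but not
#'   (c) are returned too, flagged `enriched = FALSE`.
#' @return data.frame of candidates in coordinate order: `replicon`,
#'   `position`, `strand`, `plus_tex_height`, `minus_tex_height`,
#'   `enrichment_factor`, `enriched`, `replicate`.
#' @export
call_tss <- function(minus, plus, min_height = 5, step_factor = 2,
                     min_enrichment = 2.5, pseudocount = 1,
                     keep_unenriched = FALSE) {
  stopifnot(inherits(minus, "coverage_track"), inherits(plus, "coverage_track"))
  if (length(minus$values) != length(plus$values)) {
    stop("mismatched track lengths", call. = FALSE)
  }
  if (minus$strand != plus$strand || minus$replicon != plus$replicon) {
    stop("tracks must share replicon and strand", call. = FALSE)
  }
  p <- plus$values
  m <- minus$values
  L <- length(p)
  # replicon edge has no upstream context: not callable
  prev <- if (plus$strand == "+") c(Inf, p[-L]) else c(p[-1], Inf)
  detected <- p >= min_height & p >= step_factor * prev
  enr <- p / (m + pseudocount)
  keep <- detected & (if (keep_unenriched) TRUE else enr >= min_enrichment)
  idx <- which(keep)
  data.frame(
    replicon = rep(plus$replicon, length(idx)), position = idx,
    strand = rep(plus$strand, length(idx)),
    plus_tex_height = p[idx], minus_tex_height = m[idx],
    enrichment_factor = enr[idx],
    enriched = enr[idx] >= min_enrichment,
    replicate = rep(plus$replicate, length(idx)),
    stringsAsFactors = FALSE)
}

# single-linkage clustering of sorted positions: successive gaps < max_gap
# join a cluster
cluster_positions <- function(pos, max_gap = 10) {
  if (length(pos) == 0) return(integer(0))
  o <- order(pos)
  d <- diff(pos[o])
  cl <- cumsum(c(1L, as.integer(d >= max_gap)))
  cl[order(o)]
}

# representative row index: highest +TEX height, ties broken by the most
# upstream position in transcription direction
representative_idx <- function(height, position, strand) {
  best <- which(height == max(height))
  if (length(best) > 1) {
    best <- if (strand == "+") best[which.min(position[best])] else
      best[which.max(position[best])]
  }
  best
}

#' Merge closely spaced TSS candidates
#'
#' Same-strand candidates closer than `max_gap` nt (single linkage over
#' successive gaps) are considered one TSS, represented by the member with
#' the highest +TEX height (ties: most upstream in transcription
#' direction).  Idempotent: merging a merged set changes nothing.
#'
#' @param candidates candidate data.frame from [call_tss()] (one strand and
#'   replicon).
#' @param max_gap positions with gaps strictly below this merge.
#' @return merged candidate data.frame in coordinate order.
#' @export
merge_close <- function(candidates, max_gap = 10) {
  if (nrow(candidates) == 0) return(candidates)
  stopifnot(length(unique(candidates$strand)) == 1,
            length(unique(candidates$replicon)) == 1)
  cl <- cluster_positions(candidates$position, max_gap)
  keep <- vapply(split(seq_len(nrow(candidates)), cl), function(i) {
    i[representative_idx(candidates$plus_tex_height[i],
                         candidates$position[i],
                         candidates$strand[i[1]])]
  }, integer(1))
  out <- candidates[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the replicate-consensus TSS set
#'
#' Candidates from different replicates within `max_gap` nt on the same
#' strand are treated as the same TSS; its position is taken from the
#' replicate with the highest +TEX height.  Records how many and which
#' replicates detected (and TEX-enriched) each TSS, and the mean +TEX
#' height over detecting replicates (`average_coverage`).
#'
#' @param per_replicate list of merged candidate data.frames, one per
#'   replicate (see [merge_close()]).
#' @param max_gap cross-replicate identity tolerance (same rule as within
#'   replicates).
#' @return data.frame of TSS records: `replicon`, `position`, `strand`,
#'   `support`, `n_enriched`, `detected_in`, `enriched_in`,
#'   `average_coverage`, sorted by position.
#' @export
replicate_consensus <- function(per_replicate, max_gap = 10) {
  pooled <- do.call(rbind, per_replicate)
  if (is.null(pooled) || nrow(pooled) == 0) {
    return(data.frame(replicon = character(), position = integer(),
                      strand = character(), support = integer(),
                      n_enriched = integer(), detected_in = character(),
                      enriched_in = character(), average_coverage = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- list()
  for (repl in unique(pooled$replicon)) {
    for (s in c("+", "-")) {
      sub <- pooled[pooled$replicon == repl & pooled$strand == s, , drop = FALSE]
      if (nrow(sub) == 0) next
      cl <- cluster_positions(sub$position, max_gap)
      for (i in split(seq_len(nrow(sub)), cl)) {
        rep_best <- representative_idx(sub$plus_tex_height[i],
                                       sub$position[i], s)
        reps <- sort(unique(sub$replicate[i]))
        enr_reps <- sort(unique(sub$replicate[i][sub$enriched[i]]))
        # per-replicate height = that replicate's strongest member
        h <- vapply(reps, function(r) {
          max(sub$plus_tex_height[i][sub$replicate[i] == r])
        }, numeric(1))
        out[[length(out) + 1L]] <- data.frame(
          replicon = repl, position = sub$position[i][rep_best], strand = s,
          support = length(reps), n_enriched = length(enr_reps),
          detected_in = paste(reps, collapse = ","),
          enriched_in = paste(enr_reps, collapse = ","),
          average_coverage = mean(h), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$replicon, res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Run TSS calling end to end for one fixture
#'
#' Normalizes all tracks to the shallowest library, calls candidates per
#' replicate and strand, merges closely spaced candidates within each
#' replicate, and forms the replicate consensus.
#'
#' @param coverage nested per-replicate coverage list (raw counts).
#' @param ... passed to [call_tss()].
#' @param max_gap merge distance, see [merge_close()].
#' @return consensus TSS data.frame (see [replicate_consensus()]).
#' @export
call_tss_consensus <- function(coverage, ..., max_gap = 10) {
  flat <- normalize_coverage(flatten_coverage(coverage))
  key <- vapply(flat, function(t) {
    paste(t$replicate, t$library, t$strand, sep = ".")
  }, character(1))
  names(flat) <- key
  reps <- sort(unique(vapply(flat, function(t) t$replicate, integer(1))))
  per_rep <- lapply(reps, function(r) {
    cands <- lapply(c("+", "-"), function(s) {
      minus <- flat[[paste(r, "minus_tex", s, sep = ".")]]
      plus <- flat[[paste(r, "plus_tex", s, sep = ".")]]
      merge_close(call_tss(minus, plus, ...), max_gap)
    })
    do.call(rbind, cands)
  })
  replicate_consensus(per_rep, max_gap)
}
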