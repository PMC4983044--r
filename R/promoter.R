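#' Extract the 71-base upstream sequence of each TSS
#'
#' The 71-mer lies on the TSS strand with its last base equal to the first
#' transcribed base: plus strand, `genome[pos-70 .. pos]`; minus strand,
#' the reverse complement of `genome[pos .. pos+70]`.  TSSs closer than 70
#' bases to the replicon edge, and sequences containing non-ACGT
#' characters, are skipped (counted in the `n_skipped` attribute, with a
#' warning).
#'
#' @param genome a `genome_model`.
#' @param tss classified or raw TSS data.frame (`replicon`, `position`,
#'   `strand`; `tss_id` carried if present).
#' @param width upstream window length.
#' @return data.frame with `tss_id`, `replicon`, `position`, `strand`,
#'   `seq`; attribute `n_skipped`.
#' @export
extract_upstream <- function(genome, tss, width = 71) {
  n <- nrow(tss)
  ids <- if ("tss_id" %in% names(tss)) tss$tss_id else
    sprintf("TSS%04d", seq_len(n))
  seqs <- rep(NA_character_, n)
  for (repl in unique(tss$replicon)) {
    x <- genome$seq[[repl]]
    L <- length(x)
    sel <- which(tss$replicon == repl)
    pos <- tss$position[sel]; s <- tss$strand[sel]
    ok_plus <- s == "+" & pos >= width
    ok_minus <- s == "-" & pos + width - 1 <= L
    ip <- sel[ok_plus]; im <- sel[ok_minus]
    if (length(ip)) {
      v <- Biostrings::Views(x, start = tss$position[ip] - width + 1,
                             end = tss$position[ip])
      seqs[ip] <- as.character(v)
    }
    if (length(im)) {
      v <- Biostrings::Views(x, start = tss$position[im],
                             end = tss$position[im] + width - 1)
      seqs[im] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(v)))
    }
  }
  bad <- is.na(seqs) | grepl("[^ACGT]", seqs)
  if (any(bad)) {
    warning(sum(bad), " TSS(s) skipped (contig edge or ambiguous bases)")
  }
  out <- data.frame(tss_id = ids[!bad], replicon = tss$replicon[!bad],
                    position = tss$position[!bad], strand = tss$strand[!bad],
                    seq = seqs[!bad], stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Strand-symmetric genomic background base composition
#'
#' Counts bases over all replicons on both strands (forward plus reverse
#' complement), so `q["A"] == q["T"]` and `q["C"] == q["G"]` and the
#' composition sums to one.
#'
#' @param genome a `genome_model`.
#' @return named numeric vector `q` over A, C, G, T.
#' @export
genome_background <- function(genome) {
  f <- Biostrings::alphabetFrequency(genome$seq, baseOnly = TRUE)
  f <- colSums(f[, c("A", "C", "G", "T"), drop = FALSE])
  if (sum(f) == 0) stop("empty genome", call. = FALSE)
  sym <- c(A = f[["A"]] + f[["T"]], C = f[["C"]] + f[["G"]],
           G = f[["G"]] + f[["C"]], T = f[["T"]] + f[["A"]])
  sym / sum(f) / 2
}

#' Build a position weight matrix from aligned windows
#'
#' Counts are tallied per column, converted to pseudocount-smoothed
#' frequencies `f = (count + pseudocount) / (n + 4 * pseudocount)` and to
#' log-odds `log2(f / q)` against the genomic background.
#'
#' @param windows character vector of equal-length windows (ACGT only).
#' @param q background composition from [genome_background()].
#' @param pseudocount added per base per column.
#' @return object of class `pwm`: `width`, `n`, `counts`, `freq`,
#'   `log_odds` (4 x width matrices, rows A/C/G/T), `q`, `pseudocount`.
#' @export
build_pwm <- function(windows, q, pseudocount = 0.5) {
  if (length(windows) < 2) stop("need at least 2 windows", call. = FALSE)
  W <- nchar(windows[1])
  if (any(nchar(windows) != W)) stop("length mismatch", call. = FALSE)
  m <- matrix(unlist(strsplit(windows, "")), nrow = length(windows),
              byrow = TRUE)
  counts <- vapply(seq_len(W), function(j) {
    tabulate(match(m[, j], BASES), 4)
  }, integer(4))
  rownames(counts) <- BASES
  n <- length(windows)
  freq <- (counts + pseudocount) / (n + 4 * pseudocount)
  if (any(q <= 0)) stop("degenerate background composition", call. = FALSE)
  log_odds <- log2(sweep(freq, 1, as.numeric(q[BASES]), `/`))
  structure(list(width = W, n = n, counts = counts, freq = freq,
                 log_odds = log_odds, q = q[BASES],
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm: width %d from %d windows; consensus %s\n",
              x$width, x$n, pwm_consensus(x)))
  invisible(x)
}

#' Majority consensus string of a PWM
#' @param pwm a [build_pwm()] object.
#' @return character string of per-column argmax bases.
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$log_odds, 2, which.max)], collapse = "")
}

#' Score threshold for a PWM match p-value
#'
#' Computes the exact distribution of the PWM score of a random
#' background-composition window by dynamic programming over columns, with
#' scores discretized downwards to `granularity`, and returns the upper
#' p-quantile: the largest discretized score `t` whose tail probability
#' `P(score >= t)` under the background is still at least `p`.  A match at
#' or above the returned threshold therefore has a background tail
#' probability of at most `p` up to the last distribution atom at `t`.
#'
#' @param pwm a [build_pwm()] object.
#' @param p tail probability in (0, 1).
#' @param granularity score discretization step.
#' @return numeric threshold (on the log-odds score scale), with
#'   attributes `tail_prob` (achieved tail probability) and `granularity`.
#' @export
pwm_pvalue_threshold <- function(pwm, p, granularity = 0.001) {
  stopifnot(p > 0, p < 1)
  q <- pwm$q
  if (any(q <= 0)) stop("degenerate background composition", call. = FALSE)
  s_int <- floor(pwm$log_odds / granularity)
  v <- 1; off <- 0
  for (j in seq_len(pwm$width)) {
    col <- s_int[, j]
    mn <- min(col); mx <- max(col)
    nv <- numeric(length(v) + (mx - mn))
    for (b in 1:4) {
      sh <- col[b] - mn
      idx <- seq.int(1 + sh, length(v) + sh)
      nv[idx] <- nv[idx] + v * q[b]
    }
    v <- nv
    off <- off + mn
  }
  tail_p <- rev(cumsum(rev(v)))
  i <- max(which(tail_p >= p - 1e-12))  # tail_p[1] = 1 >= p: always defined
  t_int <- off + i - 1
  structure(t_int * granularity,
            tail_prob = tail_p[i],
            granularity = granularity)
}

# encode sequences as an integer matrix (A=1 .. T=4), rows = sequences
encode_seqs <- function(seqs) {
  m <- matrix(match(unlist(strsplit(seqs, "")), BASES),
              nrow = length(seqs), byrow = TRUE)
  if (anyNA(m)) stop("sequences must be over {A,C,G,T}", call. = FALSE)
  m
}

# best hit per sequence over all offsets on the given strand only;
# returns data.frame(score, offset) with NA where no window passes
scan_encoded <- function(pwm, enc, threshold) {
  W <- pwm$width
  n_off <- ncol(enc) - W + 1
  if (n_off < 1) stop("sequence shorter than PWM width", call. = FALSE)
  lo <- pwm$log_odds
  scores <- matrix(0, nrow(enc), n_off)
  for (o in seq_len(n_off)) {
    sc <- numeric(nrow(enc))
    for (j in seq_len(W)) {
      sc <- sc + lo[cbind(enc[, o + j - 1], j)]
    }
    scores[, o] <- sc
  }
  best_off <- max.col(scores, ties.method = "first")  # ties: smallest offset
  best <- scores[cbind(seq_len(nrow(enc)), best_off)]
  pass <- best >= threshold
  data.frame(score = ifelse(pass, best, NA_real_),
             offset = ifelse(pass, best_off, NA_integer_))
}

#' Scan one upstream sequence with a PWM
#'
#' Evaluates every window offset on the given strand only and reports the
#' highest-scoring window with score at or above the threshold (ties:
#' smallest offset), or `NULL` if none passes.  The score of a window is
#' the sum of the matched log-odds matrix entries.
#'
#' @param pwm a [build_pwm()] object.
#' @param seq a single sequence (character) of length >= the PWM width.
#' @param threshold minimum reported score, e.g. from
#'   [pwm_pvalue_threshold()].
#' @return list with `score` and `offset`, or `NULL`.
#' @export
scan_pwm <- function(pwm, seq, threshold) {
  hit <- scan_encoded(pwm, encode_seqs(seq), threshold)
  if (is.na(hit$score[1])) return(NULL)
  list(score = hit$score[1], offset = hit$offset[1])
}

# modal value; ties broken towards the smallest
modal_offset <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

#' Iteratively refine a promoter PWM by positional re-alignment
#'
#' Starts from a PWM built over a fixed window of every upstream sequence,
#' then alternates: score all 71-mers against the current PWM with the
#' exact p-value threshold, keep hits whose match offset lies within
#' `max_shift` of the modal (peak) offset, re-align the kept windows at
#' their match offsets, and rebuild the PWM.  Iteration stops at complete
#' convergence (identical positive set and offsets in successive rounds)
#' or after `max_iter` rounds; oscillation between previously seen states
#' is reported as non-converged.
#'
#' @param upstreams character vector of equal-length upstream sequences
#'   (last base = first transcribed base), or an [extract_upstream()]
#'   data.frame.
#' @param q background composition.
#' @param width PWM window width.
#' @param init_offset 1-based window start of the initial alignment.  The
#'   default anchors the window 3' edge 18 nt upstream of the TSS, which
#'   covers the archaeal TATA/BRE spacing.
#' @param p match p-value used during refinement.
#' @param max_shift largest allowed deviation from the peak offset.
#' @param max_iter iteration cap.
#' @param pseudocount see [build_pwm()].
#' @param granularity see [pwm_pvalue_threshold()].
#' @return list of class `pwm_refinement`: `pwm` (final), `threshold`,
#'   `positives` (indices into `upstreams`), `offsets`, `peak_offset`,
#'   `n_iterations`, `converged`, `n_seqs`.
#' @export
refine_pwm <- function(upstreams, q, width = 28, init_offset = NULL,
                       p = 0.001, max_shift = 4, max_iter = 200,
                       pseudocount = 0.5, granularity = 0.001) {
  if (is.data.frame(upstreams)) upstreams <- upstreams$seq
  n <- length(upstreams)
  if (n < 50) warning("fewer than 50 upstream sequences; motif may be unstable")
  slen <- nchar(upstreams[1])
  stopifnot(all(nchar(upstreams) == slen), slen >= width)
  # default: window 3' edge 18 nt upstream of the TSS (last base)
  init_offset <- as.integer(init_offset %||% (slen - 18 - width + 1))
  enc <- encode_seqs(upstreams)

  positives <- seq_len(n)
  offsets <- rep(init_offset, n)
  state_keys <- character(0)
  converged <- FALSE
  pwm <- NULL; thr <- NA_real_; peak <- init_offset
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    if (length(positives) < 2) {
      stop("degenerate motif: fewer than 2 positive sequences", call. = FALSE)
    }
    windows <- substr(upstreams[positives], offsets, offsets + width - 1)
    pwm <- build_pwm(windows, q, pseudocount)
    thr <- pwm_pvalue_threshold(pwm, p, granularity)
    hits <- scan_encoded(pwm, enc, thr)
    hit_idx <- which(!is.na(hits$score))
    if (length(hit_idx) < 2) {
      stop("degenerate motif: fewer than 2 positive sequences", call. = FALSE)
    }
    peak <- modal_offset(hits$offset[hit_idx])
    keep <- hit_idx[abs(hits$offset[hit_idx] - peak) <= max_shift]
    new_off <- hits$offset[keep]
    key <- paste(keep, new_off, sep = ":", collapse = ";")
    if (identical(keep, positives) && identical(new_off, offsets)) {
      converged <- TRUE
      break
    }
    if (key %in% state_keys) break  # oscillation: revisit of an earlier state
    state_keys <- c(state_keys, key)
    positives <- keep
    offsets <- new_off
  }
  structure(list(pwm = pwm, threshold = as.numeric(thr),
                 positives = positives, offsets = offsets,
                 peak_offset = peak, n_iterations = iter,
                 converged = converged, n_seqs = n),
            class = "pwm_refinement")
}

#' @export
print.pwm_refinement <- function(x, ...) {
  cat(sprintf(
    "pwm_refinement: %d/%d positives after %d iteration(s) (%s); peak offset %d\n",
    length(x$positives), x$n_seqs, x$n_iterations,
    if (x$converged) "converged" else "not converged", x$peak_offset))
  cat("  consensus:", pwm_consensus(x$pwm), "\n")
  invisible(x)
}

#' Classify promoters as stringent, relaxed or absent
#'
#' Scans each upstream sequence with the refined PWM and assigns
#' `stringent` when the best match reaches the `p_stringent` score
#' threshold, `relaxed` when it reaches only the `p_relaxed` threshold,
#' and `none` when no match is reported.  The numeric score cutoffs
#' corresponding to the two p-values are dataset-dependent outputs and are
#' returned as attributes.
#'
#' @param pwm refined [build_pwm()] object.
#' @param upstreams [extract_upstream()] data.frame (or character vector).
#' @param p_stringent,p_relaxed match p-values of the two classes.
#' @param granularity see [pwm_pvalue_threshold()].
#' @return data.frame `tss_id`, `score`, `offset`,
#'   `promoter_class` (stringent/relaxed/none); attributes `t_stringent`,
#'   `t_relaxed`.
#' @export
classify_promoters <- function(pwm, upstreams, p_stringent = 0.001,
                               p_relaxed = 0.01, granularity = 0.001) {
  if (is.character(upstreams)) {
    upstreams <- data.frame(tss_id = sprintf("TSS%04d", seq_along(upstreams)),
                            seq = upstreams, stringsAsFactors = FALSE)
  }
  t_s <- pwm_pvalue_threshold(pwm, p_stringent, granularity)
  t_r <- pwm_pvalue_threshold(pwm, p_relaxed, granularity)
  hits <- scan_encoded(pwm, encode_seqs(upstreams$seq), t_r)
  cls <- ifelse(is.na(hits$score), "none",
                ifelse(hits$score >= as.numeric(t_s), "stringent", "relaxed"))
  out <- data.frame(tss_id = upstreams$tss_id, score = hits$score,
                    offset = hits$offset, promoter_class = cls,
                    stringsAsFactors = FALSE)
  attr(out, "t_stringent") <- as.numeric(t_s)
  attr(out, "t_relaxed") <- as.numeric(t_r)
  out
}

#' Relative-entropy logo matrix of aligned windows
#'
#' Per column j, the information content is the Kullback-Leibler
#' divergence `I_j = sum_b f_bj log2(f_bj / q_b)` (non-negative), and each
#' base contributes the signed term `c_bj = f_bj log2(f_bj / q_b)`,
#' negative when the base is rarer than the background (drawn inverted in
#' a structure logo).  `0 * log 0` is taken as 0.
#'
#' @param windows character vector of aligned equal-length windows.
#' @param q background composition.
#' @return list with `contributions` (4 x width matrix) and `information`
#'   (per-column KL, bits).
#' @export
logo_matrix <- function(windows, q) {
  W <- nchar(windows[1])
  stopifnot(all(nchar(windows) == W))
  m <- matrix(unlist(strsplit(windows, "")), nrow = length(windows),
              byrow = TRUE)
  f <- vapply(seq_len(W), function(j) {
    tabulate(match(m[, j], BASES), 4) / nrow(m)
  }, numeric(4))
  rownames(f) <- BASES
  qv <- as.numeric(q[BASES])
  contrib <- f * ifelse(f > 0, log2(sweep(f, 1, qv, `/`)), 0)
  info <- colSums(contrib)
  list(contributions = contrib, information = info)
}
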