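# shared fixtures, built in code and cached across test files

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# scaled-down synthetic study for fast unit tests
small_config <- function(seed = 42, n_replicates = 2, ...) {
  synth_config(
    n_genes = c(leaderless = 20, leadered = 10, known_rna = 3,
                intergenic_novel = 6, internal = 12, antisense = 14),
    n_replicates = n_replicates, seed = seed, ...)
}

# full default-conditions run (the study-scale fixture), computed once
default_run <- function() {
  cached("default_run", run_pipeline(synth_config(seed = 1), quiet = TRUE))
}

default_sim <- function() {
  cached("default_sim", generate_genome(synth_config(seed = 1)))
}

# antisense-rich study for reciprocity recovery, computed once
antisense_run <- function() {
  cached("antisense_run", {
    cfg <- synth_config(
      n_genes = c(leaderless = 5, leadered = 5, known_rna = 2,
                  intergenic_novel = 2, internal = 5, antisense = 300),
      seed = 71)
    run_pipeline(cfg, quiet = TRUE)
  })
}

# hand-built toy genome for coordinate-rule tests; all expectations below
# are derived by hand from these coordinates
#   geneA  CDS        +  301..600   (start codon ATG stamped at 301)
#   geneD  CDS        -  350..450   (inside geneA, opposite strand)
#   geneB  CDS        -  801..1100  (5' end at 1100)
#   R1     known_rna  +  1401..1500
#   T1     transposase+  1701..2000
#   geneC  CDS        +  1995..2294 (GTG start; overlaps T1 3' end)
#   geneE  CDS        +  3001..4000 (length 1000)
#   geneF  CDS        -  4201..5200 (length 1000)
toy_genome <- function() {
  cached("toy_genome", {
    set.seed(99)
    x <- sample(c("A", "C", "G", "T"), 6000, replace = TRUE)
    x[301:303] <- c("A", "T", "G")
    x[1098:1100] <- c("C", "A", "T")    # ATG on the minus strand
    x[1995:1997] <- c("G", "T", "G")
    feats <- data.frame(
      feature_id = c("geneA", "geneD", "geneB", "R1", "T1", "geneC",
                     "geneE", "geneF"),
      replicon = "toy",
      start = c(301L, 350L, 801L, 1401L, 1701L, 1995L, 3001L, 4201L),
      end = c(600L, 450L, 1100L, 1500L, 2000L, 2294L, 4000L, 5200L),
      strand = c("+", "-", "-", "+", "+", "+", "+", "-"),
      category = c("CDS", "CDS", "CDS", "known_rna", "transposase", "CDS",
                   "CDS", "CDS"),
      stringsAsFactors = FALSE)
    seq <- Biostrings::DNAStringSet(paste(x, collapse = ""))
    names(seq) <- "toy"
    genome_model(seq, feats)
  })
}

mk_tss <- function(position, strand, coverage = 10, replicon = "toy") {
  data.frame(tss_id = sprintf("T%03d", seq_along(position)),
             replicon = replicon, position = as.integer(position),
             strand = strand, support = 3L,
             average_coverage = coverage, stringsAsFactors = FALSE)
}

mk_track <- function(values, strand = "+", library = "plus_tex",
                     replicate = 1, mapped_reads = 100) {
  coverage_track(values, strand, library, replicate, mapped_reads,
                 replicon = "toy")
}

# brute-force PWM score-threshold oracle: enumerate all 4^W windows and
# return the largest achievable discretized score with tail >= p
brute_force_threshold <- function(pwm, p, granularity = 0.001) {
  W <- pwm$width
  s_int <- floor(pwm$log_odds / granularity)
  grid <- expand.grid(rep(list(1:4), W))
  scores <- apply(grid, 1, function(b) sum(s_int[cbind(b, seq_len(W))]))
  probs <- apply(grid, 1, function(b) prod(pwm$q[b]))
  s <- sort(unique(scores))
  tail_at <- vapply(s, function(t) sum(probs[scores >= t]), numeric(1))
  max(s[tail_at >= p - 1e-12]) * granularity
}

# exact brute-force tail probability of floor-discretized scores
brute_force_tail <- function(pwm, t, granularity = 0.001) {
  W <- pwm$width
  s_int <- floor(pwm$log_odds / granularity)
  grid <- expand.grid(rep(list(1:4), W))
  scores <- apply(grid, 1, function(b) sum(s_int[cbind(b, seq_len(W))]))
  probs <- apply(grid, 1, function(b) prod(pwm$q[b]))
  sum(probs[scores * granularity >= t - 1e-12])
}

random_pwm <- function(width, n = 12, q = c(A = .25, C = .25, G = .25, T = .25)) {
  windows <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
  }, character(1))
  build_pwm(windows, q)
}

# independent grid-search pI oracle over the same charge function
grid_pi <- function(peptide, step = 1e-4) {
  ph <- seq(0, 14, by = step)
  z <- peptide_charge(peptide, ph)
  ph[which.min(abs(z))]
}

expect_near <- function(x, y, tol) expect_true(abs(x - y) <= tol)
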