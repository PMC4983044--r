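test_that("normalization scales to the minimum-depth library", {
  t1 <- mk_track(c(0, 10, 4), mapped_reads = 100)
  t2 <- mk_track(c(0, 10, 4), mapped_reads = 200)
  n <- normalize_coverage(list(t1, t2))
  expect_equal(n[[1]]$values, c(0, 10, 4))      # min-depth library unchanged
  expect_equal(n[[2]]$values, c(0, 5, 2))       # 10 * 100/200

  t3 <- mk_track(c(30, 6, 0), mapped_reads = 150)
  n <- normalize_coverage(list(mk_track(1:3, mapped_reads = 50),
                               mk_track(1:3, mapped_reads = 100), t3))
  expect_equal(n[[3]]$values[1], 10)            # 30 * 50/150
  # within-library rank order preserved
  v <- c(5, 1, 9, 9, 0, 3)
  n <- normalize_coverage(list(mk_track(v, mapped_reads = 70),
                               mk_track(v, mapped_reads = 35)))
  expect_identical(order(n[[1]]$values), order(v))
  expect_identical(order(n[[2]]$values), order(v))

  expect_error(normalize_coverage(list(mk_track(1, mapped_reads = 0))),
               "zero mapped")
})

test_that("candidate calling applies height, step and enrichment rules", {
  minus <- numeric(60); plus <- numeric(60)
  plus[30] <- 25; minus[30] <- 10
  cands <- call_tss(mk_track(minus, library = "minus_tex"), mk_track(plus))
  expect_equal(nrow(cands), 0)                  # 25/11 = 2.27 < 2.5

  plus[30] <- 28
  cands <- call_tss(mk_track(minus, library = "minus_tex"), mk_track(plus))
  expect_equal(cands$position, 30)              # 28/11 = 2.55 >= 2.5
  expect_equal(cands$enrichment_factor, 28 / 11)

  # pseudocount: minus = 0 gives enrichment plus/1
  minus[30] <- 0; plus[30] <- 10
  cands <- call_tss(mk_track(minus, library = "minus_tex"), mk_track(plus))
  expect_equal(cands$enrichment_factor, 10)
  expect_equal(cands$position, 30)

  # flat track: no step anywhere, no candidates regardless of enrichment
  cands <- call_tss(mk_track(numeric(60), library = "minus_tex"),
                    mk_track(rep(50, 60)))
  expect_equal(nrow(cands), 0)

  # below min_height
  plus <- numeric(60); plus[30] <- 4
  cands <- call_tss(mk_track(numeric(60), library = "minus_tex"),
                    mk_track(plus))
  expect_equal(nrow(cands), 0)

  expect_error(call_tss(mk_track(numeric(10), library = "minus_tex"),
                        mk_track(numeric(20))), "mismatch")
})

test_that("the step rule is measured in transcription direction", {
  # minus strand: the upstream neighbour is position + 1
  plus <- numeric(60)
  plus[30] <- 20; plus[31] <- 15                # 20 < 2*15: step fails on '-'
  m <- mk_track(numeric(60), strand = "-", library = "minus_tex")
  expect_false(30 %in% call_tss(m, mk_track(plus, strand = "-"))$position)
  # on the plus strand the same profile steps up at 30 (neighbour is 29)
  expect_true(30 %in% call_tss(mk_track(numeric(60), library = "minus_tex"),
                               mk_track(plus))$position)
  plus[31] <- 9                                 # 20 >= 2*9: step passes
  expect_true(30 %in% call_tss(m, mk_track(plus, strand = "-"))$position)
})

test_that("closely spaced candidates merge by the <10 nt rule", {
  cands <- function(pos, h, strand = "+") {
    data.frame(replicon = "toy", position = pos, strand = strand,
               plus_tex_height = h, minus_tex_height = 0,
               enrichment_factor = h, enriched = TRUE, replicate = 1L,
               stringsAsFactors = FALSE)
  }
  m <- merge_close(cands(c(100, 105), c(5, 9)))
  expect_equal(m$position, 105)                 # higher coverage wins

  m <- merge_close(cands(c(100, 110), c(5, 9)))
  expect_equal(m$position, c(100, 110))         # gap = 10: not merged

  m <- merge_close(cands(c(100, 108, 116), c(5, 9, 4)))
  expect_equal(m$position, 108)                 # single-linkage chain

  # ties break to the most upstream position in transcription direction
  expect_equal(merge_close(cands(c(100, 105), c(7, 7)))$position, 100)
  expect_equal(merge_close(cands(c(100, 105), c(7, 7), "-"))$position, 105)

  # idempotence
  x <- cands(c(100, 108, 116, 140, 160, 165), c(5, 9, 4, 2, 8, 8))
  expect_identical(merge_close(merge_close(x)), merge_close(x))
})

test_that("replicate consensus groups TSSs across replicates", {
  cands <- function(pos, h, rep) {
    data.frame(replicon = "toy", position = pos, strand = "+",
               plus_tex_height = h, minus_tex_height = 0,
               enrichment_factor = h, enriched = TRUE, replicate = rep,
               stringsAsFactors = FALSE)
  }
  cons <- replicate_consensus(list(cands(200, 5, 1), cands(204, 9, 2),
                                   cands(260, 4, 3)))
  expect_equal(nrow(cons), 2)                   # 200+204 merge; 260 separate
  expect_equal(cons$position, c(204, 260))      # highest +TEX wins position
  expect_equal(cons$support, c(2, 1))
  expect_equal(cons$average_coverage, c(7, 4))  # mean over detecting reps

  cons <- replicate_consensus(list(cands(500, 5, 1), cands(500, 6, 2),
                                   cands(500, 7, 3)))
  expect_equal(cons$support, 3)
  expect_equal(cons$detected_in, "1,2,3")

  # disjoint far-apart sets: all support 1
  cons <- replicate_consensus(list(cands(seq(100, 300, 100), 5, 1),
                                   cands(seq(1000, 1300, 100), 5, 2),
                                   cands(seq(2000, 2400, 100), 5, 3)))
  expect_equal(nrow(cons), 12)
  expect_true(all(cons$support == 1))

  # support counts monotone
  n1 <- sum(cons$support >= 1); n2 <- sum(cons$support >= 2)
  n3 <- sum(cons$support == 3)
  expect_true(n1 >= n2 && n2 >= n3)
})

test_that("the caller recovers planted TSSs and rejects processed decoys", {
  run <- default_run()
  sim <- run$fixture
  cons <- run$consensus
  truth <- sim$truth
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(cons$strand == truth$strand[i] &
          abs(cons$position - truth$position[i]) < 10)
  }, logical(1))
  expect_gte(mean(hit), 0.9)

  # no decoy in the replicate-reproducible consensus
  repro <- cons[cons$support >= 2, ]
  dec <- vapply(seq_len(nrow(sim$decoys)), function(i) {
    any(repro$strand == sim$decoys$strand[i] &
          abs(repro$position - sim$decoys$position[i]) < 10)
  }, logical(1))
  expect_equal(sum(dec), 0)

  # consensus never exceeds the pooled candidate count
  expect_lte(nrow(cons), sum(cons$support))
})
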