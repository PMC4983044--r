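random_utr <- function(n, seed) {
  set.seed(seed)
  # GC-rich background keeps spurious ATG...stop ORFs rare
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(.165, .335, .335, .165)), collapse = "")
}

orf_of <- function(n_codons, seed = 1) {
  set.seed(seed)
  body <- vapply(seq_len(n_codons - 1), function(i) {
    repeat {
      cod <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                   collapse = "")
      if (!cod %in% c("TAA", "TAG", "TGA", "ATG")) return(cod)
    }
  }, character(1))
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

test_that("uORF scanning finds contained ORFs above the length cutoff", {
  orf <- orf_of(20)          # ATG + 19 codons + TAA: peptide of 20 aa
  utr <- paste0(substr(random_utr(200, 5), 1, 60), orf,
                substr(random_utr(200, 6), 1, 200 - 60 - nchar(orf)))
  found <- find_uorfs(utr)
  # overlapping/spurious contained ORFs are all reported; the planted one
  # must be among them with the right coordinates
  expect_gte(nrow(found), 1)
  planted <- found[found$start_offset == 60, ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$length_aa, 20)
  expect_equal(nchar(planted$peptide), 20)
  expect_equal(substr(planted$peptide, 1, 1), "M")
  expect_true(all(substr(found$peptide, 1, 1) == "M"))
  # round trip: every peptide re-translates from the UTR at its offset
  for (i in seq_len(nrow(found))) {
    nt <- substr(utr, found$start_offset[i] + 1,
                 found$start_offset[i] + 3 * found$length_aa[i])
    expect_equal(as.character(Biostrings::translate(Biostrings::DNAString(nt))),
                 found$peptide[i])
  }

  # below the default 15-aa cutoff
  utr10 <- paste0(substr(random_utr(200, 7), 1, 60), orf_of(10),
                  substr(random_utr(200, 8), 1, 107))
  expect_equal(nrow(find_uorfs(utr10)), 0)
  expect_equal(nrow(find_uorfs(utr10, min_len = 10)), 1)

  # ATG with no in-frame stop before the UTR end: not contained
  utr_open <- paste0(strrep("C", 20), "ATG", strrep("GCA", 25))
  expect_equal(nrow(find_uorfs(utr_open, min_len = 5)), 0)
})

test_that("pI is ordered by charge and matches the grid-search oracle", {
  expect_gt(peptide_pi("KKKK"), peptide_pi("GGGG"))
  expect_gt(peptide_pi("GGGG"), peptide_pi("DDDD"))
  expect_near(peptide_pi("DDDD"), grid_pi("DDDD"), 1e-3)

  # adding a basic residue never decreases the pI
  set.seed(17)
  for (i in 1:20) {
    pep <- paste(sample(names(haloTSS:::RESIDUE_MASS), 12, replace = TRUE),
                 collapse = "")
    expect_gte(peptide_pi(paste0(pep, "K")) - peptide_pi(pep), -1e-3)
  }

  expect_error(peptide_pi("ABZ"), "non-standard")
  expect_error(peptide_pi(""), "empty")
})

test_that("bisection agrees with the grid oracle on random peptides", {
  set.seed(18)
  aas <- names(haloTSS:::RESIDUE_MASS)
  for (i in 1:100) {
    pep <- paste(sample(aas, sample(5:30, 1), replace = TRUE), collapse = "")
    expect_near(peptide_pi(pep), grid_pi(pep), 1e-3)
  }
})

test_that("molecular weights are additive average masses", {
  expect_equal(peptide_mw("G"), 75.07, tolerance = 1e-2)
  set.seed(19)
  aas <- names(haloTSS:::RESIDUE_MASS)
  a <- paste(sample(aas, 8), collapse = "")
  b <- paste(sample(aas, 11), collapse = "")
  expect_equal(peptide_mw(paste0(a, b)),
               peptide_mw(a) + peptide_mw(b) - 18.0153, tolerance = 1e-9)
  expect_error(peptide_mw(""), "empty")
})

test_that("small-protein TSS counting uses the 100-aa boundary", {
  seqlen <- 3000L
  mk_gm <- function(cds_len) {
    set.seed(20)
    x <- paste(sample(c("A", "C", "G", "T"), seqlen, replace = TRUE),
               collapse = "")
    genome_model(
      setNames(Biostrings::DNAStringSet(x), "toy"),
      data.frame(feature_id = "g1", replicon = "toy", start = 501L,
                 end = 500L + cds_len, strand = "+", category = "CDS",
                 stringsAsFactors = FALSE))
  }
  tss <- mk_tss(501, "+")
  cl303 <- classify_tss(tss, mk_gm(303L))   # 100 aa + stop: counted
  expect_equal(count_small_protein_tss(cl303, mk_gm(303L)), 1)
  cl306 <- classify_tss(tss, mk_gm(306L))   # 101 aa: not counted
  expect_equal(count_small_protein_tss(cl306, mk_gm(306L)), 0)
  expect_lte(count_small_protein_tss(cl303, mk_gm(303L)),
             sum(cl303$primary_class %in% c("leaderless", "leadered")))
})

test_that("long-UTR scanning reports uORFs from the classified table", {
  # build a genome whose leadered gene has a 200-nt UTR with a planted uORF
  orf <- orf_of(16, seed = 21)
  utr <- paste0(substr(random_utr(300, 22), 1, 80), orf,
                substr(random_utr(300, 23), 1, 200 - 80 - nchar(orf)))
  set.seed(24)
  flank <- function(n, s) substr(random_utr(n + 10, s), 1, n)
  genome_str <- paste0(flank(400, 25), utr, "ATG",
                       substr(random_utr(400, 26), 1, 297), flank(300, 27))
  gm <- genome_model(
    setNames(Biostrings::DNAStringSet(genome_str), "toy"),
    data.frame(feature_id = "g1", replicon = "toy", start = 601L,
               end = 900L, strand = "+", category = "CDS",
               stringsAsFactors = FALSE))
  cl <- classify_tss(mk_tss(401, "+"), gm)
  expect_equal(cl$primary_class, "leadered")
  expect_equal(cl$utr_length, 200L)
  expect_equal(utr_sequence(gm, cl[1, ]), utr)
  res <- scan_long_utr_uorfs(cl, gm)
  expect_equal(attr(res, "n_utr_scanned"), 1)
  expect_true(nrow(res) >= 1)
  expect_true(16 %in% res$length_aa)
  expect_true(all(res$pi > 0 & res$pi < 14))
  expect_true(all(res$mw > 0))
})

test_that("intergenic concatenation sorts, links and chunks correctly", {
  expect_equal(concat_intergenic(c("AAAAA", "CCCCCCC")),
               "AAAAATTAATTAATTAACCCCCCC")   # 5 + 12 + 7 = 24

  # regions come out sorted by length
  r <- c(paste(rep("G", 30), collapse = ""),
         paste(rep("A", 10), collapse = ""),
         paste(rep("C", 20), collapse = ""))
  chunk <- concat_intergenic(r)
  expect_equal(chunk, paste0(r[2], "TTAATTAATTAA", r[3], "TTAATTAATTAA", r[1]))

  # the linker has a stop codon in all six reading frames
  linker <- "TTAATTAATTAA"
  has_stop <- function(s) {
    any(vapply(seq(1, nchar(s) - 2, 3), function(i) {
      substr(s, i, i + 2) %in% c("TAA", "TAG", "TGA")
    }, logical(1)))
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(linker)))
  frames <- c(vapply(0:2, function(f) substr(linker, 1 + f, nchar(linker)),
                     character(1)),
              vapply(0:2, function(f) substr(rc, 1 + f, nchar(rc)),
                     character(1)))
  expect_equal(sum(vapply(frames, has_stop, logical(1))), 6)

  # chunking: many 500-nt regions go into 2-3 kb chunks, unsplit
  regions <- vapply(1:20, function(i) random_utr(500, 100 + i), character(1))
  chunks <- concat_intergenic(regions)
  expect_true(all(nchar(chunks) <= 3000))
  expect_true(all(nchar(head(chunks, -1)) >= 2000))
  # every region survives intact somewhere
  expect_true(all(vapply(regions, function(r) {
    any(grepl(r, chunks, fixed = TRUE))
  }, logical(1))))
})
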