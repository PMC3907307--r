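test_that("genome generation is deterministic given the seed", {
  g1 <- generate_reference(c(chr1 = 1e5), telomere_units = 20, seed = 1)
  g2 <- generate_reference(c(chr1 = 1e5), telomere_units = 20, seed = 1)
  g3 <- generate_reference(c(chr1 = 1e5), telomere_units = 20, seed = 2)
  expect_identical(g1$seqs, g2$seqs)
  expect_identical(g1$mito, g2$mito)
  expect_false(identical(g1$seqs, g3$seqs))
})

test_that("chromosomes carry telomere caps and an interior centromere", {
  units <- 30L
  ref <- generate_reference(c(chr1 = 1e5), telomere_units = units, seed = 3)
  s <- ref$seqs$chr1
  expect_identical(substr(s, 1, 6 * units), strrep("CCCTAA", units))
  expect_identical(substr(s, nchar(s) - 6 * units + 1, nchar(s)),
                   strrep("TTAGGG", units))
  expect_gte(telomere_run(substr(s, 1, 300), side = "left")$units, 2L)
  expect_true(ref$centromere[["chr1"]] > 0 &&
                ref$centromere[["chr1"]] < nchar(s))
})

test_that("base composition is honoured within binomial bounds", {
  comp <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  ref <- generate_reference(c(chr1 = 1e6), base_composition = comp,
                            telomere_units = 0, seed = 5)
  counts <- table(strsplit(ref$seqs$chr1, "", fixed = TRUE)[[1]])
  n <- nchar(ref$seqs$chr1)
  for (b in names(comp)) {
    ci <- binom_ci99(n, comp[[b]])
    expect_gte(counts[[b]], ci[1])
    expect_lte(counts[[b]], ci[2])
  }
})

test_that("planted repeat pairs realize the requested divergence exactly", {
  ref <- generate_reference(c(chr1 = 2e5), telomere_units = 10, seed = 8)
  hamming_rc <- function(ref, row) {
    c1 <- ref_seq(ref, row$chrom, row$start1, row$end1)
    c2 <- ref_seq(ref, row$chrom, row$start2, row$end2)
    sum(strsplit(revcomp(c1), "", fixed = TRUE)[[1]] !=
          strsplit(c2, "", fixed = TRUE)[[1]])
  }
  # identity 1: exact reverse complement
  r1 <- plant_inverted_repeat_pair(ref, "AluLike", "chr1", 10000, 50000,
                                   length = 296, identity = 1, seed = 1)
  expect_identical(hamming_rc(r1, r1$repeats[1, ]), 0L)
  # the two diverged-repeat scales seen at real junctions
  r2 <- plant_inverted_repeat_pair(ref, "L1Like", "chr1", 10000, 50000,
                                   length = 330, identity = 0.95, seed = 2)
  d2 <- hamming_rc(r2, r2$repeats[1, ])
  expect_true(d2 %in% 16:17)
  expect_lt(abs((1 - d2 / 330) - 0.95), 0.02)
  r3 <- plant_inverted_repeat_pair(ref, "AluLike", "chr1", 10000, 50000,
                                   length = 296, identity = 0.82, seed = 3)
  expect_identical(hamming_rc(r3, r3$repeats[1, ]), 53L)
  # direct orientation mutates the copy itself
  r4 <- plant_inverted_repeat_pair(ref, "AluLike", "chr1", 10000, 50000,
                                   length = 100, identity = 0.9,
                                   orientation = "direct", seed = 4)
  c1 <- ref_seq(r4, "chr1", 10000, 10100)
  c2 <- ref_seq(r4, "chr1", 50000, 50100)
  expect_equal(mean(strsplit(c1, "", fixed = TRUE)[[1]] ==
                      strsplit(c2, "", fixed = TRUE)[[1]]), 0.9)
  expect_error(
    plant_inverted_repeat_pair(ref, "AluLike", "chr1", 10000, 10100,
                               length = 296, identity = 0.9),
    class = "foldback_placement_error")
})

test_that("anneal-site planting yields the exact requested microhomology", {
  ref <- generate_reference(c(chr1 = 1e5), telomere_units = 10, seed = 9)
  for (mh in c(1, 2, 4, 8)) {
    e <- 80000; d <- e - 500 - 17 * mh
    r <- plant_anneal_site(ref, "chr1", d, e, mh)
    expect_identical(inverted_mh_pair(r, "chr1", e, d), as.integer(mh))
    # canonical-stable: no maximal shift applies
    expect_false(ref_seq(r, "chr1", e, e + 1) ==
                   revcomp(ref_seq(r, "chr1", d - 1, d)))
  }
})

test_that("the mitochondrial-like donor is circular, sized and non-nuclear", {
  m1 <- generate_mito_donor(seed = 2)
  m2 <- generate_mito_donor(seed = 2)
  expect_identical(nchar(m1), 16569L)
  expect_identical(as.character(m1), as.character(m2))
  expect_true(attr(m1, "circular"))
  # sampled 70-bp windows align nowhere in a 1-Mb nuclear chromosome at
  # >= 90% identity
  ref <- generate_reference(c(chr1 = 1e6), telomere_units = 0, seed = 10)
  subject <- Biostrings::DNAString(ref$seqs$chr1)
  set.seed(99)
  for (w in sample(seq_len(16569 - 70), 25)) {
    win <- substr(m1, w, w + 69)
    hits <- length(Biostrings::matchPattern(win, subject, max.mismatch = 7)) +
      length(Biostrings::matchPattern(revcomp(win), subject, max.mismatch = 7))
    expect_identical(hits, 0L)
  }
})

test_that("FASTA + BED serialization round-trips the genome", {
  ref <- generate_reference(
    c(chr1 = 1.2e5, chr2 = 1.1e5), telomere_units = 15, seed = 12,
    repeat_plan = list(
      list(family = "AluLike", chrom = "chr1", start1 = 20000,
           start2 = 60000, length = 296, identity = 0.9,
           orientation = "inverted")))
  fa <- tempfile(fileext = ".fa"); bed <- tempfile(fileext = ".bed")
  on.exit(unlink(c(fa, bed)))
  write_genome(ref, fa, bed)
  back <- read_genome(fa, bed)
  expect_identical(back$seqs, ref$seqs)
  expect_identical(as.character(back$mito), as.character(ref$mito))
  expect_identical(back$centromere[names(ref$centromere)], ref$centromere)
  expect_identical(back$telomere_units, ref$telomere_units)
  expect_equal(back$repeats[order(back$repeats$start1), ],
               ref$repeats[order(ref$repeats$start1), ],
               ignore_attr = TRUE)
})
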