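test_that("site scan finds a uniquely planted anneal site", {
  set.seed(97)
  ref <- reference_genome(list(chr1 = rand_dna(10000)), c(chr1 = 4000))
  ref <- plant_anneal_site(ref, "chr1", d = 6000, e = 9000, mh = 10)
  # exhaustive oracle over the scan windows: k >= 10 at (e, d) iff the
  # 10-mer ending at e equals the reverse complement of the 10-mer starting
  # at d; the planted site must be the only such pair
  s <- ref$seqs$chr1
  hits <- 0
  for (e in seq(8950, 9050)) {
    suf <- substr(s, e - 9, e)
    for (d in seq(4950, e - 20)) {
      if (suf == oracle_revcomp(substr(s, d + 1, d + 10))) hits <- hits + 1
    }
  }
  expect_identical(hits, 1)
  ev <- simulate_foldback(ref, "chr1", b = 9050, min_mh = 10,
                          max_loop = 4000, r_max = 100)
  expect_identical(c(ev$d, ev$e), c(6000, 9000))
  expect_identical(ev$spacer, 3000)
  expect_identical(ev$mh_len, 10L)
})

test_that("site scan respects max_loop and reports failure honestly", {
  set.seed(17)
  ref <- generate_reference(c(chr1 = 5e4), telomere_units = 5, seed = 21)
  for (i in 1:20) {
    ev <- simulate_foldback(ref, "chr1", b = 45000 - 100 * i, min_mh = 1,
                            max_loop = 500, r_max = 50)
    expect_lte(ev$spacer, 500)
    expect_gte(ev$mh_len, 1L)
  }
  # a homopolymer has no complementary bases at all
  refA <- reference_genome(list(chr1 = strrep("A", 2e4)), c(chr1 = 1000))
  expect_error(simulate_foldback(refA, "chr1", b = 18000, min_mh = 1),
               class = "foldback_no_site")
})

test_that("the dicentric has the expected structure", {
  fx <- make_event_fixture(L = 2e4, spacer = 3000, mh = 4, deletion = 1000,
                           telomere_units = 5)
  ev <- foldback_event(fx$ref, "chr1", d = fx$d, e = fx$e)
  dic <- form_dicentric(fx$ref, ev)
  expect_identical(nchar(dic$seq), as.integer(ev$e + ev$d))
  expect_identical(substr(dic$seq, 1, ev$e), ref_seq(fx$ref, "chr1", 0, ev$e))
  spacer_seq <- ref_seq(fx$ref, "chr1", ev$d, ev$e)
  expect_identical(
    Biostrings::countPattern(spacer_seq, Biostrings::DNAString(dic$seq)), 1L)
  expect_length(dic$centromeres, 2L)
})

test_that("dicentric breakage conserves every base and partitions cleanly", {
  set.seed(53)
  for (i in 1:10) {
    fx <- make_event_fixture(L = 3e4, spacer = sample(500:3000, 1),
                             mh = sample(2:8, 1), deletion = 2000,
                             seed = i, telomere_units = 5)
    ev <- foldback_event(fx$ref, "chr1", d = fx$d, e = fx$e)
    dic <- form_dicentric(fx$ref, ev)
    p <- sample(seq(fx$ref$centromere[["chr1"]] + 1, ev$d - 1000), 1)
    pr <- break_dicentric(fx$ref, dic, p)
    # concatenation identity: stronger than multiset conservation
    expect_identical(paste0(pr$invdup$seq, pr$sibling), dic$seq)
    expect_identical(table(strsplit(paste0(pr$invdup$seq, pr$sibling), "",
                                    fixed = TRUE)[[1]]),
                     table(strsplit(dic$seq, "", fixed = TRUE)[[1]]))
    # the sibling is the proximal segment read off the dicentric
    expect_identical(pr$sibling, revcomp(ref_seq(fx$ref, "chr1", 0, p)))
  }
  fx <- make_event_fixture(L = 3e4, spacer = 1000, mh = 4, deletion = 2000,
                           telomere_units = 5)
  ev <- foldback_event(fx$ref, "chr1", d = fx$d, e = fx$e)
  dic <- form_dicentric(fx$ref, ev)
  expect_error(break_dicentric(fx$ref, dic, fx$ref$centromere[["chr1"]] - 1),
               class = "foldback_invalid_break")
  expect_error(break_dicentric(fx$ref, dic, ev$d + 10),
               class = "foldback_invalid_break")
})

test_that("reference dosage in the product follows the 2/1/0 truth profile", {
  fx <- make_event_fixture(L = 3e5, spacer = 3000, mh = 4, deletion = 5e4,
                           telomere_units = 5)
  der <- build_derivative(fx, mode = "telomere", tel_mh = 0)
  tr <- rearrangement_truth(der)
  dna <- Biostrings::DNAString(der$seq)
  dosage_at <- function(pos) {
    # occurrences of the locus = forward + reverse-complement matches of a
    # locally unique 20-mer
    kmer <- ref_seq(fx$ref, "chr1", pos, pos + 20)
    Biostrings::countPattern(kmer, dna) +
      Biostrings::countPattern(revcomp(kmer), dna)
  }
  set.seed(71)
  for (pos in sample(seq(tr$dup_start + 50, tr$dup_end - 50), 5))
    expect_identical(dosage_at(pos), 2L)
  for (pos in sample(seq(tr$spacer_start + 50, tr$spacer_end - 50), 5))
    expect_identical(dosage_at(pos), 1L)
  for (pos in sample(seq(100, tr$dup_start - 50), 5))
    expect_identical(dosage_at(pos), 1L)
  for (pos in sample(seq(tr$spacer_end + 50, tr$chrom_length - 100), 5))
    expect_identical(dosage_at(pos), 0L)
  expect_identical(tr$deletion_size, fx$L - fx$e)
  expect_identical(tr$spacer_size, fx$e - fx$d)
})

test_that("telomere healing appends a detectable phased repeat", {
  fx <- make_event_fixture(L = 1e5, spacer = 2000, mh = 3, deletion = 1e4,
                           telomere_units = 10)
  der <- build_derivative(fx, mode = "telomere", tel_units = 40, tel_mh = 2)
  jx <- der$junctions[der$junctions$id == "j_invtel", ]
  expect_identical(jx$type, "inversion_telomere")
  tail400 <- substr(der$seq, nchar(der$seq) - 399, nchar(der$seq))
  expect_gte(telomere_run(tail400, side = "right")$units, 2L)
  expect_lte(jx$anneal_k, 2L)  # achieved junction homology never exceeds
                               # the requested value
})

test_that("translocation healing captures a donor chromosome end", {
  fx <- make_event_fixture(L = 1e5, spacer = 2000, mh = 3, deletion = 1e4,
                           telomere_units = 10)
  der <- build_derivative(fx, mode = "translocation", donor_chrom = "chr2",
                          donor_seg = 3e4)
  jx <- der$junctions[der$junctions$id == "j_invtra", ]
  expect_identical(jx$left_chrom, "chr1")
  expect_identical(jx$right_chrom, "chr2")
  L2 <- nchar(fx$ref$seqs$chr2)
  expect_identical(substr(der$seq, nchar(der$seq) - 999, nchar(der$seq)),
                   ref_seq(fx$ref, "chr2", L2 - 1000, L2))
  expect_error(build_derivative(fx, mode = "translocation",
                                donor_chrom = "chr1"),
               class = "foldback_range_error")
})

test_that("ring fusion loses both telomere caps at the join", {
  fx <- make_event_fixture(L = 1e5, spacer = 2000, mh = 3, deletion = 1e4,
                           telomere_units = 10)
  der <- build_derivative(fx, mode = "ring")
  expect_true(der$circular)
  expect_lt(telomere_run(substr(der$seq, 1, 300), side = "left")$units, 2L)
  expect_lt(telomere_run(substr(der$seq, nchar(der$seq) - 299,
                                nchar(der$seq)), side = "right")$units, 2L)
  expect_true("ring_fusion" %in% der$junctions$type)
  # the disomy-inversion junction survives the cap trim with its spacer
  expect_identical(der$junctions$spacer[der$junctions$id == "j_disinv"],
                   2000)
})

test_that("amplicons carry the junction with full flanks and insertions", {
  fx <- make_event_fixture(L = 1e5, spacer = 2000, mh = 3, deletion = 1e4,
                           telomere_units = 10)
  der <- build_derivative(fx, mode = "telomere", tel_mh = 0)
  amp <- emit_amplicon(der, "j_disinv", flank = 400)
  expect_identical(nchar(amp), 800L)
  expect_false(attr(amp, "truncated"))
  deri <- add_complex_insertion(der, fx$ref, "j_disinv", "untemplated", 25,
                                seed = 5)
  ampi <- emit_amplicon(deri, "j_disinv", flank = 400)
  expect_identical(nchar(ampi), 825L)
  ins <- deri$junctions$ins_seq[deri$junctions$id == "j_disinv"]
  expect_identical(as.character(substr(ampi, 401, 425)), ins)
  # flank larger than the unresolved distal arm: truncation is flagged
  ev <- foldback_event(fx$ref, "chr1", d = fx$d, e = fx$e)
  short <- break_dicentric(fx$ref, form_dicentric(fx$ref, ev),
                           p = fx$d - 60)$invdup
  at <- emit_amplicon(short, "j_disinv", flank = 400)
  expect_true(attr(at, "truncated"))
  expect_error(emit_amplicon(short, "j_disinv", flank = 10),
               class = "foldback_range_error")
})

test_that("read pairs decide discordance through the truth mapping", {
  fx <- make_event_fixture(L = 1e5, spacer = 3000, mh = 4, deletion = 1e4,
                           telomere_units = 10)
  der <- build_derivative(fx, mode = "telomere", tel_mh = 0)
  rd <- simulate_paired_end_reads(der, coverage = 20, insert_mean = 400,
                                  insert_sd = 40, read_len = 100, seed = 13)
  expect_identical(nrow(rd), as.integer(round(20 * nchar(der$seq) / 200)))
  e <- fx$e
  spanning <- rd$der_start + 100 < e & rd$der_end - 100 > e &
    !rd$spans1 & !rd$spans2
  expect_gt(sum(spanning), 0)
  expect_true(all(rd$strand1[spanning] == rd$strand2[spanning]))
  inside <- rd$der_start > e - 3000 & rd$der_end < e
  expect_gt(sum(inside), 0)
  expect_true(all(rd$strand1[inside] == "+" & rd$strand2[inside] == "-"))
  expect_error(simulate_paired_end_reads(der, insert_mean = 150),
               class = "foldback_range_error")
})

test_that("CGH profiles step through the three dosage levels", {
  fx <- make_event_fixture(L = 2e5, spacer = 3428, mh = 4, deletion = 3e4,
                           telomere_units = 10)
  der <- build_derivative(fx, mode = "telomere", tel_mh = 0)
  tr <- rearrangement_truth(der)
  cg <- simulate_cgh(tr, probe_spacing = 200, noise_sd = 0, seed = 1)
  expect_setequal(unique(cg$probes$log2), c(0, log2(3 / 2), log2(1 / 2)))
  in_spacer <- cg$probes$pos >= tr$spacer_start & cg$probes$pos < tr$spacer_end
  expect_gte(sum(in_spacer), 16L)           # 3,428 bp / 200 bp spacing
  cg75 <- simulate_cgh(tr, probe_spacing = 75000, noise_sd = 0, seed = 1)
  expect_lt(sum(cg75$probes$pos >= tr$spacer_start &
                  cg75$probes$pos < tr$spacer_end), 1L)
})
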