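test_that("split alignment recovers overlap, gap and contiguity", {
  fx <- make_event_fixture(L = 2e5, spacer = 2000, mh = 4, deletion = 2e4,
                           telomere_units = 10)
  der <- build_derivative(fx, mode = "telomere", tel_mh = 0)
  sp <- split_align(emit_amplicon(der, "j_disinv", 400), fx$ref)
  expect_true(sp$resolved)
  expect_identical(sp$left$strand, "+")
  expect_identical(sp$right$strand, "-")
  expect_identical(sp$left$q_end - sp$right$q_start, 4L)  # 4-bp overlap

  dm <- add_complex_insertion(der, fx$ref, "j_disinv", "mitochondrial", 70,
                              seed = 4)
  spm <- split_align(emit_amplicon(dm, "j_disinv", 400), fx$ref)
  expect_identical(spm$right$q_start - spm$left$q_end, 70L)  # 70-bp gap

  contiguous <- ref_seq(fx$ref, "chr1", 10000, 10800)
  spc <- split_align(contiguous, fx$ref)
  expect_false(spc$resolved)
  expect_match(spc$diagnostic, "contiguously")
  expect_error(split_align("ACGTACGT", fx$ref),
               class = "foldback_range_error")
})

test_that("junction calls recover class, spacer and microhomology exactly", {
  fx <- make_event_fixture(L = 3e5, spacer = 2047, mh = 4, deletion = 5e4,
                           telomere_units = 10)
  der <- build_derivative(fx, mode = "telomere", tel_mh = 2)
  cd <- call_junction(split_align(emit_amplicon(der, "j_disinv", 400),
                                  fx$ref), fx$ref)
  jx <- der$junctions
  expect_identical(cd$type, "disomy_inversion")
  expect_identical(cd$spacer, jx$spacer[jx$id == "j_disinv"])
  expect_identical(cd$mh_len, jx$mh[jx$id == "j_disinv"])
  expect_identical(cd$e, as.numeric(fx$e))
  expect_identical(cd$d, as.numeric(fx$d))

  ct <- call_junction(split_align(emit_amplicon(der, "j_invtel", 400),
                                  fx$ref), fx$ref)
  expect_identical(ct$type, "inversion_telomere")
  expect_identical(ct$mh_len, jx$mh[jx$id == "j_invtel"])

  dtr <- build_derivative(fx, mode = "translocation", donor_chrom = "chr2",
                          donor_seg = 3e4)
  cr <- call_junction(split_align(emit_amplicon(dtr, "j_invtra", 400),
                                  fx$ref), fx$ref)
  expect_identical(cr$type, "inversion_translocation")
  expect_identical(sort(c(cr$left_chrom, cr$right_chrom)),
                   c("chr1", "chr2"))
})

test_that("insertion origins are classified by templated search", {
  fx <- make_event_fixture(L = 2e5, spacer = 2000, mh = 4, deletion = 2e4,
                           telomere_units = 10)
  der0 <- build_derivative(fx, mode = "telomere", tel_mh = 0)
  bp_of <- function(call) list(list(chrom = call$left_chrom,
                                    pos = call$left_pos),
                               list(chrom = call$right_chrom,
                                    pos = call$right_pos))
  run_case <- function(kind, len, ...) {
    d <- add_complex_insertion(der0, fx$ref, "j_disinv", kind, len, ...)
    call <- call_junction(split_align(emit_amplicon(d, "j_disinv", 400),
                                      fx$ref), fx$ref)
    list(truth = d$junctions[d$junctions$id == "j_disinv", ],
         call = call,
         origin = classify_insertion_origin(call$insertion, fx$ref,
                                            bp_of(call)))
  }
  # a 22-bp copy from inside the duplication, opposite orientation
  ti <- run_case("templated_inverted", 22, template_offset = 600)
  expect_identical(ti$origin$kind, "templated_inverted")
  expect_lt(abs(ti$origin$start - ti$truth$template_start), 3)
  # 70 bp from the mitochondrial-like donor
  mi <- run_case("mitochondrial", 70, seed = 9)
  expect_identical(mi$origin$kind, "mitochondrial")
  # 4-bp direct-orientation copy of nearby disomic sequence
  td <- run_case("templated_direct", 4, template_offset = 30)
  expect_identical(td$origin$kind, "templated_direct")
  # short insertions carry too little information
  expect_identical(
    classify_insertion_origin("CAA", fx$ref,
                              list(list(chrom = "chr1", pos = fx$e)))$kind,
    "unclassifiable_short")
  # a junction with an insertion never also reports microhomology
  expect_identical(ti$call$mh_len, 0L)
  expect_identical(mi$call$mh_len, 0L)
})

test_that("repeat-routed junctions are detected as hybrid repeats", {
  set.seed(61)
  L <- 2e5
  ref <- generate_reference(c(chr1 = L, chr2 = 1e5), telomere_units = 10,
                            seed = 33)
  run_repeat_case <- function(ref, family, len, identity) {
    e_anchor <- 1.6e5
    ref <- plant_inverted_repeat_pair(ref, family, "chr1",
                                      start1 = 120000,
                                      start2 = e_anchor - len,
                                      length = len, identity = identity,
                                      seed = 5)
    ev <- simulate_foldback(ref, "chr1", b = e_anchor + 50, min_mh = 12,
                            r_max = len + 100, max_loop = 60000,
                            site_choice = "max_mh")
    # the anneal routes through the diverged repeat copies
    rp <- ref$repeats[nrow(ref$repeats), ]
    expect_true(ev$d >= rp$start1 && ev$d <= rp$end1)
    expect_true(ev$e >= rp$start2 && ev$e <= rp$end2)
    der <- break_dicentric(ref, form_dicentric(ref, ev),
                           p = 60000)$invdup
    der <- resolve_derivative(der, ref, "telomere", tel_mh = 0)
    call <- call_junction(split_align(emit_amplicon(der, "j_disinv", 400),
                                      ref), ref)
    expect_identical(call$type, "disomy_inversion")
    hy <- detect_hybrid_repeat(call, ref)
    expect_false(is.null(hy))
    expect_identical(hy$family, family)
    expect_identical(hy$homology_length, as.numeric(len))
    expect_lt(abs(hy$identity - identity), 0.02)
    call
  }
  run_repeat_case(ref, "AluLike", 296, 0.90)
  run_repeat_case(ref, "L1Like", 330, 0.95)
  # a junction away from any annotation yields no call
  fx <- make_event_fixture(L = 1e5, spacer = 1500, mh = 4, deletion = 1e4,
                           telomere_units = 10)
  der <- build_derivative(fx, mode = "telomere", tel_mh = 0)
  cp <- call_junction(split_align(emit_amplicon(der, "j_disinv", 400),
                                  fx$ref), fx$ref)
  expect_null(detect_hybrid_repeat(cp, fx$ref))
})

test_that("CGH segmentation measures spacers only at sufficient resolution", {
  fx <- make_event_fixture(L = 5e6, spacer = 3428, mh = 4, deletion = 1e6,
                           telomere_units = 10)
  der <- build_derivative(fx, mode = "telomere", tel_mh = 0)
  tr <- rearrangement_truth(der)
  # noise-free high-resolution array
  sg <- segment_cgh(simulate_cgh(tr, probe_spacing = 200, noise_sd = 0,
                                 seed = 1))
  expect_lte(abs(sg$spacer_estimate - 3428), 2 * 200)
  # realistic noise
  sgn <- segment_cgh(simulate_cgh(tr, probe_spacing = 200, noise_sd = 0.15,
                                  seed = 2))
  expect_lte(abs(sgn$spacer_estimate - 3428), 2 * 200)
  # the low-resolution array cannot see the spacer
  sg75 <- segment_cgh(simulate_cgh(tr, probe_spacing = 75000, noise_sd = 0,
                                   seed = 3))
  expect_true(is.na(sg75$spacer_estimate))
  # an all-noise profile is a single disomic segment
  flat <- structure(list(probes = data.frame(
    chrom = "chr1", pos = seq(0, 2e5, 200),
    log2 = rnorm(length(seq(0, 2e5, 200)), 0, 0.1)),
    probe_spacing = 200, noise_sd = 0.1), class = "cgh_profile")
  sf <- segment_cgh(flat)
  expect_identical(sf$segments$state, "disomic")
  expect_true(is.na(sf$spacer_estimate))
})

test_that("discordant pairs cluster at rearrangement junctions", {
  fx <- make_event_fixture(L = 1e5, spacer = 3000, mh = 4, deletion = 1e4,
                           telomere_units = 10)
  der <- build_derivative(fx, mode = "telomere", tel_mh = 0)
  rd <- simulate_paired_end_reads(der, coverage = 30, seed = 7)
  cl <- cluster_discordant_pairs(rd, insert_mean = 400, insert_sd = 40)
  inv <- cl[cl$signature == "inverted_orientation", ]
  expect_identical(nrow(inv), 1L)
  expect_lt(abs(inv$bp_end - fx$e), 400 + 1)
  # concordant-only input clusters nothing
  conc <- data.frame(pair = c("a", "b"), chrom1 = "chr1",
                     start1 = c(1000, 5000), end1 = c(1100, 5100),
                     strand1 = "+", chrom2 = "chr1",
                     start2 = c(1300, 5290), end2 = c(1400, 5390),
                     strand2 = "-")
  expect_identical(nrow(cluster_discordant_pairs(conc, 400, 40)), 0L)
  # a translocation derivative yields an inter-chromosomal cluster
  dtr <- build_derivative(fx, mode = "translocation", donor_chrom = "chr2",
                          donor_seg = 3e4)
  rdt <- simulate_paired_end_reads(dtr, coverage = 30, seed = 8)
  clt <- cluster_discordant_pairs(rdt, 400, 40)
  expect_gte(sum(clt$signature == "interchromosomal"), 1L)
})

test_that("microsatellite logic infers parental origin with caveats", {
  row <- function(marker, region, person, a1, a2, h1 = 100, h2 = 100)
    data.frame(marker = marker, region = region, person = person,
               allele1 = a1, allele2 = a2, height1 = h1, height2 = h2,
               stringsAsFactors = FALSE)
  # hand-enumerated configurations and their expected calls
  cases <- list(
    list(rows = rbind(row("m1", "duplicated", "child", "A", "B", 100, 210),
                      row("m1", "duplicated", "mother", "A", "A"),
                      row("m1", "duplicated", "father", "B", "B")),
         expect = "paternal_dup"),
    list(rows = rbind(row("m2", "duplicated", "child", "A", "B", 205, 100),
                      row("m2", "duplicated", "mother", "A", "B"),
                      row("m2", "duplicated", "father", "B", "B")),
         expect = "maternal_dup"),   # doubled A only in the mother
    list(rows = rbind(row("m3", "duplicated", "child", "A", "B", 200, 100),
                      row("m3", "duplicated", "mother", "A", "B"),
                      row("m3", "duplicated", "father", "A", "B")),
         expect = "U"),
    list(rows = rbind(row("m4", "duplicated", "child", "A", "B", 100, 105),
                      row("m4", "duplicated", "mother", "A", "A"),
                      row("m4", "duplicated", "father", "B", "B")),
         expect = "U"),              # no dosage signal
    list(rows = rbind(row("m5", "deleted", "child", "A", NA),
                      row("m5", "deleted", "mother", "A", "A"),
                      row("m5", "deleted", "father", "B", "B")),
         expect = "paternal_del"),
    list(rows = rbind(row("m6", "deleted", "child", "B", NA),
                      row("m6", "deleted", "mother", "A", "A"),
                      row("m6", "deleted", "father", "B", "B")),
         expect = "maternal_del"),
    list(rows = rbind(row("m7", "deleted", "child", "A", NA),
                      row("m7", "deleted", "mother", "A", "B"),
                      row("m7", "deleted", "father", "A", "B")),
         expect = "U"),
    list(rows = rbind(row("m8", "deleted", "child", "C", NA),
                      row("m8", "deleted", "mother", "A", "A"),
                      row("m8", "deleted", "father", "B", "B")),
         expect = "inconsistent"))
  for (cs in cases) {
    res <- infer_parental_origin(cs$rows)
    expect_identical(res$per_marker$call, cs$expect)
  }
  # untyped father: retention of the maternal allele gives a caveated call
  one_parent <- rbind(row("m9", "deleted", "child", "A", NA),
                      row("m9", "deleted", "mother", "A", "B"))
  res <- infer_parental_origin(one_parent)
  expect_identical(res$per_marker$call, "paternal_del?")
  expect_true(res$summary$caveat)
  expect_identical(res$summary$origin, "paternal")
  # a jointly informative family majority-calls a paternal origin
  fam <- rbind(cases[[1]]$rows, cases[[5]]$rows, cases[[3]]$rows)
  out <- infer_parental_origin(fam)
  expect_identical(out$summary$origin, "paternal")
  expect_identical(out$summary$n_informative, 2L)
})
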