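# End-to-end orchestration: simulate a genome and a cohort of fold-back
# events, analyze the resulting amplicons, run the microhomology null model,
# and write all outputs (with a manifest) under one run directory. Every
# stochastic stage is seeded from the single top-level seed via
# derive_seed(), so stages are independently reproducible and a rerun with
# the same configuration is byte-identical.

#' Default run configuration
#'
#' @param seed Top-level seed.
#' @return Nested configuration list (genome plan, event plan, analyzer and
#'   null-model parameters); every field may be overridden before passing to
#'   [run_foldback_study()].
#' @export
default_config <- function(seed = 20140130L) {
  list(
    seed = as.integer(seed),
    genome = list(
      lengths = c(chrA = 2e6, chrB = 1e6),
      base_composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
      telomere_units = 100L,
      repeat_plan = NULL),
    events = list(
      n = 20L,
      # resolution-mode mix: mostly telomere healing, some translocations
      # and rings, echoing the cohort's outcome mix
      modes = c(telomere = 0.6, translocation = 0.25, ring = 0.15),
      spacer_range = c(700, 70466),   # bp; sequenced-spacer range
      mh_range = 2:8,                 # bp; observed junction microhomology
      deletion_range = c(1e5, 5e5),   # bp; scaled-down terminal deletions
      dup_min = 1e4,                  # bp; minimum duplication size
      insertion_fraction = 0.25,
      insertion_kinds = c("templated_direct", "templated_inverted",
                          "slippage", "mitochondrial"),
      tel_mh_range = 0:4,
      donor_seg = 5e4),
    analyzer = list(min_anchor = 20L, flank = 400L, window = 1000L,
                    cgh_w = 5L),
    null = list(n = 1000L, max_len = 70466L, max_dist_from_end = 1e6,
                min_len = 100L, threshold = 2L))
}

draw_event_plan <- function(ref, cfg, seed) {
  # draw per-event geometry; anneal sites are planted afterwards, before any
  # derivative is constructed, so all events live on one final reference
  ev_cfg <- cfg$events
  chroms <- names(ref$seqs)
  with_seed(seed, {
    plans <- list()
    taken <- list()  # planted regions per chromosome, to avoid overlap
    for (i in seq_len(ev_cfg$n)) {
      for (try in 1:50) {
        chrom <- chroms[sample.int(length(chroms), 1L)]
        L <- ref_len(ref, chrom)
        cen <- ref$centromere[[chrom]]
        del <- floor(stats::runif(1, ev_cfg$deletion_range[1],
                                  min(ev_cfg$deletion_range[2], L / 3)))
        b <- L - del
        # cohort-scale fold-back loops: log-uniform over the sequenced
        # spacer range
        s <- floor(exp(stats::runif(1, log(ev_cfg$spacer_range[1]),
                                    log(ev_cfg$spacer_range[2]))))
        k <- sample(ev_cfg$mh_range, 1L)
        r <- sample.int(500L, 1L)        # modeled resection beyond the anneal
        e <- b - r; d <- e - s
        p_lo <- cen + 1; p_hi <- d - ev_cfg$dup_min
        if (d <= cen + ev_cfg$dup_min + 2 || p_hi <= p_lo) next
        p <- floor(stats::runif(1, p_lo, p_hi))
        reg <- c(d - 2, d + k + 2, e - k - 2, e + 2)
        clash <- any(vapply(taken[[chrom]] %||% list(), function(tk)
          min(reg[c(2, 4)], tk[c(2, 4)]) + 400 > max(reg[c(1, 3)], tk[c(1, 3)]) &&
            max(reg[1], tk[1]) <= min(reg[4], tk[4]) + 400, logical(1)))
        if (clash) next
        taken[[chrom]] <- c(taken[[chrom]] %||% list(), list(reg))
        mode <- sample(names(ev_cfg$modes), 1L, prob = ev_cfg$modes)
        ins <- NULL
        if (stats::runif(1) < ev_cfg$insertion_fraction) {
          kind <- sample(ev_cfg$insertion_kinds, 1L)
          len <- if (kind == "slippage") sample(4:10, 1L)
                 else sample(10:70, 1L)
          ins <- list(kind = kind, len = len)
        }
        plans[[i]] <- list(chrom = chrom, b = b, d = d, e = e, p = p,
                           mh = k, mode = mode,
                           tel_mh = sample(ev_cfg$tel_mh_range, 1L),
                           insertion = ins,
                           ins_seed = sample.int(2^30, 1L))
        break
      }
      if (length(plans) < i)
        stop_foldback("could not place all events without overlap",
                      "foldback_placement_error")
    }
    plans
  })
}

build_event <- function(ref, plan, cfg) {
  ev_cfg <- cfg$events
  event <- foldback_event(ref, plan$chrom, d = plan$d, e = plan$e, b = plan$b)
  der <- break_dicentric(ref, form_dicentric(ref, event), plan$p)$invdup
  donor <- setdiff(names(ref$seqs), plan$chrom)
  der <- switch(plan$mode,
    telomere = resolve_derivative(der, ref, "telomere", tel_mh = plan$tel_mh),
    translocation = if (length(donor) > 0)
      resolve_derivative(der, ref, "translocation", donor_chrom = donor[1L],
                         donor_seg = ev_cfg$donor_seg)
      else resolve_derivative(der, ref, "telomere", tel_mh = 0L),
    ring = resolve_derivative(der, ref, "ring"))
  if (!is.null(plan$insertion)) {
    kind <- plan$insertion$kind
    # slippage is placed at the telomere junction (where it is observed); at
    # a disomy-inversion junction a local duplication is partly absorbed
    # into the junction microhomology
    target <- if (kind == "slippage" && der$resolution == "telomere")
      "j_invtel" else "j_disinv"
    der <- add_complex_insertion(der, ref, target, kind,
                                 plan$insertion$len,
                                 window = cfg$analyzer$window,
                                 seed = plan$ins_seed)
  }
  der
}

#' Simulate a cohort of fold-back rearrangements
#'
#' Draws per-event geometry (terminal deletion size, fold-back loop size
#' log-uniform over the sequenced spacer range, anneal microhomology,
#' resolution mode, optional junction insertion), plants the anneal sites in
#' the reference, and constructs each derivative. Because sites are planted
#' before any derivative is built, all events share one final reference.
#'
#' @param ref A `reference_genome`.
#' @param config Configuration from [default_config()].
#' @return List with `ref` (the reference carrying the planted sites) and
#'   `derivatives` (named list of `derivative` objects, `event_01`, ...).
#' @export
simulate_cohort <- function(ref, config = default_config()) {
  plans <- draw_event_plan(ref, config,
                           derive_seed(config$seed, "event_plan"))
  for (pl in plans)
    ref <- plant_anneal_site(ref, pl$chrom, pl$d, pl$e, pl$mh)
  ders <- list()
  for (i in seq_along(plans)) {
    ders[[sprintf("event_%02d", i)]] <- build_event(ref, plans[[i]], config)
  }
  list(ref = ref, derivatives = ders)
}

#' Analyze the amplicons of simulated derivatives and evaluate against truth
#'
#' Emits each junction's amplicon, runs split alignment and junction
#' calling, classifies insertions, and compares calls with simulator truth.
#'
#' @param ders Named list of `derivative`s from [simulate_cohort()].
#' @param ref A `reference_genome`.
#' @param config Configuration list.
#' @return List with `calls` (per-junction data frame) and `evaluation`
#'   (type accuracy, exact-spacer rate, microhomology agreement, insertion
#'   recovery).
#' @export
analyze_cohort <- function(ders, ref, config = default_config()) {
  rows <- list()
  for (nm in names(ders)) {
    der <- ders[[nm]]
    for (ji in seq_len(nrow(der$junctions))) {
      jrow <- der$junctions[ji, ]
      if (jrow$type == "ring_fusion") next   # taxonomy covers the three
                                             # sequenced junction classes
      amp <- emit_amplicon(der, jrow$id, flank = config$analyzer$flank)
      call <- call_junction(split_align(amp, ref,
                                        config$analyzer$min_anchor), ref)
      ins_kind_called <- NA_character_
      if (!is.na(call$insertion)) {
        orig <- classify_insertion_origin(
          call$insertion, ref,
          list(list(chrom = call$left_chrom, pos = call$left_pos),
               list(chrom = call$right_chrom, pos = call$right_pos)),
          window = config$analyzer$window)
        ins_kind_called <- orig$kind
      }
      rows[[length(rows) + 1L]] <- data.frame(
        event = nm, junction = jrow$id,
        truth_type = jrow$type, called_type = call$type,
        truth_spacer = jrow$spacer, called_spacer = call$spacer,
        truth_mh = jrow$mh, called_mh = call$mh_len,
        truth_ins_kind = jrow$ins_kind,
        truth_ins_len = jrow$ins_len,
        called_ins_kind = ins_kind_called,
        called_ins_len = ifelse(is.na(call$insertion), 0L,
                                nchar(call$insertion)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(list(calls = data.frame(), evaluation = list(n_junctions = 0L)))
  calls <- do.call(rbind, rows)
  insfree <- is.na(calls$truth_ins_kind)
  di <- insfree & calls$truth_type == "disomy_inversion"
  # slippage is junction-local direct-orientation templating
  kind_match <- function(truth, called) {
    truth2 <- ifelse(truth == "slippage", "templated_direct", truth)
    truth2 == called
  }
  with_ins10 <- !insfree & calls$truth_ins_len >= 10L
  evaluation <- list(
    n_junctions = nrow(calls),
    type_accuracy = mean(calls$called_type[insfree] ==
                           calls$truth_type[insfree]),
    spacer_exact = if (any(di))
      mean(calls$called_spacer[di] == calls$truth_spacer[di]) else NA,
    mh_agreement = if (any(di))
      mean(calls$called_mh[di] == calls$truth_mh[di]) else NA,
    insertion_recovery = if (any(with_ins10))
      mean(kind_match(calls$truth_ins_kind[with_ins10],
                      calls$called_ins_kind[with_ins10])) else NA)
  list(calls = calls, evaluation = evaluation)
}

write_truth_json <- function(ders, path) {
  truths <- lapply(ders, function(d) unclass(rearrangement_truth(d)))
  jsonlite::write_json(truths, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Run the full study: simulate, analyze, null model, report
#'
#' Writes genome FASTA/BED, derivative FASTA, truth JSON, amplicon FASTA,
#' read-pair and CGH TSVs, junction calls, null-model results and a manifest
#' (file list + md5 digests + config echo) under `outdir`. Rerunning with
#' the same configuration reproduces identical digests.
#'
#' @param config Configuration from [default_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the manifest, the evaluation and the
#'   enrichment result.
#' @export
run_foldback_study <- function(config = default_config(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(outdir, ...)

  ref <- generate_reference(config$genome$lengths,
                            config$genome$base_composition,
                            config$genome$telomere_units,
                            repeat_plan = config$genome$repeat_plan,
                            seed = derive_seed(config$seed, "genome"))
  sim <- simulate_cohort(ref, config)
  ref <- sim$ref
  ders <- sim$derivatives
  write_genome(ref, pth("genome.fa"), pth("genome.bed"))
  write_fasta(lapply(ders, `[[`, "seq"), pth("derivatives.fa"))
  write_truth_json(ders, pth("truth.json"))
  amps <- list()
  for (nm in names(ders)) {
    for (id in ders[[nm]]$junctions$id) {
      if (ders[[nm]]$junctions$type[ders[[nm]]$junctions$id == id] ==
          "ring_fusion") next
      amps[[paste(nm, id, sep = ".")]] <-
        as.character(emit_amplicon(ders[[nm]], id, config$analyzer$flank))
    }
  }
  write_fasta(amps, pth("amplicons.fa"))

  first <- ders[[1L]]
  reads <- simulate_paired_end_reads(
    first, seed = derive_seed(config$seed, "reads"))
  utils::write.table(reads, pth("read_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cgh <- simulate_cgh(rearrangement_truth(first),
                      seed = derive_seed(config$seed, "cgh"))
  utils::write.table(cgh$probes, pth("cgh_profile.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ana <- analyze_cohort(ders, ref, config)
  utils::write.table(ana$calls, pth("junction_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  spacers <- draw_spacers(ref, config$null$n, config$null$max_len,
                          config$null$max_dist_from_end,
                          config$null$min_len,
                          seed = derive_seed(config$seed, "null"))
  null <- null_distribution(ref, spacers, config$null$threshold)
  enr <- enrichment_test(null, m = 13L)
  jsonlite::write_json(
    list(n = null$n, counts = as.list(null$counts),
         threshold = null$threshold, c = null$c, m = enr$m, p = enr$p,
         length_distribution = "uniform",
         config = config["null"], seed = derive_seed(config$seed, "null")),
    pth("null_model.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    config = config,
    files = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(pth(f)))))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, evaluation = ana$evaluation,
                 enrichment = enr, ref = ref, derivatives = ders))
}
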