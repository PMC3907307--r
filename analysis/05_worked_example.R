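#!/usr/bin/env Rscript
# Worked example at full cohort scale: a fold-back event with a 5,803,294-bp
# terminal deletion, 41,659,284-bp inverted duplication and 2,047-bp disomic
# spacer on a 50-Mb synthetic chromosome, healed by telomere addition; the
# junction analyzer recovers the spacer exactly from an 800-bp amplicon.
#
#   Rscript analysis/05_worked_example.R [seed]

suppressPackageStartupMessages(library(foldback))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 20140130L
dir.create("results/worked_example", recursive = TRUE, showWarnings = FALSE)

L <- 50e6
ref <- generate_reference(c(chr2s = L), telomere_units = 500,
                          centromere = c(chr2s = 2e6),
                          seed = derive_seed(seed, "genome"))
e <- L - 5803294
d <- e - 2047
p <- d - 41659284
ref <- plant_anneal_site(ref, "chr2s", d, e, mh = 4)
event <- foldback_event(ref, "chr2s", d = d, e = e)
der <- break_dicentric(ref, form_dicentric(ref, event), p)$invdup
der <- resolve_derivative(der, ref, "telomere", tel_mh = 2)
truth <- rearrangement_truth(der)

amp <- emit_amplicon(der, "j_disinv", flank = 400)
call <- call_junction(split_align(amp, ref), ref)

write_fasta(list(disomy_inversion_amplicon = as.character(amp)),
            "results/worked_example/amplicon.fa")
jsonlite::write_json(
  list(truth = list(deletion = truth$deletion_size,
                    duplication = truth$dup_size,
                    spacer = truth$spacer_size, mh = truth$mh_len),
       call = list(type = call$type, spacer = call$spacer,
                   mh = call$mh_len, e = call$e, d = call$d)),
  "results/worked_example/roundtrip.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

message(sprintf("truth:  deletion %s bp, duplication %s bp, spacer %s bp, mh %d bp",
                format(truth$deletion_size, big.mark = ","),
                format(truth$dup_size, big.mark = ","),
                format(truth$spacer_size, big.mark = ","), truth$mh_len))
message(sprintf("called: %s junction, spacer %s bp, mh %d bp",
                call$type, format(call$spacer, big.mark = ","), call$mh_len))
message("outputs in results/worked_example/")
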