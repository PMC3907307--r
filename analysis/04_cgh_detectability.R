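#!/usr/bin/env Rscript
# Array-CGH detectability of disomic spacers: the same simulated
# rearrangement (3,428-bp spacer) probed at 200-bp spacing (the
# high-resolution custom arrays) and at 75-kb spacing (earlier genome-wide
# arrays). The spacer is measurable only on the dense design.
#
#   Rscript analysis/04_cgh_detectability.R [seed]

suppressPackageStartupMessages(library(foldback))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 20140130L
dir.create("results/cgh", recursive = TRUE, showWarnings = FALSE)

L <- 8e6
ref <- generate_reference(c(chr1 = L), telomere_units = 10,
                          seed = derive_seed(seed, "cgh_genome"))
e <- L - 2e6
d <- e - 3428
ref <- plant_anneal_site(ref, "chr1", d, e, mh = 4)
ev <- foldback_event(ref, "chr1", d = d, e = e)
der <- break_dicentric(ref, form_dicentric(ref, ev), p = d - 2.5e6)$invdup
der <- resolve_derivative(der, ref, "telomere", tel_mh = 0)
truth <- rearrangement_truth(der)

rows <- list()
for (spacing in c(200, 75000)) {
  prof <- simulate_cgh(truth, probe_spacing = spacing, noise_sd = 0.1,
                       seed = derive_seed(seed, paste0("cgh_", spacing)))
  seg <- segment_cgh(prof)
  n_in <- sum(prof$probes$pos >= truth$spacer_start &
                prof$probes$pos < truth$spacer_end)
  rows[[length(rows) + 1]] <- data.frame(
    probe_spacing = spacing, probes_in_spacer = n_in,
    spacer_estimate = seg$spacer_estimate,
    truth_spacer = truth$spacer_size)
  utils::write.table(seg$probes,
                     sprintf("results/cgh/profile_%dbp.tsv", spacing),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
tab <- do.call(rbind, rows)
utils::write.table(tab, "results/cgh/detectability.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

for (i in seq_len(nrow(tab))) {
  message(sprintf(
    "spacing %6d bp: %3d probes in the %d-bp spacer; estimate: %s",
    tab$probe_spacing[i], tab$probes_in_spacer[i], tab$truth_spacer[i],
    ifelse(is.na(tab$spacer_estimate[i]), "spacer not detected",
           paste0(tab$spacer_estimate[i], " bp"))))
}
message("outputs in results/cgh/")
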