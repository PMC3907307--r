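#!/usr/bin/env Rscript
# Summary statistics over the packaged breakpoint-junction cohort table:
# spacer sizes of sequenced disomy-inversion junctions and junction counts
# per class.
#
#   Rscript analysis/03_cohort_stats.R

suppressPackageStartupMessages(library(foldback))
dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)

tb <- cohort_table()
st <- cohort_stats(tb)

jsonlite::write_json(
  list(n_subjects = st$n_subjects,
       spacer_median = st$spacer_median, spacer_min = st$spacer_min,
       spacer_max = st$spacer_max, spacer_lt_15kb = st$spacer_lt_15kb,
       junction_counts = st$junction_counts,
       per_chrom = as.list(st$per_chrom)),
  "results/cohort/cohort_summary.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
utils::write.table(tb[order(-tb$spacer_bp), ],
                   "results/cohort/cohort_sorted_by_spacer.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

message(sprintf("%d subjects; %d sequenced junctions (%d dis-inv, %d inv-tel, %d inv-tra)",
                st$n_subjects, st$junction_counts$total,
                st$junction_counts$dis_inv, st$junction_counts$inv_tel,
                st$junction_counts$inv_tra))
message(sprintf("disomy-inversion spacers: median %s bp, range %s-%s bp; %d/%d under 15 kb",
                format(st$spacer_median, big.mark = ","),
                format(st$spacer_min, big.mark = ","),
                format(st$spacer_max, big.mark = ","),
                st$spacer_lt_15kb, st$junction_counts$dis_inv))
message("outputs in results/cohort/")
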