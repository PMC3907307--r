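# Inverted-microhomology null model: random spacers drawn near chromosome
# ends, per-spacer inverted microhomology between the spacer's two ends, and
# the combinatorial empirical p-value for enrichment at observed junctions;
# plus summary statistics over the packaged breakpoint-junction cohort table.

#' Draw random spacer intervals near chromosome q-termini
#'
#' Spacer lengths are uniform on `[min_len, max_len)` (the cohort fixes only
#' the upper bound, the longest sequenced spacer; the uniform choice is
#' declared in output metadata) and the distal spacer end is uniform within
#' `max_dist_from_end` bp of the q-terminus of a uniformly chosen
#' chromosome. Chromosomes shorter than `max_dist_from_end` are excluded.
#'
#' @param ref A `reference_genome`.
#' @param n Number of spacers.
#' @param max_len Maximum spacer length (bp); default 70,466, the maximum
#'   sequenced spacer.
#' @param max_dist_from_end Maximum distance of the distal spacer end from
#'   the chromosome end (bp); default 5.5 Mb, the cohort's median terminal
#'   deletion.
#' @param min_len Minimum spacer length (default 100).
#' @param seed Seed.
#' @return Data frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
draw_spacers <- function(ref, n, max_len = 70466L,
                         max_dist_from_end = 5.5e6, min_len = 100L,
                         seed = NULL) {
  if (max_len < 2 || min_len < 2 || min_len >= max_len)
    stop_foldback("need 2 <= min_len < max_len", "foldback_range_error")
  if (max_dist_from_end < max_len)
    stop_foldback("max_dist_from_end must be >= max_len",
                  "foldback_range_error")
  lens <- vapply(ref$seqs, nchar, integer(1))
  eligible <- names(lens)[lens >= max_dist_from_end]
  if (length(eligible) == 0)
    stop_foldback("no chromosome is at least max_dist_from_end long",
                  "foldback_range_error")
  with_seed(seed, {
    chrom <- eligible[sample.int(length(eligible), n, replace = TRUE)]
    len <- floor(stats::runif(n, min_len, max_len))
    # distal end within max_dist_from_end of the q-terminus, interval inside
    # the chromosome
    L <- lens[chrom]
    end <- L - floor(stats::runif(n, 0, pmin(max_dist_from_end, L) - len + 1))
    data.frame(chrom = chrom, start = end - len, end = end,
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

#' Tabulate the inverted-microhomology null distribution
#'
#' Applies the inverted-microhomology operator (basepairs shared between the
#' 3' end of each spacer and the reverse complement of its 5' end, exact
#' matching) to each interval and tabulates counts per microhomology length
#' `k`, along with `c`, the number of spacers at or above the threshold.
#'
#' @param ref A `reference_genome`.
#' @param intervals Data frame from [draw_spacers()] (`chrom`, `start`,
#'   `end`).
#' @param threshold Threshold for `c` (default 2 bp, the minimum
#'   microhomology among sequenced disomy-inversion junctions).
#' @return A `mh_null` object: `n`, `draws` (intervals plus `k`), `counts`
#'   (named vector over `k`), `threshold`, `c`.
#' @export
null_distribution <- function(ref, intervals, threshold = 2L) {
  k <- vapply(seq_len(nrow(intervals)), function(i)
    inverted_mh_pair(ref, intervals$chrom[i],
                     e = intervals$end[i], d = intervals$start[i]),
    integer(1))
  draws <- intervals
  draws$k <- k
  counts <- table(factor(k, levels = 0:max(c(k, threshold))))
  structure(list(n = nrow(draws), draws = draws,
                 counts = stats::setNames(as.integer(counts),
                                          names(counts)),
                 threshold = as.integer(threshold),
                 c = sum(k >= threshold)),
            class = "mh_null")
}

#' @export
print.mh_null <- function(x, ...) {
  cat(sprintf("mh_null: %d simulated spacers; %d (%.1f%%) with k >= %d\n",
              x$n, x$c, 100 * x$c / x$n, x$threshold))
  print(x$counts)
  invisible(x)
}

#' Combinatorial empirical p-value for inverted-microhomology enrichment
#'
#' The ratio of the number of distinct `m`-junction groups that can be
#' formed from the `c` simulated junctions at or above the microhomology
#' threshold to the number formable from all `n` simulated junctions:
#' `C(c, m) / C(n, m)`, computed as the product of `(c - i) / (n - i)` for
#' `i = 0..m-1` for numerical stability. This estimates the probability that
#' all `m` observed junctions would reach the threshold by chance.
#'
#' @param c Simulated junctions at or above the threshold (`0 <= c <= n`).
#' @param n Total simulated junctions.
#' @param m Observed junctions (`1 <= m <= n`).
#' @return The empirical p-value in `[0, 1]` (0 when `c < m`).
#' @export
#' @examples
#' empirical_p(134, 1000, 13)  # ~2.7e-12
empirical_p <- function(c, n, m) {
  stopifnot(length(c) == 1, length(n) == 1, length(m) == 1)
  if (m > n) stop_foldback("m must not exceed n", "foldback_domain_error")
  if (!(c >= 0 && c <= n && m >= 1))
    stop_foldback("require 0 <= c <= n and m >= 1", "foldback_domain_error")
  if (c < m) return(0)
  i <- 0:(m - 1)
  prod((c - i) / (n - i))
}

#' Enrichment of inverted microhomology at observed junctions
#'
#' @param null A `mh_null`.
#' @param m Number of observed junctions at or above the null's threshold.
#' @return An `enrichment_result`: `m`, `threshold`, `c`, `n`, `p`.
#' @export
enrichment_test <- function(null, m) {
  structure(list(m = as.integer(m), threshold = null$threshold,
                 c = null$c, n = null$n,
                 p = empirical_p(null$c, null$n, m)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: %d/%d simulated spacers with k >= %d; m = %d observed; p = %.3g\n",
    x$c, x$n, x$threshold, x$m, x$p))
  invisible(x)
}

# --- cohort table -----------------------------------------------------------

#' Load the packaged breakpoint-junction cohort table
#'
#' The 25 subjects with sequenced breakpoint junctions: deletion,
#' duplication and spacer sizes in bp and indicators for sequenced
#' disomy-inversion, inversion-telomere and inversion-translocation
#' junctions.
#'
#' @param path Optional path to an alternative TSV with the same columns.
#' @return Data frame with columns `subject`, `chrom`, `cnv_type`,
#'   `deletion_bp`, `duplication_bp`, `spacer_bp`, `capture_method`,
#'   `inheritance`, `dis_inv`, `inv_tel`, `inv_tra`.
#' @export
cohort_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cohort_junctions.tsv",
                                package = "foldback", mustWork = TRUE)
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject", "spacer_bp", "dis_inv", "inv_tel", "inv_tra")
                %in% names(tb)),
            all(tb$spacer_bp > 0),
            all(tb$dis_inv %in% 0:1), all(tb$inv_tel %in% 0:1),
            all(tb$inv_tra %in% 0:1))
  tb
}

#' Cohort summary statistics
#'
#' Over subjects with a sequenced disomy-inversion junction: median, minimum
#' and maximum spacer size; junction counts per class and in total.
#'
#' @param table Cohort data frame as returned by [cohort_table()].
#' @return List of summaries; when no disomy-inversion junction is present,
#'   `has_disomy_inversion` is `FALSE` and no spacer statistics are emitted.
#' @export
cohort_stats <- function(table) {
  stopifnot(nrow(table) > 0)
  di <- table[table$dis_inv == 1, , drop = FALSE]
  counts <- list(dis_inv = sum(table$dis_inv),
                 inv_tel = sum(table$inv_tel),
                 inv_tra = sum(table$inv_tra))
  counts$total <- counts$dis_inv + counts$inv_tel + counts$inv_tra
  if (nrow(di) == 0)
    return(list(has_disomy_inversion = FALSE, junction_counts = counts,
                n_subjects = nrow(table)))
  list(has_disomy_inversion = TRUE,
       n_subjects = nrow(table),
       spacer_median = stats::median(di$spacer_bp),
       spacer_min = min(di$spacer_bp),
       spacer_max = max(di$spacer_bp),
       spacer_lt_15kb = sum(di$spacer_bp < 15000),
       junction_counts = counts,
       per_chrom = table(table$chrom))
}
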