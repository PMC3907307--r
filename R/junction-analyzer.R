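# Analysis of breakpoint junction sequences: split alignment against the
# reference, junction classification (disomy-inversion, inversion-telomere,
# inversion-translocation), microhomology and insertion calling with the
# maximal-shift breakpoint convention, insertion-origin classification,
# hybrid-repeat detection, CGH segmentation, discordant-pair clustering and
# microsatellite parent-of-origin inference.

# --- split alignment --------------------------------------------------------

extend_run <- function(ok, lo, hi) {
  # maximal run of TRUE containing [lo, hi] (1-based indices into ok)
  a <- lo
  while (a > 1L && ok[a - 1L]) a <- a - 1L
  b <- hi
  while (b < length(ok) && ok[b + 1L]) b <- b + 1L
  c(a, b)
}

align_one_seed <- function(amp_chars, seed, q0, ref, max_hits = 50L) {
  # q0: 0-based query offset of the seed; returns the longest ungapped exact
  # extension over all chromosomes and strands, or NULL
  n <- length(amp_chars)
  k <- nchar(seed)
  best <- NULL
  consider <- function(cand) {
    if (is.null(best) || cand$len > best$len ||
        (cand$len == best$len && cand$ref_start < best$ref_start))
      best <<- cand
  }
  for (ch in names(ref$seqs)) {
    subject <- Biostrings::DNAString(ref$seqs[[ch]])
    Lc <- length(subject)
    plus_hits <- Biostrings::start(
      Biostrings::matchPattern(seed, subject))
    minus_hits <- Biostrings::start(
      Biostrings::matchPattern(revcomp(seed), subject))
    if (length(plus_hits) > max_hits) plus_hits <- plus_hits[seq_len(max_hits)]
    if (length(minus_hits) > max_hits) minus_hits <- minus_hits[seq_len(max_hits)]
    for (h in plus_hits) {
      rs <- h - 1L                      # 0-based ref start of the seed match
      c0 <- rs - q0                     # diagonal: query i <-> ref c0 + i
      qlo <- max(0L, -c0); qhi <- min(n, Lc - c0)
      ref_chars <- strsplit(substr(ref$seqs[[ch]], c0 + qlo + 1L, c0 + qhi),
                            "", fixed = TRUE)[[1L]]
      ok <- amp_chars[(qlo + 1L):qhi] == ref_chars & ref_chars != "N"
      run <- extend_run(ok, q0 - qlo + 1L, q0 - qlo + k)
      qs <- qlo + run[1L] - 1L; qe <- qlo + run[2L]
      consider(list(q_start = qs, q_end = qe, chrom = ch,
                    ref_start = c0 + qs, ref_end = c0 + qe, strand = "+",
                    diag = c0, len = qe - qs))
    }
    for (h in minus_hits) {
      rs <- h - 1L
      c2 <- rs + k - 1L + q0            # diagonal: query i <-> ref c2 - i
      qlo <- max(0L, c2 - Lc + 1L); qhi <- min(n, c2 + 1L)
      ref_chars <- comp_bases(rev(strsplit(
        substr(ref$seqs[[ch]], c2 - qhi + 2L, c2 - qlo + 1L),
        "", fixed = TRUE)[[1L]]))
      ok <- amp_chars[(qlo + 1L):qhi] == ref_chars & ref_chars != "N"
      run <- extend_run(ok, q0 - qlo + 1L, q0 - qlo + k)
      qs <- qlo + run[1L] - 1L; qe <- qlo + run[2L]
      consider(list(q_start = qs, q_end = qe, chrom = ch,
                    ref_start = c2 - qe + 1L, ref_end = c2 - qs + 1L,
                    strand = "-", diag = c2, len = qe - qs))
    }
  }
  best
}

refpos_at <- function(aln, q) {
  # reference coordinate corresponding to query position q on the
  # alignment's diagonal (0-based)
  if (aln$strand == "+") aln$diag + q else aln$diag - q
}

#' Split-align a junction amplicon against the reference
#'
#' Exact k-mer seeding (`min_anchor` bases from each end of the amplicon)
#' into the reference on both strands, followed by maximal ungapped
#' exact-match extension; returns the two anchored local alignments covering
#' a prefix and a suffix of the amplicon. Their query overlap is candidate
#' microhomology; a query gap is a candidate insertion. A telomeric amplicon
#' end (two or more `TTAGGG`/`CCCTAA` units, any phase) is detected before
#' seeding and reported instead of a reference alignment for that side.
#'
#' @param amplicon Junction amplicon sequence (length >= `2 * min_anchor`).
#' @param ref A `reference_genome`.
#' @param min_anchor Exact seed length per side (default 20 bp; on a
#'   multi-megabase genome a 20-mer anchors by chance with negligible
#'   probability).
#' @return A `split_alignment` object; `resolved` is `FALSE` when fewer than
#'   two anchored alignments were found or the amplicon aligns contiguously.
#' @export
split_align <- function(amplicon, ref, min_anchor = 20L) {
  amplicon <- dna_check(amplicon)
  n <- nchar(amplicon)
  if (n < 2L * min_anchor)
    stop_foldback("amplicon shorter than 2 * min_anchor",
                  "foldback_range_error")
  amp_chars <- strsplit(amplicon, "", fixed = TRUE)[[1L]]
  tel_left <- telomere_run(amplicon, side = "left")
  tel_right <- telomere_run(amplicon, side = "right")

  left <- right <- NULL
  if (tel_left$units < 2L)
    left <- align_one_seed(amp_chars, substr(amplicon, 1L, min_anchor), 0L, ref)
  if (tel_right$units < 2L)
    right <- align_one_seed(amp_chars,
                            substr(amplicon, n - min_anchor + 1L, n),
                            n - min_anchor, ref)

  res <- structure(list(amplicon = amplicon, n = n,
                        left = left, right = right,
                        tel_left = tel_left, tel_right = tel_right,
                        min_anchor = min_anchor,
                        resolved = FALSE, diagnostic = NA_character_),
                   class = "split_alignment")
  left_ok <- !is.null(left) || tel_left$units >= 2L
  right_ok <- !is.null(right) || tel_right$units >= 2L
  if (!left_ok || !right_ok) {
    res$diagnostic <- "fewer than two anchored alignments"
    return(res)
  }
  if (!is.null(left) && !is.null(right) &&
      left$chrom == right$chrom && left$strand == right$strand &&
      left$diag == right$diag) {
    res$diagnostic <- "amplicon aligns contiguously to the reference"
    return(res)
  }
  res$resolved <- TRUE
  res
}

# --- junction classification ------------------------------------------------

junction_call <- function(type, left = NULL, right = NULL, e = NA_real_,
                          d = NA_real_, spacer = NA_real_, mh = NA_integer_,
                          insertion = NA_character_, diagnostic = NA_character_,
                          split = NULL) {
  structure(list(type = type,
                 left_chrom = as.character(left$chrom %||% NA),
                 left_pos = as.numeric(left$pos %||% NA),
                 left_strand = as.character(left$strand %||% NA),
                 right_chrom = as.character(right$chrom %||% NA),
                 right_pos = as.numeric(right$pos %||% NA),
                 right_strand = as.character(right$strand %||% NA),
                 e = as.numeric(e), d = as.numeric(d),
                 spacer = as.numeric(spacer),
                 mh_len = mh, insertion = insertion,
                 diagnostic = diagnostic, split = split),
            class = "junction_call")
}

#' @export
print.junction_call <- function(x, ...) {
  cat("junction_call:", x$type, "\n")
  if (!is.na(x$spacer)) cat("  spacer:", format(x$spacer, big.mark = ","), "bp\n")
  if (!is.na(x$mh_len)) cat("  microhomology:", x$mh_len, "bp\n")
  if (!is.na(x$insertion)) cat("  insertion:", nchar(x$insertion), "bp\n")
  if (!is.na(x$diagnostic)) cat("  diagnostic:", x$diagnostic, "\n")
  invisible(x)
}

#' Classify a split-aligned junction
#'
#' Applies the junction taxonomy in order: (1) a telomeric amplicon side
#' (two or more telomere units) makes the junction inversion-telomere;
#' (2) sides on different chromosomes make it inversion-translocation;
#' (3) sides on one chromosome on opposite strands, with the reverse-side
#' coordinate `d` proximal to the forward-side coordinate `e`, make it
#' disomy-inversion with spacer `s = e - d`. The query overlap of the two
#' alignments is the junction microhomology and a query gap is an insertion;
#' breakpoints are reported with shared bases assigned maximally to the
#' left/forward (disomic) side. Inconsistent geometries return `unresolved`
#' with a diagnostic.
#'
#' @param split A `split_alignment`.
#' @param ref A `reference_genome` (reserved for coordinate checks).
#' @return A `junction_call`.
#' @export
call_junction <- function(split, ref) {
  if (!split$resolved)
    return(junction_call("unresolved", diagnostic = split$diagnostic,
                         split = split))
  n <- split$n
  amp <- split$amplicon

  overlap_or_gap <- function(q_left_end, q_right_start) {
    o <- q_left_end - q_right_start
    ins <- if (o < 0) substr(amp, q_left_end + 1L, q_right_start) else NA_character_
    list(mh = max(0L, as.integer(o)), insertion = ins)
  }

  # rule 1: telomeric side
  if (split$tel_right$units >= 2L || split$tel_left$units >= 2L) {
    tel_on_right <- split$tel_right$units >= 2L
    aln <- if (tel_on_right) split$left else split$right
    if (is.null(aln))
      return(junction_call("unresolved",
                           diagnostic = "telomeric side without a partner alignment",
                           split = split))
    if (tel_on_right) {
      tel_q_start <- n - split$tel_right$run_length
      og <- overlap_or_gap(aln$q_end, tel_q_start)
      bp <- refpos_at(aln, aln$q_end)   # maximal extension; shared bases left
      left <- list(chrom = aln$chrom,
                   pos = if (aln$strand == "+") bp else bp + 1L,
                   strand = aln$strand)
      return(junction_call("inversion_telomere", left = left,
                           right = list(chrom = NA, pos = NA, strand = "+"),
                           mh = og$mh, insertion = og$insertion,
                           split = split))
    } else {
      tel_q_end <- split$tel_left$run_length
      og <- overlap_or_gap(tel_q_end, aln$q_start)
      bp <- refpos_at(aln, aln$q_start)
      right <- list(chrom = aln$chrom,
                    pos = if (aln$strand == "+") bp else bp + 1L,
                    strand = aln$strand)
      return(junction_call("inversion_telomere", right = right,
                           left = list(chrom = NA, pos = NA, strand = "+"),
                           mh = og$mh, insertion = og$insertion,
                           split = split))
    }
  }

  L <- split$left; R <- split$right
  og <- overlap_or_gap(L$q_end, R$q_start)
  left_bp <- refpos_at(L, L$q_end)       # half-open end of left coverage
  left <- list(chrom = L$chrom,
               pos = if (L$strand == "+") left_bp else left_bp + 1L,
               strand = L$strand)
  # right side trimmed by the overlap (or starting after the gap)
  q_right_eff <- max(L$q_end, R$q_start)
  right_bp <- refpos_at(R, q_right_eff)
  right <- list(chrom = R$chrom,
                pos = if (R$strand == "+") right_bp else right_bp + 1L,
                strand = R$strand)

  # rule 2: different chromosomes
  if (L$chrom != R$chrom)
    return(junction_call("inversion_translocation", left = left,
                         right = right, mh = og$mh, insertion = og$insertion,
                         split = split))

  # rule 3: one chromosome, opposite strands, fold-back geometry
  if (L$strand == "+" && R$strand == "-") {
    e_called <- left$pos
    d_called <- right$pos
    if (e_called > d_called)
      return(junction_call("disomy_inversion", left = left, right = right,
                           e = e_called, d = d_called,
                           spacer = e_called - d_called,
                           mh = og$mh, insertion = og$insertion,
                           split = split))
    return(junction_call("unresolved", left = left, right = right,
                         diagnostic = sprintf(
                           "inconsistent geometry: e (%d) <= d (%d)",
                           e_called, d_called), split = split))
  }
  if (L$strand == "-" && R$strand == "+")
    return(junction_call("unresolved", left = left, right = right,
                         diagnostic = "reverse-then-forward geometry (ring-like fusion)",
                         split = split))
  junction_call("unresolved", left = left, right = right,
                diagnostic = "colinear same-strand sides", split = split)
}

# --- insertion origin -------------------------------------------------------

#' Classify the origin of a junction insertion
#'
#' Searches the `window` bp around each breakpoint, in both orientations,
#' for an exact or near-exact (>= 90% identity) copy of the insertion:
#' a hit makes the insertion templated (direct or inverted relative to the
#' reference plus strand). Otherwise the mitochondrial-like donor is
#' searched (circularly, both orientations); otherwise the insertion is
#' untemplated. Insertions shorter than 4 bp carry too little information
#' and are reported as `unclassifiable_short`.
#'
#' @param insertion Inserted sequence (as called in amplicon orientation).
#' @param ref A `reference_genome` (with mito donor, if any).
#' @param breakpoints List of breakpoints, each `list(chrom =, pos =)`;
#'   `chrom = NA` entries (e.g. a telomere side) are skipped.
#' @param window Search window half-width in bp (default 1,000).
#' @return List with `kind` (`templated_direct`, `templated_inverted`,
#'   `mitochondrial`, `untemplated`, `unclassifiable_short`), `chrom`,
#'   `start`, `end`, `orient`, `mismatches`.
#' @export
classify_insertion_origin <- function(insertion, ref, breakpoints,
                                      window = 1000L) {
  insertion <- dna_check(insertion)
  len <- nchar(insertion)
  if (len < 1L) stop_foldback("empty insertion", "foldback_range_error")
  no_hit <- list(kind = "untemplated", chrom = NA_character_,
                 start = NA_real_, end = NA_real_, orient = NA_character_,
                 mismatches = NA_integer_)
  if (len < 4L) { no_hit$kind <- "unclassifiable_short"; return(no_hit) }
  max_mm <- floor(0.1 * len)

  scan_subject <- function(subject_str, offset0) {
    subject <- Biostrings::DNAString(subject_str)
    hits <- list()
    for (orient in c("+", "-")) {
      pat <- if (orient == "+") insertion else revcomp(insertion)
      m <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mm,
                                    with.indels = FALSE)
      if (length(m) > 0) {
        patc <- strsplit(pat, "", fixed = TRUE)[[1L]]
        mm <- vapply(as.character(m), function(v)
          sum(strsplit(v, "", fixed = TRUE)[[1L]] != patc), integer(1),
          USE.NAMES = FALSE)
        i <- which.min(mm)
        hits[[length(hits) + 1L]] <-
          list(start = offset0 + Biostrings::start(m)[i] - 1L,
               end = offset0 + Biostrings::end(m)[i],
               orient = orient, mismatches = mm[i])
      }
    }
    hits
  }

  best <- NULL
  for (bp in breakpoints) {
    if (is.null(bp$chrom) || is.na(bp$chrom)) next
    Lc <- ref_len(ref, bp$chrom)
    lo <- max(0L, bp$pos - window); hi <- min(Lc, bp$pos + window)
    for (h in scan_subject(ref_seq(ref, bp$chrom, lo, hi), lo)) {
      h$chrom <- bp$chrom
      if (is.null(best) || h$mismatches < best$mismatches ||
          (h$mismatches == best$mismatches && h$orient == "+" &&
           best$orient == "-"))
        best <- h
    }
  }
  if (!is.null(best))
    return(list(kind = if (best$orient == "+") "templated_direct"
                       else "templated_inverted",
                chrom = best$chrom, start = best$start, end = best$end,
                orient = best$orient, mismatches = best$mismatches))
  if (!is.null(ref$mito)) {
    circ <- paste0(as.character(ref$mito),
                   substr(as.character(ref$mito), 1L, min(len, nchar(ref$mito))))
    hits <- scan_subject(circ, 0L)
    if (length(hits) > 0) {
      h <- hits[[order(vapply(hits, `[[`, integer(1), "mismatches"))[1L]]]
      return(list(kind = "mitochondrial", chrom = "chrM_like",
                  start = h$start %% nchar(ref$mito), end = h$end,
                  orient = h$orient, mismatches = h$mismatches))
    }
  }
  no_hit
}

# --- hybrid repeats ---------------------------------------------------------

#' Detect a repeat-mediated (hybrid-repeat) disomy-inversion junction
#'
#' When both called breakpoints fall inside the two copies of an annotated
#' inverted repeat pair, the junction has crossed from one repeat copy into
#' the other at homologous sites, creating a hybrid repeat. The two copies
#' are compared (one reverse-complemented; planted divergence is
#' substitution-only, so the comparison is positional) and the homology
#' length and identity reported. Calls are made only for homology of at
#' least 50 bp at identity of at least 0.7.
#'
#' @param call A disomy-inversion `junction_call`.
#' @param ref A `reference_genome` with repeat annotations.
#' @return A list (`family`, `homology_length`, `identity`, copies), or
#'   `NULL` when the junction is not repeat-mediated.
#' @export
detect_hybrid_repeat <- function(call, ref) {
  if (!identical(call$type, "disomy_inversion")) return(NULL)
  rp <- ref$repeats
  if (nrow(rp) == 0) return(NULL)
  for (i in seq_len(nrow(rp))) {
    if (rp$orientation[i] != "inverted" || rp$chrom[i] != call$left_chrom)
      next
    d_in_1 <- call$d >= rp$start1[i] && call$d <= rp$end1[i]
    e_in_2 <- call$e >= rp$start2[i] && call$e <= rp$end2[i]
    d_in_2 <- call$d >= rp$start2[i] && call$d <= rp$end2[i]
    e_in_1 <- call$e >= rp$start1[i] && call$e <= rp$end1[i]
    if (!((d_in_1 && e_in_2) || (d_in_2 && e_in_1))) next
    c1 <- ref_seq(ref, rp$chrom[i], rp$start1[i], rp$end1[i])
    c2 <- ref_seq(ref, rp$chrom[i], rp$start2[i], rp$end2[i])
    a <- strsplit(revcomp(c1), "", fixed = TRUE)[[1L]]
    b <- strsplit(c2, "", fixed = TRUE)[[1L]]
    identity <- mean(a == b)
    if (rp$length[i] >= 50 && identity >= 0.7)
      return(list(family = rp$family[i],
                  homology_length = rp$length[i],
                  identity = identity,
                  copy1 = c(rp$start1[i], rp$end1[i]),
                  copy2 = c(rp$start2[i], rp$end2[i])))
  }
  NULL
}

# --- CGH segmentation -------------------------------------------------------

#' Segment a CGH profile into deleted / disomic / duplicated states
#'
#' Three-state segmentation: the running median of the log2 ratios over a
#' `w`-probe window is thresholded at the midpoints between the theoretical
#' states (`-0.5` between disomic and a heterozygous deletion at `-1`;
#' `+0.29` between disomic and a heterozygous duplication at `+0.585`),
#' then segments shorter than `min_seg` probes are merged into their
#' neighbours. A running median keeps copy-number transitions sharp (a
#' running mean interpolates through the disomic band at a direct
#' duplication-to-deletion boundary, inventing a spacer where none is
#' probed). The spacer estimate is the distance from the most distal
#' duplicated probe to the most proximal deleted probe.
#'
#' @param profile A `cgh_profile` (>= 10 probes).
#' @param w Running-mean window in probes (odd; default 5).
#' @param min_seg Minimum segment length in probes (default 3).
#' @return List with `probes` (plus `state` column), `segments` data frame
#'   and `spacer_estimate` (bp; `NA` when no disomic gap separates
#'   duplication from deletion).
#' @export
segment_cgh <- function(profile, w = 5L, min_seg = 3L) {
  pr <- profile$probes
  if (nrow(pr) < 10L)
    stop_foldback("need at least 10 probes", "foldback_range_error")
  x <- pr$log2
  if (w %% 2L == 0L) w <- w + 1L
  rm <- as.numeric(stats::runmed(x, w, endrule = "median"))
  state <- rep("disomic", length(x))
  state[rm < -0.5] <- "deleted"
  state[rm > log2(3 / 2) / 2] <- "duplicated"
  # merge short segments into the preceding (or following, at the start) one
  repeat {
    r <- rle(state)
    short <- which(r$lengths < min_seg)
    if (length(short) == 0L || length(r$lengths) == 1L) break
    i <- short[1L]
    r$values[i] <- if (i > 1L) r$values[i - 1L] else r$values[i + 1L]
    state <- inverse.rle(r)
  }
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  segments <- data.frame(state = r$values,
                         start_pos = pr$pos[starts],
                         end_pos = pr$pos[ends],
                         n_probes = r$lengths, stringsAsFactors = FALSE)
  dup_pos <- pr$pos[state == "duplicated"]
  del_pos <- pr$pos[state == "deleted"]
  est <- if (length(dup_pos) > 0 && length(del_pos) > 0 &&
             min(del_pos) > max(dup_pos) &&
             any(state == "disomic" & pr$pos > max(dup_pos) &
                 pr$pos < min(del_pos)))
    min(del_pos) - max(dup_pos) else NA_real_
  pr$state <- state
  list(probes = pr, segments = segments, spacer_estimate = est)
}

# --- discordant-pair clustering ---------------------------------------------

#' Cluster discordant read pairs into candidate breakpoints
#'
#' A pair is discordant when its reference-space span falls outside
#' `insert_mean +/- 4 * insert_sd`, the two reads are not in
#' forward-reverse orientation, their order is inverted, or they map to
#' different chromosomes. Discordant pairs sharing a discordance signature,
#' chromosome pair, and lying within `insert_mean` of each other form one
#' cluster; each cluster reports a breakpoint interval spanned by the inner
#' read edges.
#'
#' @param pairs Data frame from [simulate_paired_end_reads()] (columns
#'   `chrom1`, `start1`, `end1`, `strand1`, idem for read 2).
#' @param insert_mean,insert_sd Library insert-size parameters (bp).
#' @return Data frame of clusters (possibly 0 rows): `signature`, `chrom1`,
#'   `chrom2`, `n_pairs`, `bp_start`, `bp_end`.
#' @export
cluster_discordant_pairs <- function(pairs, insert_mean = 400,
                                     insert_sd = 40) {
  if (nrow(pairs) == 0)
    stop_foldback("need at least one pair", "foldback_range_error")
  p <- pairs[!is.na(pairs$chrom1) & !is.na(pairs$chrom2), , drop = FALSE]
  sig <- character(nrow(p))
  span <- pmax(p$end1, p$end2) - pmin(p$start1, p$start2)
  left_first <- p$start1 <= p$start2
  left_strand <- ifelse(left_first, p$strand1, p$strand2)
  right_strand <- ifelse(left_first, p$strand2, p$strand1)
  sig[p$chrom1 != p$chrom2] <- "interchromosomal"
  same <- p$chrom1 == p$chrom2
  sig[same & p$strand1 == p$strand2] <- "inverted_orientation"
  todo <- same & sig == ""
  sig[todo & left_strand == "-" & right_strand == "+"] <- "wrong_order"
  todo <- same & sig == ""
  sig[todo & span > insert_mean + 4 * insert_sd] <- "too_far"
  todo <- same & sig == ""
  sig[todo & span < insert_mean - 4 * insert_sd] <- "too_close"
  disc <- sig != ""
  if (!any(disc))
    return(data.frame(signature = character(0), chrom1 = character(0),
                      chrom2 = character(0), n_pairs = integer(0),
                      bp_start = numeric(0), bp_end = numeric(0),
                      stringsAsFactors = FALSE))
  d <- p[disc, , drop = FALSE]
  d$sig <- sig[disc]
  d$inner_lo <- pmin(d$end1, d$end2)
  d$inner_hi <- pmax(d$start1, d$start2)
  d$anchor <- pmin(d$start1, d$start2)
  out <- list()
  for (key in unique(paste(d$sig, d$chrom1, d$chrom2))) {
    g <- d[paste(d$sig, d$chrom1, d$chrom2) == key, , drop = FALSE]
    g <- g[order(g$anchor), , drop = FALSE]
    cl <- cumsum(c(1, diff(g$anchor) > insert_mean))
    for (ci in unique(cl)) {
      gg <- g[cl == ci, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        signature = gg$sig[1L], chrom1 = gg$chrom1[1L],
        chrom2 = gg$chrom2[1L], n_pairs = nrow(gg),
        bp_start = min(gg$inner_lo), bp_end = max(gg$inner_hi),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# --- parent-of-origin -------------------------------------------------------

person_alleles <- function(g, who) {
  r <- g[g$person == who, , drop = FALSE]
  if (nrow(r) == 0) return(NULL)
  a <- c(r$allele1[1L], r$allele2[1L])
  a[!is.na(a) & a != ""]
}

#' Infer the parental origin of deletion and duplication alleles
#'
#' Microsatellite logic: in the duplicated region, the child allele with
#' doubled peak height marks the duplicated haplotype; if it is carried by
#' the father only, the duplication is paternal (and vice versa). In the
#' deleted region the child is hemizygous; retention of an allele found only
#' in the mother means the deleted allele was paternal (and vice versa).
#' With one parent untyped the same logic runs against the available parent
#' and calls carry a `?` caveat. Markers whose child alleles cannot come
#' from the given parents are flagged Mendelian-inconsistent and excluded
#' from the summary, which majority-calls the origin.
#'
#' @param genotypes Long data frame with columns `marker`, `region`
#'   (`deleted`, `duplicated`, `other`), `person` (`child`, `mother`,
#'   `father`), `allele1`, `allele2`, `height1`, `height2`.
#' @param dosage_ratio Minimum taller/shorter peak-height ratio to call the
#'   duplicated allele (default 1.5).
#' @return List with `per_marker` data frame (`marker`, `region`, `call`)
#'   and `summary` (`origin`, `caveat`, `n_informative`, `n_inconsistent`).
#' @export
infer_parental_origin <- function(genotypes, dosage_ratio = 1.5) {
  need <- c("marker", "region", "person", "allele1", "allele2",
            "height1", "height2")
  stopifnot(all(need %in% names(genotypes)))
  calls <- character(0); markers <- character(0); regions <- character(0)
  for (mk in unique(genotypes$marker)) {
    g <- genotypes[genotypes$marker == mk, , drop = FALSE]
    region <- g$region[1L]
    child <- g[g$person == "child", , drop = FALSE]
    if (nrow(child) == 0) next
    mo <- person_alleles(g, "mother"); fa <- person_alleles(g, "father")
    ch_alleles <- person_alleles(g, "child")
    caveat <- if (is.null(mo) || is.null(fa)) "?" else ""
    call <- "U"
    if (!is.null(mo) && !is.null(fa) &&
        !all(ch_alleles %in% c(mo, fa))) {
      call <- "inconsistent"
    } else if (region == "duplicated") {
      h <- c(child$height1[1L], child$height2[1L])
      a <- c(child$allele1[1L], child$allele2[1L])
      if (length(ch_alleles) == 2L && !any(is.na(h)) &&
          max(h) / min(h) >= dosage_ratio) {
        dup_allele <- a[which.max(h)]
        in_mo <- !is.null(mo) && dup_allele %in% mo
        in_fa <- !is.null(fa) && dup_allele %in% fa
        if (is.null(fa)) {
          if (!in_mo) call <- "paternal_dup?"
        } else if (is.null(mo)) {
          if (!in_fa) call <- "maternal_dup?"
        } else if (in_fa && !in_mo) call <- "paternal_dup"
        else if (in_mo && !in_fa) call <- "maternal_dup"
      }
    } else if (region == "deleted") {
      if (length(unique(ch_alleles)) == 1L) {
        a <- ch_alleles[1L]
        in_mo <- !is.null(mo) && a %in% mo
        in_fa <- !is.null(fa) && a %in% fa
        if (is.null(fa)) {
          if (in_mo) call <- "paternal_del?"
        } else if (is.null(mo)) {
          if (in_fa) call <- "maternal_del?"
        } else if (in_mo && !in_fa) call <- "paternal_del"
        else if (in_fa && !in_mo) call <- "maternal_del"
      }
    }
    markers <- c(markers, mk); regions <- c(regions, region)
    calls <- c(calls, call)
  }
  per_marker <- data.frame(marker = markers, region = regions, call = calls,
                           stringsAsFactors = FALSE)
  informative <- grepl("^(pat|mat)ernal", calls)
  stripped <- sub("\\?$", "", calls[informative])
  n_pat <- sum(grepl("^paternal", stripped))
  n_mat <- sum(grepl("^maternal", stripped))
  origin <- if (n_pat > n_mat) "paternal"
            else if (n_mat > n_pat) "maternal"
            else if (n_pat + n_mat > 0) "ambiguous" else "uninformative"
  list(per_marker = per_marker,
       summary = list(origin = origin,
                      caveat = any(grepl("\\?$", calls[informative])),
                      n_informative = sum(informative),
                      n_inconsistent = sum(calls == "inconsistent")))
}
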