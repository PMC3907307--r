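# Mechanistic model of fold-back inverted-duplication formation:
# a double-strand break deletes the chromosome end; 5'-3' resection exposes a
# 3' overhang that intrastrand-pairs at a site of short inverted homology
# (or within a planted inverted repeat pair); replication yields a dicentric
# with a disomic spacer at the fold-back loop; a second break between the
# centromeres resolves it into an inverted-duplication product and a sibling
# terminal deletion; the free end is then healed by telomere addition,
# translocation, or ring fusion.
#
# All breakpoints in truth records use the maximal-shift convention (shared
# junction bases assigned to the forward/disomic side), the same convention
# the junction caller applies, so spacer sizes compare exactly.

# --- event -----------------------------------------------------------------

#' Construct a fold-back event at explicit coordinates
#'
#' Builds the full parameterization of one simulated rearrangement from the
#' double-strand-break position `b` and the anneal geometry `(d, e)`:
#' `[d, e)` is the disomic spacer (fold-back loop), `e` the distal-most
#' retained disomic base + 1, and `k = inverted_mh_pair(ref, chrom, e, d)`
#' the inverted microhomology at the anneal. Breakpoints are canonicalized by
#' maximal shift toward the deleted side (`(e, d) -> (e+1, d-1)` while
#' `ref[e] == complement(ref[d-1])`), the convention under which analyzer
#' calls and truth agree exactly.
#'
#' @param ref A `reference_genome`.
#' @param chrom Chromosome.
#' @param d,e Spacer bounds (0-based half-open), `d < e`.
#' @param b Double-strand-break position (`e <= b`; terminal deletion removes
#'   `[b, L)` before resection). Defaults to `e` (fully resected to the
#'   anneal).
#' @param hybrid Optional row index into `ref$repeats` when the anneal routes
#'   through a planted inverted repeat pair.
#' @return A `foldback_event`.
#' @export
foldback_event <- function(ref, chrom, d, e, b = e, hybrid = NULL) {
  L <- ref_len(ref, chrom)
  cen <- ref$centromere[[chrom]]
  if (!(0 < d && d < e && e <= b && b <= L))
    stop_foldback("require 0 < d < e <= b <= L", "foldback_range_error")
  if (b <= cen)
    stop_foldback("DSB must lie beyond the centromere (q-arm event)",
                  "foldback_range_error")
  # canonical maximal shift
  s <- ref_chrom(ref, chrom)
  while (e < L && d > 1 &&
         substr(s, e + 1, e + 1) ==
         comp_bases(substr(s, d, d))) {
    e <- e + 1
    d <- d - 1
  }
  b <- max(b, e)
  k <- inverted_mh_pair(ref, chrom, e, d)
  structure(list(chrom = chrom, b = b, resection_len = b - e,
                 d = d, e = e, mh_len = k, spacer = e - d,
                 hybrid = hybrid, L = L, centromere = cen),
            class = "foldback_event")
}

#' @export
print.foldback_event <- function(x, ...) {
  cat(sprintf(
    "foldback_event on %s: DSB b=%s, anneal d=%s, spacer end e=%s\n  spacer %s bp, microhomology %d bp%s\n",
    x$chrom, format(x$b, big.mark = ","), format(x$d, big.mark = ","),
    format(x$e, big.mark = ","), format(x$spacer, big.mark = ","), x$mh_len,
    if (!is.null(x$hybrid)) " (repeat-mediated)" else ""))
  invisible(x)
}

# --- anneal-site search ----------------------------------------------------

encode_bases <- function(s) {
  # A,C,G,T -> 0..3; anything else -> NA
  code <- utf8ToInt(s)
  v <- rep(NA_integer_, length(code))
  v[code == 65L] <- 0L; v[code == 67L] <- 1L
  v[code == 71L] <- 2L; v[code == 84L] <- 3L
  v
}

#' Simulate a fold-back event by scanning for an admissible anneal site
#'
#' Scans spacer ends `e` in `[b - r_max, b]` and anneal sites `d` in
#' `[e - max_loop, e - 2*min_mh]` for inverted microhomology
#' `inverted_mh_pair(ref, chrom, e, d) >= min_mh`, and additionally considers
#' anneal sites routed through planted inverted repeat pairs whose distal
#' copy lies in the scan window (the junction is placed at the longest exact
#' inverted-match run between the two diverged copies). A site is selected
#' according to `site_choice`:
#' \describe{
#'   \item{nearest}{smallest spacer `e - d` (fold-back loops observed in
#'     patients are mostly a few kb); ties broken by larger microhomology,
#'     then smaller `d`.}
#'   \item{max_mh}{largest microhomology among the per-`e` nearest candidates
#'     and any repeat-routed candidates (prefers repeat-mediated anneals).}
#'   \item{random}{uniform draw among the per-`e` nearest candidates.}
#' }
#'
#' @param ref A `reference_genome`.
#' @param chrom Chromosome.
#' @param b Double-strand-break position (beyond the centromere).
#' @param min_mh Minimum inverted microhomology at the anneal (>= 1).
#' @param max_loop Maximum spacer (fold-back loop) size in bp; default
#'   70,466, the largest sequenced spacer.
#' @param r_max Maximum modeled resection in bp (how far `e` may retreat
#'   from `b`).
#' @param site_choice Site-selection policy (see above).
#' @param use_repeats Consider planted inverted repeat pairs as anneal
#'   routes.
#' @param seed Seed (used by `site_choice = "random"`).
#' @return A `foldback_event`.
#' @export
simulate_foldback <- function(ref, chrom, b, min_mh = 2L, max_loop = 70466L,
                              r_max = 2000L,
                              site_choice = c("nearest", "max_mh", "random"),
                              use_repeats = TRUE, seed = NULL) {
  site_choice <- match.arg(site_choice)
  if (min_mh < 1) stop_foldback("min_mh must be >= 1", "foldback_range_error")
  L <- ref_len(ref, chrom)
  cen <- ref$centromere[[chrom]]
  if (!(b > cen && b <= L))
    stop_foldback("DSB must lie beyond the centromere (q-arm event)",
                  "foldback_range_error")
  m <- as.integer(min_mh)
  e_lo <- max(b - r_max, cen + 2L * m + 2L)
  d_lo <- max(e_lo - max_loop, cen + 1L)
  win_start <- max(0L, d_lo - 1L)
  s <- ref_chrom(ref, chrom)
  v <- encode_bases(substr(s, win_start + 1L, b))
  off <- win_start  # v[i + 1] is base at 0-based position off + i

  # k-mer codes: F(d) = code of forward m-mer starting at d;
  # T(e) = code of revcomp of the m-mer ending at e. F(d) == T(e) iff
  # ref[e-m..e) == revcomp(ref[d..d+m)).
  nv <- length(v)
  cv <- 3L - v
  pow <- 4^(seq_len(m) - 1L)
  idx_max_start <- nv - m + 1L
  Fcode <- numeric(idx_max_start); Tend <- numeric(idx_max_start)
  # Fcode[i]: m-mer starting at v index i; Tend[i]: revcomp code of the same
  # m-mer (usable for e = off + i - 1 + m)
  na_mask <- rep(FALSE, idx_max_start)
  for (j in seq_len(m)) {
    col <- v[(j):(nv - m + j)]
    ccol <- cv[(j):(nv - m + j)]
    na_mask <- na_mask | is.na(col)
    col[is.na(col)] <- 0L; ccol[is.na(ccol)] <- 0L
    Fcode <- Fcode + col * 4^(m - j)
    Tend <- Tend + ccol * 4^(j - 1L)
  }
  Fcode[na_mask] <- NA; Tend[na_mask] <- NA

  d_all <- off + seq_len(idx_max_start) - 1L        # candidate d positions
  keep_d <- d_all >= d_lo & d_all + 2L * m <= b & !is.na(Fcode)
  dpos <- d_all[keep_d]
  dmap <- split(dpos, Fcode[keep_d])

  cands <- list()
  for (e in seq.int(b, e_lo, by = -1L)) {
    i <- e - m - off + 1L              # Tend index for suffix ending at e
    if (i < 1L || i > idx_max_start || is.na(Tend[i])) next
    dvec <- dmap[[as.character(Tend[i])]]
    if (is.null(dvec)) next
    hi <- e - 2L * m
    lo <- max(e - max_loop, d_lo)
    j <- findInterval(hi, dvec)
    if (j < 1L || dvec[j] < lo) next
    d <- dvec[j]                        # nearest admissible d for this e
    cands[[length(cands) + 1L]] <-
      list(e = e, d = d, hybrid = NULL)
  }

  if (use_repeats && nrow(ref$repeats) > 0) {
    rp <- ref$repeats
    for (ri in seq_len(nrow(rp))) {
      if (rp$chrom[ri] != chrom || rp$orientation[ri] != "inverted") next
      s1 <- rp$start1[ri]; s2 <- rp$start2[ri]; Lr <- rp$length[ri]
      copy1 <- strsplit(ref_seq(ref, chrom, s1, s1 + Lr), "", fixed = TRUE)[[1L]]
      copy2 <- strsplit(ref_seq(ref, chrom, s2, s2 + Lr), "", fixed = TRUE)[[1L]]
      mv <- copy2 == comp_bases(rev(copy1)) & copy2 != "N"
      r <- rle(mv)
      ends <- cumsum(r$lengths)
      runs <- which(r$values & r$lengths >= 1L)
      if (length(runs) == 0L) next
      best_run <- runs[which.max(r$lengths[runs])]
      q <- ends[best_run]               # junction q bases into copy2
      k_run <- r$lengths[best_run]
      e <- s2 + q; d <- s1 + Lr - q
      ok <- e >= e_lo && e <= b && d >= d_lo && d < e &&
        (e - d) <= max_loop && (e - d) >= 2L
      if (ok && min(k_run, (e - d) %/% 2) >= 1L)
        cands[[length(cands) + 1L]] <- list(e = e, d = d, hybrid = ri)
    }
  }

  if (length(cands) == 0L)
    stop_foldback(
      sprintf("no admissible anneal site on %s in e-window [%d, %d] (min_mh=%d, max_loop=%d)",
              chrom, e_lo, b, m, max_loop),
      "foldback_no_site")

  spacers <- vapply(cands, function(cc) cc$e - cc$d, numeric(1))
  pick <- switch(
    site_choice,
    nearest = {
      o <- order(spacers)
      top <- o[spacers[o] == spacers[o[1L]]]
      if (length(top) > 1L) {
        ks <- vapply(cands[top], function(cc)
          inverted_mh_pair(ref, chrom, cc$e, cc$d), integer(1))
        ds <- vapply(cands[top], function(cc) cc$d, numeric(1))
        top <- top[order(-ks, ds)]
      }
      top[1L]
    },
    max_mh = {
      ks <- vapply(cands, function(cc)
        inverted_mh_pair(ref, chrom, cc$e, cc$d), integer(1))
      order(-ks, spacers)[1L]
    },
    random = with_seed(seed, sample.int(length(cands), 1L)))
  cc <- cands[[pick]]
  foldback_event(ref, chrom, d = cc$d, e = cc$e, b = b, hybrid = cc$hybrid)
}

# --- dicentric and BFB resolution ------------------------------------------

#' Form the post-replication dicentric chromosome
#'
#' Sequence `ref[0..e) + revcomp(ref[0..d))`: the fold-back intermediate
#' after DNA replication, carrying the disomic spacer `ref[d..e)` exactly
#' once between the inverted sides, and both centromere copies.
#'
#' @param ref A `reference_genome`.
#' @param event A `foldback_event`.
#' @return A `dicentric` object (`seq`, 0-based `centromeres`, `event`).
#' @export
form_dicentric <- function(ref, event) {
  ch <- event$chrom
  seq <- paste0(ref_seq(ref, ch, 0, event$e),
                revcomp(ref_seq(ref, ch, 0, event$d)))
  cen <- event$centromere
  structure(list(seq = seq, chrom = ch,
                 centromeres = c(cen, event$e + event$d - 1 - cen),
                 event = event),
            class = "dicentric")
}

new_derivative <- function(seq, chrom, segmap, junctions, event, p,
                           resolution = NA_character_, circular = FALSE) {
  structure(list(seq = seq, chrom = chrom, segmap = segmap,
                 junctions = junctions, event = event, p = p,
                 resolution = resolution, circular = circular),
            class = "derivative")
}

empty_junction_table <- function() {
  data.frame(id = character(0), type = character(0), der_pos = numeric(0),
             left_chrom = character(0), left_pos = numeric(0),
             left_strand = character(0),
             right_chrom = character(0), right_pos = numeric(0),
             right_strand = character(0),
             mh = integer(0), anneal_k = integer(0), spacer = numeric(0),
             ins_seq = character(0), ins_kind = character(0),
             ins_len = integer(0),
             template_chrom = character(0), template_start = numeric(0),
             template_end = numeric(0), template_orient = character(0),
             notes = character(0), stringsAsFactors = FALSE)
}

junction_row <- function(id, type, der_pos, left, right, mh, anneal_k = mh,
                         spacer = NA_real_, notes = "") {
  data.frame(id = id, type = type, der_pos = der_pos,
             left_chrom = left[[1]], left_pos = as.numeric(left[[2]]),
             left_strand = left[[3]],
             right_chrom = right[[1]], right_pos = as.numeric(right[[2]]),
             right_strand = right[[3]],
             mh = as.integer(mh), anneal_k = as.integer(anneal_k),
             spacer = spacer,
             ins_seq = NA_character_, ins_kind = NA_character_,
             ins_len = 0L,
             template_chrom = NA_character_, template_start = NA_real_,
             template_end = NA_real_, template_orient = NA_character_,
             notes = notes, stringsAsFactors = FALSE)
}

# run lengths of agreement used to place truth breakpoints under the
# maximal-shift convention: `back` compares bases left of the junction with
# the right side's upstream reference continuation; `fwd` compares bases
# right of the junction with the left side's downstream continuation.
match_run <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  ok <- a[seq_len(n)] == b[seq_len(n)] & a[seq_len(n)] != "N"
  mism <- which(!ok)
  if (length(mism) == 0L) n else mism[1L] - 1L
}

seq_chars_rev <- function(seq, pos, len) {
  # bases seq[pos-1], seq[pos-2], ... (0-based pos; len clipped)
  len <- min(len, pos)
  if (len <= 0L) return(character(0))
  rev(strsplit(substr(seq, pos - len + 1L, pos), "", fixed = TRUE)[[1L]])
}

seq_chars_fwd <- function(seq, pos, len) {
  len <- min(len, nchar(seq) - pos)
  if (len <= 0L) return(character(0))
  strsplit(substr(seq, pos + 1L, pos + len), "", fixed = TRUE)[[1L]]
}

#' Break the dicentric into its two monocentric products
#'
#' A second double-strand break at `p`, strictly between the two centromere
#' copies (and proximal to the duplicated segment, `p < d`), yields the
#' inverted-duplication product `ref[0..e) + revcomp(ref[p..d))` and a
#' sibling terminal deletion. The sibling is returned as read off the
#' dicentric, i.e. `revcomp(ref[0..p))` — the same double-stranded molecule
#' as `ref[0..p)` — so that the two products concatenate exactly to the
#' dicentric (base conservation).
#'
#' @param ref A `reference_genome`.
#' @param dic A `dicentric`.
#' @param p Break position (0-based, in reference coordinates).
#' @return List with `invdup` (a `derivative`) and `sibling` (sequence
#'   string).
#' @export
break_dicentric <- function(ref, dic, p) {
  ev <- dic$event
  cen <- ev$centromere
  if (!(p > cen && p < ev$d))
    stop_foldback("break must fall strictly between the centromere copies and proximal to the duplication (cen < p < d)",
                  "foldback_invalid_break")
  n_keep <- ev$e + ev$d - p
  invdup_seq <- substr(dic$seq, 1L, n_keep)
  sibling <- substr(dic$seq, n_keep + 1L, nchar(dic$seq))
  segmap <- data.frame(
    der_start = c(0, ev$e), der_end = c(ev$e, n_keep),
    chrom = dic$chrom, ref_start = c(0, p), ref_end = c(ev$e, ev$d),
    strand = c("+", "-"), origin = "chromosome", stringsAsFactors = FALSE)
  # truth breakpoints under the maximal-shift convention; for a canonical
  # event the forward extension is 0 and the backward run equals mh_len
  s <- ref_chrom(ref, dic$chrom)
  scan <- max(ev$mh_len + 2L, 32L)
  back <- match_run(seq_chars_rev(invdup_seq, ev$e, scan),
                    comp_bases(seq_chars_fwd(s, ev$d, scan)))
  jx <- junction_row("j_disinv", "disomy_inversion", der_pos = ev$e,
                     left = list(dic$chrom, ev$e, "+"),
                     right = list(dic$chrom, ev$d, "-"),
                     mh = back, anneal_k = ev$mh_len, spacer = ev$e - ev$d)
  list(invdup = new_derivative(invdup_seq, dic$chrom, segmap, jx, ev, p),
       sibling = sibling)
}

# --- resolution of the free end --------------------------------------------

TEL_UNIT <- c("T", "T", "A", "G", "G", "G")

#' Heal the inverted-duplication free end
#'
#' Resolves the broken end of the inverted-duplication product as one of the
#' three outcomes observed for such chromosomes:
#' \describe{
#'   \item{telomere}{appends `(TTAGGG)` repeats, choosing the repeat phase so
#'     the junction shares `tel_mh` bases with the telomere repeat when
#'     achievable (the achieved value is recorded in truth);}
#'   \item{translocation}{appends the terminal (q) segment of a donor
#'     chromosome, telomere cap included, creating an
#'     inversion-translocation junction;}
#'   \item{ring}{fuses the free end to the p-arm end of the same chromosome;
#'     both fusing ends first lose their telomere caps, so neither side of
#'     the join is telomeric.}
#' }
#'
#' @param der A `derivative` from [break_dicentric()].
#' @param ref A `reference_genome`.
#' @param mode `"telomere"`, `"translocation"` or `"ring"`.
#' @param tel_units Telomere units appended in telomere mode.
#' @param tel_mh Desired junction microhomology with the telomere repeat
#'   (0-4 bp).
#' @param donor_chrom Donor chromosome for translocation mode.
#' @param donor_seg Donor terminal-segment length (bp).
#' @return The resolved `derivative` with an added junction record.
#' @export
resolve_derivative <- function(der, ref,
                               mode = c("telomere", "translocation", "ring"),
                               tel_units = 100L, tel_mh = 0L,
                               donor_chrom = NULL, donor_seg = 50000L) {
  mode <- match.arg(mode)
  ev <- der$event
  n <- nchar(der$seq)
  p <- der$p
  s <- ref_chrom(ref, der$chrom)
  # the left side of the new junction is the inverted-duplication end, whose
  # reference continuation (minus strand) is complement(ref[p-1-i])
  left_next <- comp_bases(seq_chars_rev(s, p, 64L))

  if (mode == "telomere") {
    if (!(tel_mh >= 0 && tel_mh <= 4))
      stop_foldback("tel_mh must be in 0..4", "foldback_range_error")
    end_chars <- seq_chars_rev(der$seq, n, 12L)
    ach <- integer(6)
    for (phase in 0:5) {
      prev <- TEL_UNIT[((phase - seq_len(12L)) %% 6L) + 1L]
      ach[phase + 1L] <- match_run(end_chars, prev)
    }
    if (any(ach == tel_mh)) {
      phase <- which(ach == tel_mh)[1L] - 1L
    } else {
      feas <- which(ach < tel_mh)
      phase <- if (length(feas) > 0L) feas[which.max(ach[feas])] - 1L
               else which.min(ach) - 1L
    }
    achieved <- ach[phase + 1L]
    appended <- paste(TEL_UNIT[((phase + seq_len(6L * tel_units) - 1L) %% 6L) + 1L],
                      collapse = "")
    fwd <- match_run(strsplit(appended, "", fixed = TRUE)[[1L]][1:32],
                     left_next)
    jx <- junction_row("j_invtel", "inversion_telomere",
                       der_pos = n,
                       left = list(der$chrom, p - fwd, "-"),
                       right = list(NA_character_, NA_real_, "+"),
                       mh = achieved + fwd, anneal_k = achieved,
                       notes = sprintf("tel_phase=%d;tel_units=%d", phase,
                                       tel_units))
    segmap <- rbind(der$segmap, data.frame(
      der_start = n, der_end = n + nchar(appended), chrom = NA_character_,
      ref_start = NA_real_, ref_end = NA_real_, strand = "+",
      origin = "telomere", stringsAsFactors = FALSE))
    return(new_derivative(paste0(der$seq, appended), der$chrom, segmap,
                          rbind(der$junctions, jx), ev, p,
                          resolution = "telomere"))
  }

  if (mode == "translocation") {
    if (is.null(donor_chrom) || identical(donor_chrom, der$chrom))
      stop_foldback("translocation mode needs a distinct donor chromosome",
                    "foldback_range_error")
    L2 <- ref_len(ref, donor_chrom)
    if (donor_seg >= L2)
      stop_foldback("donor segment longer than donor chromosome",
                    "foldback_range_error")
    seg_start <- L2 - donor_seg
    appended <- ref_seq(ref, donor_chrom, seg_start, L2)
    s2 <- ref_chrom(ref, donor_chrom)
    back <- match_run(seq_chars_rev(der$seq, n, 32L),
                      seq_chars_rev(s2, seg_start, 32L))
    fwd <- match_run(seq_chars_fwd(s2, seg_start, 32L), left_next)
    jx <- junction_row("j_invtra", "inversion_translocation",
                       der_pos = n,
                       left = list(der$chrom, p - fwd, "-"),
                       right = list(donor_chrom, seg_start + fwd, "+"),
                       mh = back + fwd, anneal_k = 0L)
    segmap <- rbind(der$segmap, data.frame(
      der_start = n, der_end = n + donor_seg, chrom = donor_chrom,
      ref_start = seg_start, ref_end = L2, strand = "+",
      origin = "chromosome", stringsAsFactors = FALSE))
    return(new_derivative(paste0(der$seq, appended), der$chrom, segmap,
                          rbind(der$junctions, jx), ev, p,
                          resolution = "translocation"))
  }

  # ring: trim the p-arm telomere cap, fuse end to start
  cap <- 6L * ref$telomere_units
  newseq <- substr(der$seq, cap + 1L, n)
  segmap <- der$segmap
  segmap$der_start <- segmap$der_start - cap
  segmap$der_end <- segmap$der_end - cap
  segmap$ref_start[1] <- cap
  segmap$der_start[1] <- 0
  jx_tab <- der$junctions
  jx_tab$der_pos <- jx_tab$der_pos - cap
  n2 <- nchar(newseq)
  back <- match_run(seq_chars_rev(newseq, n2, 32L),
                    seq_chars_rev(s, cap, 32L))
  fwd <- match_run(seq_chars_fwd(s, cap, 32L), left_next)
  jx <- junction_row("j_ring", "ring_fusion",
                     der_pos = n2,
                     left = list(der$chrom, p - fwd, "-"),
                     right = list(der$chrom, cap + fwd, "+"),
                     mh = back + fwd, anneal_k = 0L)
  new_derivative(newseq, der$chrom, segmap, rbind(jx_tab, jx), ev, p,
                 resolution = "ring", circular = TRUE)
}

# --- junction insertions ----------------------------------------------------

#' Add a complex insertion at a junction
#'
#' Inserts sequence at the junction point and records its provenance:
#' \describe{
#'   \item{templated_direct}{copies a segment from within `window` bp of the
#'     (disomic-side) breakpoint, in direct orientation relative to the
#'     reference;}
#'   \item{templated_inverted}{copies a nearby segment in opposite
#'     orientation;}
#'   \item{slippage}{duplicates the `length` (<= 10) bases immediately left
#'     of the junction, in direct orientation;}
#'   \item{mitochondrial}{copies a segment of the circular mitochondrial-like
#'     donor;}
#'   \item{untemplated}{random bases.}
#' }
#' A junction carries either microhomology or an insertion, never both: the
#' junction's microhomology is zeroed (the anneal microhomology remains
#' recorded as `anneal_k`).
#'
#' @param der A `derivative`.
#' @param ref A `reference_genome`.
#' @param junction_id Junction id (e.g. `"j_disinv"`).
#' @param kind Insertion kind (see above).
#' @param length Insertion length in bp.
#' @param window Template search window around the breakpoint (bp).
#' @param template_offset Distance from the breakpoint to the template start
#'   for templated kinds; drawn uniformly from `[20, window - length]` when
#'   `NULL`.
#' @param seed Seed.
#' @return The modified `derivative`.
#' @export
add_complex_insertion <- function(der, ref, junction_id,
                                  kind = c("templated_direct",
                                           "templated_inverted", "slippage",
                                           "mitochondrial", "untemplated"),
                                  length = 10L, window = 1000L,
                                  template_offset = NULL, seed = NULL) {
  kind <- match.arg(kind)
  ji <- match(junction_id, der$junctions$id)
  if (is.na(ji)) stop_foldback("unknown junction id", "foldback_range_error")
  jrow <- der$junctions[ji, ]
  jpos <- jrow$der_pos
  with_seed(seed, {
    template <- list(chrom = NA_character_, start = NA_real_, end = NA_real_,
                     orient = NA_character_)
    if (kind %in% c("templated_direct", "templated_inverted")) {
      off <- template_offset %||% sample(20:(window - length), 1L)
      anchor <- jrow$left_pos
      t_start <- anchor - off - length
      if (t_start < 0 || off + length > window)
        stop_foldback("template window too small", "foldback_insertion_error")
      tseq <- ref_seq(ref, jrow$left_chrom, t_start, t_start + length)
      ins <- if (kind == "templated_direct") tseq else revcomp(tseq)
      template <- list(chrom = jrow$left_chrom, start = t_start,
                       end = t_start + length,
                       orient = if (kind == "templated_direct") "+" else "-")
    } else if (kind == "slippage") {
      if (length > 10L)
        stop_foldback("slippage insertions duplicate at most 10 junction-local bases",
                      "foldback_insertion_error")
      ins <- substr(der$seq, jpos - length + 1L, jpos)
      # junction-local duplication; record in reference space of the left side
      template <- list(chrom = jrow$left_chrom,
                       start = jrow$left_pos - length, end = jrow$left_pos,
                       orient = "+")
    } else if (kind == "mitochondrial") {
      if (is.null(ref$mito))
        stop_foldback("reference has no mitochondrial-like donor",
                      "foldback_insertion_error")
      Lm <- nchar(ref$mito)
      t0 <- sample.int(Lm, 1L) - 1L
      circ <- paste0(ref$mito, substr(ref$mito, 1L, length))
      ins <- substr(circ, t0 + 1L, t0 + length)
      template <- list(chrom = "chrM_like", start = t0, end = t0 + length,
                       orient = "+")
    } else {
      ins <- random_dna(length)
    }
    newseq <- paste0(substr(der$seq, 1L, jpos), ins,
                     substr(der$seq, jpos + 1L, nchar(der$seq)))
    segmap <- der$segmap
    segmap$der_start[segmap$der_start >= jpos] <-
      segmap$der_start[segmap$der_start >= jpos] + length
    segmap$der_end[segmap$der_end > jpos] <-
      segmap$der_end[segmap$der_end > jpos] + length
    segmap <- rbind(segmap, data.frame(
      der_start = jpos, der_end = jpos + length, chrom = template$chrom,
      ref_start = template$start, ref_end = template$end,
      strand = template$orient %||% "+", origin = paste0("insertion_", kind),
      stringsAsFactors = FALSE))
    segmap <- segmap[order(segmap$der_start), ]
    jx <- der$junctions
    jx$der_pos[jx$der_pos > jpos] <- jx$der_pos[jx$der_pos > jpos] + length
    jx$ins_seq[ji] <- ins
    jx$ins_kind[ji] <- kind
    jx$ins_len[ji] <- as.integer(length)
    jx$template_chrom[ji] <- template$chrom
    jx$template_start[ji] <- template$start
    jx$template_end[ji] <- template$end
    jx$template_orient[ji] <- template$orient
    jx$mh[ji] <- 0L
    new_derivative(newseq, der$chrom, segmap, jx, der$event, der$p,
                   resolution = der$resolution, circular = der$circular)
  })
}

# --- observable outputs -----------------------------------------------------

#' Emit a junction amplicon
#'
#' Returns `flank` bases on each side of the junction point (insertions
#' included in full), the in-silico stand-in for a long-range PCR product
#' sequenced across the junction.
#'
#' @param der A `derivative`.
#' @param junction_id Junction id.
#' @param flank Flank length (>= 50 bp).
#' @return Sequence string with attributes `name` and `truncated`.
#' @export
emit_amplicon <- function(der, junction_id, flank = 400L) {
  if (flank < 50L) stop_foldback("flank must be >= 50", "foldback_range_error")
  ji <- match(junction_id, der$junctions$id)
  if (is.na(ji)) stop_foldback("unknown junction id", "foldback_range_error")
  jrow <- der$junctions[ji, ]
  n <- nchar(der$seq)
  lo <- jrow$der_pos - flank
  hi <- jrow$der_pos + jrow$ins_len + flank
  truncated <- FALSE
  if (der$circular) {
    left <- if (lo >= 0) substr(der$seq, lo + 1L, jrow$der_pos)
            else paste0(substr(der$seq, n + lo + 1L, n),
                        substr(der$seq, 1L, jrow$der_pos))
    right <- if (hi <= n) substr(der$seq, jrow$der_pos + 1L, hi)
             else paste0(substr(der$seq, jrow$der_pos + 1L, n),
                         substr(der$seq, 1L, hi - n))
    amp <- paste0(left, right)
  } else {
    if (lo < 0 || hi > n) truncated <- TRUE
    amp <- substr(der$seq, max(0L, lo) + 1L, min(n, hi))
  }
  attr(amp, "name") <- junction_id
  attr(amp, "truncated") <- truncated
  amp
}

map_der_interval <- function(der, a, b) {
  # map derivative interval [a, b) to reference space through the segment
  # with the largest overlap; returns chrom (NA for non-chromosomal origin),
  # ref interval of the overlapping part, segment strand, and whether the
  # interval crosses segment boundaries
  sm <- der$segmap
  ov_lo <- pmax(sm$der_start, a); ov_hi <- pmin(sm$der_end, b)
  ov <- pmax(0, ov_hi - ov_lo)
  i <- which.max(ov)
  spans <- sum(ov > 0) > 1L
  if (ov[i] <= 0 || is.na(sm$chrom[i]))
    return(list(chrom = NA_character_, start = NA_real_, end = NA_real_,
                strand = NA_character_, spans = spans))
  lo <- ov_lo[i]; hi <- ov_hi[i]
  if (sm$strand[i] == "+") {
    rs <- sm$ref_start[i] + (lo - sm$der_start[i])
    re <- sm$ref_start[i] + (hi - sm$der_start[i])
  } else {
    re <- sm$ref_end[i] - (lo - sm$der_start[i])
    rs <- sm$ref_end[i] - (hi - sm$der_start[i])
  }
  list(chrom = sm$chrom[i], start = rs, end = re, strand = sm$strand[i],
       spans = spans)
}

#' Simulate paired-end reads from a derivative chromosome
#'
#' Uniform fragment sampling; each pair carries its true derivative
#' coordinates and the reference-space alignment induced through the truth
#' segment map (a junction-spanning read is assigned to the segment holding
#' most of it), so discordance is decidable without an external aligner.
#' Read strands are reported in reference space (`strand1`/`strand2`), with
#' read 1 on the derivative plus strand at the fragment start and read 2 on
#' the derivative minus strand at the fragment end.
#'
#' @param der A `derivative`.
#' @param coverage Haploid fold coverage of the derivative.
#' @param insert_mean,insert_sd Fragment-size distribution (bp);
#'   `insert_mean > 2 * read_len` required.
#' @param read_len Read length (bp).
#' @param seed Seed.
#' @return Data frame, one row per pair.
#' @export
simulate_paired_end_reads <- function(der, coverage = 30, insert_mean = 400,
                                      insert_sd = 40, read_len = 100,
                                      seed = NULL) {
  if (insert_mean <= 2 * read_len)
    stop_foldback("insert_mean must exceed 2 * read_len",
                  "foldback_range_error")
  n <- nchar(der$seq)
  n_pairs <- round(coverage * n / (2 * read_len))
  with_seed(seed, {
    isize <- pmin(pmax(round(stats::rnorm(n_pairs, insert_mean, insert_sd)),
                       2 * read_len), n)
    start <- floor(stats::runif(n_pairs, 0, n - isize + 1))
    end <- start + isize
    r1 <- Map(function(a) map_der_interval(der, a, a + read_len), start)
    r2 <- Map(function(b) map_der_interval(der, b - read_len, b), end)
    fld <- function(lst, f) vapply(lst, function(x) x[[f]],
                                   if (f %in% c("chrom", "strand"))
                                     NA_character_ else NA_real_)
    flip <- function(s) ifelse(s == "+", "-", "+")
    s1seg <- fld(r1, "strand"); s2seg <- fld(r2, "strand")
    data.frame(
      pair = sprintf("p%06d", seq_len(n_pairs)),
      der_start = start, der_end = end,
      chrom1 = fld(r1, "chrom"), start1 = fld(r1, "start"),
      end1 = fld(r1, "end"), strand1 = s1seg,               # read 1: der +
      chrom2 = fld(r2, "chrom"), start2 = fld(r2, "start"),
      end2 = fld(r2, "end"), strand2 = flip(s2seg),         # read 2: der -
      spans1 = vapply(r1, function(x) isTRUE(x$spans), logical(1)),
      spans2 = vapply(r2, function(x) isTRUE(x$spans), logical(1)),
      stringsAsFactors = FALSE)
  })
}

#' Assemble the truth record for a resolved derivative
#'
#' @param der A `derivative`.
#' @return A `rearrangement_truth` list: deletion/duplication/spacer sizes
#'   and intervals, resolution mode, per-junction truth and insertions.
#' @export
rearrangement_truth <- function(der) {
  ev <- der$event
  structure(list(
    chrom = der$chrom, chrom_length = ev$L,
    dsb_pos = ev$b, resection_len = ev$resection_len,
    anneal_d = ev$d, spacer_end_e = ev$e, break_p = der$p,
    mh_len = ev$mh_len,
    deletion_size = ev$L - ev$e,
    dup_start = der$p, dup_end = ev$d, dup_size = ev$d - der$p,
    spacer_start = ev$d, spacer_end = ev$e, spacer_size = ev$e - ev$d,
    resolution = der$resolution,
    hybrid_repeat = ev$hybrid,
    junctions = der$junctions),
    class = "rearrangement_truth")
}

#' Simulate an array-CGH profile for a diploid carrying one rearranged
#' homolog
#'
#' Probes every `probe_spacing` bp along the rearranged chromosome; expected
#' log2 test/reference ratio is 0 over disomic sequence, `log2(3/2)` over the
#' duplicated interval `[p, d)` and `log2(1/2)` over the terminal deletion
#' `[e, L)`, plus Gaussian noise.
#'
#' @param truth A `rearrangement_truth` (or a list with `chrom`,
#'   `chrom_length`, `dup_start`, `dup_end`, `spacer_end`).
#' @param probe_spacing Probe spacing in bp (>= 1).
#' @param noise_sd Gaussian noise standard deviation on the log2 ratio.
#' @param seed Seed.
#' @return A `cgh_profile`: probe data frame (`chrom`, `pos`, `log2`) plus
#'   spacing metadata.
#' @export
simulate_cgh <- function(truth, probe_spacing = 200, noise_sd = 0.1,
                         seed = NULL) {
  if (probe_spacing < 1)
    stop_foldback("probe_spacing must be >= 1", "foldback_range_error")
  pos <- seq.int(0L, truth$chrom_length - 1L, by = probe_spacing)
  expected <- rep(0, length(pos))
  expected[pos >= truth$dup_start & pos < truth$dup_end] <- log2(3 / 2)
  expected[pos >= truth$spacer_end] <- log2(1 / 2)
  log2r <- with_seed(seed,
                     expected + stats::rnorm(length(pos), 0, noise_sd))
  structure(list(probes = data.frame(chrom = truth$chrom, pos = pos,
                                     log2 = log2r, stringsAsFactors = FALSE),
                 probe_spacing = probe_spacing, noise_sd = noise_sd),
            class = "cgh_profile")
}
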