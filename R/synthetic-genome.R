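# Synthetic reference genomes carrying the structural features the fold-back
# analysis assumes: telomere caps at both chromosome ends, a centromere
# position, planted (possibly diverged) repeat pairs, and a mitochondrial-like
# donor used only as an insertion source. No attempt is made to mimic real
# Alu/L1 consensus sequences, CpG structure, or real-genome coordinates.

#' Construct a reference_genome object
#'
#' @param seqs Named list of chromosome sequences (uppercase ACGTN strings).
#' @param centromere Named numeric vector of 0-based centromere positions.
#' @param telomere_units Integer count of 6-bp telomere units per cap.
#' @param repeats Data frame of planted repeat annotations (may be empty).
#' @param mito Mitochondrial-like donor sequence or `NULL`.
#' @return A `reference_genome` object.
#' @export
reference_genome <- function(seqs, centromere, telomere_units = 0L,
                             repeats = empty_repeat_table(), mito = NULL) {
  stopifnot(is.list(seqs), !is.null(names(seqs)),
            all(names(centromere) %in% names(seqs)))
  lens <- vapply(seqs, nchar, integer(1))
  for (ch in names(centromere)) {
    if (!(centromere[[ch]] > 0 && centromere[[ch]] < lens[[ch]]))
      stop_foldback("centromere must lie strictly inside the chromosome",
                    "foldback_range_error")
  }
  structure(list(seqs = seqs, centromere = centromere,
                 telomere_units = as.integer(telomere_units),
                 repeats = repeats, mito = mito),
            class = "reference_genome")
}

empty_repeat_table <- function() {
  data.frame(family = character(0), chrom = character(0),
             start1 = numeric(0), end1 = numeric(0),
             start2 = numeric(0), end2 = numeric(0),
             orientation = character(0), identity = numeric(0),
             length = numeric(0), stringsAsFactors = FALSE)
}

#' @export
print.reference_genome <- function(x, ...) {
  lens <- vapply(x$seqs, nchar, integer(1))
  cat("reference_genome:", length(lens), "chromosome(s)\n")
  for (ch in names(lens))
    cat(sprintf("  %s: %s bp, centromere %s\n", ch,
                format(lens[[ch]], big.mark = ","),
                format(x$centromere[[ch]], big.mark = ",")))
  cat(sprintf("  telomere caps: %d units; planted repeats: %d; mito donor: %s\n",
              x$telomere_units, nrow(x$repeats),
              if (is.null(x$mito)) "none" else paste0(nchar(x$mito), " bp")))
  invisible(x)
}

# accessors -----------------------------------------------------------------

ref_chrom <- function(ref, chrom) {
  seqs <- if (inherits(ref, "reference_genome")) ref$seqs else ref
  s <- seqs[[chrom]]
  if (is.null(s)) stop_foldback(paste0("unknown chromosome: ", chrom),
                                "foldback_range_error")
  s
}

#' Extract reference bases over a 0-based half-open interval
#'
#' @param ref A `reference_genome`.
#' @param chrom Chromosome identifier.
#' @param start,end 0-based half-open bounds.
#' @return Sequence string.
#' @export
ref_seq <- function(ref, chrom, start, end) {
  s <- ref_chrom(ref, chrom)
  n <- nchar(s)
  if (!(start >= 0 && start <= end && end <= n))
    stop_foldback("interval outside chromosome", "foldback_range_error")
  substr(s, start + 1, end)
}

ref_len <- function(ref, chrom) nchar(ref_chrom(ref, chrom))

random_dna <- function(n, composition = c(A = 0.25, C = 0.25, G = 0.25,
                                          T = 0.25)) {
  if (n == 0L) return("")
  composition <- composition[c("A", "C", "G", "T")]
  stopifnot(abs(sum(composition) - 1) < 1e-6)
  codes <- utf8ToInt("ACGT")
  intToUtf8(codes[sample.int(4L, n, replace = TRUE, prob = composition)])
}

#' Generate a synthetic reference genome
#'
#' Each chromosome starts with a `(CCCTAA)n` cap, ends with a `(TTAGGG)n`
#' cap, and has iid random interior bases with the requested composition.
#' Repeat pairs listed in `repeat_plan` are planted afterwards. Deterministic
#' given `seed`.
#'
#' @param lengths Named numeric vector of chromosome lengths (bp, including
#'   caps). Lengths of at least 100 kb are recommended for rearrangement work.
#' @param base_composition Named probabilities for A, C, G, T (sum to 1).
#' @param telomere_units Telomere units per cap (default 500, i.e. 3-kb caps:
#'   long enough for telomere-run detection, short enough for desk scale).
#' @param centromere Named vector of 0-based centromere positions; default is
#'   1/4 of each chromosome length (a proximal centromere leaves a long q arm
#'   for terminal-deletion events).
#' @param repeat_plan Optional list of lists with fields `family`, `chrom`,
#'   `start1`, `start2`, `length`, `identity`, `orientation`
#'   (`"inverted"`/`"direct"`), passed to [plant_inverted_repeat_pair()].
#' @param mito Logical; also generate a mitochondrial-like donor.
#' @param seed Integer seed.
#' @return A `reference_genome` object.
#' @export
generate_reference <- function(lengths,
                               base_composition = c(A = 0.25, C = 0.25,
                                                    G = 0.25, T = 0.25),
                               telomere_units = 500L,
                               centromere = NULL,
                               repeat_plan = NULL,
                               mito = TRUE,
                               seed = 1L) {
  stopifnot(is.numeric(lengths), !is.null(names(lengths)))
  cap_len <- 6L * telomere_units
  if (any(lengths < 2 * cap_len + 1000))
    stop_foldback("chromosome too short for telomere caps", "foldback_range_error")
  with_seed(seed, {
    seqs <- lapply(lengths, function(L) {
      paste0(strrep("CCCTAA", telomere_units),
             random_dna(L - 2L * cap_len, base_composition),
             strrep("TTAGGG", telomere_units))
    })
    names(seqs) <- names(lengths)
    if (is.null(centromere)) {
      centromere <- vapply(lengths, function(L) floor(L / 4), numeric(1))
    }
    ref <- reference_genome(seqs, centromere, telomere_units,
                            mito = if (mito) random_dna(16569L) else NULL)
    for (rp in repeat_plan %||% list()) {
      ref <- plant_inverted_repeat_pair(
        ref, family = rp$family, chrom = rp$chrom,
        start1 = rp$start1, start2 = rp$start2, length = rp$length,
        identity = rp$identity,
        orientation = rp$orientation %||% "inverted")
    }
    ref
  })
}

replace_bases <- function(ref, chrom, start, replacement) {
  s <- ref_chrom(ref, chrom)
  substr(s, start + 1, start + nchar(replacement)) <- replacement
  ref$seqs[[chrom]] <- s
  ref
}

mutate_to_identity <- function(seqstr, identity) {
  # substitution-only divergence: exactly round((1 - identity) * L) positions
  # changed to a different base, uniform positions; realized identity is then
  # exact by construction
  L <- nchar(seqstr)
  m <- round((1 - identity) * L)
  if (m == 0) return(seqstr)
  chars <- strsplit(seqstr, "", fixed = TRUE)[[1L]]
  pos <- sample.int(L, m)
  alt <- c("A", "C", "G", "T")
  for (p in pos) {
    choices <- setdiff(alt, chars[p])
    chars[p] <- choices[sample.int(length(choices), 1L)]
  }
  paste(chars, collapse = "")
}

#' Plant a diverged repeat pair in a chromosome
#'
#' The first copy is the sequence already at `[start1, start1 + length)`;
#' the second copy, written at `[start2, start2 + length)`, is its (reverse
#' complement for `orientation = "inverted"`) mutated to the requested
#' divergence by point substitutions at uniform random positions. Realized
#' identity is exact (`1 - round((1-identity) * L) / L`). Copies must not
#' overlap each other or the telomere caps.
#'
#' @param ref A `reference_genome`.
#' @param family Repeat family label (e.g. `"AluLike"`, `"L1Like"`).
#' @param chrom Chromosome to plant in (both copies on one chromosome).
#' @param start1,start2 0-based starts of the two copies; `start1 < start2`.
#' @param length Repeat length in bp.
#' @param identity Target pairwise identity in `[0, 1]`.
#' @param orientation `"inverted"` (default) or `"direct"`.
#' @param seed Optional seed for the mutation draw.
#' @return The modified `reference_genome` with an added annotation row.
#' @export
plant_inverted_repeat_pair <- function(ref, family, chrom, start1, start2,
                                       length, identity = 0.9,
                                       orientation = c("inverted", "direct"),
                                       seed = NULL) {
  orientation <- match.arg(orientation)
  L <- ref_len(ref, chrom)
  cap <- 6L * ref$telomere_units
  ok <- start1 >= cap && start2 >= cap &&
    start1 + length <= L - cap && start2 + length <= L - cap &&
    (start1 + length <= start2 || start2 + length <= start1)
  if (!ok)
    stop_foldback("repeat copies overlap each other or the telomere caps",
                  "foldback_placement_error")
  with_seed(seed, {
    copy1 <- ref_seq(ref, chrom, start1, start1 + length)
    template <- if (orientation == "inverted") revcomp(copy1) else copy1
    copy2 <- mutate_to_identity(template, identity)
    ref <- replace_bases(ref, chrom, start2, copy2)
    ref$repeats <- rbind(ref$repeats, data.frame(
      family = family, chrom = chrom,
      start1 = start1, end1 = start1 + length,
      start2 = start2, end2 = start2 + length,
      orientation = orientation, identity = identity, length = length,
      stringsAsFactors = FALSE))
    ref
  })
}

#' Plant an exact inverted-microhomology anneal site
#'
#' Writes bases so that `inverted_mh_pair(ref, chrom, e, d) == mh` exactly:
#' the `mh` bases ending at `e` become the reverse complement of the `mh`
#' bases starting at `d`, the next base pair outward is forced to mismatch
#' (so the microhomology is not longer than requested), and the junction is
#' made canonical-stable (`ref[e] != complement(ref[d-1])`), so a fold-back
#' event constructed at `(d, e)` keeps exactly this spacer after the
#' maximal-shift breakpoint convention is applied.
#'
#' @param ref A `reference_genome`.
#' @param chrom Chromosome.
#' @param d,e Spacer bounds, 0-based half-open; `e - d >= 2 * mh + 2`.
#' @param mh Desired microhomology length (>= 1).
#' @return The modified `reference_genome`.
#' @export
plant_anneal_site <- function(ref, chrom, d, e, mh) {
  stopifnot(mh >= 1, e - d >= 2 * mh + 2)
  L <- ref_len(ref, chrom)
  stopifnot(d >= 1, e < L - 1)
  prefix <- ref_seq(ref, chrom, d, d + mh)
  ref <- replace_bases(ref, chrom, e - mh, revcomp(prefix))
  flip_if <- function(ref, pos, banned) {
    # ensure base at pos differs from `banned`
    b <- ref_seq(ref, chrom, pos, pos + 1)
    if (b == banned) {
      repl <- setdiff(c("A", "C", "G", "T"), banned)[1L]
      ref <- replace_bases(ref, chrom, pos, repl)
    }
    ref
  }
  # cap the microhomology at exactly mh
  ref <- flip_if(ref, e - mh - 1,
                 comp_bases(ref_seq(ref, chrom, d + mh, d + mh + 1)))
  # canonical stability: no maximal-shift past (e, d)
  ref <- flip_if(ref, e, comp_bases(ref_seq(ref, chrom, d - 1, d)))
  ref
}

#' Generate a mitochondrial-like donor sequence
#'
#' A 16,569-bp circular iid random sequence tagged as non-nuclear, used only
#' as a junction-insertion source. Being random, any window of a few tens of
#' bp is overwhelmingly unlikely to match nuclear sequence at high identity.
#'
#' @param seed Integer seed.
#' @param length Donor length (default 16,569 bp).
#' @return Sequence string with attribute `circular = TRUE`.
#' @export
generate_mito_donor <- function(seed = 1L, length = 16569L) {
  s <- with_seed(seed, random_dna(length))
  attr(s, "circular") <- TRUE
  s
}

# serialization --------------------------------------------------------------

#' Write a reference genome to FASTA + BED6
#'
#' The FASTA holds the chromosomes (and the mito donor as record `chrM_like`);
#' the BED6 file holds telomere caps, centromere positions (1-bp features)
#' and planted repeat copies. BED is 0-based half-open by definition, so
#' internal coordinates serialize unchanged.
#'
#' @param ref A `reference_genome`.
#' @param fasta,bed Output paths.
#' @return Invisibly, a character vector of the paths written.
#' @export
write_genome <- function(ref, fasta, bed) {
  seqs <- ref$seqs
  if (!is.null(ref$mito)) seqs <- c(seqs, list(chrM_like = as.character(ref$mito)))
  write_fasta(seqs, fasta)
  cap <- 6L * ref$telomere_units
  rows <- list()
  for (ch in names(ref$seqs)) {
    L <- ref_len(ref, ch)
    if (cap > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = c(0L, L - cap), end = c(cap, L),
        name = c("telomere_cap_p", "telomere_cap_q"), score = 0L,
        strand = c("-", "+"))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ch, start = ref$centromere[[ch]],
      end = ref$centromere[[ch]] + 1L,
      name = "centromere", score = 0L, strand = "+")
  }
  if (nrow(ref$repeats) > 0) {
    rp <- ref$repeats
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = rep(rp$chrom, 2L),
      start = c(rp$start1, rp$start2), end = c(rp$end1, rp$end2),
      name = paste0(rep(rp$family, 2L), "_p", rep(seq_len(nrow(rp)), 2L),
                    "_copy", rep(1:2, each = nrow(rp)),
                    "_id", rep(round(rp$identity * 100), 2L)),
      score = 0L,
      strand = c(rep("+", nrow(rp)),
                 ifelse(rp$orientation == "inverted", "-", "+")))
  }
  bed_df <- do.call(rbind, rows)
  utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(fasta, bed))
}

#' Read a reference genome written by [write_genome()]
#'
#' @param fasta,bed Paths written by [write_genome()].
#' @return A `reference_genome` (annotation set recovered from BED names).
#' @export
read_genome <- function(fasta, bed) {
  seqs <- read_fasta(fasta)
  mito <- NULL
  if ("chrM_like" %in% names(seqs)) {
    mito <- seqs[["chrM_like"]]
    attr(mito, "circular") <- TRUE
    seqs[["chrM_like"]] <- NULL
  }
  bed_df <- utils::read.table(bed, sep = "\t", header = FALSE,
                              col.names = c("chrom", "start", "end", "name",
                                            "score", "strand"),
                              stringsAsFactors = FALSE)
  cen <- bed_df[bed_df$name == "centromere", ]
  centromere <- stats::setNames(as.numeric(cen$start), cen$chrom)
  caps <- bed_df[bed_df$name == "telomere_cap_p", ]
  telomere_units <- if (nrow(caps) > 0) (caps$end[1] - caps$start[1]) %/% 6L else 0L
  reps <- bed_df[grepl("_p\\d+_copy[12]_id", bed_df$name), ]
  rep_tab <- empty_repeat_table()
  if (nrow(reps) > 0) {
    key <- sub("_copy[12]_id.*$", "", reps$name)
    for (k in unique(key)) {
      pair <- reps[key == k, ]
      pair <- pair[order(pair$name), ]
      stopifnot(nrow(pair) == 2)
      rep_tab <- rbind(rep_tab, data.frame(
        family = sub("_p\\d+$", "", k), chrom = pair$chrom[1],
        start1 = as.numeric(pair$start[1]), end1 = as.numeric(pair$end[1]),
        start2 = as.numeric(pair$start[2]), end2 = as.numeric(pair$end[2]),
        orientation = if (pair$strand[2] == "-") "inverted" else "direct",
        identity = as.numeric(sub("^.*_id", "", pair$name[1])) / 100,
        length = as.numeric(pair$end[1] - pair$start[1]),
        stringsAsFactors = FALSE))
    }
  }
  reference_genome(seqs, centromere, telomere_units, rep_tab, mito)
}
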