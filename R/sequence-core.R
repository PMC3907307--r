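# DNA-string primitives shared by the simulator, analyzer and null model.
# Sequences are plain uppercase character strings over {A,C,G,T,N}; all
# coordinates are 0-based, half-open. 1-based inclusive coordinates appear
# only in BED/report serialization.

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Validate and normalize a DNA sequence
#'
#' Uppercases the input and checks the alphabet `{A,C,G,T,N}`.
#'
#' @param seq Character scalar.
#' @return Uppercased sequence string.
#' @keywords internal
dna_check <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    stop_foldback("sequence contains characters outside {A,C,G,T,N}",
                  "foldback_alphabet_error")
  seq
}

#' Reverse complement
#'
#' Watson-Crick reverse complement; `N` maps to `N`. Input is validated
#' against the `{A,C,G,T,N}` alphabet and uppercased.
#'
#' @param seq DNA sequence (character scalar).
#' @return Reverse-complemented sequence.
#' @export
#' @examples
#' revcomp("TTAGGG")  # "CCCTAA"
revcomp <- function(seq) {
  seq <- dna_check(seq)
  if (nchar(seq) == 0L) return(seq)
  # chartr + reverse; avoids a DNAString round trip for short strings
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# fast complement of a character vector of single bases
comp_bases <- function(x) unname(.COMP[x])

#' Inverted self-microhomology of a spacer sequence
#'
#' Number of basepairs of microhomology between the 3' end of a sequence and
#' the reverse complement of its 5' end: the largest `k` such that
#' `suffix(S, k) == revcomp(prefix(S, k))`, exact matching only (`N` never
#' matches anything, including `N`). `k` is capped at `floor(n/2)` so that the
#' prefix and suffix never overlap; real disomic spacers (hundreds of bp and
#' up) never reach the cap, but degenerate short inputs need the rule.
#'
#' The condition is nested in `k` (it is equivalent to
#' `S[n - j] == complement(S[j - 1])` for all `j <= k`, 0-based), so the
#' maximum is found by extending from `j = 1` until the first mismatch.
#'
#' @param spacer DNA sequence of length >= 2.
#' @return Non-negative integer microhomology length.
#' @export
#' @examples
#' inverted_mh_self("GATCAAAAAGATC")  # 4
inverted_mh_self <- function(spacer) {
  spacer <- dna_check(spacer)
  n <- nchar(spacer)
  if (n < 2L)
    stop_foldback("spacer must have length >= 2", "foldback_range_error")
  cap <- n %/% 2L
  if (cap == 0L) return(0L)
  suf <- strsplit(substr(spacer, n - cap + 1L, n), "", fixed = TRUE)[[1L]]
  pre <- strsplit(substr(spacer, 1L, cap), "", fixed = TRUE)[[1L]]
  # j-th pair: S[n-j] (0-based) vs complement(S[j-1])
  ok <- rev(suf) == comp_bases(pre) & rev(suf) != "N"
  mismatch <- which(!ok)
  if (length(mismatch) == 0L) cap else mismatch[1L] - 1L
}

#' Inverted microhomology between the two ends of a genomic interval
#'
#' Junction-level inverted-microhomology operator: for a disomic spacer
#' `[d, e)` on one chromosome, the largest `k` with
#' `ref[e-k..e) == revcomp(ref[d..d+k))` — the basepairs shared between the 3'
#' end of the spacer and the reverse complement of its 5' end, exactly the
#' quantity the fold-back anneal requires and the quantity counted by the null
#' model. Capped at `floor((e-d)/2)` so the two ends never overlap. `N` never
#' matches. Applied to a "chromosome" consisting of the spacer alone
#' (`d = 0`, `e = n`) it reduces to [inverted_mh_self()].
#'
#' @param ref A [reference_genome] object (or a bare named list of sequences).
#' @param chrom Chromosome identifier.
#' @param e Spacer end, 0-based half-open (distal-most retained disomic
#'   base + 1).
#' @param d Spacer start, 0-based; `d < e`.
#' @return Non-negative integer microhomology length.
#' @export
inverted_mh_pair <- function(ref, chrom, e, d) {
  s <- ref_chrom(ref, chrom)
  n <- nchar(s)
  if (!(d >= 0 && d < e && e <= n))
    stop_foldback("require 0 <= d < e <= chromosome length",
                  "foldback_range_error")
  cap <- (e - d) %/% 2
  if (cap == 0) return(0L)
  k <- 0L
  # chunked extension: windows of 256 bp are ample for junction microhomology
  chunk <- 256L
  repeat {
    take <- min(chunk, cap - k)
    if (take <= 0L) break
    suf <- strsplit(substr(s, e - k - take + 1L, e - k), "", fixed = TRUE)[[1L]]
    pre <- strsplit(substr(s, d + k + 1L, d + k + take), "", fixed = TRUE)[[1L]]
    ok <- rev(suf) == comp_bases(pre) & rev(suf) != "N"
    mism <- which(!ok)
    if (length(mism) > 0L) return(k + mism[1L] - 1L)
    k <- k + take
  }
  as.integer(k)
}

#' Telomere-repeat run at the ends of a sequence
#'
#' Finds the longest stretch at either end of `seq` that tiles the periodic
#' telomere repeat — `(TTAGGG)n` on the plus strand or `(CCCTAA)n` on the
#' minus strand — in any of the six phase offsets. Units are complete 6-bp
#' periods (`floor(run_length / 6)`); a side is considered telomeric when
#' `units >= 2`.
#'
#' @param seq DNA sequence.
#' @param side `"both"` (default, report the better end), `"left"` or
#'   `"right"`.
#' @return List with `units`, `strand` (`"+"`/`"-"`), `phase` (0..5 offset
#'   into the repeat unit at the run start), `side` (`"left"`/`"right"`) and
#'   `run_length` in bp.
#' @export
#' @examples
#' telomere_run("TTAGGGTTAGGGTTAGGG")  # 3 units, + strand, phase 0
telomere_run <- function(seq, side = c("both", "left", "right")) {
  side <- match.arg(side)
  seq <- dna_check(seq)
  n <- nchar(seq)
  chars <- if (n > 0L) strsplit(seq, "", fixed = TRUE)[[1L]] else character(0)
  motifs <- c("+" = "TTAGGG", "-" = "CCCTAA")
  best <- list(units = 0L, strand = "+", phase = 0L, side = side,
               run_length = 0L)
  scan_end <- function(which_end) {
    for (st in names(motifs)) {
      m <- strsplit(motifs[[st]], "", fixed = TRUE)[[1L]]
      for (phase in 0:5) {
        if (which_end == "left") {
          i <- 0L
          while (i < n && chars[i + 1L] == m[(phase + i) %% 6L + 1L]) i <- i + 1L
          run <- i
          run_phase <- phase
        } else {
          # match backwards from the right end; phase reported at run start
          i <- 0L
          while (i < n && chars[n - i] == m[(phase - 1L - i) %% 6L + 1L])
            i <- i + 1L
          run <- i
          run_phase <- ((phase - run) %% 6L)
        }
        units <- run %/% 6L
        if (units > best$units ||
            (units == best$units && run > best$run_length)) {
          best <<- list(units = as.integer(units), strand = st,
                        phase = as.integer(run_phase), side = which_end,
                        run_length = as.integer(run))
        }
      }
    }
  }
  if (side %in% c("both", "left")) scan_end("left")
  if (side %in% c("both", "right")) scan_end("right")
  best
}

#' Read a (multi-)FASTA file
#'
#' Sequences are uppercased on input and validated against `{A,C,G,T,N}`.
#'
#' @param path FASTA file path.
#' @return Named list of sequence strings.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- lapply(as.character(x), dna_check)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param seqs Named list or character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
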