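# Brute-force oracles and fixture builders shared across the suite.
# Oracles deliberately use whole-substring scans (not the incremental
# two-pointer extension of the implementation) so the two routes are
# independent.

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(map[strsplit(s, "", fixed = TRUE)[[1]]])), collapse = "")
}

# largest k <= floor(n/2) with suffix(S,k) == revcomp(prefix(S,k)), scanning
# every k; N disqualifies a k outright
oracle_mh_self <- function(s) {
  n <- nchar(s)
  best <- 0L
  for (k in seq_len(n %/% 2)) {
    suf <- substr(s, n - k + 1, n)
    pre <- substr(s, 1, k)
    if (!grepl("N", suf) && !grepl("N", pre) &&
        suf == oracle_revcomp(pre)) best <- k
  }
  best
}

oracle_mh_pair <- function(chrom_seq, e, d) {
  # ref[e-k..e) == revcomp(ref[d..d+k)), k <= floor((e-d)/2)
  best <- 0L
  for (k in seq_len((e - d) %/% 2)) {
    suf <- substr(chrom_seq, e - k + 1, e)
    pre <- substr(chrom_seq, d + 1, d + k)
    if (!grepl("N", suf) && !grepl("N", pre) &&
        suf == oracle_revcomp(pre)) best <- k
  }
  best
}

# longest telomeric stretch at one end by comparing against an explicitly
# built periodic string, over all strands and phases
oracle_telomere_end <- function(s, end = c("left", "right")) {
  end <- match.arg(end)
  n <- nchar(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  best <- 0L
  for (motif in c("TTAGGG", "CCCTAA")) {
    period <- strsplit(strrep(motif, ceiling(n / 6) + 2), "",
                       fixed = TRUE)[[1]]
    for (phase in 0:5) {
      tile <- period[(phase + 1):(phase + n)]
      agree <- chars == tile
      run <- if (end == "left") {
        w <- which(!agree); if (length(w) == 0) n else w[1] - 1L
      } else {
        w <- which(!rev(agree)); if (length(w) == 0) n else w[1] - 1L
      }
      best <- max(best, run)
    }
  }
  best %/% 6L
}

# a compact reference with a planted anneal site; no telomere caps so base
# statistics stay iid where needed
make_event_fixture <- function(L = 3e5, spacer = 3000, mh = 4,
                               deletion = 5e4, seed = 7,
                               telomere_units = 50) {
  lengths <- c(chr1 = L, chr2 = ceiling(L * 0.6))
  ref <- generate_reference(lengths, telomere_units = telomere_units,
                            seed = seed)
  e <- L - deletion
  d <- e - spacer
  ref <- plant_anneal_site(ref, "chr1", d, e, mh)
  list(ref = ref, chrom = "chr1", e = e, d = d, L = L)
}

build_derivative <- function(fx, p = NULL, mode = "telomere", ...) {
  ev <- foldback_event(fx$ref, fx$chrom, d = fx$d, e = fx$e)
  p <- p %||% floor((fx$ref$centromere[[fx$chrom]] + fx$d) / 2)
  der <- break_dicentric(fx$ref, form_dicentric(fx$ref, ev), p)$invdup
  resolve_derivative(der, fx$ref, mode, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

binom_ci99 <- function(n, p) qbinom(c(0.005, 0.995), n, p)
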