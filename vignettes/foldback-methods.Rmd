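---
title: "Fold-back inverted duplications: model, junction analysis, and null model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fold-back inverted duplications: model, junction analysis, and null model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldback)
```

## The mechanistic model

The package simulates the fold-back route to an inverted duplication
adjacent to a terminal deletion, in five explicit steps:

1. **Double-strand break.** A break at position `b` on the q arm removes
   the terminal segment `[b, L)` together with its telomere.
2. **Resection and intrastrand annealing.** 5′→3′ resection exposes a 3′
   overhang whose end retreats to `e <= b`. The overhang pairs with the
   same strand at a more proximal site `d` wherever the sequence ending at
   `e` is the reverse complement of the sequence starting at `d` — the
   inverted microhomology `k = inverted_mh_pair(ref, chrom, e, d)`. The
   hairpin loop `[d, e)` is the future **disomic spacer**.
3. **Replication to a dicentric.** After DNA synthesis and replication the
   molecule is the linear dicentric `ref[0..e) + revcomp(ref[0..d))`,
   carrying the spacer once and two centromere copies. Hairpin
   intermediates are never materialized: every observable derives from this
   post-replication product.
4. **Breakage-fusion-bridge resolution.** A second break at `p` (between
   the centromere copies, proximal to the duplication) yields the
   inverted-duplication product `ref[0..e) + revcomp(ref[p..d))` — dosage 2
   over `[p, d)`, 1 over `[0, p)` and the spacer `[d, e)`, 0 beyond `e` —
   and a sibling terminal deletion that shows no trace of the fold-back.
5. **Healing.** The free end is resolved by telomere addition (a phased
   `(TTAGGG)n` array, with 0–4 bp of junction homology to the repeat when
   the sequence allows it), by capture of another chromosome's terminal
   segment (inversion-translocation), or by fusion with the p arm into a
   ring. Ring fusion first trims both fusing telomere caps, since a ring
   forms only after the ends have lost telomere protection.

Junction insertions are modeled as events at the junction point: templated
copies of nearby sequence in either orientation, replication-slippage
duplications of up to 10 junction-local bases, segments of a circular
mitochondrial-like donor, or untemplated bases. A junction carries either
microhomology or an insertion, never both; when an insertion is added the
anneal microhomology is retained in truth as `anneal_k` but the junction's
observable microhomology becomes 0.

### Assumptions

* Resection is modeled only through its observable consequence `e <= b`;
  resection length and loop length are not separately identifiable from a
  junction, so only `e` and `d` are treated as testable.
* Divergence of planted repeats is substitution-only. This keeps all
  junction arithmetic exact (no indel offsets) and suffices to realize any
  target identity.
* One BFB cycle is simulated; the junction set of a resolved single cycle
  is the observable unit.
* Amplicon sequencing is error-free (a stand-in for finished capillary
  reads); an error model would sit between `emit_amplicon` and
  `split_align` and is out of scope.

## Junction operators and the breakpoint convention

The central operator counts the basepairs shared between the 3′ end of a
spacer and the reverse complement of its 5′ end:
`suffix(S, k) == revcomp(prefix(S, k))`, exact matching, `N` never matching,
capped at `floor(n/2)` so prefix and suffix cannot overlap (real spacers
never approach the cap; degenerate short inputs need the rule). The
junction-level form `inverted_mh_pair(ref, chrom, e, d)` applies the same
comparison to `[e-k..e)` versus `[d..d+k)` and reduces to the self form
when the spacer is the whole sequence. This is the anneal condition of the
mechanism, the quantity tabulated by the null model, and the query overlap
that split alignment of a junction amplicon produces — one operator,
measured three ways, which is what makes exact round-trips possible.

Microhomology makes breakpoint coordinates ambiguous within `k` bases, so a
convention is required. Both the simulator's truth records and the junction
caller shift shared bases maximally onto the forward (disomic) side: truth
coordinates are canonicalized by `(e, d) -> (e+1, d-1)` while
`ref[e] == complement(ref[d-1])`, and the caller reports the forward
alignment at its maximal extension. Under one shared convention, called
spacer sizes equal truth exactly; under different conventions they may
differ by up to `k` bases, which is also the caveat that applies when
comparing any two studies' published coordinates.

## The analyzer

`split_align` seeds with `min_anchor = 20` exact bases from each amplicon
end against both strands of every chromosome, then extends each seed to its
maximal ungapped exact run. Twenty exact bases anchor by chance with
probability about `L / 4^20` per side — negligible even on a 50-Mb genome —
and ungapped extension is correct because the generator's divergence is
substitution-only. Query overlap of the two alignments is the
microhomology; a query gap is the insertion. Telomeric amplicon ends (two
or more `TTAGGG`/`CCCTAA` units in any phase) are recognized before seeding,
because a telomere array belongs to no reference chromosome.

Classification applies the junction taxonomy in order: telomeric side →
inversion-telomere; sides on different chromosomes →
inversion-translocation; one chromosome, opposite strands, reverse-side
coordinate proximal → disomy-inversion with spacer `e - d`. Anything else —
colinear sides, reverse-then-forward geometry (a ring fusion reads this
way), `e <= d` — is returned `unresolved` with a diagnostic rather than
forced into a class.

Insertion origins are sought within ±1 kb of each breakpoint (most real
junction insertions are junction-local), in both orientations, at ≥90%
identity, then against the mitochondrial-like donor; insertions under 4 bp
are reported `unclassifiable_short` because a ≤3-bp string matches
essentially anywhere. A slippage insertion is junction-local
direct-orientation templating, and is recovered as `templated_direct`.

## Array CGH

Probes are placed every `probe_spacing` bp; a diploid with one rearranged
homolog gives expected log2 ratios of `log2(3/2) ≈ +0.585` over the
duplication, `log2(1/2) = -1` over the deletion, and 0 elsewhere, plus
Gaussian noise (`noise_sd`, default 0.1 — a typical per-probe spread for
oligonucleotide arrays). Segmentation smooths with a **running median**
(window `w = 5` probes) and thresholds at the midpoints (−0.5, +0.2925),
merging segments shorter than 3 probes. A running median rather than a mean
is deliberate: at a direct duplication-to-deletion boundary a mean
interpolates through the disomic band and invents a spacer where none is
probed, while a median switches states within `w %/% 2` probes. The spacer
estimate — distance from the most distal duplicated probe to the most
proximal deleted probe — is therefore accurate to about two probe spacings,
which is also why a ~3.4-kb spacer is measurable at 200-bp spacing (17
probes inside it) and undetectable at 75-kb spacing (expected probes inside:
fewer than one).

## The null model

`draw_spacers` draws interval lengths uniformly on `[100, 70466)` bp — the
upper bound is the largest sequenced spacer; only the bound is dictated by
the cohort, so the length law is a declared choice echoed in output
metadata — with the distal end uniform within 5.5 Mb (the cohort's median
terminal deletion, treated as a constant) of a uniformly chosen
chromosome's q terminus. `null_distribution` applies the microhomology
operator to each interval; `empirical_p(c, n, m)` is the ratio of
`m`-subset counts, computed as a running product so that values near
`1e-12` lose no precision. It is exactly 0 when `c < m` and exactly 1 when
`c = n`; `m > n` is a domain error.

On iid synthetic genomes the null tail obeys `P(k >= x) = 4^-x`, and the
suite checks `x = 1..4` at 10,000 draws against exact binomial 99%
intervals. On a real genome the zero-microhomology fraction is lower than
the iid 75% (repeats and base composition create excess self-similarity);
the package records its own null rather than asserting any genome-specific
fraction, which is also why the enrichment p-value computed from a
synthetic null differs from one computed from a published null count — both
are reported separately by `analysis/02_microhomology_null.R`.

## The synthetic-data generator

Generated chromosomes emulate the features the analysis actually consumes:
telomere caps at both ends (default 500 units — long enough for telomere
detection, small at desk scale), a centromere position (a coordinate, not a
sequence feature: it only decides which BFB products are monocentric),
planted repeat pairs at controlled identity and length (e.g. 90%/296 bp,
95%/330 bp — the scales at which hybrid-repeat junctions arise), and a
16,569-bp circular mitochondrial-like donor. The cohort simulator draws
fold-back loop sizes log-uniformly over the sequenced-spacer range
(700–70,466 bp; a log-uniform law puts the bulk of mass at a few kb, where
observed spacers concentrate) and anneal microhomologies uniformly on
2–8 bp, planting each anneal site before any derivative is built so that
every event lives on one final reference.

What the generator does **not** emulate: real repeat family consensus and
density, CpG and isochore structure, assembly gaps, sequencing error, and
real-genome coordinates. Passing round-trip tests therefore demonstrates
the internal consistency of simulator, convention, and analyzer — not
performance on real reads, where alignment ambiguity in repeat-rich
breakpoint regions is the dominant difficulty.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; 1-based appears
  only in serialized reports and BED is half-open by definition.
* Anneal-site search encodes `min_mh`-mers in base 4 and matches reverse
  complements through a code table, then verifies candidates by extension;
  the `nearest` policy (smallest spacer, ties by larger `k` then smaller
  `d`) is the default and is deterministic.
* Telomere-healing phase: among the six phases of the telomere repeat, the
  one realizing the requested junction homology is chosen when achievable;
  otherwise the largest achievable value below it, with the achieved value
  recorded in truth. (Not every requested value is realizable: the junction
  bases are fixed by the derivative's end.)
* Stage seeds derive from one top-level seed by hashing the stage name into
  `[1, 2^31 - 2]`, so each stage is independently reproducible and reruns
  are byte-identical (manifests carry md5 digests to prove it).
* Degenerate inputs fail loudly with classed conditions: no admissible
  anneal site, a break outside the inter-centromere interval, an amplicon
  shorter than two anchors, an infeasible repeat placement, `m > n` in the
  p-value.

## Problem sizes

The shipped analyses use 0.5–2-Mb chromosomes for cohort simulation (36
junctions per default run), 10,000 draws for the null, and one 50-Mb
chromosome for the full-scale worked example; the test suite re-runs the
same computations at these sizes, including 200 insertion-free round trips
for the recovery rates. These sizes were chosen so that each driver
completes in seconds to a couple of minutes on one CPU while keeping every
rate estimate's confidence interval tight enough to be meaningful.

## Known limitations

* Ungapped alignment only: indel-containing junction flanks would defeat
  the extension step (consistent with the generator, which never introduces
  indels).
* Ring-fusion junctions are constructed and emitted but classified
  `unresolved` (with a ring-geometry diagnostic): the junction taxonomy
  models the three junction classes that are sequenced in practice.
* Multi-cycle BFB is not tracked beyond re-entry with the invdup product;
  truth bookkeeping covers a single resolved cycle.
* The discordant-pair clusterer is a toy over truth-mapped reads — it
  demonstrates the signatures (inverted orientation, interchromosomal,
  span/order violations), not an aligner-grade SV caller.
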