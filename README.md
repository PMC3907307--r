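# foldback

Simulation and breakpoint-junction analysis of fold-back inverted
duplications.

## The problem

Large inverted duplications adjacent to terminal deletions are a recurrent
class of chromosome rearrangement in constitutional disease and in cancer.
Sequenced breakpoint junctions of such chromosomes show a characteristic
architecture: a short **disomic spacer** (hundreds of bp to tens of kb at
normal copy number) separates the non-inverted and inverted copies of the
duplication, and short **inverted microhomology** (2–8 bp) joins the distal
end of the spacer to the start of the inverted duplication. Both features
are signatures of a *fold-back* mechanism: a double-strand break removes the
chromosome end; 5′→3′ resection exposes a 3′ overhang; the overhang
intrastrand-pairs with nearby inverted-homologous sequence (the loop of the
hairpin becomes the spacer); DNA replication then yields a dicentric
chromosome that breaks in a breakage-fusion-bridge (BFB) cycle, leaving an
inverted-duplication chromosome healed by telomere addition, translocation,
or ring formation.

This package is for researchers studying structural-variant formation who
want to (i) simulate that mechanism end to end on synthetic genomes with
full truth records, (ii) recover junction structure from junction (amplicon)
sequences the way breakpoint studies do — split alignment, junction
classification, microhomology/insertion calling, spacer measurement — and
(iii) test whether observed junction microhomology exceeds chance.

## The statistics at the core

For a spacer `S = ref[d..e)` the inverted microhomology is the largest `k`
with

```
ref[e-k..e) == revcomp(ref[d..d+k))        (exact match, N never matches)
```

i.e. the basepairs shared between the 3′ end of the spacer and the reverse
complement of its 5′ end. Under an iid base model `P(k >= x) = 4^-x`, a
property the package verifies against its own null draws.

The enrichment test is combinatorial: with `c` of `n` simulated spacers at
or above the threshold and `m` observed junctions all at or above it, the
empirical p-value is

```
p = C(c, m) / C(n, m) = prod_{i=0}^{m-1} (c - i) / (n - i)
```

With the reported null counts (`c = 134`, `n = 1000`, `m = 13` junctions at
the 2-bp threshold) this gives `p = 2.7e-12` (2 s.f.).

## Worked example

A cohort-scale event on a 50-Mb synthetic chromosome — terminal deletion
5,803,294 bp, inverted duplication 41,659,284 bp, disomic spacer 2,047 bp,
4-bp anneal microhomology — simulated, healed by telomere addition, and
recovered by the analyzer from one 800-bp amplicon:

```sh
Rscript analysis/05_worked_example.R
```

prints

```
truth:  deletion 5,803,294 bp, duplication 41,659,284 bp, spacer 2,047 bp, mh 4 bp
called: disomy_inversion junction, spacer 2,047 bp, mh 4 bp
```

The call is exact because simulator truth and junction caller share one
breakpoint convention (shared junction bases assigned maximally to the
disomic side).

The other analysis drivers:

```sh
Rscript analysis/01_simulate_and_call.R    # simulate a 36-junction cohort, call every junction,
                                           # evaluate against truth (100% type accuracy,
                                           # 100% exact spacer recovery on the default run)
Rscript analysis/02_microhomology_null.R   # 10,000-spacer null; observed tail P(k>=2) = 0.0611
                                           # vs iid 0.0625; enrichment p for m = 13
Rscript analysis/03_cohort_stats.R         # packaged junction table: median spacer 3,428 bp,
                                           # range 766-70,466 bp, 34 sequenced junctions
Rscript analysis/04_cgh_detectability.R    # a 3,428-bp spacer: 17 probes and a 3,600-bp estimate
                                           # at 200-bp array spacing; invisible at 75-kb spacing
```

Each writes its tables under `results/`.

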