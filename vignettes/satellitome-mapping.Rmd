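---
title: "Satellitome characterization and in silico chromosome mapping with satmapper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Satellitome characterization and in silico chromosome mapping with satmapper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satmapper)
```

## The problem

Satellite DNA (satDNA) is non-coding DNA organized as long tandem arrays
of a repeated unit (the *monomer*; its length is the repeat unit length,
RUL). The complete catalogue of satDNA families in a genome is its
*satellitome*. Classically satDNA was equated with pericentromeric
heterochromatin, but chromosome-scale assemblies make it possible to ask
where every family actually sits: a consensus monomer can be located on
assembled chromosomes directly, an in silico counterpart to FISH that
also reveals families too scarce or too dispersed to produce a
hybridization signal.

`satmapper` implements that workflow end to end for a library of
consensus monomers (one per family, e.g. derived from read-clustering
tools upstream):

1. **Annotation** — locate every monomer-scale match of each family on
   each chromosome at a similarity threshold, and merge runs of matches
   into tandem arrays (`annotate_assembly()`, serialized with
   `write_gff3()` / `write_bed()`).
2. **Quantification** — estimate each family's genome fraction and its
   Kimura two-parameter (K2P) divergence from unassembled sequencing
   reads masked against per-family search libraries
   (`mask_and_quantify()`), plus the abundance-by-divergence *repeat
   landscape* (`repeat_landscape()`).
3. **Summary and graphics** — satellitome aggregates
   (`summarize_satellitome()`), per-chromosome two-track distribution
   maps (`plot_chromosome_maps()`), and a single-call pipeline
   (`run_pipeline()`).
4. **Synthetic truth** — a generator that plants arrays of known
   location, copy number and divergence and simulates reads
   (`plant_arrays()`, `simulate_reads()`), so every step above is
   testable without external data.

De novo discovery of families from raw reads is deliberately out of
scope: the package consumes already-derived consensus monomers.

## The alignment model

Annotation and read masking share one scoring model: match `+1`,
mismatch `-1`, a gap of length $k$ costs $2 + k$ (gap opening 2,
extension 1). *Identity* is defined as matched columns divided by all
alignment columns, with indel columns counting against identity. This is
a deliberate, reproducible choice: annotation tools used interactively
report a "similarity" percentage without a published alignment model, so
the package fixes a conservative, tool-independent definition and
honors the conventional 70% threshold under it.

The chromosome scan aligns the *monomer itself* semi-globally — the
query end to end, against a free-standing window of the chromosome — at
**every** subject offset, on both strands, via a single-pass dynamic
program in C++ (`O(monomer x chromosome)` time, linear memory). Because
every offset is scanned, phase is irrelevant: inside a tandem array,
every in-register window matches the consensus no matter where the
array's first copy starts relative to the consensus origin. This is why
the scan does not need to query a dimer and post-split matches at
monomer boundaries; dimerization earns its keep only with heuristic
seed-based search engines, and splitting a gapped dimer alignment at the
monomer boundary is ill-defined. A brute-force per-offset reference
implementation (separate code path, quadratic time) ships in the package
and the test suite checks both routes against each other.

Candidate matches above the identity threshold are resolved within each
family by keeping the higher-identity hit wherever two candidates
overlap (ties: leftmost, then plus strand). Families are annotated
independently, so arrays of different families may interleave — as they
do in real pericentromeric blocks. Consecutive same-strand hits closer
than `max_gap_factor x RUL` (default 1 repeat unit) merge into one
array, the unit drawn on the chromosome maps.

Substitution columns of every alignment are classified as transitions
(A↔G, C↔T) or transversions; gap and N columns are excluded. This feeds
the K2P distance

$$d = -\tfrac{1}{2}\,\ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big)$$

with $P$ and $Q$ the transition and transversion proportions over the
unambiguous, gap-free columns.

### Very short monomers

Percent identity over fewer than 20 columns at a 70% threshold is
meaninglessly permissive (a 5-bp telomeric motif would "match"
everywhere). Monomers under 20 bp are therefore annotated by exact
tandem-run detection instead: maximal runs of at least 4 exact
head-to-tail copies, on either strand, reported copy by copy at 100%
identity. The 4-copy floor keeps isolated chance occurrences of short
motifs out of the annotation.

## Read-based quantification

Abundance estimation mirrors library-masking quantification from
shotgun reads. Each family's *search library* is its monomer
concatenated head to tail: a dimer for RUL > 100 bp, otherwise the
smallest concatemer reaching 200 bp. The 200-bp floor guarantees that a
101-bp read drawn from any phase of a tandem array fits inside the
library sequence, which is the reason this dimer/concatemer rule exists
at all. A repeat unit of exactly 100 bp takes the dimer branch — its
dimer already reaches 200 bp, so both readings of the rule coincide.

Each read is aligned locally against every library sequence on both
strands (same scoring as the annotator; a single scoring model across
modules was preferred over per-module tuning). A read is masked when its
best alignment reaches the identity threshold (default 70%, mirroring
annotation) *and* covers at least half the read — without the coverage
floor, short perfect chance matches of a few bp would mask random reads.
Multi-matching reads are assigned deterministically: highest identity,
then longer aligned interval, then lower family rank.

Per family, abundance is masked bp over total read bp, and divergence is
the aligned-bp-weighted mean of per-read K2P estimates — weighting by
aligned length keeps a 30-bp edge fragment from counting as much as a
full-read alignment. Whether an unweighted mean was intended by masking
tools' per-family averages is genuinely ambiguous; the weighted choice
is declared here and applied consistently. Reads whose substitution
proportions saturate the K2P formula (log argument ≤ 0) stay in the
masked-bp tally but are excluded from the divergence mean, with a
warning.

The repeat landscape histograms masked bp by K2P bin (default 1% bins
over 0–30%); divergences above the top edge are clamped into the last
bin so each family's bins sum exactly to its abundance attributable to
K2P-defined hits.

## Satellitome summaries

`summarize_satellitome()` reports family count, total genome fraction,
combined top-*k* abundance, the divergence range and unweighted mean,
the RUL range, and a 100-bp-binned RUL histogram. One subtlety: the
divergence *range* is computed over non-telomeric families only (name
suffix `-tel`), while the *mean* covers all families. A telomeric
simple-sequence repeat is kept in the table as the catalogue demands,
but it is not a satDNA family proper, and its near-zero divergence would
otherwise define the satellitome's minimum; published satellitome
accounts follow exactly this convention, quoting a range that excludes
the telomeric entry alongside a mean that includes it.

The packaged table `inst/extdata/camericana_satellitome.tsv` transcribes
the 165-family satellitome of the beetle *Chrysolina americana* at
printed precision (family, % genome, K2P divergence, RUL, A+T%). One quirk is
preserved rather than silently corrected: the telomeric entry
`CameSat035-5-tel` prints 40.0% A+T although every rotation or
complement of TTAGG has 60% — the table is transcribed verbatim and the
discrepancy noted, not resolved. Aggregate
comparisons in the tests use a ±0.02 absolute tolerance to absorb
printed rounding.

Naming follows the standard satellitome convention
(`name_family()`): genus initial + three species letters + `Sat` +
3-digit abundance rank + `-` + RUL, e.g. `CameSat001-141`. Three digits
accommodate catalogues up to 999 families; rank 1000 is an error rather
than a silent format change. Ranking ties break by masked bp, then
input order, so re-runs are reproducible.

## The synthetic-data generator

`plant_arrays()` builds i.i.d. background chromosomes at 64.2% A+T — an
insect-like, satDNA-consistent composition (configurable) — and
overwrites planned intervals with tandem arrays. Each copy is mutated
independently to a target K2P divergence: per-site substitution
probability solved from the K2P closed form so the *expected* estimate
equals the target, transition:transversion odds 2:1 by default (typical
for nuclear DNA). Copies therefore scatter around the target as a real
homogenizing family would; family-level recovery, not per-copy
exactness, is the design goal. Targets requiring more than half the
sites to change are refused as saturated. `simulate_reads()` draws
uniform error-free 101-bp reads (both strands equiprobable) at a chosen
coverage; an optional uniform error rate and a paired mode (350-bp
fragments) exist but default off.

What the generator deliberately does **not** emulate: higher-order
repeat structure, variant monomers and indel-rich array edges, library
and GC bias in read sampling, and realistic sequencer error profiles.
Green tests on this generator therefore demonstrate the *estimators*
(alignment, masking, K2P arithmetic, merging) — not robustness to every
artifact of real sequencing data.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally, 1-based inclusive in
  GFF3, 0-based half-open in BED — each format's native convention.
* Tie-breaks are fixed everywhere (alignment: score, then matches, then
  shorter; overlap resolution: identity, then leftmost, then plus
  strand; read assignment: identity, length, family rank), so every
  stage is byte-reproducible from its inputs and seed.
* Empty sequences, all-N sequences, ambiguity codes beyond N, empty read
  sets, empty assemblies, rank overflow, saturated distances and
  out-of-bounds or overlapping planting plans are errors, not silent
  results. N excludes itself from A+T content (no compositional
  information) and from transition/transversion counts (K2P is defined
  over unambiguous substitutions).
* Equal-scoring gapped alignments can place an array edge a base or two
  differently between algorithmically distinct but model-identical
  implementations; the oracle-equivalence tests allow that while
  requiring identical starts, counts and identities.

## Validation scale

The shipped tests validate on deliberately small problems chosen to
exercise every code path: oracle equivalence on chromosomes up to 30 kb
(60–141-bp monomers), planted-array recovery on 100–150-kb chromosomes
with per-copy divergence up to 0.15, and read-based recovery with ~500
planted copies and ~10,000 reads per run (binomial-error bounds at that
depth). The package itself has no scale-dependent logic: the same scan
is linear in chromosome length, and full-genome runs differ only in
wall-clock time.

## A small worked run

```{r worked, eval = FALSE}
fam <- sat_families(
  monomer = paste(sample(c("A", "C", "G", "T"), 141, TRUE), collapse = ""),
  family = "famA"
)
plan <- plant_plan("famA", "chr1", 20000, 50, divergence = 0.07)
syn <- plant_arrays(plan, fam, c(chr1 = 100000), seed = 1)
ann <- annotate_assembly(fam, syn$genome, min_identity = 70)
reads <- simulate_reads(syn$genome, coverage = 2, seed = 2)
mq <- mask_and_quantify(reads, fam)
glance(ann)
repeat_landscape(mq)
autoplot(ann)
```

## Known limitations

* The annotator reports arrays of one family at a time; it does not
  segment higher-order repeats or call centromeres, and makes no
  inference about chromatin state.
* Read quantification assumes clean reads (no adapter or quality
  trimming is performed) and ignores base qualities.
* Abundance from masking is slightly conservative at array boundaries:
  read fragments overlapping an array by less than half a read length
  are not masked.
* The divergence of a family far beyond ~26% at the 70% threshold would
  be censored by the threshold itself; within the range observed in real
  satellitomes the tests show recovery within ±1.5 divergence points.
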