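---
title: "Methods: stage-ordered EST analysis with est454"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-ordered EST analysis with est454}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(est454)
```

## The problem

Early transcriptome projects for non-model crops sequenced cDNA libraries
from organs sampled along a biological gradient — here, blueberry flower
buds across cold acclimation (0, 397, 789 and 1333 chill units, a chill
unit being one hour between 0 and 7 °C), fruit across four ripening stages
(green, white, pink, blue), and leaves — on a 454 pyrosequencer, then
answered three questions from the reads alone:

1. **What genes are expressed?** Reads are assembled into unigenes —
   contigs (consensus of two or more overlapping reads) plus singletons.
2. **Which genes change with stage?** For each library's most abundant
   contigs, homologous reads are counted in every library; the percent of
   total reads per library forms a stage profile that is labelled *up*,
   *down*, *up then down*, *down then up* or *flat*. Selected predictions
   are checked by qPCR with the ΔΔCT method.
3. **Which unigenes can seed markers?** Unigenes are mined for SSRs
   (microsatellites) and filtered to primer-friendly candidates, which are
   then screened for amplification and polymorphism in mapping
   populations.

`est454` implements this chain as testable, deterministic components, with
a synthetic-data generator that plants known trends and SSR loci so every
downstream inference can be scored against ground truth.

## Synthetic data: the study conditions

`synthetic_config()` fixes the simulated conditions:

* **Design** — nine libraries (four bud stages, four fruit stages, one
  leaf library) sampled from one shared transcript pool
  (`stage_design()`).
* **Reads** — lengths are normal with mean 287 nt and sd 50 nt (the
  project-scale average read length for this platform generation),
  truncated to `[50, transcript length]`; each read is a uniformly placed
  substring of its transcript with i.i.d. substitutions at `error_rate`
  (0.5% by default). The error model is substitution-only: the pipeline
  never revisits basecalling, and the flowgram-specific homopolymer indel
  errors of real 454 data are deliberately out of scope. Consequences: the
  assembler can use an ungapped (diagonal) overlap layout, and alignment
  tests are not blurred by indels. Real-data behaviour around homopolymers
  is therefore *not* exercised by the test suite.
* **Trends** — each transcript carries one pattern label per
  trend-bearing organ group. Expression paths are multiplicative: a
  per-stage log2 exponent path (for four stages: `up` = 0,1,2,3; `down`
  reversed; `up_down` = 0,2,2,0; `down_up` = 2,0,0,2; `flat` = 0) scaled
  by `log2(effect_size)`. A single `effect_size` knob (default 2) thus
  controls the strength of every planted signal. Project-scale datasets
  of this kind only name qualitative patterns, so the multiplicative
  encoding is this package's formalization; it makes recovery tests
  parameterizable by one number.
* **Abundance** — base transcript weights follow a rank power law
  `r^-0.5`, a mild skew that gives a meaningful "most abundant" set
  without starving the tail. Per library, weights times trend multipliers
  are renormalized to proportions (so they sum to 1), and exactly
  `reads_per_library` reads are drawn multinomially. Because proportions
  are compositional, renormalization perturbs step ratios; the default
  trend mix keeps monotone trends to ~20% of the pool and pairs the tent
  patterns, which bounds that distortion well inside the trend-call band.
* **SSRs** — background sequence is i.i.d. uniform ACGT *rejection
  sampled* so that it contains no run meeting the mining thresholds; the
  requested loci are then copied in verbatim and the transcript is
  re-screened (and resampled if a planted run was extended by its flank).
  Mining over the pool must therefore return exactly the planted loci —
  a clean false-positive surface that random unscreened background would
  not give.
* **qPCR** — CT values follow the planted log2 paths relative to flat
  reference genes (`CT = base − log2(effect_size) × exponent + noise`),
  in triplicate, capped at 40 cycles. At zero noise the ΔΔCT round trip
  is exact by construction.

Determinism: the pipeline consumes one RNG stream seeded from
`config$seed`; the individually callable `sample_library_reads()` derives
a fixed per-library sub-seed from `config$seed` and the library's design
position, so single-library calls reproduce identically regardless of
call order.

## Read QC

`mask_adapters()` trims a read prefix matching an adapter suffix (and
vice versa) over at least 10 exact bases; matching is exact-substring and
end-anchored, which is sufficient at the simulated 0–1% substitution
rates but will miss adapters hit by an error — a documented limitation,
not an alignment-based trimmer. No adapter sequence is hard-coded: primer
sets are project-specific inputs. `filter_short()` then drops reads under
50 nt. The proprietary quality filtering of the original basecaller is
replaced by an optional mean-quality threshold, disabled by default,
because synthetic reads carry no meaningful qualities.

## Greedy overlap-consensus assembly

The original studies used a vendor assembler whose internals are
unpublished; `assemble_greedy()` is this package's own desk-scale
replacement that reproduces the bookkeeping downstream stages need
(contig/singleton partition, per-library member counts).

* Candidate pairs come from a 16-mer index (a repeat guard skips k-mers
  occurring more than `max_bucket` times); overlap diagonals between a
  candidate pair are enumerated with 12-mers for sensitivity on noisy
  overlaps.
* An admissible merge is an ungapped end overlap of ≥ 30 nt (the relaxed
  overlap length this pipeline targets) at ≥ 95% identity, on either
  strand; its score is the number of matching bases.
* Merges are applied best-score-first; ties prefer the longer overlap,
  then the lexicographically smaller id pair. Reads are canonically
  ordered by id internally, so results are invariant under input order.
* After a merge the unit's consensus is recomputed by per-column majority
  vote over its reads, ties resolved by the first-placed member's base;
  no quality weighting (synthetic inputs carry none).
* Internally, the merge queue revalidates pair overlaps lazily: an event
  created from stale halves is re-scored against the current consensus
  when it surfaces. This keeps the run near-linear in practice without
  changing determinism; in rare low-coverage layouts an overlap that only
  emerges across a merge junction is surfaced at the minimum admissible
  priority rather than its final score, which can alter merge *order* but
  not the partition property.

The partition invariant — every input read in exactly one contig or
exactly one singleton — is asserted after assembly in the test suite, as
is the no-chimera property on error-free 5× synthetic libraries.

## Local alignment and E-values

Wherever the original chain called BLAST (read counting across libraries,
unigene-set comparison), `est454` uses its own `seed_extend_search()`:
an 11-mer subject index, seed diagonals clustered per subject, and banded
affine-gap (Gotoh) refinement around each cluster (±16 diagonals),
on both strands, keeping the best hit per query–subject pair. Scores use
BLASTN-like values (+1/−2, gap open −5, extend −2, where the first gapped
base costs the open penalty). Significance is the Karlin–Altschul formula
`E = K·m·n·exp(−λS)` with the classical ungapped nucleotide constants
K = 0.621, λ = 1.33 applied to gapped scores — a standard approximation,
declared as such. Hits are reported at E ≤ 1e−5, the conventional cutoff
for this kind of cross-library comparison.

`sw_align_oracle()` is the exact full-matrix Smith–Waterman the heuristic
is tested against: the heuristic can never exceed it, and equals it
whenever an exact shared 11-mer lies on the optimal path within the band.
Score ties in read assignment go to the lexicographically smaller contig
id, so counting is deterministic.

## Digital expression and trend calls

Read counts per contig and library come from best-hit-only assignment —
each read contributes to at most one contig, preventing double counting
(the original procedure does not state its rule; best-hit is the
conservative choice). Frequencies are percent of *total assembled reads*
per library, not reads-in-contigs, matching the "percent of total reads"
convention. The ~30 most abundant contigs per library (`top_n = 30`,
"approximately 30" resolved to exactly 30) are profiled across all
libraries.

The qualitative trend vocabulary is formalized as a fold band: step
`i → i+1` is *up* if `(f[i+1]+p)/(f[i]+p) ≥ τ`, *down* if `≤ 1/τ`, else
*flat*, with τ = 1.5 and pseudocount p = 1 read rescaled to frequency
space (`100·p/total`). The step string is collapsed with flats absorbed:
monotone → `up`/`down`; one sign change → `up_down`/`down_up`; all flat →
`flat`; two or more sign changes → `complex`. τ and p are configurable
and echoed in the report header. τ = 1.5 sits between the fold-2 planted
signal and the renormalization jitter of flat profiles; the reversal and
scale-invariance properties of the rule are asserted in the tests.

## ΔΔCT and concordance

Replicate CTs are summarized by arithmetic mean; the per-stage reference
level is the mean over reference genes of their mean CT (equivalent to a
geometric mean of linear quantities — the unpublished "global
normalization" of the original software is replaced by this standard
construction); `ΔCT = gene − reference`, and
`fold = 2^−(ΔCT − ΔCT(baseline))` with the baseline stage (unacclimated
buds; green fruit) at fold 1 exactly. No outlier rejection and no
amplification-efficiency correction are applied. Fold profiles are
classified with the same trend rule, and `concordance()` counts exact
pattern equality — the strictest reading of "similar to what was
predicted". Because several housekeeping candidates are plausible,
`ref_genes` is always an explicit input.

## EST-SSR mining

`find_ssrs()` reports every maximal perfect tandem repeat with a
primitive motif of length 2–5 meeting the thresholds DNR ≥ 5, TNR ≥ 4,
tetra ≥ 3, penta ≥ 3 repeats, on sequences ≥ 120 nt. A run is reported
once, under its primitive motif at its leftmost phase (an AT run is never
also ATAT); mononucleotide runs and motifs longer than 5 are never
reported; non-ACGT characters break runs; compound/interrupted repeats
stay separate maximal runs (no merging). Coordinates are 0-based
half-open everywhere, with `end − start = motif length × repeats`.

The canonical class of a motif is the lexicographic minimum over its
rotations and the rotations of its reverse complement (AG/GA/TC/CT → AG).
Summaries report category (motif-length) counts as percent of all SSRs
and percent of mined sequences, and class counts as percent of their
category — the arithmetic of the classic EST-SSR summary tables.

Primer candidacy uses whole-sequence GC between 40 and 60% and ≥ 20 nt of
flank on both sides. Whether the GC window should instead apply to the
primer-design region is genuinely ambiguous in the source conventions;
whole-sequence GC is the simpler reading and is what `primer_candidates()`
documents and applies. Marker screens are summarized as the percent of
primers amplifying in ≥ 1 accession and the percent called polymorphic,
integer-rounded.

## Unigene-set comparison

How "shared" unigenes between organ assemblies were originally counted is
unstated; `compare_unigene_sets()` declares its criterion: a unigene is
shared iff it has a cross-set homology hit at E ≤ 1e−5, and shared
entities are connected components of the bipartite cross-hit graph that
span both sets (so identical sets of size n share exactly n).

## Problem sizes and numerical choices

The shipped demo pipeline simulates 30 transcripts × 9 libraries × 400
reads and runs in well under a minute; the property suites use up to
1000 background sequences for SSR mining, 50 transcripts at 5× coverage
for assembly integrity, and 4 × 5000 reads for trend recovery — sizes
chosen so the full suite exercises every claim at desk scale. Reference
tables (the published category/class counts, per-assembly counts, the
100-primer screen and the 17 predicted-vs-observed trend pairs) are
shipped as TSVs under `inst/extdata/` and re-summarized through the same
package functions rather than asserted as constants.

Degenerate inputs are defined, not accidental: empty FASTA files parse to
empty read sets; empty assemblies summarize to zero rows; a zero library
total is an error for frequency tables; trend classification requires at
least two stages; `sw_align_oracle()` refuses sequences over 5000 nt
(it is quadratic by design).

## Known limitations

* No homopolymer/indel error model, hence no claims about flowgram-type
  errors.
* Adapter masking is exact and end-anchored only.
* Karlin–Altschul constants are the ungapped approximation applied to
  gapped scores.
* The assembler is a greedy desk-scale tool: it reproduces partition
  bookkeeping and clean-data reconstruction, not the contig counts of a
  production assembler on real, repeat-laden data.
* Frequencies-as-percentages are compositional; strong monotone trends in
  a small pool can shift apparent steps of other transcripts. The default
  generator mix bounds this, and the vignette section on synthetic data
  states the mechanism.
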