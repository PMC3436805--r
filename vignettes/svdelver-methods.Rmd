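---
title: "Structural variant discovery with svdelver: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural variant discovery with svdelver: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Structural variants (SVs) — deletions, tandem duplications, inversions and
translocations of genomic segments — leave two complementary footprints in
paired-end sequencing data. First, a read pair whose fragment straddles an SV
junction maps *discordantly*: its outer insert size, mate order, strand
combination or chromosome assignment violates what the sequencing library's
insert-size distribution predicts. Second, a read that crosses the junction
itself cannot be aligned contiguously and is either left unmapped (its mate
anchoring nearby) or soft-clipped; such *split reads* carry the breakpoint at
single-nucleotide resolution. svdelver integrates both: discordant-pair
clustering proposes candidate SV intervals with high sensitivity, and
split-read consensus alignment refines each candidate to exact breakpoints
with high specificity, including non-template microinsertions and
microhomology at the junction.

## Paired-end component

### Library profiles

Each input alignment file is one library with its own insert distribution.
`estimate_library_profile()` samples properly paired alignments (default
10,000), takes the modal relative orientation (`FR` for short-insert
paired-end, `RF` for mate-pair libraries) as the library default, and
estimates the outer insert size median and spread. The spread is the scaled
median absolute deviation rather than a plain standard deviation: in real
data the insert sample is contaminated by SV-spanning outliers, and the MAD
is consistent with the Normal SD (factor 1.4826) while ignoring them — hence
the `--mad-cutoff` name of the cutoff flag. A pair is a deletion-type outlier
when its outer insert exceeds `median + 3 * sd` (the `cutoff_sd = 3`
default).

### Signature classification

Uniquely mapping pairs (both mates mapped, mapping quality at least
`map_qual`, default 1 — the threshold is deliberately permissive and
configurable because aligner mapping-quality scales differ) are normalised so
the lexicographically smaller (chromosome, position) mate comes first, then
classified:

* `DEL`: default orientation, insert beyond the cutoff;
* `DUP`: mate order swapped with strands kept (an `RF` pattern in an `FR`
  library);
* `INV_LEFT` / `INV_RIGHT`: both mates on the same strand, the side naming
  which junction of the inversion the pair spans;
* `TRA_1..4`: interchromosomal pairs keyed by the normalised strand
  combination, which encodes both whether the chromosome order is preserved
  and whether the segments are relatively inverted;
* `CONCORDANT` otherwise.

Classification is a partition: every mapped primary pair receives exactly one
label. Secondary, supplementary and duplicate-flagged alignments are ignored
at BAM import. Coordinates are 0-based half-open internally; all text output
is 1-based.

### Variant graph and clique clustering

Per signature class (inversion sides and the four translocation classes are
clustered separately, and per chromosome or chromosome pair), discordant
pairs become nodes of an undirected weighted graph. Two pairs are connected
when both their left ends and their right ends lie within the expected insert
range; for pairs from different libraries the larger library's cutoff is
used, since an edge should exist if either library could explain the spread.
The weight is the absolute difference of the predicted SV sizes (outer span),
or for translocations the sum of the absolute differences of both mates'
leftmost positions. Because the input is sorted by leftmost position, a line
sweep terminates each inner scan at the first pair out of range.

Sequencing noise and mapping artifacts mean a connected component is usually
not a clique. Within each component the reported cluster is a heuristic
maximal clique: seeded with the minimum-weight edge, then repeatedly extended
through the smallest-weight incident edge whose endpoint is adjacent to every
current member. Ties in weight break toward smaller node index so results are
deterministic. One clique per component is reported; singletons are
discarded, so the minimum paired-end support is 2 (`--min-pairs`).

Cluster coordinates use the innermost member coordinates approaching each
breakpoint: for a deletion, the maximum upstream read end and the minimum
downstream read start. The mirrored rule is applied per breakpoint side for
the other types (the duplication interval is `[min left-read start, max
right-read end)`, and each inversion side uses the coordinates its reads
approach from). The resulting paired-end call is *imprecise*: it contains the
true event and is wider or narrower by at most roughly one insert length.

## Split-read component

For every paired-end call the package (i) collects candidate split reads,
(ii) builds a rearranged local reference, (iii) counts k-mer hits per
alignment diagonal for each candidate, (iv) selects and votes on the SV
offset, (v) builds a gapless majority-vote consensus, and (vi) aligns the
consensus with a double dynamic programming that resolves the breakpoint.

**Candidates.** A single-anchored pair (one mate mapped, one unmapped)
nominates its unmapped mate. The anchored mate's strand and the library
orientation imply the search direction; a binary search finds the closest
call breakpoint, accepted when it lies within `median_insert + 2 * sd` in the
search direction (the unmapped mate sits up to about one insert away from its
anchor) with `2 * sd` of slop against the direction, tolerating the
imprecision of the paired-end estimate. Ties between flanking breakpoints go
to the lower coordinate. The anchored strand also fixes the single alignment
orientation of the candidate — the k-mer stage never counts the disallowed
strand. Candidate sets are capped at `L = 1000` reads per call so repeat
pile-ups cannot dominate runtime. Optionally soft-clipped mapped reads are
admitted as well (`include_softclips`).

**SV reference.** The junction is reduced to a "deletion-type" prefix/suffix
split in every geometry. For deletions the call interval plus flanking
windows is extracted as-is. For the other types, windows of `median + 3 * sd`
around each predicted breakpoint are concatenated: suffix-origin before
prefix-origin for tandem duplications, one window reverse-complemented for
inversions, and partner-chromosome windows ordered and stranded by the
translocation class. A segment map back-translates any position in the
rearranged sequence to unique genomic coordinates; windows clamped at contig
ends are recorded in the map.

**Diagonals and offsets.** A k-mer index (`k = 7`) of the SV reference is
queried with each candidate's k-mers (skipping k-mers containing N), tallying
hits per alignment diagonal (reference offset minus read offset). Diagonals
are post-processed in decreasing hit order and each read k-mer counts only
toward the first diagonal processed that contains it, so repeated content
cannot double-count. Diagonals with fewer than `k_min = 3` hits are dropped;
a read survives only with at least two remaining diagonals whose two best
jointly cover at least half of the read's k-mers (which bounds detectable
microinsertions to less than half the read length). Survivor diagonals are
sorted by index and the offset between the most supported consecutive pair is
the read's vote. The modal offset across reads wins, unbiased by the
paired-end predicted length; ties break toward the paired-end length, then
toward the smaller offset. Calls with fewer than `min_split = 2` supporting
reads stay imprecise.

**Consensus.** Supporting reads are placed in the SV-reference frame by their
prefix diagonal (the pair member whose counted k-mers sit earlier in the
read) and each column takes the modal nucleotide; ties break toward the
earliest read, uncovered edge columns are trimmed, and internal coverage gaps
fail the call. The consensus is gapless by construction — indel sequencing
errors are not modelled, and a realignment-based gapped consensus is out of
scope.

**Split alignment.** Two affine-gap (Gotoh) scoring passes over the consensus
against the SV reference — global in the consensus, free at both reference
ends — yield a forward vector `f` (`f_i` = best alignment score of the
consensus prefix `1..i`) and a reverse vector `r` (`r_j` = best score of the
suffix `j..n`). The breakpoint maximises `f_i + r_j` over `j >= i + 1`;
`j > i + 1` leaves `c[i+1..j-1]` as a non-template microinsertion. When the
optimum is a clean split attained on a run of consecutive `i`, the run length
minus one is reported as microhomology and the breakpoint is left-aligned to
the run start. The affine scheme is match +5, mismatch −4, gap open −10, gap
extension −1 (a gap of length `g` costs `10 + g`); the scheme is exposed as a
parameter since the method itself does not prescribe one. The two passes are
implemented in C++ (the only hot inner loop in the package); the test suite
checks them against an exhaustive split-point enumeration built on
`Biostrings::pairwiseAlignment`. A minimum aligned flank of 10 bp on each
junction side avoids degenerate splits. Back-translation through the segment
map gives genomic breakpoints; a refined call is accepted when the consensus
identity is at least `min_quality = 0.8` and, for intrachromosomal events,
the split-read SV length confirms the paired-end length within 10%.

One subtlety deserves a note: with free reference ends, a true microinsertion
competes against alignments that absorb the inserted bases into a flank with
mismatches or small gaps. When the insertion is short and happens to
resemble the reference near a landing site, the absorbing alignment can score
equally or better, and the breakpoint shifts within a few bases. This is a
property of the scoring objective, not of the implementation — the exhaustive
oracle makes the same choice — and it is why reported microinsertions are a
lower bound on junction complexity.

## Merging and output

Inversions produce complementary left- and right-spanning calls. Calls whose
intervals have a reciprocal overlap (intersection over the longer interval)
of at least 80% are merged best-first by smallest absolute breakpoint
distance; each call merges at most once. Merged coordinates come from the
precise partner when exactly one is precise, from the higher split-read
support when both are, and from the interval midpoints when neither is —
merging never moves a precise call's breakpoints. Translocation junction
calls merge when they support the same relative orientation and their
predicted insertion positions are less than `z = 300` bp apart (strict),
closest pairs first. The same merging is applied to the paired-end-only call
set, so both caller modes are scored on event-level calls.

Output is VCF 4.2 with symbolic alleles (`<DEL>`, `<DUP>`, `<INV>`) and
breakend pairs for translocations, INFO keys for paired-end and split-read
support, mean mapping quality, consensus alignment quality
(matches over aligned consensus length), `CIPOS` for imprecise calls, and
microinsertion/microhomology annotations; genotype fields are emitted as
missing. A flat TSV mirror is available. Record order is deterministic, and
two runs from the same seed produce byte-identical files.

## The simulator

`sv_simulate()` generates the whole study: a seeded uniform-random reference
(a repeat-free stand-in for a real region; a user FASTA can be substituted),
non-overlapping planted events of configurable counts and sizes, FR read
pairs with Normal insert sizes truncated at twice the read length, and
i.i.d. substitution errors. Translocated segments remain in place in the donor the reads are sampled from, but are
excised from the calling reference and appended as separate contigs, so pairs
spanning the segment ends map interchromosomally.

`project_alignments()` replaces a real aligner with an exact truth lift-over:
a read inside one collinear donor/reference block (tolerating 5 bp of
junction overhang, mimicking an aligner's willingness to absorb a few
clipped bases) maps at its lifted coordinate; a read deeper across a junction
is emitted unmapped with its mapped mate, exactly the single-anchored pattern
the split-read search consumes. Mapped reads get mapping quality 60; an
optional exact-search check assigns 0 to reads whose sequence occurs more
than once in the reference, though on uniform random references duplicate
75-mers are vanishingly improbable, so the check is off by default. The
projection can be written as a real sorted, indexed BAM (`write_bam()`) and
read back (`read_alignments()`), which the tests use to show the BAM path and
the in-memory path produce identical calls.

What the simulator does *not* emulate — repeats and segmental duplications,
coverage and GC biases, indel errors, chimeric fragments, alignment ambiguity
— is exactly what makes real genomes harder. Passing benchmarks on this
harness therefore demonstrates the correctness of the clustering and
refinement machinery under the stated noise model, and bounds from above what
the same pipeline would achieve on real data. For that reason benchmark
comparisons against reference operating points for this class of caller are
read as "meets or exceeds", never as equality claims.

## Benchmark harness

`run_benchmark()` drives a parameter grid: per cell and replicate it
simulates, projects, calls in both modes, and scores with
`match_calls()` — greedy one-to-one matching by descending reciprocal
overlap, requiring at least 0.8 (the matching rule is declared here, since
benchmark studies rarely state theirs); translocations count as
recovered when the insertion-site and the partner-chromosome breakpoints are
both within the insert cutoff of the truth. Replicate `r` uses seed
`seed + r - 1` and medians over five replicates are reported. The default
desk scale is a 5 Mbp reference with 50 events per type (25 translocated
segments), which keeps the full grid within minutes on one CPU; sizes are uniform on 500–5000 bp and the
default cell is 15x coverage, 75 bp reads, Normal(300, 30) inserts, 1%
error.

A null observation worth recording: on an SV-free 5 Mbp genome at 15x, about
0.14% of pairs land beyond the 3-SD insert cutoff by chance, and with ~500k
pairs these tail pairs form a few dozen spurious low-support (2–4 pairs)
deletion clusters. This is why paired-end PPV *decreases* with coverage while
split-read PPV stays near 1: spurious clusters have no junction reads and
never refine. The package reproduces this behaviour rather than suppressing
it; the `LowQual` filter (imprecise calls with fewer than 3 pairs or mean
mapping quality below 20) marks most of them.

## Design choices and open parameters

| Parameter | Default | Why |
|---|---|---|
| `cutoff_sd` (`--mad-cutoff`) | 3 | standard outlier cutoff for a Normal-like insert distribution |
| `map_qual` | 1 | "uniquely mapping" operationalised; aligner-dependent |
| `min_pairs` | 2 | singleton clusters are discarded by construction |
| `k` / `k_min` | 7 / 3 | small k keeps recall high on short reads; the guided region preserves specificity |
| `L` (candidate cap) | 1000 | bounds work in repeat pile-ups |
| `min_split` | 2 | two independent junction reads; raise to enforce specificity |
| length consistency `c` | 10% | tolerates the paired-end interval's insert-scale slack |
| inversion merge overlap | 0.8 reciprocal | pairs only genuinely complementary sides |
| translocation merge `z` | 300 bp | about one insert length |
| scores (match/mismatch/open/ext) | +5/−4/−10/−1 | unspecified by the method; CLI-overridable |
| `min_quality` | 0.8 | consensus identity floor; unspecified, exposed |
| flanking window | median + 3·sd | covers junction-read placement error |
| junction margin `m` | 5 bp | mapped-vs-unmapped boundary; aligner-dependent |

Known limitations: no read-depth integration or genotyping (GT is emitted
missing); no enumeration of all maximal cliques, so two same-type events
sharing an endpoint collapse into one call; non-template insertions of at
least half the read length are undetectable by design of the top-2-diagonal
coverage rule; `FF_like` libraries are profiled but not classified.
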