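---
title: "Methods: BAC-end-sequence genome survey analysis with oakbes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BAC-end-sequence genome survey analysis with oakbes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oakbes)
```

## Scope

Before a genome is sequenced, a BAC library and a sample of BAC-end
sequences (BES) are often the first genome-wide view of its composition.
`oakbes` implements the statistics of such a survey: how deep the library
covers the genome, how much of the sequence is repetitive (both against
known repeat families and *ab initio*), how many microsatellites and
genes the genome likely carries, and whether mate pairs mapped onto a
related genome reveal conserved microsynteny. Because the real inputs of
such a survey (trace archives, repeat databases, reference genomes) are
external and large, the package ships a synthetic-data generator that
plants every feature with known truth, so the full pipeline is testable
at desk scale.

## Library coverage model

For a library of `N` random inserts of mean size `I` from a genome of
size `GS`, the probability that a given locus is present is the
Clarke–Carbon relation

$$P = 1 - (1 - I/GS)^N, \qquad N = \frac{\ln(1-P)}{\ln(1 - I/GS)}.$$

`recovery_probability()` evaluates the first form with `log1p`/`expm1`
so that the tiny per-clone probability `I/GS` (about `1.8e-4` for a
135 kb insert on a 740 Mb genome) loses no precision. Effective fold
coverage multiplies out clones that contribute no nuclear sequence:

$$\text{depth} = N\,(1-f_\text{empty})\,(1-f_\text{organelle})\,I/GS.$$

The simulated marker screen (`simulate_marker_screen()`) is the
empirical counterpart: single-copy loci are dropped uniformly on the
genome and each non-empty, non-organelle clone covering a locus scores a
hit, so hit counts are Binomial(N, I/GS), approximately Poisson(depth).
Contamination rates come with Clopper–Pearson intervals
(`contamination_rate()`), which the original style of survey reports as
bare percentages; the interval is extra information, not a changed
estimate.

## Repeat discovery by self-comparison

### The match rule

Two reads "match" when they share a local alignment that is at least 100
columns long and has at least 90% identity in **every** sliding
100-column window (`window_identity_pass()`). Gap columns count as
mismatches; alignments shorter than one window never pass. The
every-window form is deliberately conservative: a long alignment with one
diverged stretch fails, which suppresses chance matches gluing unrelated
regions together.

### The binomial null model

Under an i.i.d. background with base frequencies $f_i$, the probability
that a fixed pair of reads shows 90 matching positions in a 100-bp
window is approximated by the independence model

$$p_0 = \Big(\sum_i f_i^2\Big)^{90},$$

i.e. the per-position match probability raised to the required match
count. With uniform frequencies this is $0.25^{90} = 6.5\times10^{-55}$.
Comparing one read against `n_trials` others, the number of matches is
Binomial(`n_trials`, $p_0$); `match_count_threshold()` returns the
smallest `T` with $P(X \ge T) \le \alpha$ by exact tail evaluation
(a Poisson tail is used when `n_trials * p0 < 1e-3`, where the two are
numerically indistinguishable). At any realistic $p_0$ the threshold is
`T = 1`: a single match already refutes the random-background null, so
every matching read can be treated as repetitive. `n_trials` defaults to
`n_reads - 1` (each read is compared against every other read once) and
is overridable, since published analyses have used a fixed trial count.

### Aligner

`local_align()` is a desk-scale seed-gated local aligner: exact 11-mer
words shared between query and subject (either orientation) gate the
comparison, exactly as word seeding gates database search tools. Gated
pairs are aligned by an exact affine-gap local DP (Smith–Waterman with
traceback; gap of length $L$ costs $|open| + L\,|extend|$, defaults
+1/−2/−5/−2, minimum reported score 28). Additional hits are extracted
by masking the residues of earlier hits and re-running. Because the DP
is exact, the best-hit score equals an independent Smith–Waterman
implementation's score whenever a seed exists — this is a property test,
with `Biostrings::pairwiseAlignment` as the oracle.

All-vs-all comparison (`self_match_counts()`) uses a staged fast path,
again mirroring how production search tools behave: candidate pairs
sharing a word are enumerated once from sorted word lists; each seed is
extended ungapped with an x-drop bound (20); the window rule is applied
to the extended run. The exact DP is invoked only when the ungapped
stage shows the one signature it cannot resolve itself — several
ungapped runs on different diagonals (an indel split), jointly long
enough to span a window, with at least one strong run. On
substitution-only divergence the ungapped stage is complete, so the DP
almost never runs and a thousand-read dataset finishes in seconds.

Masking known repeats replaces masked residues with `N`, which the
aligner treats as matching nothing (not even another `N`). This excludes
masked intervals from seeding and from passing windows in one mechanism
and guarantees that masking can only decrease match counts.

### Families and copy numbers

Reads with at least six window-passing partners (after masking) are
novel-repeat candidates (`candidate_repeats()`). Families are connected
components of the candidate match graph (`cluster_families()`, via
igraph) — a transparent, testable surrogate for motif discovery, which
needs external tooling and is out of scope. An isolated candidate forms
no family: one read cannot evidence a repeat family. Genome copy numbers
extrapolate linearly (`extrapolate_copies()`): a family seen `k` times
in `total_bes_bp` sampled bases scales by `genome_size / total_bes_bp`.
For elements near 200 bp read by ~600 bp reads, the read-level count is
a nearly unbiased copy estimator, because the +1 window-length edge
correction almost exactly cancels (an element of length $E$ is detected
from $E + L - 199$ read start positions, and $(E+L-199)/L \approx 1$
when $E \approx 200$).

A note on divergence: the 90%-identity window rule is a detection limit.
Copies that diverge ~5% **pairwise** (2.5% each from the consensus) sit
at that limit and are still recovered; copies diverging 5% each from the
consensus (~10% pairwise) fall below it and drop out of families. The
generator's `divergence` parameter is the per-copy substitution rate
against the consensus, so family recovery properties are stated against
pairwise divergence.

## Perfect microsatellites

`find_perfect_ssrs()` reports every maximal perfect tandem repetition
with a primitive motif of period 1–6, with per-period minimum spans of
16 bp (di-, tetra-), 15 bp (tri-, penta-) and 18 bp (hexanucleotide) —
the classical perfect-repeat parameterization with no imperfections
allowed. Detection is a shift-and-compare: positions where
`s[i] == s[i+p]` form runs whose maximal stretches are exactly the
maximal period-`p` repetitions, so maximality is structural, not
heuristic. Primitive-motif filtering removes period multiples (an
`(AT)n` run is never also `(ATAT)m`), and a locus lying entirely inside
a smaller-period locus is suppressed, so each position is reported under
its smallest period. Trailing partial copies are allowed (`copies` may
be fractional). Mononucleotide runs are detected internally (span ≥ 10)
but excluded from period 2–6 statistics, matching how such surveys
report SSR content. Runs break at `N`; the finder is case-insensitive; a
brute-force enumeration oracle checks equivalence on random sequences.

`canonical_class()` folds a motif's rotations and the rotations of its
reverse complement into one label (e.g. `GA`, `TC`, `CT` → `AG`), since
a tandem repeat is the same object on either strand and in any phase.

## Gene content

Homology hit tables (the 12-column tabular search format) are filtered
at the survey's cutoffs: translated protein searches at E ≤ 1e-4,
high-stringency nucleotide searches at E ≤ 1e-50 plus the window rule
(`filter_hits()`). The genome-wide gene number is the genic fraction of
sampled nucleotides scaled to the genome and divided by the mean gene
length (default 2 kb, the canonical plant mean):

$$\hat{n}_\text{genes} = \frac{n_\text{hit} \cdot \bar{L}}{B}\cdot
\frac{GS}{\bar{\ell}_\text{gene}},$$

with $n_\text{hit}$ the reads with a (non-organelle) protein hit,
$\bar L$ the mean read length and $B$ the total read base count.
`adjust_for_novel()` divides by $1 - f_\text{novel}$ for the fraction of
genes absent from the search database.

On synthetic data the generator plants gene-like intervals and
`simulate_protein_hits()` stands in for the protein search: a read is
called genic when at least half of the mean read length overlaps a gene.
The half-length rule mirrors the fact that a marginal overlap rarely
yields a significant translated alignment, and it makes the estimator
unbiased: the detection window per gene is
$\ell_\text{gene} + L - 2\,(L/2) = \ell_\text{gene}$.

## Mate-pair microsynteny

`classify_pair()` applies a fixed rule order: no hits → `no_hit`; one
end hits → `single_end`; both hit → `paired_end`; any forward/reverse
combination on one target sequence → `colocalized`; any such combination
with span in [15, 250] kb (inclusive) → `non_gapped`, otherwise
`gapped`; the best in-range combination (maximum summed hit length, ties
by lowest target coordinate) is `collinear` when the two hits are on
opposite strands with the plus-strand hit 5′ of the minus-strand hit —
the inward-facing geometry of BAC ends — and `rearranged` otherwise.
Span is measured between the outermost coordinates of the two hits, the
implied insert footprint. The hierarchy identities
`colocalized = gapped + non_gapped` and
`non_gapped = collinear + rearranged` hold structurally and are asserted
on randomized inputs. Classification is invariant under swapping the F/R
labels and under reflecting the reference axis (mirrored coordinates
with flipped strands); those are the physical symmetries of the
geometry. When several in-range combinations tie on summed length the
coordinate tie-break keeps output deterministic, at the cost of exact
reflection invariance in tied cases — tests therefore use tie-free hit
lengths.

## GO category comparison

`chi2_category_compare()` runs, for each top-level term, a one-vs-rest
goodness-of-fit chi-squared (df = 1) of `[x, n - x]` against
`[np, n(1-p)]` under the reference proportion `p`, flagging direction
and significance at α = 0.05. Per-term tests (rather than one
multinomial test) are used because per-category significance is what
such surveys report. No multiple-testing correction is applied by
default, matching that reporting style; a Bonferroni option exists.
Expected cells under 5 are flagged, not suppressed.

## The synthetic-data generator

`build_genome()` draws an i.i.d. background (default composition 35.33%
GC, typical of the broadleaf-tree genomes this kind of survey targets)
and plants, at non-overlapping intervals: repeat families (consensus
plus per-copy substitutions), perfect SSRs (flanking bases adjusted so
the planted locus is maximal), gene-like segments (default 2 kb) and
organelle segments. Placement allocates random inter-feature gaps of at
least `min_gap` left-to-right in random order, which always succeeds
when capacity allows and keeps placement O(n). A `min_gap` above the
read length guarantees no read bridges two planted features, keeping
family recovery unambiguous.

`library_sim_spec()` defaults are the study conditions this package
emulates: 135 kb mean inserts truncated to [50, 205] kb (sd 30 kb — the
source distribution is not published, a symmetric truncated normal is
the simplest shape consistent with its range), 7% empty clones, 2.2%
chloroplast clones, 599 bp mean reads truncated to [100, 967] bp
(sd 100 bp, same reasoning), and 66.96% read retention. Clone positions
are uniform; restriction-site bias is real in such libraries but is only
described qualitatively in the sources, and uniform sampling keeps the
truth analytic. All stages derive tagged sub-seeds from one global seed
(`derive_seed()`), so adding a stage never shifts another stage's random
stream and every run is exactly reproducible.

What the generator does **not** emulate: sequencing error and quality
trimming (retention is modelled as a coin flip, not recomputed from
chromatograms), indels within repeat copies (divergence is
substitution-only; the aligner's gapped rescue path exists for real
data, and is exercised directly in alignment tests), chimeric clones,
and restriction-site clone bias. Passing tests therefore demonstrate
correctness of the statistics and detection rules, not robustness to
every artifact of real trace data.

## Problem sizes and numerical choices

Test and pipeline scales were chosen so the full suite runs in well
under a minute of alignment time: planted-family recovery uses a 1.2 Mb
genome with two families of 500 and 400 copies read at 0.5× (about
1,000 reads) — a repeat-dense genome under sparse sampling, the same
regime as a real BES survey, where self-matches reflect repeat content
rather than positional read overlap; gene recovery uses a 2 Mb genome
with 200 genes at 5× BES coverage; the marker screen uses 2,000 markers
against an effective 7× library. Copy-number recovery is asserted within
±15% and gene recovery within ±20%, both a little over twice the
binomial sampling error of the respective designs.

Percentages are rounded half-up (`round_half_up()`) to match printed-
table conventions rather than R's round-half-even. All tail
probabilities and $p_0$ evaluations run in log space. Coordinates are
1-based inclusive internally; BED interchange is 0-based half-open on
disk with conversion centralized in the rtracklayer-based reader/writer.
Hit tables canonicalize reverse-strand subject coordinates to
`s_start <= s_end` plus a strand flag. When external tabular hits carry
no alignment strings, match vectors can be reconstructed with
non-identical columns spread uniformly (`approximate_match_vector`) —
an explicit approximation that callers must opt into before window
filtering.

## Known limitations

* Single-linkage components over-merge families that share reads or
  homologous segments; motif-based discovery would separate them.
* The window rule's 90% threshold is a hard detection limit: families
  beyond ~5% pairwise divergence are invisible to self-comparison.
* At BES coverage above ~1× of the simulated genome, self-match counts
  mix repeat-driven and position-driven redundancy; interpret the
  redundancy fraction only under sparse sampling.
* E-values in tabular hits are consumed and thresholded, never
  recomputed; the built-in aligner reports scores, not E-values.
* The gene estimator inherits the survey formula's assumptions (uniform
  gene length, fully genic hit reads); its synthetic validation shows
  calibration under those assumptions, not under real gene structure.
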