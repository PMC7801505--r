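---
title: "circPipe: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circPipe: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circPipe)
```

# Scope and model

circPipe covers the downstream half of a circRNA discovery study: it
starts from the backsplice-junction (BSJ) tables two detection tools
emit and ends at conservation calls, sponge candidates, differential
expression and term enrichment. Read QC, alignment and the detection
tools themselves are out of scope; so are negative-binomial GLM
differential expression and any online service — everything here runs
offline and deterministically.

The guiding assumption throughout is that a circRNA is adequately
represented by its two backsplice coordinates plus per-sample junction
read counts. That is what the callers report, what liftover can move
across genomes, and what databases of circRNAs record. Internal
structure (which exons the circle actually contains as isoforms) is
deliberately not modelled; `exonCount()` counts annotated exons falling
inside the backsplice span, which is the standard proxy.

# Coordinates

Callers disagree about conventions: some emit 1-based closed
coordinates, BED-like outputs are 0-based half-open. Every reader
declares the convention of its source (`convention =` on
`readCallerTable`, `readCircDb`) and normalizes once, at the boundary,
into the package's single internal convention — `GRanges`, 1-based
closed. BED output converts back on the way out. Keeping exactly one
internal convention matters here more than usually: the conservation
classifier works at ±2 nt, so a single off-by-one halves its tolerance
in one direction.

# Consensus filter

Junctions match between callers only on identical (chrom, start, end);
strands must be compatible, where "unknown" (reported `.` or missing,
stored `*`, never silently coerced to `+`) is compatible with anything.
Strict strand equality is a flag. Exact matching is intentional — a
reciprocal tolerance window would blur the ±2 nt conservation analysis
downstream and is a non-goal.

The expression filter interprets "expressed in the same N samples in
both tools" literally: a sample supports a junction only when its count
reaches `minCount` (default 2) in that same sample in *both* callers,
and `minSamples` (default 3) such samples are required — over all
samples for a single-condition design, or within one treatment group
for a multi-group design. The looser reading (each caller satisfied by
possibly different samples) is exposed as `samplesShared = FALSE`
because the strict rule is a choice, and comparing both on real data is
legitimate. Duplicate junction rows within one caller are summed rather
than rejected: real caller output occasionally repeats a junction
across annotation contexts.

Sequential candidate IDs are assigned after sorting by (chrom, start,
end), so numbering does not depend on input row order. Reference counts
come from one designated caller (argument `reference`), reflecting the
common practice of treating one tool's quantification as the abundance
reference.

# Liftover and conservation

`liftInterval()` implements chain-file liftover directly: the
best-scoring chain overlapping the query is chosen (ties broken by
lowest chain id, deterministically — the behaviour of liftOver's
defaults for overlapping equal-score chains is not documented, so this
package documents its own rule), each query base is mapped through the
chain's gapless blocks, and the query is `mapped` when at least
`minRatio` (default 0.95) of its bases map colinearly to one target
chromosome and strand. Backsplice ends are lifted as 1-base intervals,
for which the ratio is all-or-none; a config option could lift the full
span instead, but splice-site conservation is a property of the ends,
not the body, so ends are the default and the whole classifier is
phrased around them.

A lifted end matches a database record when both lie on the same target
chromosome within ±`toleranceNt` (default 2, inclusive on both sides,
i.e. 5 positions per site). Matching ignores database strand by
default, because circRNA databases vary in strand reliability; strict
strand mode is a flag. The six categories partition every candidate:

| category | meaning |
|---|---|
| `not_aligned` | an end failed to lift |
| `homologous` | one record uses both ends |
| `both_sites_utilized` | both ends used, only by different records |
| `five_prime_utilized` | only the 5′ end matches |
| `three_prime_utilized` | only the 3′ end matches |
| `no_homologous` | neither end matches |

5′/3′ identity is strand-resolved; unknown-strand candidates are
treated as plus-strand and flagged (`strandAssumed`). Summary
percentages divide by **all** detected circRNAs, including
`not_aligned` — the convention the acceptance script checks against the
published per-tissue values.

# Sponge screen

The screen follows the usual funnel: candidate clusters of miRNA
binding sites on the target genome are intersected with lifted circRNA
intervals, requiring ≥ 75 % of the *cluster* to be covered (the
question is whether the circRNA contains the reported sponge; the
fraction-of-circRNA variant is a flag). miRNAs without orthology
support in the study species are dropped: either a high-confidence
orthologue, or a precomputed hairpin alignment with identity ≥ 0.90
over ≥ 0.95 coverage (both inclusive). Running the alignment itself is
out of scope; the filter consumes its results.

`scanBindingSites()` is a deliberately simple integer duplex model, not
a thermodynamic one: gapless antiparallel alignment of the miRNA
(position 1 pairing the target window's 3′ end), scored WC −2, G:U −1,
mismatch +1 (a gap penalty of +3 belongs to the documented score scale
but gapless scanning never applies it). A window is a site when ≥ 6 of
seed positions 1–8 pair (G:U counts toward pairing) and the total score
is ≤ −10, with the duplex capped at 20 target bases. The parameters
mirror the common screen settings (seed 1:8/6, energy −10, length 20).
The substitution is justified because the downstream quantities —
presence and density of clustered sites, seed pair counts — depend on
site presence, not on exact free energies; absolute scores from this
model should not be interpreted energetically.

Overlap removal is greedy: strongest (most negative) score first, ties
by leftmost start then shortest, keeping a site only when it overlaps
nothing already kept. The original overlap-removal procedure this
stands in for is not precisely specified in the literature we follow,
so the greedy rule is this package's documented choice and is tested
against an independent oracle. `duplexProfile()` reports canonical
(Watson–Crick only — wobbles pair but are not canonical) seed pairs and
total mismatches for a single end-to-end duplex, the numbers quoted
when one discusses a specific miRNA/circRNA pair.

One caveat the tests respect: under a pure Watson–Crick model, sites
mirror exactly when both the target and the miRNA are
reverse-complemented; G:U wobble breaks that symmetry at borderline
scores. The orientation property is therefore asserted on perfect
planted sites, not on arbitrary windows.

# Differential expression

SRPBM (`count / mapped_total × 1e9`) normalizes junction counts by the
sample's mapped-read total — supplied by the user, since "reads aligned
to the reference annotation" can mean uniquely or multiply mapped
depending on the upstream pipeline, and the package does not guess.
Group differences are tested per circRNA with the Kruskal–Wallis rank
test (standard tie correction, chi-square approximation on k−1 df; an
exact permutation p-value is available via `exact = TRUE` for tiny n),
then Benjamini–Hochberg across circRNAs, significance at adjusted
p < 0.05. With all values identical the test is defined as H = 0,
p = 1 rather than an error — an all-zero circRNA row is data, not a
bug.

The optional batch adjustment is a clearly-labelled simple stand-in:
per-batch median-centering of log1p SRPBM per circRNA, off by default
(the single-timepoint design needs none). PCA-based batch correction is
out of scope.

At four samples per group the rank test is conservative: discrete
negative-binomial counts produce many ties and the chi-square
approximation undershoots. The calibration test therefore asserts only
the upper bound (type-I fraction ≤ 0.05 + 3 binomial SE on a
1000-circRNA null), and the null-pipeline test asserts the qualitative
outcome — zero significant circRNAs after correction in ≥ 95 % of 50
seeded replicates of 500 null circRNAs.

# Enrichment

Term sets come from an offline GMT file, so results are reproducible
without a service. Term genes are intersected with the background
*before* size filtering (5–400 genes kept); where an online tool
applies its filters in that order is undocumented, so this package
fixes and documents one order. Testing is a one-sided Fisher's exact
test (over-representation — the enrichment convention), BH-corrected
across tested terms, FDR < 0.05. The test suite verifies the p-values
against the closed-form hypergeometric tail.

# Synthetic data: what it emulates, and what it does not

The generators are pure functions of (seed, parameters) and exist to
give every downstream stage a planted, exactly checkable truth:

- `genAnnotation()` places non-overlapping genes proportionally to
  chromosome length (defaults: 40 genes on 300 kb + 150 kb chromosomes,
  2–8 exons of 80–300 nt, introns 200–1000 nt), so "longer chromosome,
  more genes/circRNAs" holds in fixtures as it does in real genomes.
- `genChain()` emits one chain of 40 gapless blocks (2–10 kb) with
  gaps ≤ 150 nt and optional target-strand inversion. The chain is
  sized to cover the default toy genome, as real liftover chains cover
  most of a genome.
- `genTruth()` plants circRNAs whose ends sit at exon boundaries (or at
  ±5 nt offsets, to populate all boundary classes) and inside chain
  blocks, except `not_aligned` plants, which get one end inside a
  source gap. All planted end positions keep ≥ 300 nt apart in source
  *and* lifted coordinates, so database records planted for one circRNA
  cannot accidentally match another.
- `genCircDb()` realizes the planted conservation category for each
  circRNA: positive matches at offsets drawn from the full inclusive
  ±2 window, negatives at exactly ±3 — probing both sides of the
  classifier's boundary. Impossible requests (a `homologous` plant
  whose end cannot lift) are generation errors, not silent fixes.
- `genCallerTables()` draws counts per caller and sample from a
  negative binomial with mean 4 and dispersion 0.5 — low counts with
  super-Poisson variance, the regime backsplice reads live in — scaled
  by planted group fold-changes; false positives are caller-private
  junctions and dropout removes true ones per caller. `countFloor`
  exists solely for noiseless fixtures where every sample must pass the
  expression threshold.
- `genSpongeFixture()` rejection-samples background sequence until no
  window anywhere reaches the scanner's seed criterion, then implants
  exact reverse complements of the miRNA at recorded positions — hence
  planted-site recall and background false positives are exact (100 %
  and 0), not statistical.

What the fixtures do **not** emulate: realistic splice-site sequence
context, isoform structure, correlated counts between callers (real
tools share reads; the fixtures draw independently), GC or mappability
biases, and realistic chain complexity (real chains nest and overlap
far more). Passing on fixtures therefore demonstrates the *logic* —
filters, classifier boundaries, calibration under the stated model —
not performance on any particular real dataset.

# Numerical and degenerate-input choices

- All thresholds are inclusive (≥ 2 counts, ≥ 3 samples, ≥ 0.75
  overlap, ≥ 0.90/0.95 orthology, ±2 nt, 5–400 term size).
- Tie-breaks are deterministic everywhere: chain selection by score
  then lowest id; overlap removal by score, start, width; candidate IDs
  by genomic sort.
- Empty inputs return empty results (empty annotation file, empty
  match list, empty site table); contract violations (negative counts,
  unknown samples, non-homologous calls passed to the human host-gene
  screen, zero mapped totals) are errors naming the offender.
- Problem sizes in the test suite were chosen to make the statistical
  assertions sharp at desk scale: 1000 random chains against the
  per-base oracle, a 200-circRNA noiseless consensus fixture, a
  1000-circRNA null for type-I calibration and 50 × 500 for the
  null-pipeline property.

# Known limitations

- Only two callers are merged; multi-caller consensus is a non-goal.
- The scanner's linear scan ignores the circular junction: a binding
  site spanning the backsplice point of the sequence is missed. Users
  who care can scan the sequence rotated by half its length.
- The duplex score is not an energy; ranking sites across miRNAs by
  score is not meaningful beyond strong/weak.
- `not_aligned` is resolved against the supplied chain set only; a
  region absent from the chains is indistinguishable from one that
  truly does not align.
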