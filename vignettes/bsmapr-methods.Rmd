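---
title: "Mapping bisulfite-treated reads with bsmapr: models and methods"
author: "bsmapr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping bisulfite-treated reads with bsmapr: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsmapr)
```

# The mapping problem

Sodium bisulfite converts unmethylated cytosines to uracil, which PCR
amplifies as thymine; 5-methylcytosines are protected and remain cytosine.
A sequenced bisulfite read therefore differs from its genomic origin at an
unknown subset of its cytosines, and the strand and amplification step it
came from decide *which* cytosines. A directional protocol yields reads
from the two converted strands (classes `+FW` and `-FW`); a non-directional
protocol adds their reverse complements (`+RC`, `-RC`), for four classes in
total.

Two complications follow. First, the search space doubles or quadruples,
because each class needs its own comparison between read and genome.
Second, the mismatch structure is *asymmetric*: a read `T` over a genome
`C` is biologically a match (the cytosine may simply be unmethylated),
while a read `C` over a genome `T` is a real mismatch. A mapper that
scores these two the same either loses unmethylated reads or accepts
wrong placements — and a mapper that only forgives `T`-over-`C` favours
methylated reads and biases downstream methylation levels upward.

`bsmapr` takes the unbiased *3-letter alphabet reduction* route: reads and
genome are projected into an alphabet where the bisulfite asymmetry
disappears (`C -> T`, or `G -> A` for the complementary classes), aligned
there with an ordinary (but complete) string search, and the surviving
candidates are re-examined in the original 4-letter alphabet where the
asymmetric rule can be applied exactly.

## The pass plan

Both converted genomes are built once from the forward (Watson) strand.
Each read is then aligned in two or four passes, always in forward
orientation against the forward genome — the orchestrator materialises
reverse-complemented query sets rather than searching two orientations,
which makes the pass-to-class mapping a bijection:

| pass | query transform    | conversion | origin class |
|------|--------------------|-----------|--------------|
| 1    | identity           | C2T       | `+FW`        |
| 2    | reverse complement | G2A       | `-FW`        |
| 3    | identity           | G2A       | `-RC`        |
| 4    | reverse complement | C2T       | `+RC`        |

Directional libraries run passes 1–2, non-directional ones 1–4. The
bijection rests on the conversion algebra — the reverse complement of a
C→T-converted fragment equals the G→A conversion of its reverse
complement — and is certified empirically by the simulator round-trip
tests: at zero sequencing error, a read's own pass always achieves the
perfect 3-letter score, so a wrong-pass placement can at best tie, and
ties are flagged ambiguous rather than mis-assigned.

## The 3-letter search

Three modes are provided, all free of heuristic misses at their stated
budget:

* **ungapped** — every genome window within Hamming distance
  `min(max_diff, 4)` of the query (at most four mismatches are searched in
  3-letter space). Candidate positions come from a k-mer occurrence index
  (k = 12) queried with `max_mm + 1` non-overlapping pieces of the read: by
  the pigeonhole principle any placement within the budget leaves one piece
  exact, and the k-mer prefix of an exact piece is exact, so the candidate
  set is a superset of the true hit set; every candidate is verified in
  full. Short queries fall back to a plain complete scan.
* **e2e** — two steps, the classic fast-filter-then-verify layout of
  modern short-read mappers: an ungapped first step at `step1_mm`
  mismatches (default 0), then banded semi-global dynamic programming for
  reads the first step left unresolved. The full query is aligned
  end-to-end; the reference window ends are free.
* **local** — seeded Smith–Waterman with affine gaps; read ends may be
  soft-clipped. Clipped bases are free in score and mismatch count, but a
  hit clipping more than `max_clip_frac` (default 50%) of the read is
  discarded as a sanity bound.

Gapped seeding uses `max_diff + 1` non-overlapping pieces (minimum seed 8
bp; pieces of at least 12 bp go through the k-mer index). This is
pigeonhole-complete at the *full* difference budget, which is deliberately
stronger than seeding at the step-1 budget only: seeds tuned to the
first-step mismatch allowance would miss reads whose total differences
exceed it, precisely the reads the dynamic-programming step exists to
recover. The price is more anchors to verify, which the index keeps cheap
at these genome sizes.

Dynamic programming uses Gotoh's affine-gap recursion over a window of
`band_width` margin around each anchor diagonal, so the effective band is
a window constraint rather than an explicit diagonal band. Scoring
defaults are match `+1`, mismatch `-2`, gap open `-3`, gap extend `-1`
(a gap of length *k* costs `open + (k-1)*extend`); a DP alignment is
reported only if its score reaches `dp_trigger = 0.3` of the perfect score
`L * match`. These constants are conventional short-read DP settings; they
are exposed because nothing in the method depends on their exact values,
only on `match > 0 > mismatch` and `gap_open <= gap_extend < 0`. Indels in
the reported edit script are left-aligned (shifting a gap run past an
equal flanking base changes neither columns nor score), and ties in the
traceback are broken deterministically (diagonal, then deletion, then
insertion; alignment ends prefer the leftmost coordinate).

`N` never matches anything — not even another `N` — in any stage: search,
validation, digestion and methylation calling all treat it as a mismatch
or skip it. Reads containing more than `max_diff` `N`s are reported
unmapped without alignment, since no placement could validate.

## 4-letter validation and ambiguity

Every 3-letter hit is recounted over the *original* read and genome by
walking its edit script. An aligned column matches when the bases are
equal, or read `T` over genome `C` in C2T space, or read `A` over genome
`G` in G2A space; every other aligned pair, and every inserted or deleted
base, counts one difference ("differences" therefore means mismatches
and/or indels in the gapped modes). Hits with more than `max_diff`
differences are the false positives of the reduced-alphabet strategy —
3-letter-identical placements such as read `C` over genome `T` — and are
removed. The same user budget `max_diff` governs both the search and this
recount; the method describes one constraint, applied post hoc in the
alphabet where it is meaningful. The bound is inclusive (`diff4 <=
max_diff` is valid).

Reads are then resolved across passes. With `b` the best score among a
read's valid hits, the read is **ambiguous** iff (i) hits achieving `b`
exist in two or more passes, or (ii) two or more hits achieve `b` within
one pass. Ambiguous reads are dropped by default (`keep_ambiguous`
retains their deterministic best hit, written with mapping quality 0);
otherwise the single best hit — ties broken by fewer differences, then
sequence name, start and pass — makes the read unique-best, the default
unit of all downstream analysis.

Validation runs *before* resolution. The alternative order (resolve on
3-letter scores, then validate the winner) can drop a read whose best
3-letter hit is a 4-letter false positive even though a perfectly valid
second hit exists. Reduced-alphabet mappers rarely document which order
they use; validating first is the choice here, it is strictly more
permissive, and a regression test pins it.

The hit cap (`max_hits`, default 2) applies per pass after best-score
sorting, and again after passes are merged. Whether the historical `-l`
flag capped per pass or per read is likewise undocumented; per-pass with a
merged re-cap is the interpretation implemented, and truncated reads are
flagged. Note that a cap of 1 makes within-pass ambiguity (rule ii)
undetectable by construction — the default of 2 is the smallest cap that
preserves it.

# RRBS mode

Reduced-representation libraries enrich CpG-rich territory by restriction
digestion (MspI, site `C^CGG`, written `"C-CGG"`) followed by size
selection. `bsmapr` reproduces this in silico: every exact occurrence of
the recognition site on the forward strand cuts at the dash offset
(overlapping occurrences included; the MspI site is its own reverse
complement, so forward-strand search suffices — non-palindromic enzymes
are out of scope). Fragments are the intervals between consecutive cuts.

A fragment is *retained* iff its length lies within the size-selection
bounds **and** both its ends are cut sites. The second condition is a
deliberate design choice: a genuine restriction fragment carries
enzyme-cut ends, so the chromosome-terminal pieces — cut on one side
only — are never ligated and sequenced in a real RRBS library, whatever
their length. The degenerate case of a sequence without any site keeps
its single spanning fragment, judged by length alone. Masking then
replaces every position of non-retained fragments with `N` in both
converted genomes before alignment, which both shrinks the search space
and guarantees that reads from outside the retained territory cannot map.
Masking is strict by fragment interval: territory is not restored around
cut sites for reads overhanging a fragment end, because the simulator and
the protocol both anchor reads at cut sites, where an end-to-end read
never crosses into masked ground.

# The read simulator

The generator exists so that every pipeline stage can be verified without
external data, and its defaults are the study conditions of the synthetic
evaluation: read lengths around 75 bp, a **uniform bisulfite conversion
rate of 0.5** applied independently to every cytosine of the fragment's
source strand regardless of context, and a mean sequencing error rate
between 0 and 6% distributed along the read by an exponential profile
`e_k = c * exp(lambda * (k-1)/(L-1))` normalised so `mean(e_k)` equals the
requested rate — errors concentrate toward the 3' end, as real base
callers degrade. The decay constant `lambda` defaults to 3 (about a
20-fold 5'-to-3' ratio); the cited error model specifies the shape, not
the constant, so it is exposed as a parameter. Errors are substitutions
only by default (uniform over the three other bases) and may coincide
with converted positions; both position lists are recorded in the truth
ledger, and at zero error rate the emitted read is exactly reproducible
from genome plus ledger — a tested invariant.

A second conversion model (`per-cytosine`) draws a methylation state per
eligible site per read with probability `p` (scalar, or a per-position
map) and converts exactly the unmethylated sites. This is the model under
which methylation-level recovery is tested: at coverage `c` the estimated
level at a site is `Binomial(c, p)/c`, so the estimate should fall within
two binomial standard errors of `p` at the vast majority of sites.

Origin classes are drawn uniformly over the classes the library type
allows; loci uniformly over N-free windows (bounded resampling); RRBS
reads start at the 5' end of a uniformly drawn retained fragment on the
sampled strand and are truncated to the fragment length. Qualities are
constant `I` (Q40) because the pipeline is quality-agnostic by default.
Identical specification and seed give byte-identical FASTQ and ledger.

What the simulator does **not** emulate — and what passing tests
therefore do not demonstrate about real libraries: PCR duplicates,
quality-correlated and indel sequencing errors, context-dependent or
incomplete bisulfite conversion chemistry, adapter read-through (local
mode is exercised with constructed adapter cases instead), fragment-size
biases within the selection window, and real-genome repeat structure
beyond what planted duplications cover.

# Methylation calling

Only unique-best alignments contribute (an `all-best` switch admits kept
ambiguous reads at the user's risk). Walking each alignment's aligned
columns (indel and soft-clip columns skipped): over a genome `C`, reads
of the C2T-space classes (`+FW`, `+RC`) vote methylated on `C` and
unmethylated on `T`; over a genome `G`, the G2A-space classes (`-FW`,
`-RC`) vote methylated on `G` and unmethylated on `A`. Any other read
base at a cytosine column is ignored — a sequencing error and a SNP are
indistinguishable here and counting them either way would bias levels.
The level estimator is the count ratio `n_meth / (n_meth + n_unmeth)`,
the community standard; records exist only for covered sites, so the
ratio is always defined. Context is read from the two bases downstream on
the cytosine's own strand (`CG…` CpG, `C[ACT]G` CHG, `C[ACT][ACT]` CHH);
a base that the decision needs but that is `N` or beyond the sequence end
yields `unknown` — CpG needs only the first downstream base, the others
need both. No base-quality filter is applied by default (a minimum-Phred
option exists), and M-bias trimming and duplicate marking are out of
scope.

# Evaluation harness

`score_mappings()` calls a unique-best read *correct* iff sequence name,
start (within a tolerance) and origin class all match the simulator's
truth. Precision is correct over unique-best, recall correct over all
reads, and F1 their harmonic mean. Because "correctly mapped" has no
canonical start convention for clipped alignments, the tolerance is an
explicit parameter, always reported with the metric: 0 bp for ungapped
and end-to-end modes, 5 bp conventionally for local mode, where
soft-clipping shifts starts. `cumulative_by_differences()` reproduces the
unique-best-by-differences view of mapper comparisons: the fraction of
reads unique-best with at most *k* differences, nondecreasing in *k*.

# Problem sizes and numerical checks

The package's own verification runs at desk scale, chosen so the whole
suite completes in a few minutes on one core while leaving every
statistical check well-powered: 20 kb random references with 10,000
simulated 75 bp directional reads for the round-trip operating point
(precision 1.0 at zero error); brute-force sliding-window equivalence on
100 random instances up to 50 kb; full-matrix dynamic-programming
equivalence on 200 instances up to 50x120; 1,000 random edit scripts for
the 4-letter recount oracle; 50x coverage for methylation recovery at
five methylation levels; and 10^5-read calibrations of the simulator's
conversion fraction. The acceptance script (`scripts/acceptance.R`)
re-runs the same design end to end from a caller-supplied seed.

# Known limitations

Single-end reads only (the pass algebra extends to read pairs, but no
paired-end orchestration is implemented). One enzyme with an exact
recognition site per digestion; no degenerate sites or double digests; no
conversion-efficiency spike-in handling. Mapping quality is a fixed
convention (255, or 0 for kept ambiguous reads), not a probability model.
The banded dynamic programming is optimal only within its window around
each anchor; an alignment whose true path leaves the window would be
scored suboptimally — widen `band_width` for longer indels. Performance
is adequate for method development and evaluation at megabase scale, not
for production mammalian-genome workloads.
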