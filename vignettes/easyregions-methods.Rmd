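---
title: "Deriving sample-agnostic easy regions from a pangenome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving sample-agnostic easy regions from a pangenome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(easyregions)
```

## The problem

Short-read variant callers look very accurate when judged inside curated
confident regions, and much worse outside them.  For a sample without
curated regions, genome-wide error rates can be an order of magnitude
higher than benchmark numbers suggest.  *Easy regions* are sample-agnostic
intervals of the reference where generic callers reach high accuracy
without sophisticated filtering; they trade a modest loss of genome
coverage for a large reduction in spurious calls.

Reference-only uniqueness masks (k-mer mappability tracks) miss a key
failure mode: a locus unique in the reference but duplicated in other
individuals.  Reads from the extra copy in such a sample pile onto the
unique reference locus and their paralogous differences surface as
confident false variants.  This package therefore assesses uniqueness
against a *collection* of assemblies (a pangenome), combining the
reference-only and population-aware viewpoints.

## The model

Let the collection hold $N$ genomes, the reference included.  A reference
k-mer is **sufficiently unique** if

1. it has exactly one hit at edit distance $\le d_1$ in the reference, and
2. it has fewer than $c \cdot N$ hits at edit distance $\le d_2$ across all
   $N$ genomes, with $d_2 > d_1$ and $c > 1$.

Condition 1 guards against mismapping under sequencing errors and
mutations: if the second-best reference placement is more than $d_1$ edits
away, a read is unlikely to jump loci.  Condition 2 counts copies in the
whole collection; $c > 1$ tolerates rare copy-number gains (at $c = 1.01$,
one extra copy among $N = 100$ genomes crosses the threshold; at
$c = 1.02$, two are needed).  The comparison `count < c*N` is evaluated in
real arithmetic with no rounding: 101 hits against a threshold of 101.0
fails.  The known blind spot — a k-mer deleted in some genomes and
duplicated in others, so the total count stays at $N$ — is inherited by
this design and is deliberately not addressed; the simulator's
`sample_deletion` feature documents the behavior.

One k-mer is sampled every $w$ bases (plus the final offset `len - k`, so
sequence tails are tested), and each insufficiently unique k-mer masks its
footprint $[i, i+k)$.  The remaining covered bases, after dropping
fragments shorter than 50 bp, form the **lenient** set.  Removing
low-complexity regions longer than 18 bp (symmetric DUST) and re-applying
the length filter yields the **strict** set, a per-base subset of lenient.
Bases never spanned by a sampled k-mer — sequences shorter than $k$ — are
treated as untested, not easy.

Defaults (`mask_params()`): $k = 151$ (matching common read lengths),
$w = 10$, $c = 1.01$, $d_1 = 3$, $d_2 = 7$, Hamming rescue radius 3, 50 bp
minimum region, 18 bp low-complexity cutoff, DUST window 64 and threshold
2.0.  These mirror the operating point published for human pangenomes of
several hundred assemblies and are sensible for other species with multiple
well-assembled genomes.

## Search engines

The masking decision needs *complete* bounded-distance hit sets.  Two
engines share one contract (every end-to-end placement within `max_d`
unit-cost edits; per candidate start, the minimal distance and earliest
end):

* `find_hits_exact()` — full dynamic programming over all windows,
  $O(Lk)$ per sequence via a reversed-string pass that yields all per-start
  minima at once.  It is the oracle engine.
* `find_hits_seeded()` — pigeonhole seeding: the query is split into
  `max_d + 1` non-overlapping seeds; any qualifying placement must contain
  one exact seed, so locating seed matches and verifying the induced
  candidate starts with banded dynamic programming is complete.  This is
  the production engine; its output is tested to be identical to the exact
  engine's on randomized suites.

Published pipelines at human scale use heuristic index-based aligners that
can miss inexact hits, patched by an exact gapless mappability scan.  At
the scales this package targets, completeness is affordable, which makes
every test deterministic; the gapless Hamming rescue stage
(`multi_mapping_mask()`, forward strand, radius `hamming_d`) is still
implemented and applied to every sampled k-mer for fidelity to the
published staging, even though the edit-distance engines subsume it here
(a property the tests assert).

Raw hits include "alignment jitter": an alignment with $\le d$ edits can
shift its reported start by up to $d$ (delete $j$ leading bases and an
end-to-end placement at $i + j$ costs $j$).  `collapse_hits()` therefore
groups hits on the same (assembly, sequence, strand) by single linkage,
starting a new group when successive starts differ by more than `max_d`,
and keeps each group's minimum-distance hit.  Tandem copies with period
greater than `max_d` stay distinct; shifts inside a homopolymer or
short-period repeat collapse into the self hit.  Whether published counts
are per-strand or strand-combined is unstated in the literature this
follows; here both strands are searched by default (`strand_mode = "both"`)
and collapsed groups are counted per strand, a convention the package
defines and documents.

## Symmetric DUST

A window of length $\ell \ge 3$ has $n = \ell - 2$ overlapping triplets;
with $c_t$ the count of triplet type $t$, its score is
$\sum_t c_t (c_t - 1) / 2$ divided by $n - 1$ (0 for a single triplet).  A
**perfect interval** has score strictly above the threshold (default 2.0,
the classical cutoff of 20 expressed per unit triplet), no proper
subinterval scoring strictly higher, and is not properly contained in
another reported interval; intervals are limited to the 64 bp scan window
but overlapping or abutting perfect intervals chain into longer merged
regions (`lcr_regions()`).  A homopolymer of length $\ell$ scores
$(\ell - 2)/2$, so runs of 7 or more are flagged while a 6 bp run (score
exactly 2.0) is not.  The 18 bp strict-set cutoff is applied to chained
merged regions, and "longer than 18 bp" is strict: an 18 bp dinucleotide
run survives in the strict set, a 19 bp run is excised.  Triplets have no
identity across `N` bases: non-ACGT characters split a sequence into
independently scanned runs.

## The synthetic pangenome and its truth labels

`simulate_pangenome()` builds a reference from random backbone segments
alternating with planted feature blocks, then derives each sample assembly
from the same blocks: reference duplications (both copies in the
reference), sample-only duplications carried by a configurable number of
assemblies, sample deletions, low-complexity runs, and short-period tandem
arrays.  Sample SNP noise is restricted to backbone interiors at least $k$
from any feature block, so planted geometry is never perturbed; extra SNPs
can only *remove* pangenome hits (a sample self-hit drifts past $d_2$),
never add them, which is why the expected region sets remain exact under
noise.

The central design problem is making truth labels *base-sharp*: near a
planted copy the true edit distance of a boundary-straddling k-mer to the
other copy would normally depend on chance matches against that site's
flanking sequence.  Two alphabet devices remove the chance:

* inserted copies are wrapped in **poly-T guards** of length $d_2 + 2$
  while the source locus is flanked by sequence over $\{A,C,G\}$ to the
  same depth.  A k-mer protruding $p$ bases beyond the shared segment pays
  at least $\min(p, d_2 + 2)$ unavoidable edits (T never matches a T-free
  flank, in either direction, gapped or not), so "hit at radius $d$" is
  exactly "$p$ plus divergence edits in span $\le d$";
* periodic features get **break pads** over letters outside their motif,
  so a shifted self-alignment pays at least $2\min(|\delta|,
  \text{pad})$ edits.  Shifts within the search radius collapse into the
  self hit; larger shifts cost more than the radius.  Low-complexity runs
  (kept shorter than $k$) are therefore never uniqueness-masked — they are
  excised from the strict set only — while tandem arrays with period
  between $d_1$ and $k$ are always condition-1 masked.

Residual short-range self-shift effects (the gapless mappability scan sees
1–2 bp shifts at run boundaries) are evaluated exactly as Hamming
distances between the constructed strings at the designed offsets; these
"pairings" are recorded by the generator and consumed by
`expected_regions()`, which never invokes the search engines.  One
exception is documented: backbone sequence adjacent to a planted run can by
chance form a low-complexity interval that chains with it, lengthening the
excised region; the generator resamples such surroundings until the
detector reports a sterile boundary.  This uses the DUST scanner as a
rejection filter during construction — the scanner itself is validated
against an independent brute-force oracle, so the check does not let a
scanner defect confirm itself.

What the simulator does *not* emulate: real segmental-duplication families
(divergence here is a few substitutions, not large indel-rich homology),
diploidy and phasing, sequencing-error read models, GC bias, and
centromeric satellite structure.  Passing the recovery tests shows the
masking logic implements its definition exactly; it does not certify
accuracy numbers on real genomes.

## Scale choices and numerical details

Test and acceptance runs use a 50 kb reference with $N = 20$ assemblies
and k-mers of 31 bp, with radii scaled to the k-mer length ($d_1 = 1$,
$d_2 = 2$, Hamming 1): keeping $d_2 = 7$ at $k = 31$ would accept 23%
divergence — far outside the regime the published radii represent at
$k = 151$ (4.6%) — and would make chance radius-7 matches between random
31-mers frequent enough to defeat exact truth labels.  The published radii
are exercised directly in a $k = 151$ spot-check on a smaller collection.
The threshold sweep uses $N = 100$ assemblies over a 2 kb reference, where
the planted duplication flips from easy to masked at exactly one carrier
($c = 1.01$) and exactly two ($c = 1.02$).

Determinism: all randomness flows from a single seed; identical inputs
and parameters produce byte-identical BED output.  Ties in hit collapse go
to the leftmost minimal-distance hit; the reported end is the smallest end
achieving the minimal distance.  Counting in the classifier early-exits at
the decision threshold, so the audit TSV reports hit counts capped there.
Degenerate inputs: sequences shorter than $k$ yield no sampled positions
and no easy bases; queries containing `N` are rejected by the engines and
classified as ambiguous upstream; an empty region set complements to whole
sequences.

## Evaluation statistics

`coverage_fraction()`, `subset_fraction()`, `variant_density()` (with
optional density relative to a confident set) and `site_concordance()`
mirror the region-level comparisons used when easy-region sets are
evaluated against benchmark callsets.  Site matching is exact on the
normalized `(seq, pos, ref, alt)` representation with genotypes ignored —
deliberately weaker than haplotype-aware comparison engines: equivalent
complex-region representations count as errors.  A multi-base variant
belongs to a region iff its 0-based start position lies inside it.  Indel
normalization (left-alignment against a supplied reference) happens at VCF
read time.

## Limitations

* The deletion-plus-duplication blind spot described above.
* Site concordance is not haplotype-aware.
* The seeded engine degenerates gracefully but slowly when
  `max_d + 1` approaches `k` (seeds of length 1–2 match everywhere); the
  intended regime is `k` well above the radius.
* Easy regions are conservative by construction: they do not replace
  pipeline-specific filtering, and sophisticated callers can exceed them
  in power.
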