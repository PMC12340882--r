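# easyregions

Sample-agnostic **easy regions** for short-read variant calling, derived
from a pangenome of assemblies.

Variant callers reach benchmark-grade accuracy only inside curated
confident regions; genome-wide, error rates are several-fold higher.  Easy
regions are reference intervals where generic short-read calling is
reliable for *any* sample.  Reference-only mappability tracks miss loci
that are unique in the reference but duplicated in other individuals —
reads from the extra copy mismap onto the unique locus and their
differences become confident false calls.  `easyregions` addresses this by
testing k-mer uniqueness against a whole collection of assemblies.

## Model

With $N$ genomes (reference included), a sampled reference k-mer is
*sufficiently unique* iff

1. it has exactly **one** hit within edit distance $d_1$ in the reference,
   and
2. it has **fewer than $c \cdot N$** hits within edit distance $d_2$
   across all $N$ genomes ($d_2 > d_1$, $c > 1$; the comparison is
   real-valued and strict).

One k-mer is sampled every $w$ bases; each failing k-mer masks its
footprint $[i, i+k)$.  An exhaustive Hamming-distance scan of the
reference (radius `hamming_d`) additionally drops gapless multi-mapping
k-mers.  Remaining regions shorter than 50 bp are discarded, giving the
**lenient** set; excising low-complexity regions longer than 18 bp
(symmetric DUST, window 64, threshold 2.0) gives the **strict** set, a
per-base subset of lenient.  Defaults: `k = 151, w = 10, c = 1.01,
d1 = 3, d2 = 7`.

The package ships two complete bounded-edit-distance search engines (an
exact full-DP oracle and a pigeonhole-seeded production engine with an
identical contract), BED interval algebra, FASTA/BED/VCF-site readers, a
synthetic pangenome simulator with planted features and exact truth
labels, and region-restricted evaluation statistics (coverage, variant
density, site-level FDR/FNR).

## Worked example

Simulate a small pangenome with planted features, derive the easy
regions, and compare them with the truth implied by the construction:

```r
library(easyregions)

cfg <- sim_config(seed = 5, ref_len = 20000, n_samples = 5, k = 31)
sim <- simulate_pangenome(cfg)
params <- sim_params(cfg)

res <- easy_regions(sim$collection, params)
res$lenient
#> RegionSet: 7 intervals on 1 sequence(s), 19,384 bp total
res$strict
#> RegionSet: 9 intervals on 1 sequence(s), 19,321 bp total

exp <- expected_regions(sim$truth, params)
identical(res$lenient$intervals, exp$lenient$intervals)
#> [1] TRUE

table(res$verdicts$status)
#>
#> fail_pan_excess  fail_ref_multi          unique
#>              11              38            1949
```

Of the 1,998 sampled 31-mers, 38 fail reference uniqueness (the two
planted reference duplications and the tandem array), 11 fail the
pangenome copy-number condition (the sample-only duplication carried by
one of five assemblies: $7 \ge 1.01 \times 6 = 6.06$), and the rest are
sufficiently unique.  The lenient set covers 19,384 of 20,000 bp; the
strict set excises a further 63 bp of planted low-complexity runs longer
than 18 bp.  `write_bed(res$lenient, "out.lenient.bed")` writes the
standard BED3 output.

A thin command-line front-end mirrors the R API
(`inst/cli/easyregions`): `mask`, `sdust`, `mappability`, `stats` and
`simulate` subcommands; see `run_cli("--help")`.

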