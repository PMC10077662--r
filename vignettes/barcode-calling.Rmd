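---
title: "Calling cell barcodes from nanopore single-cell reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling cell barcodes from nanopore single-cell reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanodemux)
```

## The problem

Droplet-based 10x Chromium 3' libraries tag every cDNA molecule with a
16-nt cell barcode and a 10--12-nt UMI. With short reads, the barcode bases
are essentially error-free and the set of cell-associated barcodes (the
*whitelist*) can be read off a barcode-rank "knee" plot. Nanopore long
reads of the same libraries carry per-base error rates of roughly 4--5%,
so a naive census of observed 16-mers is swamped by corrupted copies of
real barcodes, and tools that ignore this either miss cells or call large
numbers of spurious ones.

`nanodemux` calls the whitelist directly from the long reads in three
steps, then assigns every read to a whitelist entry so that downstream
gene/isoform quantification can proceed without matched short-read data.

## The procedure

**Step 1 -- locate the putative barcode.** Each read (and its reverse
complement, since either cDNA strand is sequenced) is scanned for the last
10 nt of the 10x adaptor, `CTTCCGATCT`, within its first 200 nt. The
adaptor tail is aligned semi-globally -- the tail end-to-end, free placement
inside the window -- under unit edit costs, keeping placements with at most
2 mismatches, insertions or deletions. Because a 10-mer at edit distance 2
is not rare in 200 nt of sequence (about one window in five contains a
chance match), a hit only becomes *valid* when 4 consecutive Ts are found
20--50 nt downstream of its end: the polyT tract that follows the UMI,
searched leniently because nanopore basecalling truncates homopolymers.
Reads with exactly one valid adaptor across both strands contribute the 16
bases after the adaptor as their *putative barcode* plus the next 12 bases
as UMI; all other reads are rejected and tallied by reason (no adaptor, no
polyT, multiple adaptors, too short).

**Step 2 -- select high-quality putative barcodes.** Basecalling errors
concentrate at low-quality bases, so for each putative barcode the minimum
Phred score over its 16 bases (*minQ*) is computed, and barcodes with
minQ < 15 are discarded. When the list of all possible 10x barcodes is
supplied, putative barcodes absent from it are discarded first -- they
cannot be genuine.

**Step 3 -- call cells by a quantile threshold.** Unique high-quality
barcodes are counted and ranked (descending, ties broken lexicographically
for reproducibility). For an expected cell number $N$ (default 500), let
$c$ be the count at 1-based rank $\lceil 0.95\,N \rceil$; the whitelist is
every barcode with count strictly greater than $T = 0.05\,c$. Taking $c$
near the low end of the presumed cell block and then dropping two orders
of magnitude in count makes $T$ land inside the cells-versus-ambient count
gap for any plausible $N$, which is what makes the call robust to
mis-specifying $N$. A *high-sensitivity* mode reduces $T$ to 10% of the
default, trading precision for recall; by construction its whitelist
always contains the default one. For downstream empty-droplet analysis the
package can also emit background barcodes constrained to Levenshtein
distance > 4 from every whitelist entry, so reads from real cells cannot
be mis-assigned to them and distort the ambient profile.

**Assignment.** Each read's putative barcode is matched to the whitelist:
exact match wins; otherwise the unique entry at minimal edit distance
$\le 2$ wins; ties leave the read unassigned. Assignment runs on the full
putative stream (not only the minQ-filtered one): a read whose barcode has
one low-quality base is still perfectly usable once the whitelist is
known, and this is how the usable-read fraction is counted.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `adaptor_tail` | `CTTCCGATCT` | last 10 nt of the 10x adaptor |
| `max_ed` | 2 | edit budget for adaptor search and assignment |
| `search_window` | 200 nt | leading bases scanned on each strand |
| `polyt_start`, `polyt_end` | 20, 50 nt | downstream window for the T-run |
| `t_run` | 4 | required consecutive Ts |
| `min_q_threshold` | 15 | minQ cutoff (Phred) |
| `expected_cells` | 500 | $N$ in the quantile rank |
| `umi_len` | 12 nt | UMI length (10x v3: 10--12) |

## The simulator

`simulateDataset()` builds each read as
nanopore adaptor + 10x adaptor + barcode + UMI + 15 nt polyT + 200 nt cDNA
fragment + TSO, reverse-complemented with probability 1/2, then injects
per-base errors. The error model is deliberately parametric and explicit:
independent substitution (2%), insertion (1.5%) and deletion (1.5%) events
-- 5% total, the typical nanopore regime -- with Phred scores drawn from a
two-component rounded-Gaussian model (correct bases around Q20, error
bases around Q8, sd 3, clamped to [1, 40]). That coupling of low quality
to true error is exactly the signal the minQ filter exploits, and it makes
the filter behave on synthetic data the way it does on real basecalls.

Defaults describe the desk-scale study conditions used throughout the test
suite: 500 true cells with negative-binomial depth (mean 60, size 10 --
size 10 gives a coefficient of variation of about 0.34, a realistic
per-cell depth spread), and 5000 ambient background barcodes observed in
1--3 reads each. Fragments are uniform random sequence by default or
windows of a user-supplied transcript FASTA; cell and background barcodes
are distinct random 16-mers or draws from a supplied universe. Every read
is recorded in a truth table (barcode, UMI, strand, fragment, cell or
background) and the true-cell barcodes form the ground-truth whitelist
for precision-recall evaluation.

What the simulator does **not** emulate: correlated/adjacent errors and
homopolymer-length miscalls (real nanopore error structure is burstier
than independent per-base events), full-length transcript read-length
variation, chimeric reads, and any sequence bias in where errors fall. A
pipeline that is perfect on these simulations is therefore validated for
its logic and thresholds, not certified on real flow-cell data.

## Numerical conventions and edge cases

* Coordinates are 0-based half-open throughout; an adaptor hit's
  `end_pos` is the first base after the alignment, and the polyT window is
  `[end_pos + 20, end_pos + 50)`.
* Overlapping adaptor placements (end positions within 10 nt) collapse to
  the cheapest one (ties: leftmost), so one noisy adaptor cannot trigger
  the multiple-adaptor discard; placements further apart stay distinct
  candidates.
* `N` in a read never matches the adaptor or the polyT run.
* The quantile rank clamps to the table size with a warning, so small
  datasets run; the threshold comparison is strictly `count > T`, with
  `T` kept fractional.
* Precision of an empty prediction set is defined as 1; the PR-curve AUC
  is a trapezoid over recall with an anchored (0, first-precision)
  endpoint, walking recall ties in descending-threshold order so a perfect
  separation integrates to exactly 1.
* All randomness (simulation, background draws) flows through R's RNG, so
  a seed makes runs bit-reproducible, including the C++ error injector.

## Design choices where the method is genuinely open

* *Filter order*: membership filtering against the full 10x list runs
  before the minQ filter and before counting.
* *Assignment ties*: left unassigned rather than rescued by abundance or
  quality -- a conservative choice that never invents evidence.
* *Background draws*: preferentially observed non-whitelist barcodes
  (they carry a genuine ambient profile downstream), topped up with random
  16-mers under the same distance constraint.
* *Exactly-one rule*: counted across both strands after polyT validation;
  the collapse rule above decides what "one" means for near-duplicate
  placements.

## Known limitations

* **Adaptor-mimicking barcodes.** A barcode whose sequence (with its
  context) contains a chance edit-distance-2 copy of the adaptor tail
  positioned so that the true polyT also validates it will produce two
  valid adaptors in *every* read of that cell, and the exactly-one rule
  then discards the whole cell systematically -- even from error-free
  reads. With random 16-mers this affects roughly 1 cell in 100. It is a
  property of the method, not of the implementation.
* **Shallow-depth regimes.** The quantile threshold presumes a
  multiplicative count gap between cells and ambient barcodes. At desk
  scale (tens of reads per cell) $T = 0.05c$ can fall below 1, and then
  *every* observed high-quality barcode passes: ambient barcodes seen 1--3
  times enter the whitelist and precision collapses even though recall
  stays near 1. The threshold separates cleanly when cells carry hundreds
  to thousands of reads, as in real flow-cell datasets. The test suite
  exercises both regimes deliberately.
* UMIs are carried through but never deduplicated or corrected; that is
  downstream quantification's job.

## Problem sizes in the tests

The suite validates the adaptor scan against an exhaustive
dynamic-programming oracle on 1000 random reads, the edit distance against
a full DP matrix on 1000 pairs, and the PR curve against per-threshold set
algebra on 100 random tables. End-to-end runs use 100 cells x 50 reads
(noiseless) and the 500-cell default conditions above (~40,000 reads),
sizes chosen so the whole suite completes in a couple of minutes on one
core while still exercising every stage at realistic ratios.

## A minimal session

```{r example, eval = FALSE}
sim <- simulateDataset(simConfig(n_cells = 100, reads_per_cell = 60,
                                 n_background = 0, seed = 60))
pbs <- extractPutativeBarcodes(sim$reads)
tab <- countBarcodes(filterHighQuality(
  filterKnownBarcodes(pbs, sim$universe)))
wl  <- buildWhitelist(tab, expected_cells = 100)
asn <- assignReads(pbs, wl)
pr  <- precisionRecallCurve(tab, sim$truth_whitelist)
```
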