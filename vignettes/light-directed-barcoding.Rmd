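---
title: "Simulating and processing light-directed spatial barcoding data"
author: "LightSeqKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and processing light-directed spatial barcoding data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LightSeqKit)
```

# The measurement being modelled

Light-directed barcoding turns a microscope into a spatial demultiplexer:
cDNAs synthesized in situ carry a docking site, a photo-crosslinkable
barcode strand is hybridized everywhere, and UV light projected through a
photomask covalently fixes the barcode only inside the chosen region of
interest (ROI). Stringent washes remove the rest, and the process repeats
with an orthogonal barcode per round. A cross-junction synthesis reaction
then copies barcode and cDNA into one readable strand, so that Read 1 of
the sequencing library has the fixed architecture

```
[barcode (12 nt)] [UMI (8 nt)] [junction remnant (7–8 nt)] [cDNA (≤ 40 nt)]
```

The junction remnant is the shared priming ("P") domain that lets the
polymerase cross the crosslink junction; it is 7 nt, and becomes 8 nt when
the polymerase A-tails, which is why the extra base — when present — is an
A on the read strand.

The package implements this measurement twice over: once as a generative
simulator with per-read ground truth, and once as the analysis pipeline
(parse → assign → deduplicate → quantify → benchmark) that a real
experiment would run. Having both in one place lets every pipeline stage
be validated as a round trip against the truth tables.

# Photomasks and the scatter model

ROIs are drawn as polygons in micron coordinates and rasterized by the
pixel-center rule: a pixel belongs to a polygon iff its center is inside
(even-odd crossing), with a half-open pixel convention and the physical
origin at the raster corner. This makes areas unambiguous — an axis-aligned
10 × 10 µm square at 1 µm/px is exactly 100 pixels. Overlaps resolve by
draw order (last wins), mirroring the fact that a cDNA dock can crosslink
only once across iterative rounds.

Out-of-ROI barcoding is modelled mechanistically rather than optically:
the binary round mask is convolved with a unit-mass Gaussian of scale
`sigmaUm`, and a molecule crosslinks where this dose reaches
`crosslinkThreshold`. Threshold crossings just outside a bright ROI are
therefore the model's scatter errors, which is the intended noise
mechanism; real point-spread functions, focal-plane selection and DMD
hardware are out of scope. Because no published estimate of the scatter
magnitude exists, `sigmaUm` and `crosslinkThreshold` are free simulator
parameters (defaults 0 µm and 0.5), not calibrated values. Erosion of a
mask by a Euclidean disk (`erodeMask`, 1–3 µm in practice) reproduces the
standard countermeasure of drawing photomasks slightly inside the intended
boundary; it is implemented as the exact disk-offset definition, so a
brute-force structuring-element test agrees pixel for pixel. Grayscale
target images become binary masks with Floyd–Steinberg error diffusion on
a fixed serpentine scan, chosen so output is bit-reproducible; summed
intensity is conserved up to the residual carried off the last row.

Two wash-related noise channels complete the model. `carryoverRate` is the
probability that an uncrosslinked barcode survives the stringent washes on
a molecule that was *not* dosed in that round (default 0). A separate
`swapRate` relabels a barcoded molecule to a different round uniformly,
standing in for misassignment with no mechanistic attribution. With two
rounds, carryover c and swap s, the expected correct-barcode fraction is
1 − s for the round-1 species but (1 − c)(1 − s) + c·s for the round-2
species, because its cells are exposed to round-1 carryover before their
own round arrives. The benchmark tests use exactly these closed forms.

# What the simulator emulates — and what it does not

`makeTissue` seeds non-overlapping circular cells into rectangular
regions; `makeTranscriptome` builds a merged two-species reference of
random sequences (500–2,000 nt) with log-normal per-cell-type expression
means, so every gene id is unique across species as in a merged-genome
mapping. Molecule pools are Poisson per (cell, gene). Reads prime
uniformly over the transcript positions that leave a full mappable
fragment: the extraction step uses at most 40 nt of cDNA, and priming
sites that cannot produce a mappable fragment would be invisible to any
aligner, so the simulator does not emit them. Substitution errors are
i.i.d. per base over the whole read; PCR duplicates replicate a molecule
(same UMI, same priming site) with independent errors; Read 2, when
emitted, reads from the A-tail end as a leading T-run plus the reverse
complement of the fragment, with an optional chimera rate that splices in
a fragment of an unrelated transcript.

Deliberately not modelled: RT kinetics and photochemistry rates, quality
scores (dummy Phred+33), indels, splicing, rRNA-specific sequence content
(rRNA-like genes are emulated by boosted expression means plus a biotype
flag), diffusion of molecules before crosslinking, and real image
registration. Passing tests therefore demonstrate the correctness of the
pipeline's logic under the declared read architecture — they do not certify
performance on real data, where alignment ambiguity, indels and coverage
biases are richer than this generator produces.

Two structural parameters are not published for the real assay and are
package choices, flagged here for users. The UMI length defaults to 8 nt
(65,536 possible UMIs), chosen so the saturation guard is exercisable at
desk scale; and the UMI is placed immediately after the barcode, so one
fixed-offset extraction recovers both (the barcode oligo carries both
elements, but their exact internal layout is not printed anywhere we can
cite, and adjacency matches fixed-layout extraction practice).

# Parsing and the 7-vs-8 junction ambiguity

Demultiplexing is by exact string equality of the first 12 bases against
the whitelist — no mismatch tolerance — so at substitution rate e the
expected acceptance is (1 − e)^12; a Hamming-1 correction mode exists
behind `correctBarcodes = TRUE` but is off by default. The junction
remnant is trimmed adaptively: 7 bases are always skipped, and an 8th iff
it equals the A-tail base. When a 7-nt junction is followed by a cDNA that
genuinely starts with A, this rule trims one real base; the fragment is
then still an exact (one-shorter) substring of its transcript, which is
why the assignment stage tolerates the misresolution by construction.

# Assignment, rescue and deduplication

Because the reference is synthetic and unspliced, a deterministic
substring search replaces a spliced aligner: exact 12-mer seeds at offsets
0, 12, 24 … of the fragment (pigeonhole coverage of the mismatch budget),
candidate placements verified over the full fragment allowing at most one
mismatch per 20 nt, both strands searched. The unique-mapping rule is
absolute: verified hits in two or more genes discard the read as
multimapped. This design is exactly oracle-checkable — a brute-force
substring scan must agree read for read — which is the reason to prefer it
over a heuristic aligner here.

Reads left unassigned are compared with a designated rescue sequence
(e.g. a transgene absent from the reference) by local Smith–Waterman
alignment with scores match +2, mismatch −3, gap open 5, gap extend 2
(striped-implementation defaults; a gap of length L costs
open + (L−1)·ext) and are rescued iff the score reaches 40 *and* their UMI
has not been seen among rescued reads of the same barcode, first
occurrence in input order winning. Only the threshold 40 is an external
constant; the scoring values are a package default, and sensitivity to
them is not resolved here — users changing them should re-derive the
boundary cases (20 exact bases score 40; 19 score 38).

Deduplication reimplements the directional-adjacency method: a directed
edge u → v between Hamming-1 UMIs whenever count(u) ≥ 2·count(v) − 1, with
molecules counted as absorption clusters grown from count-sorted roots
(ties broken lexicographically, so input order never matters). Two
properties deserve emphasis because they shape what "exact recovery" can
mean. First, the method is count-sensitive: PCR duplication changes
per-UMI counts and can legitimately change the collapse. Second, two
*distinct* molecules whose random UMIs happen to sit at Hamming distance 1
satisfy 1 ≥ 2·1 − 1 and merge; at m molecules per (gene, barcode) group
the expected loss is roughly m·25/4^8/2 — about 1% at m = 30 but over 10%
at m = 600. End-to-end tests therefore compare pipeline counts with the
directional collapse of the truth table's own UMI multisets (an exact
statement), not with the raw number of distinct molecules (unattainable by
any UMI method at finite UMI length). The saturation guard drops a gene
when its unique UMI count reaches floor(0.9 · 4^umiLen) — the 0.9 is a
documented default standing in for "came close to saturation", not a
published constant — and every decision is logged with both numbers.

# Quantification conventions

log2(TPM + 1) normalizes counts by gene length in kilobases and scales
each sample to 10^6; RPKM divides counts by length in kilobases and again
by the per-condition total over 10^6. Spatial yield is reported per
10 × 10 µm² unit area: total UMIs × 100 / barcoded area, with the area
taken either from mask pixel counts or from an externally measured value.
Cell numbers follow the arclength scaling
total = arc_total × cells_small / arc_small, optionally multiplied by the
0.72 bipolar fraction when only bipolar cells should be counted; fractions
are kept unrounded internally and rounded half-up only at report time.

Sensitivity is reported as observed / expected × 100%, where the
expectation is the mean smFISH puncta per cell over non-excluded subtypes
(the BC1B-like subtype is excluded because its cell bodies lie outside the
barcoded layer) times the estimated cell count. The inverted ratio is
available behind `invert = TRUE` for compatibility with sources that write
the definition the other way around; the default orientation is the one
that makes a few-percent efficiency read as a few percent.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in a couple of minutes on one core: two species ×
25 cells × 25 genes (≈ 50–60k molecules) for round trips, 50,000 sampled
reads for the exactness checks, 10–20 seeds for the noise- and
sensitivity-recovery studies, and a 3,000-cell synthetic smFISH reference
(large enough that reference noise is negligible against the across-seed
CI). Statistical recovery checks use 99% binomial or t intervals computed
from the run itself. Degenerate inputs are defined rather than accidental:
empty phantoms and empty UMI multisets are valid (count 0), a region may
erode away entirely, an all-zero expression sample warns and returns
zeros, and a species with no mapped reads reports NA rather than 0.

# Known limitations

The pipeline inherits the simulator's assumptions listed above; in
particular, the k-mer assignment is not a general aligner and should not
be pointed at real genomes. Differential expression is consumed, not
computed — `layerMarkers` takes externally produced fold-change /
adjusted-p tables and applies only the both-pairwise-comparisons marker
rule. The directional dedup reproduces the standard method's semantics,
including its intentional merging behaviour near saturation; if that is
undesirable at very high molecule densities, lengthen the UMI in the
layout rather than re-tuning the guard.
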