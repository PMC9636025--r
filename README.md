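# LightSeqKit

Light-directed in situ barcoding attaches photo-crosslinkable DNA barcodes
to cDNA molecules inside selected regions of interest (ROIs) of a fixed
sample, round by round, and reads them out by ordinary short-read
sequencing. Each Read 1 then carries, in fixed order, a spatial barcode, a
unique molecular identifier (UMI), a short junction remnant left by the
cross-junction synthesis reaction (7 nt, or 8 nt when the polymerase
A-tails), and up to 40 nt of mappable cDNA.

LightSeqKit is an R package for people building or validating the
computational side of such experiments. It provides, end to end and fully
exercisable on synthetic data:

- **Photomask tools** — polygon-to-raster conversion by the pixel-center
  rule, morphological erosion by a Euclidean disk (to pre-shrink ROIs
  against light scatter), Floyd–Steinberg serpentine dithering, and a
  Gaussian scatter-dose model with a hard crosslink threshold.
- **A read simulator** — tissue phantoms of non-overlapping cells, a merged
  two-species synthetic transcriptome, iterative barcoding with carryover /
  scatter / swap noise, and FASTQ-style reads with a per-read ground-truth
  table (internal priming, substitution errors, PCR duplicates, optional
  Read 2 with chimeras).
- **The processing pipeline** — fixed-layout parsing with exact-match
  barcode demultiplexing, deterministic k-mer transcript assignment with
  the unique-mapping rule (multimappers discarded), Smith–Waterman rescue
  of unmapped reads against a designated sequence (score ≥ 40 and a unique
  UMI), and directional-adjacency UMI deduplication with a saturation
  guard.
- **Quantification and benchmarks** — log2(TPM+1), RPKM, UMIs per
  10 × 10 µm² unit area, arclength-scaled cell-count estimates (with the
  72% bipolar fraction), species discrimination ratios, pseudo-bulk
  pooling, smFISH-anchored sensitivity, layer-marker logic, gene body
  coverage, chimeric-pair rates and replicate correlation.

## Core definitions

For a UMI multiset within one (gene, barcode) group, molecules are counted
by the directional collapse: an edge u → v exists between UMIs at Hamming
distance 1 when count(u) ≥ 2·count(v) − 1, and each absorption cluster is
one molecule. Normalizations follow the standard forms
TPM_g = 10^6 · (c_g / l_g) / Σ_j (c_j / l_j) and
RPKM = c / (l/10³) / (N/10⁶); spatial yield is UMIs · 100 µm² / barcoded
area; cell counts scale as cells_total = arc_total · cells_small /
arc_small. Sensitivity against an smFISH reference is
observed / expected · 100%, with the expectation being the mean puncta per
cell over non-excluded subtypes times the estimated cell number.

## Worked example

```r
library(LightSeqKit)

reg <- data.frame(region = c("left", "right"),
                  xmin = c(0, 120), xmax = c(100, 220), ymin = 0, ymax = 100,
                  n_cells = 25L, species = c("human", "mouse"),
                  cell_type = c("HEK", "3T3"))
tissue <- makeTissue(reg, boundsUm = c(220, 100), seed = 2)
tx   <- makeTranscriptome(meanLog = log(40), seed = 3)
wl   <- barcodeWhitelist(2, seed = 4)
mask <- polygonToMask(list(cbind(c(0,100,100,0),  c(0,0,100,100)),
                           cbind(c(120,220,220,120), c(0,0,100,100))),
                      labels = 1:2, umPerPixel = 2,
                      widthUm = 220, heightUm = 100)

bc  <- simulateBarcoding(tissue, tx, mask, ScatterModel(), seed = 5)
sim <- simulateReads(bc, tx, ReadLayout(), wl, tissue, seed = 6)
parsed <- parseReads(sim$r1, ReadLayout(), wl)
asg    <- assignTranscripts(parsed, buildTranscriptIndex(tx))
um     <- countMolecules(asg, parsed)
um
#> UMICountMatrix: 50 genes x 2 barcodes; 41703 molecules
#>   BC1   BC2
#> 21359 20344
discriminationRatio(asg, parsed, setNames(c("human","mouse"), wl$barcode_id))
#> human mouse
#>     1     1
#> attr(,"n")
#> human mouse
#> 30010 27572
```

On this noise-free run every read's barcode, UMI and transcript assignment
match the simulator's truth table, so both species discriminate perfectly;
the molecule totals are the directional-collapse counts per barcode.
Adding `ScatterModel(sigmaUm = 3, carryoverRate = 0.05)` and
`swapRate = 0.1` degrades the discrimination exactly as the injected rates
predict.

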