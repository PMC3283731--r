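# alnscope

Pre-phylogenetic diagnostics for amplicon multiple sequence alignments.

Environmental sequencing studies (fungal ITS / 28S-LSU clone libraries and
their successors) routinely push a multiple sequence alignment straight into
OTU clustering and tree building. When the alignment is gap-riddled and
ambiguously alignable — as ITS alignments across genetically distant taxa
are — every downstream number (OTU counts, Chao1, rarefaction curves,
bootstrap supports) silently inherits that noise. `alnscope` quantifies
alignment quality *before* those steps, for molecular ecologists choosing
markers, treatments and OTU cutoffs.

## What it computes

**Gap-aware column entropy and relative heterogeneity.** The entropy at
column *i* is `H_i = -Σ p(x_i) ln p(x_i)` (nats) over the five states
{A, C, G, T, E}, where E is the real-indel state. A gap or `N` may be any
of the four bases or a real indel, so it feeds 1/5 to each state; other
IUPAC codes feed equal shares to their constituent bases (Y → ½C + ½T).
Summing over columns gives the cumulative entropy `H`, partitioned exactly
into gap-free (`H_f`) and gap-containing (`H_g`) columns, and the relative
heterogeneity `h = H / H_max ∈ [0, 1]` — 0 for a fully conserved alignment,
1 when every column's occurring states are equidistributed. Runs of
consecutive columns with `H > 1.5` nats localise the ambiguously alignable
blocks.

**Alignment treatments.** T1 is the raw alignment; T2 recodes every
leading/trailing `-` as `N` (a terminal gap is missing data, not an indel);
T3 additionally excises ambiguously alignable column ranges (from a mask
file or the windowed gap/entropy auto-detector).

**OTU clustering and diversity.** Greedy seed clustering by percentage
sequence identity (ignoring gap-containing columns) at cutoffs
0.95/0.97/0.98/0.99, with single-linkage as an alternative; OTUs classed as
singleton, quasi-singleton (≥2 identical sequences — no measurable internal
distance) or multiton; Shannon `H' = -Σ p_i ln p_i`, evenness `E = H'/ln S`,
classic Chao1 `S + F1²/(2F2)`, and analytic (hypergeometric) or Monte-Carlo
rarefaction.

**Distances, saturation and trees.** Pairwise transition/transversion
counts and K2P distances `d = -½ ln(1-2P-Q) - ¼ ln(1-2Q)`; DAMBE-style
saturation profiles with the transversion/transition crossover distance;
BioNJ/NJ trees (via ape) with seeded column-bootstrap supports and
monophyly reports.

**OTU distance areas.** The internal distance of an OTU is the maximum path
length from its last-common-ancestor node to a member leaf. With *n*
members in an alignment of *N* sequences,
`IODA = 100 · d_int · n / N` and `RODA = 100 · d_int · n / (N · Σ_j d_int_j)`
place every OTU in a distance-area plot bounded by the *n* = 2 and *n* = N
lines — a compact picture of how the genetic diversity space is filled and
how OTUs split as the cutoff tightens (`cutoffSweep()`).

A seeded simulator (`simulateAlignment()`) generates aligned amplicon sets
with planted OTU clusters, conserved/hypervariable/gap-rich blocks, IUPAC
ambiguities and terminal overhangs, so every statistic is testable against
known truth.

## Worked example

```r
library(alnscope)

sim <- simulateAlignment(nSequences = 120, nClusters = 20, seed = 42)
aln <- sim$alignment

prof <- entropyProfile(aln)
het  <- heterogeneitySummary(prof)
#> H_total = 361.59 nats (H_f = 211.90, H_g = 149.69)
#> h = 0.460, h_f = 0.362, h_g = 0.744
highEntropyRuns(prof)
#>   start  end length meanGapFrequency
#> 1     1    6      6         86.11111
#> 2   993 1000      8         82.70833

tab <- classifyOTUs(clusterOTUs(aln, 0.95), aln)
diversityIndices(otuSizes(tab))
#> S = 20, Chao1 = 20.00, H' = 2.996, E = 1.000

tree <- buildNJTree(k2pMatrix(aln))
head(distanceAreaTable(tab, tree, N = 120), 3)
#>   otuId n        dInt       ioda      roda    class onMinLine excluded
#> 1  OTU1 6 0.009855496 0.04927748 0.2641153 multiton     FALSE    FALSE
#> 2  OTU2 6 0.010255203 0.05127602 0.2748270 multiton     FALSE    FALSE
#> 3  OTU3 6 0.010530838 0.05265419 0.2822136 multiton     FALSE    FALSE
```

Reading the numbers: the cumulative entropy concentrates in gap-containing
columns (`h_g = 0.744` versus `h_f = 0.362`), and both high-entropy runs sit
in the gap-dominated overhang flanks (mean gap frequency > 82%) — the
signature of ambiguously alignable regions. Clustering at 95% identity
recovers exactly the 20 planted OTUs (Chao1 = S = 20: no singletons, so no
estimated unseen richness; evenness 1.0 because the planted clusters are
equally sized). Each OTU's internal K2P distance (~0.01) matches the
simulated within-cluster divergence, and its IODA/RODA coordinates place it
far below the `n = N` ceiling of the distance-area plot.

## Command line

`exec/alnscope` exposes the same operations as subcommands:

```sh
alnscope simulate --seed 42 --out sim.fasta --truth truth.tsv
alnscope summary  sim.fasta --out summary.tsv
alnscope entropy  sim.fasta --out profile.tsv --summary het.json --runs runs.tsv
alnscope otu      sim.fasta --cutoff 0.95 --out otus.tsv --diversity div.json
alnscope tree     sim.fasta --bootstrap 100 --seed 17 --out tree.nwk
alnscope roda     sim.fasta --cutoff 0.95 --out roda.tsv
alnscope pipeline sim.fasta --seed 7 --out manifest.json
```

## Acceptance script

`scripts/acceptance.R` re-runs the full diagnostic battery from scratch on
the package's stated-world synthetic fixture (120 sequences, 20 planted
clusters, hypervariable and gap-rich blocks) across the T1/T2/T3 treatments
and the standard cutoff series, printing the per-treatment summary
statistics and writing the JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`, so reruns are bit-identical.
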