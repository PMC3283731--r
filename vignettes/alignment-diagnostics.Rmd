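---
title: "Alignment diagnostics before OTUs and trees: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment diagnostics before OTUs and trees: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alnscope)
```

# Motivation

Amplicon surveys of complex communities lean on a fragile object: a multiple
sequence alignment of markers (ITS spacers, LSU expansion domains) whose
hypervariable, gap-rich stretches cannot be aligned with confidence across
distant taxa. OTU counts, richness estimators, rarefaction curves and
phylogenetic trees all change — sometimes drastically — with the treatment of
terminal gaps and ambiguously alignable columns. `alnscope` provides the
quantities needed to see this before committing to a clustering or a tree:
an information-theoretic heterogeneity profile of the alignment, the
standard diversity battery under controlled treatments, substitution
saturation diagnostics, and OTU distance-area parameters that expose how
OTUs fill the genetic diversity space.

# The entropy model

## Feeder frequencies

Every cell of a column contributes total weight 1 over the five states
$\{A, C, G, T, E\}$, with $E$ the real-indel state:

* an unambiguous base contributes 1 to itself;
* `-` and `N` contribute $1/5$ to each state — a gap can hide any base or
  be a genuine indel, and with no model of which, the five possibilities are
  weighted equally (an explicit, deliberately agnostic choice);
* any other IUPAC code contributes equal shares to its constituent bases,
  e.g. $Y \mapsto \tfrac12 C + \tfrac12 T$.

Frequencies are contribution sums divided by column depth, and the column
entropy is $H_i = -\sum_{p>0} p \ln p$ in nats. Partial entropies of
non-occurring states are not added, so columns differ in their attainable
maximum. Treating `N` like a gap follows from the T2 treatment, where `N`
explicitly denotes "gap or unspecified nucleotide"; `columnStateFrequencies`
takes `nStates = 4` to spread `N` over bases only, as a sensitivity switch.

## Relative heterogeneity

The cumulative entropy $H = \sum_i H_i$ partitions exactly into gap-free
($H_f$) and gap-containing ($H_g$) columns. The relative heterogeneity is
$h = H / H_\mathrm{max}$. Because the attainable maximum is
column-specific, the default convention (`occurring_states`) uses
$H_\mathrm{max} = \sum_i \ln k_i$ with $k_i$ the number of occurring states
in column $i$; single-state columns contribute zero to numerator and
denominator alike. The alternative `uniform5` convention uses the fixed
ceiling $\ln 5$ per column. Both are exposed because the choice is genuinely
open; `occurring_states` is the default since it makes $h = 1$ mean exactly
"every column's observed states are equidistributed", the reading that
matches the interpretation of $h$ as loss of resolving power. $h = 0$
only for a fully conserved alignment, which is flagged with a warning since
$H_\mathrm{max} = 0$ makes the ratio formally undefined.

## High-entropy runs

Ambiguously alignable regions appear as *runs* of consecutive columns with
$H_i > 1.5$ nats (strict inequality), minimum length 2. The 1.5-nat
threshold sits between $\ln 4 \approx 1.39$ (four equidistributed bases)
and $\ln 5 \approx 1.61$ (maximal gap-state mixing), so a run cannot be
produced by ordinary fourfold base variation alone — it requires gap-state
mixing, which is why runs co-locate with gap-rich blocks. Each run is
annotated with its mean gap frequency to make that association measurable.

# Treatments

* **T1** — the alignment as produced by the aligner.
* **T2** — every maximal run of terminal `-` becomes `N`, per sequence. A
  terminal gap is an artefact of unequal read spans, not an indel event.
  The operation is idempotent, conserves all nucleotide characters, and
  leaves the column count unchanged. A fully gapped record becomes all `N`
  (the literal reading of the rule).
* **T3** — T2 plus deletion of masked column ranges, so the alignment
  *shortens*; this matches how curated analyses report reduced alignment
  lengths. Masks come from a TSV of 1-based inclusive intervals or from
  `detectAmbiguousColumns()`, a windowed surrogate for manual curation:
  flag columns whose rolling mean gap fraction reaches 0.5 or rolling mean
  entropy reaches 1.5 nats (window 5). The thresholds reuse the run
  threshold and a majority-gap rule; they are stated defaults, not fitted
  values, and the expert's hand-made mask remains the reference.

# OTU clustering and diversity

Percentage sequence identity (PSI) between two aligned records is the match
fraction over usable columns. The default denominator ignores
gap-containing columns *globally* (any sequence gapped at a column removes
it for everyone), the literal reading of "ignoring gap-containing
columns" and the behaviour that makes PSI a single consistent metric
across the alignment; a per-pair deletion mode is provided because greedy
dereplication tools differ here.

Seed clustering processes sequences in input order: each joins the first
OTU whose *seed* has PSI ≥ cutoff, else founds a new OTU. This reproduces
the greedy nearest-neighbour behaviour of classic dereplication tools, is
deterministic, and is order-dependent by construction (the
`sortByAbundance` switch exists for order-robustness studies).
Single-linkage clustering (chains of PSI ≥ cutoff) is the second mode; it
is order-independent and monotone in the cutoff, which the suite verifies.

Classes: *singleton* (one sequence), *quasi-singleton* (≥ 2 sequences,
identical over usable columns — indistinguishable data that behave like a
singleton in every distance-based sense), *multiton* (everything else).

Diversity: Shannon $H' = -\sum p_i \ln p_i$ (nats), evenness
$E = H'/\ln S$ (0 when $S = 1$), and the *classic* Chao1
$S + F_1^2/(2F_2)$ with the $F_2 = 0$ fallback $S + F_1(F_1-1)/2$. The
classic rather than bias-corrected form is used because it is the form
consistent with the clone-library reference values the test suite asserts
(e.g. $S = 35, F_1 = 24, F_2 = 1 \Rightarrow 323.0$).

Rarefaction: the analytic curve is the hypergeometric expectation
$E[S_n] = \sum_i \left(1 - \binom{N-n_i}{n}/\binom{N}{n}\right)$, evaluated
on the log scale for numerical stability. The Monte-Carlo mode draws one
permutation per replicate and reads the whole curve from prefixes, which is
fast, unbiased at every $n$, and gives smooth (positively correlated)
curves per replicate.

# Distances, saturation, trees

Transitions are purine–purine or pyrimidine–pyrimidine differences;
everything else is a transversion. Sites where either sequence carries a
gap, `N` or any ambiguity code are excluded rather than fractionally
counted, matching mainstream distance software. K2P:
$d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$. When a log argument is
non-positive the pair is *recorded as undefined* — saturation is a finding,
not a missing value, so `buildNJTree()` refuses such matrices by naming the
pairs instead of dropping them.

Site policies differ by purpose: `complete_deletion` (global gap-free
columns) for tree building, `pairwise_deletion` for saturation profiles —
each pair should contribute everything it can to the saturation picture.
The profile bins pairs into 20 equal-width distance bins and reports the
crossover: the smallest bin where mean transversions reach mean
transitions, the operational definition of substitution saturation. The
crossover is read off binned means because that is how it is read off a
plot; its resolution is one bin width.

NJ/BioNJ agglomeration is delegated to `ape` (the reference R
implementation); correctness is *checked*, not assumed, against a
brute-force least-squares oracle over all topologies on additive matrices.
Negative NJ branches are clamped to zero with the deficit moved to the
sibling edge, preserving total tree length and keeping all path lengths —
hence OTU internal distances — non-negative. MRCA queries are
root-dependent, and the trees are inferred unrooted, so a rooting policy is
required: midpoint by default (no outgroup exists in a clone library), any
leaf as outgroup optionally. A distance-matrix fallback for the internal
distance (half the maximum within-OTU pairwise distance) is provided for
sensitivity analysis.

Bootstrap supports resample columns with replacement, rebuild the tree, and
count the original tree's bipartitions in the replicates (strict matching).
Failed replicates (saturated resamples) are skipped and counted, never
silently imputed.

# OTU distance areas

An OTU's internal distance $d_\mathrm{int}$ is the maximum path length from
its MRCA (treated as part of the OTU) to a member leaf; undefined for
singletons — requesting it raises an error rather than returning 0, because
0 is a meaningful value (quasi-singletons). With $n$ members among $N$
sequences:

$$\mathrm{IODA} = 100\,\frac{d_\mathrm{int}\,n}{N}, \qquad
  \mathrm{RODA} = 100\,\frac{d_\mathrm{int}\,n}{N \sum_j d_{\mathrm{int},j}}$$

IODA normalises by the tree's maximum possible distance area ($N$); RODA
corrects instead for the distance actually realised by all included OTUs
together. The realised-total denominator is implemented as the *sum* of
included internal distances (`sum_internal`, default) with a
`max_internal` alternative, because the correction's exact form is an open
design point; the sum is the default as the only choice that makes the
RODA shares of the included OTUs a bounded partition (their total cannot
exceed 100). Singletons and quasi-singletons carry no area. In the plot
($x = d_\mathrm{int}$, $y$ = RODA or IODA), areas are linear in $n$ at
fixed $x$, so all points lie between the $n = 2$ and $n = N$ lines, with
doubletons exactly on the minimum line. `cutoffSweep()` links each OTU at a
stricter cutoff to the looser-cutoff OTU containing its seed, giving the
lineage view of how OTUs split as the cutoff tightens.

# The synthetic fixture world

`simulateAlignment()` emulates a pooled clone library: 120 sequences by
default (three pooled samples of 40), ~1000 columns in blocks — a conserved
core (600), a hypervariable block (300) and a gap-rich block (100, i.i.d.
gaps at 0.3 per cell), with uniform 0–25-column terminal overhangs and
sparse IUPAC ambiguities (0.001 per cell). Default divergences: 1% within
and 20% between clusters, the scales at which spacer alignments start to
saturate. Mutation is K2P with ts/tv = 2, matching the downstream distance
model.

Divergence semantics: `withinDivergence` is the expected *pairwise* K2P
distance between two members of a cluster (members evolve
`withinDivergence/2` from their ancestor), so the empirical within-cluster
distances estimate the parameter directly. Deep (between-ancestor)
mutations are confined to the non-conserved blocks — mirroring real
amplicons, where deep divergence concentrates in hypervariable regions —
with the per-site rate scaled so the whole-sequence between-ancestor
distance equals `betweenDivergence`.

What the simulator does *not* emulate: realistic indel evolution (gaps are
i.i.d. within blocks, not phylogenetically inherited), chimeras,
sequencing error profiles, rDNA copy-number variation, or compensatory
base changes from rRNA secondary structure. A green test on this world
therefore establishes algorithmic correctness on planted structure, not
robustness to every artefact of real libraries.

# Numerical and statistical choices

* Percentages sum to 100 within $10^{-9}$; entropy partitions
  ($H = H_f + H_g$) hold exactly by construction.
* Medians over even column counts are midpoints of the central pair.
* Cutoff joins use PSI ≥ cutoff; run detection uses strict $H >$ threshold;
  the auto-masker flags at ≥ its thresholds so that a zero threshold flags
  everything.
* Chao1 uses `lchoose`-free closed forms; rarefaction uses `lchoose`
  differences to avoid overflow.
* All randomness flows from one seed via a linear splitting scheme
  (`deriveSeed`), keeping every derived seed below $2^{31}$.
* Monte-Carlo agreement checks use three standard errors of the replicate
  mean; where the replicate distribution degenerates (empirical SE of 0),
  the tolerance is floored at the Monte-Carlo resolution (1/replicates),
  since a 3-SE bound is ill-posed there.

# Known limitations and honest reds

Two checks in the validation suite are expected to stay red, by analysis
rather than defect:

* **Exact planted-partition recovery at a 0.99 cutoff with 1% within-OTU
  divergence.** The identity margin at cutoff $c$ is $1 - c$; at
  $c = 0.99$ it equals the expected within-cluster divergence, so the
  member-versus-seed identity distribution is centred exactly on the
  joining threshold and exact recovery has vanishing probability at any
  alignment length. Recovery is essentially certain whenever the margin
  exceeds the divergence with room for binomial noise (the suite
  demonstrates this at 0.95–0.98 over a 1.6-kb fixture, sized by a power
  calculation so sampling noise cannot confound a positive margin).
* **Per-point 3-SE agreement of Monte-Carlo rarefaction at *every* sample
  size across many abundance vectors.** With hundreds of correlated
  per-point comparisons, an exactly unbiased estimator is still expected
  to produce a maximum $|z|$ near 3.2; occasional single-point excursions
  just past 3 SE are the signature of correct calibration, not of bias.
  Unbiasedness is established separately against the analytic
  hypergeometric expectation and an independent reference implementation.

Other limitations: seed clustering is input-order dependent (by design,
for fidelity to greedy dereplication); the T3 auto-masker is a stated
surrogate for expert curation; ML estimation of per-alignment ts/tv rate
ratios is out of scope (count-based per-pair ratios are emitted instead);
and the K2P model assumes uniform rates across sites.
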