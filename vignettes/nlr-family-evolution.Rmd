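---
title: "Methods: NBS-LRR family evolution with nlrevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NBS-LRR family evolution with nlrevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nlrevol` implements a desk-scale version of the workflow used in
comparative surveys of plant NBS-LRR (NLR) resistance-gene families: how
many NLRs does each genome carry, in which architecture subclasses, how do
they cluster into families, when did the duplications happen, under what
selective pressure, and which copies respond to infection. This vignette is
the package's own account of the models and the design choices behind each
stage; it states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## Subclass classification

A gene qualifies as an NBS-LRR when its domain table contains at least one
NB-ARC hit and at least one LRR hit, from any annotation source. The
subclass is decided by the N-terminal domain, *operationalised* as a
qualifying hit whose `aa_start` precedes the first (smallest `aa_start`)
NB-ARC hit — annotation pipelines report coordinates, not "N-terminality",
so a coordinate rule is needed. Precedence is TIR > RPW8+CC > CC > RPW8 >
none, yielding TNL, RPW8-CNL, CNL′, RPW8-XNL, XNL′. A gene carrying both an
N-terminal TIR and CC is classified TNL — TIR is the subgroup-defining
domain in this taxonomy — and flagged `ambiguous` for QC rather than
silently absorbed. Coordinates are 1-based inclusive amino-acid positions
throughout.

Running InterProScan/SMART/Pfam themselves is out of scope: the classifier
consumes their tabular output (both a native 4-column dialect and the
headerless InterProScan column order are parsed), or the simulator's
equivalent.

## Family clustering

Similarity edges carry percent identity (matches over aligned columns of
the best local alignment; match +1, mismatch −2, gap open −5, gap extend
−2) and percent coverage. Two open choices had to be fixed:

* **Coverage denominator** — the shorter sequence of the pair. This is the
  permissive standard choice and is applied identically to internally
  aligned and BLAST-supplied edges (where the HSP alignment length is used).
* **Linkage** — pairwise criteria do not define families by themselves;
  single-linkage connected components are the simplest rule consistent with
  building families from pairwise hits, and they make the family count and
  multi-gene count well defined. The test suite checks the components
  against a literal transitive-closure oracle on random graphs.

Thresholds are strict (`> 70`, `> 80`, `> 90` percent on *both* criteria),
so a pair at exactly 70.0 does not cluster. Raising the level only removes
edges, so multi-gene counts are non-increasing in the level — asserted on
every simulated dataset. Reciprocal asymmetric hits merge into one
undirected edge keeping the maximum identity and coverage; only the best
HSP per pair is used (no HSP tiling — a documented limitation). A family's
average identity is the mean over its threshold-surviving edges (`NA` for
singletons, excluded from summary means).

## Ka/Ks, diversity, and dating

CDS pairs are aligned through their translations (Needleman–Wunsch,
BLOSUM62, gap open 10, gap extend 0.5) and back-threaded to codons, so
alignment columns are codons and frame is never broken. Rates use the
Nei–Gojobori (1986) counting method:

* synonymous sites per codon are the per-position fractions of single-
  nucleotide changes that preserve the amino acid, with changes to stop
  codons removed from the denominator;
* differences for multi-hit codons are averaged over all minimal mutational
  pathways, excluding pathways through stop codons (falling back to all
  pathways only if every one is blocked);
* the Jukes–Cantor correction `d = -(3/4) log(1 - (4/3) p)` maps raw
  proportions to rates. A proportion at or above 3/4 saturates: the pair is
  flagged and reported not-computable rather than clamped.

NG86 rather than a maximum-likelihood (codeml-style) estimator is a
deliberate choice: the surveys this package mirrors use distance-style
counting, NG86 is the classical default, and its site/pathway arithmetic
can be verified exhaustively against an independent single-codon enumerator
(the test suite does exactly that over all 61 × 61 codon pairs). Pairs with
`ks = 0` have undefined ω and are excluded from ω summaries rather than set
to infinity. Gap columns are pairwise-deleted for both rates and diversity.

Family nucleotide diversity (*Pi*) is the mean over unordered member pairs
of the proportion of differing sites among mutually ungapped columns,
computed per pair rather than on one family-wide multiple alignment — with
pairwise deletion the two agree on the package's indel-free simulations,
and the pairwise form matches its brute-force oracle exactly.

**Dating.** `T = Ks * gen_years / mu`, with defaults μ = 9.48e-9 point
mutations per site per generation and 3 years per generation, reported in
million years. Two remarks. First, the formula string this convention
descends from can be read left-to-right as `(Ks / mu) / 3`, which gives
ages 9× smaller; the implementation follows the convention that reproduces
the published ages (31.65 MY at Ks = 0.1, 63.29 at 0.2, 158.23 at 0.5),
and those three values are pinned in the acceptance checks. Second, there
is no division by 2 for two diverging lineages — again fixed by the printed
ages rather than by the more common `T = Ks / 2r` convention, and
documented so users comparing against other pipelines are not surprised.
`dating_params()` makes both constants explicit and overridable.

Group contrasts (e.g. TNL vs non-TNL *Ks*) use Welch's t-test — the
equal-variance assumption is not defensible for these skewed distributions
— plus type-7 quantile box-plot summaries. The *Ks* histogram uses
half-open bins `[k/10, (k+1)/10)` on `[0, 1)` after the `Ks < 1` filter;
modal bins are local maxima with plateaus collapsed to their first bin.

## Trees and duplicated clades

Internal trees are neighbor joining on Jukes–Cantor distances over the
NB-ARC nucleotide regions (coordinates from the domain table), with
negative branch lengths clamped to zero, midpoint rooting, and a
column-resampling bootstrap whose supports are the percentage of replicate
trees containing each original bipartition. NJ + bootstrap, not maximum
likelihood, keeps the stage dependency-free and fast; externally built ML
trees can be supplied as Newick (`read_newick()`, which also rescales
fraction-valued supports to percent) because the clade classifier is
tree-agnostic. A bootstrap replicate can resample a saturated pair
(p ≥ 3/4); its undefined distance is capped at twice the largest finite
distance so NJ stays defined — this only affects branch lengths deep in
replicate trees, not the counted bipartitions of clean splits.

Clade calling walks the rooted tree from the root and calls a node when its
support strictly exceeds the threshold (default 50) and it holds ≥ 2 genes:

* one species ⇒ **species-specific** duplicated clade;
* ≥ 2 species *and* at least one within-species pair ⇒ **lineage-specific**
  duplicated clade. A mixed clade with no within-species pair evidences
  speciation, not duplication, and is *not* called.

Calls are **maximal**: descendants of a called node are skipped. Whether
nested supported clades should be counted once or repeatedly is genuinely
open in this literature; maximality makes the per-type gene counts a
partition (no gene counted twice), which is the only reading under which
"x% of genes arose by species-specific duplication" is interpretable. The
root is never called — it has no bipartition support. Note that maximality
means the *number* of calls is not mathematically monotone in the support
threshold in adversarial trees (removing a called ancestor can expose two
supported descendants); on the package's planted simulations, where event
clades are cleanly separated and near-fully supported, monotonicity holds
and is asserted.

## Expression screening

DEG criteria are conjunctive: `|logFC| >= 2` (boundary passes), `p < 0.05`
and `FDR < 0.05` (boundaries fail). The logFC base is log2 — the standard
reading of a fold-change-4 cutoff. DE estimation itself is out of scope;
the screen consumes precomputed tables and is agnostic to which contrast
produced them. Sample clustering uses 1 − Pearson correlation on
log2(FPKM + 1) profiles with average linkage — the common heatmap default,
configurable in spirit by clustering any matrix the caller passes — and
drops constant gene rows (their correlation is undefined) with a warning.
The early/late contrast splits the course at ≤ 12 h vs ≥ 24 h and reports
per-gene and aggregate means per genotype with Welch tests.

## The synthetic-data generator

The generator is the package's test bed, not a biological simulator. Its
defaults encode the study conditions the package mirrors: six species,
eight time points (0, 3, 6, 9, 12, 24, 48, 72 h), 48 planted DEGs among
318 genes, low-*Ks* (≈ 0.1–0.3) species-specific and high-*Ks* (≈ 0.5–0.9)
lineage-specific duplication events — event timing is encoded purely
through *Ks* magnitude, mirroring the dating argument, not through an
explicit coalescent.

**Divergence control.** `simulate_diverged_pair()` keeps the ancestor as
one copy and mutates the other: random single-nucleotide proposals are
accepted against separate synonymous and nonsynonymous budgets, each
accepted change hits a fresh position and never creates a stop codon. The
budgets are the raw proportions obtained by *inverting* the Jukes–Cantor
correction at the requested `target_ks` (and `omega * target_ks`), so the
JC-corrected NG86 estimate recovers the target in expectation — the
recovery tests (200 pairs × 500 codons) ask for the corrected estimate to
land within ±0.03 of the target, which fixes this interpretation. Placing
all divergence on one branch is deliberate: only pair divergence is
observable downstream, and one-sided mutation gives exact budget control.

**Family geometry.** Families diverge from one master sequence with ~45% of
sites substituted per family ancestor — far below any clustering threshold
(~55% identity) yet below Jukes–Cantor saturation, so inter-family
distances stay finite and midpoint rooting falls on the long inter-family
branch. A species-specific family is g same-species copies duplicated at
the event *Ks*; a lineage-specific family duplicates the ancestor at the
event *Ks* *before* a shallow (*Ks* 0.05) speciation into ≥ 2 species, so
both duplicate copies occur in several species and the clade joining them
contains within-species pairs. Each family carries one of the five domain
architectures, cycled, with unambiguous coordinates.

**Expression.** Each planted DEG gets its own response amplitude
(uniform on 1–4 log2 units) times a genotype-specific time shape: a
logistic rise to a late plateau (midpoint 18 h) in the resistant genotype
and a wave peaking around 6–12 h in the susceptible one. The per-gene
amplitude matters: a gene-independent multiplier would shift every log
profile by a constant that correlation distance removes, leaving noise to
drive the clustering. The DE table guarantees exact truth recovery under
the screening criteria (planted |logFC| in [2.5, 6], p ≤ 1e-3 so
BH-adjusted FDR stays below 0.05 at 48/318; background |logFC| ≤ 1.5,
p ≥ 0.1).

**What passing tests do and do not show.** The simulator emits equal-length,
indel-free, recombination-free sequences with uniform substitution
processes, clean domain tables and well-separated families. Passing tests
therefore demonstrate the *correctness of the operations* — counting,
clustering, tree annotation, screening — under known truth, not robustness
to fragmented assemblies, chimeric annotations, gene conversion (explicitly
out of scope), alignment ambiguity or borderline family divergences.
Genome-scale published counts are not reproducible at desk scale and are
covered only as arithmetic through the reporting operations.

**Determinism.** One root seed feeds named substreams per generator, so
identical configs produce byte-identical files and adding a generator does
not perturb the others. The bootstrap and all simulation loops are seeded;
callers' RNG state is saved and restored.

## Problem sizes and numerical conventions

The test suite and acceptance script run, by choice, at: 500-codon genes ×
200 replicate pairs for estimator recovery; 100-codon genes, 2 families × 4
genes, 100 bootstrap replicates × 100 seeds for planted-event recovery; 318
genes × 16 samples × 100 seeds for expression. Percentages are printed with
two decimals, half-up. Ages are reported unrounded and rounded only for
display, so linearity (`date(2k) = 2 date(k)`) holds exactly.

## Known limitations

No indel simulation (the aligner is still exercised on constructed gapped
cases); no HSP tiling; no ML/Bayesian trees internally; no DE model
fitting; sequence-exchange (gene-conversion) detection is out of scope. The
`run_pipeline()` NB-ARC tree stage requires equal-length domain slices (as
the simulator emits); for real data, supply an external alignment or tree.
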