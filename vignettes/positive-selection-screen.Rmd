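---
title: "Screening and characterizing positively selected genes: methods and design notes"
author: "PSGscreen"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Screening and characterizing positively selected genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
assumptions each stage makes, and why the genuinely open design choices
were settled the way they were. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

# The screen

## Divergence estimation

Both estimators operate on in-frame codon alignments of ortholog pairs.
Columns in which either codon is a stop codon or contains `N`, a gap or
another ambiguity character are excluded *pairwise* (both codons of the
column dropped). Pairwise deletion is the convention of counting-method
tools; the alternative — trimming per sequence — would break the shared
site denominator.

**NG86.** For each sense codon, each of the nine single-nucleotide
mutations is classified synonymous or nonsynonymous against the standard
genetic code; mutations creating a stop codon count as nonsynonymous, so
`S + N = 3` per codon and `S + N = 3 × n` per pair. Differences between
codons with `k` mismatching positions are averaged over the `k!`
mutational pathways; pathways passing through a stop codon are removed
and the average renormalized over the survivors. If *every* pathway hits
a stop (possible only for `k ≥ 2`), each differing position is classified
by substituting it alone into the first codon — a documented fallback
that keeps `Sd + Nd = k`. Proportions are corrected with the Jukes–Cantor
formula; a proportion at or beyond 3/4 has no finite correction and the
pair is flagged `saturated` rather than given a fabricated number.

One subtlety worth knowing: pathway averaging can assign fractional
nonsynonymous differences to a pair even when the underlying history was
purely synonymous (e.g. CGT→CGA→AGA is synonymous throughout, but the
other order CGT→AGT→AGA passes through serine). So `Ka` under a true
ω = 0 is *near* zero, not identically zero, once codons are hit more than
once; the tests assert the real guarantee (protein identity, `Ka ≪ Ks`).

**YN00-style.** κ is estimated first, from codon positions that are
fourfold degenerate in both codons of a column pooled with positions
nondegenerate in both. At fourfold positions every change is synonymous;
at nondegenerate positions every change is nonsynonymous, so within each
class the transition/transversion ratio is untouched by selection.
Transition and transversion proportions over the pooled positions are
corrected with the K80 two-parameter model and κ is the ratio of the
corrected transition distance to half the transversion distance (pooling
the two classes rather than averaging per-class estimates is a
simplification; the recovery tests bound its cost — κ̂ within ±0.3 of 1
and ±1 of 4 at 10⁴ codons). Site counting then weights each possible
mutation by the F3×4 target-nucleotide frequency times κ for transitions;
difference counting weights each pathway by the product of its step rates
including ω on nonsynonymous steps; synonymous and nonsynonymous
proportions are corrected separately with K80; and the ω-dependent
weighting is iterated to a relative tolerance of 1e-6 with a cap of 100
iterations (the last iterate is returned flagged `not_converged`
otherwise — in practice convergence takes a handful of iterations). With
κ = 1 and uniform frequencies all weights cancel and the site counts
reduce to NG86 exactly; this is a regression test. No bit-compatibility
with PAML's `yn00` is claimed, which is why the NG86 estimate is always
available for co-reporting.

## Thresholds

Two filters define the PSG call, both read strictly off their
inequalities and both exposed as arguments:

* `maxKs = 0.3` — pairs with `Ks > 0.3` are discarded as saturated
  *before* classification. The filter counts pairs, and the output header
  says so, because a "gene" and a "pair" coincide only in a one-to-one
  ortholog set.
* `omegaThreshold = 1.2` — a pair is a PSG iff ω is defined and
  `ω > 1.2`. Pairs with `Ks = 0` have no defined ω and are carried in a
  separate `undefined` tier rather than silently dropped, so the
  accounting chain input = removed + undefined + retained, and
  PSG ⊆ retained, is checkable at every stage.

# Distribution, enrichment, expression

**Chromosomal distribution.** The 2×C PSG/non-PSG table per chromosome is
tested by Pearson chi-square without continuity correction (df = C−1) and
by a Fisher exact test. For 2×2 tables the exact two-sided hypergeometric
p is used; wider tables use a Monte-Carlo estimate: `B` tables drawn with
the observed margins fixed (Patefield's algorithm via `r2dtable`), and
`p = (1 + #{P(table) ≤ P(observed)}) / (B + 1)`. The plus-one rule means
the smallest attainable p at `B = 2000` is 1/2001 ≈ 5.0e-4; B defaults to
2000 because that resolution suffices for tables whose true p is far
smaller, and the Monte-Carlo path is implemented directly (not via
`fisher.test(simulate.p.value=)`) so that the same code covers 2×2
tables, where its convergence to the exact p is a test.

**Randomization test.** The literature this screen follows cites its
randomization procedure without specifying it, so this package defines
its instantiation precisely: the statistic is the Pearson chi-square of
observed per-chromosome PSG counts against expectation proportional to
per-chromosome gene totals; the null is built from `B` uniform draws of
equally sized gene sets from the universe; the empirical p uses the
plus-one rule (never 0) and per-chromosome two-sided enrichment/depletion
p-values are emitted alongside. Its type-I error is checked by
simulation (200 null replicates, acceptance band 0.02–0.09 at α = 0.05).

**Enrichment.** Hypergeometric upper-tail p per term (depletion behind a
flag), BH step-up across all tested terms. The background defaults to the
Ks-filtered ortholog set — the universe from which the study set was
actually drawn. Raw p and BH q are both emitted because downstream
conventions differ on which to threshold. The six-family contingency
analysis (R genes, protein kinases, transcription factors, flower genes,
auxin genes, glucosinolate genes) reuses the distribution tests and also
reports the transcription-factor share of family-assigned PSGs.

**Expression.** "Expressed" means FPKM at or above a threshold the data
do not dictate; the default is 1.0 FPKM — the conventional reporting
floor for tissue atlases — and every class-dependent output records the
threshold used. Classes follow breadth over the six tissues (root, stem,
leaf, flower, silique, callus): specific = 1, constitutive = 6,
silent = 0, intermediate = 2–5. Exactly these six columns are accepted;
extra columns are rejected rather than ignored, so a mislabeled tissue
surfaces immediately. Group comparisons are Mann–Whitney (two-sided),
Kruskal–Wallis, or one-sided Welch t with caller-specified direction;
rank tests use the standard tie-corrected implementations, verified
against first-principles reimplementations. Post-hoc letters-style
comparisons after a Kruskal–Wallis rejection use Dunn z tests on mean
ranks with BH adjustment — a convention chosen here because the H-test
itself names no post-hoc procedure. WGT-retention stratification reports
the PSG fraction and PSG expression (mean ± SE of per-gene six-tissue
means) per retention class (1, 2, 3 copies), with a Fisher test on the
2×3 counts and KW across classes; empty classes are flagged, not
imputed.

# Methylation

Each gene is partitioned into five regions. Promoter: `promoterLength` bp
(default 2000 — the common plant upstream-regulatory window; no value is
dictated by the data) immediately 5′ of the TSS, strand-aware, truncated
at the chromosome start with a warning. UTR5/UTR3: exonic sequence 5′/3′
of the CDS, strand-aware. Exon: CDS-overlapping exon segments. Intron:
gaps between exons. UTR5 ∪ exon ∪ intron ∪ UTR3 tiles the transcript span
exactly, which makes read-count conservation a sharp invariant: summing
region read totals (promoter excluded) must reproduce the transcript-span
totals to the read.

The methylation level of a region×context cell is **read-weighted**:
Σ methylated reads / Σ total reads over its covered cytosines — the
standard aggregate for WGBS data because it weights evidence by depth; a
per-site mean is a different estimator and deliberately not the default.
Zero-coverage cells are undefined (NA), never 0. Cytosine strand is
ignored in aggregation since contexts arrive annotated per cytosine.
TE-overlap stratification asks whether a gene's *region* (not merely the
gene) shares ≥1 bp with a TE; under BED's half-open input convention an
abutting TE does not overlap, and the tests pin that boundary. The
methylation–expression relation is summarized by Spearman rank
correlation of per-gene read-weighted methylation (chosen context and
region scope) against per-gene mean FPKM.

Internally all intervals live in GenomicRanges objects (1-based closed),
the Bioconductor convention, with GFF3 (1-based inclusive) passing
through unchanged and BED (0-based half-open) converted at the boundary
by rtracklayer. A uniform 0-based half-open internal convention was
considered and rejected: the ecosystem's interval arithmetic,
overlap machinery and tests all speak GRanges, and the one behavioural
consequence that matters — abutting intervals do not overlap — holds
either way and is tested.

# The synthetic-data layer

The generators define the study conditions; they are not tuned per run.

* **Codon pairs** evolve from a uniform sense-codon ancestor, each
  lineage for `t/2`, under a GY94-style Markov process: single-nucleotide
  changes, rate ×κ for transitions, ×ω for nonsynonymous changes, rate 0
  into stop codons; exact stochastic simulation with per-codon
  exponential waiting times (no matrix exponentials needed at desk
  scale). Rates are normalized so `t` is the expected number of
  substitutions per nucleotide site between the two sequences. Defaults:
  κ = 2 (typical plant nuclear bias), ω = 0.2 background with a 2%
  fraction at ω = 2, `t = 0.05` — chosen so synonymous divergence
  (≈ 0.125, since synonymous sites absorb most substitutions at
  ω = 0.2) sits well below the 0.3 saturation filter, the regime of a
  congeneric crop comparison where only a small percentage of pairs is
  discarded.
* **Genome annotation**: genes on 10 chromosomes (round-robin under
  uniform weights so tiny cases are exactly balanced; multinomial under
  explicit weights to plant clustering), 1–3 exons with 150–450 bp CDS
  chunks, 80–400 bp introns, 100–400 bp UTRs, intergenic gaps that
  reserve two promoter lengths so the downstream promoter of a
  minus-strand gene can never collide with its neighbour's upstream
  promoter. TEs drop into gene regions independently at `teRate` per
  region and the planted overlaps are ledgered.
* **Expression**: planted class labels (defaults 20% specific, 30%
  constitutive, 10% silent, remainder intermediate) with expressed
  entries at threshold + log-normal(median `fpkmScale` = 8 FPKM) and
  unexpressed entries below half the threshold, so classification
  recovers labels exactly.
* **Methylation**: cytosines placed along region intervals at
  `siteDensity`, per-site rates Beta-distributed around region×context
  means (defaults follow the plant gene-body pattern: CG high in introns
  and UTRs ≈ 0.30–0.35, low in exons ≈ 0.05; CHG concentrated in introns;
  CHH ≈ 0.005 everywhere), an additive `teEffect` for ledgered
  TE-overlapped regions, Poisson coverage, binomial methylated counts.
  The TE–methylation effect size is a free parameter of the generator,
  not an estimate of any real genome.

What the generators deliberately do **not** emulate: indels and
alignment error (inputs are pre-aligned), recombination, chromosome-scale
sequence (only cytosine positions with context labels are placed),
between-tissue methylation structure, GO-term dependency structure, and
any correlation between expression class and selective regime. Passing
tests therefore demonstrate correctness of the estimators and bookkeeping
under the stated model, not robustness to misalignment or annotation
error in real data.

# Problem sizes and determinism

Validation runs at desk scale, chosen as the smallest sizes at which the
recovery bands are statistically meaningful: ω recovery at 100 replicates
× 500 codons per true ω; κ recovery at 10⁴ codons; permutation
calibration over 200 null replicates of 50 genes in a 1000-gene universe
(B = 199 within each); methylation-rate recovery at >10⁴ intron-CG sites;
planted-enrichment power at 100 simulations of n = 200 against N = 5000.
Every stochastic function takes an explicit seed and derives its streams
from it; the pipeline writes its seeds and thresholds into the report log,
and two runs under one seed are byte-identical — this is itself a test.

# Interface notes and limitations

The package is organized as an R/Bioconductor-style API — S4 container
for ortholog pairs, GRanges-based annotation objects, `runPipeline()` as
the one-call orchestrator reading a YAML or list config — rather than a
shell tool; the exported functions are the stable interface.

Known limitations: counting estimators (no ML codon models, no site or
branch tests — a fixed ω cutoff is a screen, not a hypothesis test per
gene); one mRNA per gene (the first) when a GFF3 offers several; a single
whole-plant cytosine report (per-tissue methylomes can be profiled by
running the methylation stage once per report); and the Ks filter's
gene/pair ambiguity noted above.
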