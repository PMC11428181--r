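---
title: "Methods: specificity scoring, peak association, seed-site scanning and ceRNA ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: specificity scoring, peak association, seed-site scanning and ceRNA ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemlinc)
```

`stemlinc` implements a pipeline for finding lincRNAs expressed specifically
in one condition of an expression atlas (typically embryonic stem cells),
intersecting them with transcription-factor ChIP peaks, and characterizing a
candidate sponge lncRNA's microRNA response elements (MREs) and
competing-endogenous-RNA (ceRNA) partners. This vignette documents the
models, the tunable parameters, the synthetic data the tests run on, and the
design decisions taken where the methodology was genuinely open.

## Coordinates

All genomic coordinates are 0-based half-open on the forward strand,
whatever the input dialect: GTF/GFF (1-based closed) is shifted on read,
BED is native. One consequence worth spelling out: the TSS of a minus-strand
gene is `end - 1`. A single internal convention removes the classic
off-by-one family of bugs; the round-trip and dual-dialect tests pin it.

## Specificity scoring and selection

For gene expression vector $X$ over $m$ samples, the specificity of sample
$i$ is the cosine of $X$ against the ideal one-hot profile:

$$\mathrm{SPM}_i = \frac{x_i}{\lVert X \rVert_2} \in [0, 1],
\qquad \sum_i \mathrm{SPM}_i^2 = 1 .$$

The score is scale-invariant, 1 exactly for a gene expressed in a single
sample, and $1/\sqrt{m}$ for a perfectly uniform gene. The literature
carries both this cosine and its square under the same name; we use the
cosine and note that the downstream 2-means partition is invariant to any
monotone transform of the score (property-tested), so the choice cannot
change which genes are selected.

Selection proceeds in three steps, each with an explicit default:

* **Abundance filter** (`filter_expressed`, `min_fpkm = 1`): genes below
  1 FPKM in every sample are removed. 1 FPKM is the conventional detection
  threshold for this data type and is reused below as the "detected" rule.
* **Clustering** (`cluster_specific`, `k = 2`): k-means on the 1-D
  focal-sample SPM, 10 restarts under a caller-supplied seed. The task is a
  binary specific/non-specific split, so $k = 2$; clustering in one
  dimension keeps the optimum checkable by exhaustive threshold search, and
  the test suite verifies the partition against that oracle. Degenerate
  inputs (fewer distinct values than clusters) raise an error rather than
  returning an arbitrary split.
* **Exclusivity rule** (`select_lincES`, `max_other_tissues = 1`): from the
  high-centroid cluster, keep genes detected in the focal sample and in at
  most one non-focal sample. This operationalizes "exclusively expressed in
  the focal condition, allowing a single other tissue" with the same 1-FPKM
  detection threshold as the filter.

## Peak categorization and association

Peaks are classified by their **summit** — the single base of maximal
binding evidence — rather than by whole-interval overlap, which yields one
unambiguous category per peak. Precedence is promoter > exon > first intron
> other intron > distal intergenic; the exon category is split by host-gene
biotype (coding vs non-coding). The promoter window is TSS ± 1 kb on the
gene's orientation by default (`promoter_up`, `promoter_down`): no single
published convention exists for the category plot, so the window is an
explicit parameter rather than a hidden constant. The first intron is the
5′-most intron *on the gene's strand*, which is the biologically meaningful
reading for a minus-strand gene.

Association (`associate_peak`) follows the ±5 kb TSS rule: for each strand
independently, the gene minimizing |summit − TSS| is associated when that
distance is within the window, giving up to two genes per peak (at most one
per strand). Distances are signed as summit − TSS on the forward axis,
which is what the TSS-distance density plot consumes. Proximity ties are
broken deterministically (lexicographically smaller gene ID) and reported.
Gene-body overlap without a nearby TSS does not associate: the rule is a
TSS-distance rule throughout. `call_lincS` then returns the specific
lincRNAs having at least one associated peak, with their peak counts.

## Strict seed-site scanning

A site is located by its **t1 coordinate** — the target base opposite miRNA
position 1, i.e. the 3′-most base of the site. Anchoring on t1 makes the
8mer/7mer variants at one locus collapse to a single best-class site, so a
22-element ladder counts as 22 sites, not 22 plus embedded sub-matches.
With $S_{2\text{-}8}$ the extended seed (miRNA positions 2–8) and
$S_{2\text{-}7}$ the core seed:

* **8mer-1a** — revcomp($S_{2\text{-}8}$) immediately 5′ of an A at t1;
* **7mer-m8** — revcomp($S_{2\text{-}8}$) with a non-A t1 base (the non-A
  requirement keeps the classes a partition, as hierarchical counting
  conventions do);
* **7mer-1a** — revcomp($S_{2\text{-}7}$) with an A at t1, only when the
  position-8 extension fails.

Matching is strict: no G:U wobble, no 3′-supplementary pairing, DNA input
transcribed T→U on read. A seed match flush with the 3′ end of the sequence
has no t1 base and is not reported. The scanner is verified base-for-base
against an independent brute-force window enumeration on thousands of
random sequence × miRNA pairs.

**Enrichment** uses the Poisson model: with background rate $\lambda$
(sites/kb, from `background_lambda` over a reference transcriptome) and
transcript length $L$ kb, $p = P(X \ge k)$ for $X \sim
\mathrm{Poisson}(\lambda L)$, evaluated through the survival function (log
space internally) so counts far in the tail do not underflow; a zero
background with a nonzero count is refused as degenerate rather than
reported as $p = 0$. Whether the background should be whole transcripts or
3′UTRs only is left to the caller — `background_lambda` accepts either.

**Spacing regularity** computes successive t1 differences, calls the most
frequent difference the modal spacing (ties to the smallest), and counts a
site as regular when the gap to its previous *or* next neighbour equals the
modal spacing exactly. Tolerance is deliberately zero — regularity claims
at single-nucleotide resolution should not be softened silently; an
approximate ladder can be assessed by inspecting the difference vector.

## ceRNA ranking

Candidates are mRNAs sharing at least one MRE family with the sponge, with
transcripts and miRNAs both gated on focal expression (`expressed_subset`,
threshold inclusive). The susceptibility score of mRNA $m$ for sponge $s$ is

$$\mathrm{score}(m) = \sum_{f \in \mathrm{shared}(m, s)}
E(\mathrm{miR}_f)\; n_f(m)\;
\frac{n_f(s)\, E(s)}{\sum_{t} n_f(t)\, E(t)},$$

where $n_f(\cdot)$ are strict site counts from this package's scanner and
the denominator runs over every expressed transcript carrying family-$f$
sites (the family's target pool). The bracketed pool share lies in (0, 1]
and equals 1 when the sponge is the family's only expressed target; the
score is nonnegative, linear in miRNA abundance, and monotone in every site
count. The exact scoring function used in prior ceRNA prediction work is
not recoverable in closed form from the literature we follow; this formula
is **this package's own definition**, chosen to capture the cited principle
— relative expression of the MRE-containing RNAs — with every term
individually testable. It is deliberately small enough to swap out:
`susceptibility_score` is a plain function over a site-count table and an
expression vector. Ranking is a stable descending sort with ID tie-breaks.

## TF enrichment

`tf_promoter_enrichment` compares real peaks against a random-peak null
over the promoters (default: 1 kb upstream of the TSS, protein-coding
genes) of a gene set: $a$ = set promoters hit by ≥ 1 real peak (half-open,
≥ 1 bp), $c$ = hit by the shuffled peaks, $b, d$ the complements, one-sided
Fisher exact $p = P(A \ge a)$ under the hypergeometric null, odds reported
as the sample estimate $ad/bc$ (infinite when $bc = 0$). The null is
length-preserving uniform placement — chromosome chosen proportional to
length, start uniform among fitting positions — with no gap or blacklist
exclusion; that is the simplest reproducible choice, and the calibration
test confirms the resulting $p$ is super-uniform. An alternative 2×2 design
(gene set vs all genes under real peaks) can be assembled from
`overlap_counts` directly. No multiple-TF correction is applied by default;
`stats::p.adjust` composes naturally downstream. Enrichment thresholds for
the odds/significance scatter are mandatory arguments — no default
pretends to be canonical.

## Synthetic data: what it emulates, what it does not

All generators are pure functions of their arguments including the seed.

* `make_atlas` emulates an FPKM atlas: gene baselines
  $\mathrm{lognormal}(\mu_{\log} = 1, \sigma_{\log} = 1)$ (heavy right tail,
  strictly positive, FPKM-like) with multiplicative log-normal noise
  (`noise_sd`, default study condition 0.3). Planted specific genes follow
  an **on/off model**: ON in the focal sample at `fold` × baseline, OFF
  elsewhere at baseline / `fold`², noise applied everywhere. The quadratic
  suppression makes the OFF state fall below the 1-FPKM detection threshold
  once the activation is strong (fold 10 in the study conditions), which is
  what "exclusively expressed" genes look like; and the model collapses
  exactly to the background at fold 1, so a null atlas is literally
  indistinguishable from one with no planting (tested as a bit-identity).
  A plain "multiply the focal sample only" model cannot represent exclusive
  expression at all — with $\sigma_{\log} = 1$ such genes would be detected
  in most tissues regardless of fold.
* `make_genome` places 2–6-exon stranded genes with ≥ 12 kb between bodies,
  so every ±5 kb association has unambiguous truth; biotypes are assigned
  at a configurable lincRNA fraction.
* `make_peaks` derives exact category regions by interval arithmetic under
  the same promoter definition the categorizer uses, rounds the requested
  composition by largest remainder (counts sum exactly), and samples
  summits uniformly within regions — so planted categories are recoverable
  by construction.
* `make_mre_sequence` plants sites of exact classes at exact t1 positions
  on a uniform background, then scrubs accidental matches by resampling
  offending windows (linear in length) until the scan returns exactly the
  planted truth. Planting a 7mer-m8 forces a non-A t1 base; planting a
  7mer-1a forces a mismatching position-8 base, so classes cannot silently
  upgrade.
* `make_cerna_system` draws a conflict-free miRNA family set (no seed can
  shadow another inside a planted footprint), plants all families on the
  sponge and exactly the assigned families on each 3′UTR, and draws
  expressions uniformly in configurable ranges. The planted-truth ranking
  tests use *nested* sharing sets, for which the score ordering is implied
  by the formula for any positive expression draws.
* `lncenc1_like_transcript` is a **synthetic reconstruction**, not a real
  transcript: a 3.3 kb sequence carrying the published sponge MRE
  architecture (22 miR-128-3p sites — 21 7mer-m8, 20 on a 22-nt ladder
  with two trailing irregular sites — and 17 miR-138-5p sites — 12 8mer-1a,
  5 7mer-1a) with the real mature miRNA sequences. It exercises scanner,
  enrichment and spacing code against a fixed, documented truth.

What the generators do **not** emulate: read-level data and mapping noise,
isoform structure and alternative TSSs, correlated tissue blocks in the
atlas, GC/repeat composition of real sequence, peak-width/summit-offset
distributions of a real peak caller, or binding-site conservation. Passing
the synthetic suites therefore demonstrates algorithmic correctness on
known truth — not that real-data preprocessing choices (annotation merging,
FPKM quantification, peak calling, all out of scope here) are reproduced.

## Numerical and degenerate-input choices

* Poisson and hypergeometric tails come from `stats::ppois` /
  `stats::phyper` survival paths; the tests pin them to closed-form partial
  sums and exhaustive enumeration (absolute error < 1e-12; the direct
  $1 - \sum$ form itself cancels below ~1e-16, which is why comparisons are
  absolute).
* k-means restarts make the 1-D clustering deterministic per seed; the
  exhaustive-threshold oracle guards against local optima.
* Empty inputs: empty peak files parse to empty sets with a warning;
  all-zero genes score SPM 0 everywhere; an empty filter result warns; an
  empty candidate list ranks to an empty table. Errors are reserved for
  contract violations (negative FPKM, overlapping plants, degenerate
  background, unknown chromosome).
* Ties anywhere (proximity, score, modal spacing) break deterministically
  and are reported, never silent.

## Problem sizes used by the checks

The bundled verification runs use 2000-gene × 22-sample atlases (5 seeds),
a 60-gene toy genome with 500 planted peaks, a 300-gene genome with 149
planted specific lincRNAs of which 11 receive peaks, 1000 random kilobases
× 5 miRNAs for the scanner oracle, all 2×2 tables with N ≤ 60 plus 1000
null simulations for the Fisher machinery, and 20 seeded ceRNA systems —
sizes at which every planted truth is exactly recoverable and the whole
suite runs in about a minute.

## Known limitations

* Gene-level TSS only: when isoforms with alternative TSSs exist, the
  annotation's gene record decides; isoform-aware association is out of
  scope.
* The ceRNA score is an interpretable expression-weighted heuristic, not a
  kinetic mass-action model; absolute score values have no physical unit
  and only the ranking is meaningful.
* The random-peak null ignores mappability/blacklist structure of real
  genomes; `random_peaks` is a hook point for exclusion-aware placement.
* The scanner is deliberately strict (no wobble, no context scoring); it
  counts canonical MREs, it does not predict repression efficacy.
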