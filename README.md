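# stemlinc

Discovery of transcription-factor-dependent, embryonic-stem-cell-specific
lincRNAs and characterization of their microRNA-sponge behaviour.

`stemlinc` is an R package for the computational arc that leads from an
expression atlas and a set of ChIP-seq peaks to a ranked list of candidate
competing-endogenous-RNA (ceRNA) partners of a sponge lncRNA:

1. **Specificity scoring (`spm_scores`, `select_lincES`)** — for a gene with
   expression vector *X* over samples, the specificity of sample *i* is the
   cosine against the ideal single-condition profile,
   *SPM<sub>i</sub> = x<sub>i</sub> / ‖X‖₂*. Genes are abundance-filtered
   (max FPKM ≥ 1), 2-means-clustered on the focal-sample SPM, and the
   high-centroid cluster is reduced to genes detected in the focal condition
   and at most one other tissue — the focal-condition-specific lincRNA set.
2. **Peak annotation (`categorize_peak`, `associate_peak`, `call_lincS`)** —
   ChIP peaks are classified by summit position (promoter > exon > first
   intron > other intron > distal intergenic) and associated with the nearest
   gene on each strand whose TSS lies within ±5 kb of the summit; specific
   lincRNAs with at least one associated peak are the TF-dependent calls.
3. **Seed-site scanning (`scan_sites`)** — strict canonical miRNA sites
   (8mer-1a, 7mer-m8, 7mer-A1; no wobble) located by their t1 coordinate,
   with Poisson enrichment *P(X ≥ k)*, *X ~ Poisson(λL)* against a
   transcriptome background rate λ (sites/kb), and spacing-regularity
   analysis of the site ladder.
4. **ceRNA ranking (`rank_cerna_partners`)** — every expressed mRNA sharing
   at least one miRNA family with the sponge is scored by
   *Σ<sub>f</sub> E(miR<sub>f</sub>) n<sub>f</sub>(mRNA) ·
   n<sub>f</sub>(lnc)E(lnc) / Σ<sub>t</sub> n<sub>f</sub>(t)E(t)* — the
   sponge's share of each family's expression-weighted target pool — and
   ranked by decreasing score.
5. **TF enrichment (`tf_promoter_enrichment`)** — one-sided Fisher exact test
   of a TF's peaks at gene-set promoters against a length-preserving
   random-peak null.

Every stage runs on synthetic data with planted ground truth
(`make_atlas`, `make_genome`, `make_peaks`, `make_mre_sequence`,
`make_cerna_system`), so the whole pipeline is testable without downloads.
`lncenc1_like_transcript()` provides a clearly-synthetic 3.3 kb
reconstruction of a sponge transcript's published MRE architecture (22
miR-128 sites, 21 of them 7mer-m8, 20 on a regular 22-nt ladder; 17 miR-138
sites, 12 8mer-1a + 5 7mer-1a) using the real mature miR-128-3p /
miR-138-5p sequences bundled under `inst/extdata/`.

## Worked example

```r
library(stemlinc)

# 100 ESC-specific genes planted in a 2000-gene, 22-sample atlas
atlas     <- make_atlas(2000, 22, 100, fold = 10, noise_sd = 0.3, seed = 1)
filtered  <- filter_expressed(atlas$matrix, min_fpkm = 1)
clustered <- cluster_specific(spm_scores(filtered), k = 2, seed = 17)
lincES    <- select_lincES(clustered, filtered)
recover_truth(lincES, atlas$truth)
#> sensitivity   precision
#>           1           1

# strict seed-site scan of the synthetic sponge-transcript reconstruction
lnc  <- lncenc1_like_transcript()
s128 <- scan_sites(lnc$sequence, lnc$mirnas[["mmu-miR-128-3p"]])
count_by_class(s128)
#> 8mer-1a 7mer-m8 7mer-1a
#>       1      21       0
spacing_regularity(s128)
#> $modal_spacing
#> [1] 22
#> $regular_count
#> [1] 20
poisson_enrichment(nrow(s128), 3.3, 0.15)
#> Poisson enrichment: k = 22 over 3.300 kb (lambda = 0.15/kb), P(X >= k) = 1.059e-28
```

The selection recovers all 100 planted specific genes with no false
positives; the scan finds the 22-site miR-128 ladder (21 7mer-m8, 20 at the
modal 22-nt spacing), which at a background rate of 0.15 sites/kb would occur
by chance with probability ~10⁻²⁸.

## Vignette

`vignettes/stemlinc-methods.Rmd` documents the models, the parameter
choices and their defaults, what the synthetic generators do and do not
emulate, and the package's known limitations.
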