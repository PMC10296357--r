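# degronScan

Computational pipeline for pooled **tiled-peptidome protein stability
screens** and composition-based **degron prediction**.

In this assay family, every protein of interest is expressed as a set of
overlapping 17-residue peptides fused to a GFP reporter (with an internal
mCherry control), cells are FACS-sorted into four gates by their
GFP-to-Cherry ratio, and each gate is deep-sequenced. A peptide that acts
as a *degron* — a sequence element sufficient to route the fusion into
ubiquitin–proteasome degradation — depletes GFP and accumulates in the
low-ratio gates. degronScan implements every computational stage of such
a screen, plus a ground-truth simulator that makes the whole pipeline
testable end to end:

1. **Library design** — each coding sequence is split into 51-nt tiles
   stepping 15 nt (17-aa peptides with 12-residue overlaps), flanked by
   vector-complementary primer anchors for oligo-pool synthesis
   (`tileCDS()`, `tileLibrary()`, `addFlanks()`).
2. **Counting** — per-gate reads are trimmed to their 51-nt insert and
   matched against the library allowing a single mismatch (a pigeonhole
   split index; ambiguous reads dropped), then each gate is normalized to
   10^6 reads (`countBins()`, `normalizeBins()`).
3. **PSI scoring** — each peptide's Protein Stability Index is its
   frequency-weighted mean gate number,

   PSI_i = Σ_g g·f_{i,g} / Σ_g f_{i,g},  g ∈ {1..4},

   ranging 1 (unstable, degron-like) to 4 (stable). PSI is projected
   onto protein residues (central-residue or coverage-mean track) and
   smoothed with a ±2-residue running median (`psiTable()`,
   `residueProfiles()`).
4. **Degron model** — peptides with ≥50 combined reads are labeled
   unstable (PSI < 2.2) or stable (PSI > 2.8; mid-range omitted) and a
   logistic regression on amino-acid composition with ridge penalty
   λ = 0.001 (intercept unpenalized, deterministic Newton optimizer) maps
   any 17-mer to a degron probability. Scanning a protein gives one
   probability per residue (positions 9..L−8); maximal runs above a 0.85
   cutoff are called as degrons (`trainDegronModel()`, `scanProtein()`,
   `callDegrons()`).
5. **Structure features** — Kyte–Doolittle hydropathy vs degron
   probability, a torsion/curvature secondary-structure classifier,
   Shrake–Rupley accessible surface area and a Mann–Whitney U comparison
   of degron-residue ASA against the proteome (`kdScore()`,
   `assignSecondaryStructure()`, `shrakeRupleyASA()`,
   `degronStructureReport()`).
6. **Simulator** — random proteomes, latent degron strengths from a known
   amino-acid weight vector, Gaussian-gated multinomial reads per FACS
   bin and error-bearing raw reads, so parameter recovery is measurable
   (`simConfig()`, `generateProteome()`, `simulateBins()`,
   `emitReads()`).

## Worked example

A complete synthetic screen (20 proteins, 10^5 reads per gate, default
ground-truth weights), run through sequencing-read emission, counting,
PSI, training and proteome scanning:

```r
library(degronScan)
cfg <- pipelineConfig(sim = simConfig(nProteins = 20L,
                                      readsPerBin = 1e5, seed = 7L))
res <- runPipeline(cfg, "demo")
res$model
#> DegronModel (ridge logistic regression on amino-acid composition)
#>   lambda: 0.001  features: counts
#>   intercept: -2.402
#>   top destabilizing: L=2.670 I=2.426 F=2.375
#>   top stabilizing:   D=-3.191 E=-2.791 K=-2.123
#>   trained on 214 degron / 402 stable peptides; grad norm 2.06e-12
cor(weights(res$model), cfg$sim$trueWeights)
#> [1] 0.999
attr(res$hydropathy, "spearman")
#> [1] 0.842
head(res$scan$calls, 3)
#>   protein_id start end length peak_probability cutoff
#> 1    sim0001    27  35      9        0.9998955   0.85
#> 2    sim0001    67  84     18        0.9999997   0.85
#> 3    sim0001   109 119     11        0.9996278   0.85
```

The fitted residue weights recover the simulator's ground truth almost
perfectly (Pearson r = 0.999, sign and rank structure intact: leucine and
isoleucine most destabilizing, aspartate and glutamate most stabilizing),
and predicted degron probability correlates positively with peptide
hydrophobicity (Spearman ρ = 0.84) — the hallmark of quality-control
degrons. Each call is a maximal run of residues whose centered 17-mer
scores above the 0.85 probability cutoff.

All stage outputs (tile manifest, count table, PSI table, residue
tracks, model JSON, scan and BED-like degron calls) are written under
the run directory together with a `manifest.json` of parameters and
checksums; reruns with the same seed are bit-identical, and
`resume = TRUE` regenerates only stages downstream of a missing output.

A thin command-line wrapper over the same functions is included at
`inst/cli/degronscan.R`
(`Rscript degronscan.R <design|simulate|count|psi|train|predict|features|run> ...`).

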