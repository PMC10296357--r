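---
title: "Models and methods behind degronScan"
author: "degronScan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind degronScan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degronScan)
```

# The assay and its quantitative readout

degronScan analyses pooled stability screens in which a library of
17-residue peptides, tiled across proteins of interest, is fused to a
GFP reporter co-expressed with an mCherry control. Cells are sorted into
four FACS gates ordered by GFP-to-Cherry ratio and each gate's plasmid
inserts are deep-sequenced. A destabilizing peptide (a degron) shifts
its carrier cells into the low-ratio gates; the per-peptide read
distribution across gates is therefore a quantitative stability readout.

The index extracted from that distribution is the **Protein Stability
Index**,

$$\mathrm{PSI}_i \;=\; \frac{\sum_{g=1}^{4} g\, f_{i,g}}{\sum_{g=1}^{4} f_{i,g}},$$

the frequency-weighted mean gate number, bounded in $[1, 4]$ with low
values indicating degron activity. $f_{i,g}$ are the per-gate
frequencies **after** each gate's total has been scaled to $10^6$
reads; normalizing first makes the four gates count equally even when
their sequencing depths differ, which is not equivalent to computing PSI
on raw counts (both behaviors are tested; the normalized form is the
package's definition). Rows whose raw counts are zero in every gate
carry no information and are omitted rather than scored.

# Library design

Coding sequences are tiled into 51-nt fragments every 15 nt, i.e.
17-residue peptides overlapping by 12 residues, after removal of the
terminal stop codon (the peptides are N-terminal fusions to the
reporter; a retained stop would truncate it). When the CDS length minus
51 is not a multiple of 15 the default tiling leaves the last few
residues uncovered; `anchorFinal = TRUE` adds one 3'-anchored remainder
tile, flagged `anchored_final`, so the protein's C terminus is covered.
Dropping the remainder is the default because C-terminal coverage is
rarely the focus of tiled screens and an anchored tile breaks the
regular 5-residue phase; both behaviors are exercised by tests.
Coordinates are 0-based half-open internally; user-facing residue
positions are 1-based. Proteins containing non-standard residues (U, X)
or internal stops are rejected with explicit errors rather than silently
skipped, and proteins shorter than one tile raise `"protein too short"`
unless `skipShort = TRUE`.

# The synthetic screen

The simulator exists so that every downstream stage can be validated
against known ground truth. It emulates, in order: a random proteome
(uniform residues; CDS drawn uniformly over synonymous codons), the
latent degron strength of every tile, FACS sorting, and sequencing.

**Latent model.** Each peptide's true degron probability is
$p = \mathrm{logistic}(b + \sum_a w_a n_a)$ with $n_a$ the residue
counts, and its latent stability index is the linear map
$\mathrm{PSI}_\mathrm{true} = 4 - 3p$. Any monotone decreasing map would
do; the linear one is the simplest testable choice.

**Sorting.** Each of the `cellsPerPeptide` cells carrying a peptide
draws a Gaussian jitter around $\mathrm{PSI}_\mathrm{true}$ (sd `sigma`,
default 0.5) and falls into the gate delimited by `binBoundaries`
(default 1.75, 2.5, 3.25 — symmetric quarters of the PSI range). Real
FACS gates are drawn by hand on fluorescence space; a Gaussian around
the latent index is the simplest model that reproduces the averaging
behavior PSI assumes. Per gate, reads are a single multinomial draw of
size `readsPerBin` with probabilities proportional to gate cell counts,
so raw per-gate totals are conserved exactly.

**Defaults.** The ground-truth weights (`defaultTrueWeights()`) make
hydrophobic residues destabilizing (L 0.50 … C 0.25) and charged
residues stabilizing (D −0.50 … R −0.25), with small values elsewhere,
mirroring the hydrophobicity preference of quality-control degrons so
that the hydropathy-trend analysis has a real signal to find. The
intercept −1.5 puts random 17-mers at a mean degron probability near
0.35 with a spread covering (0.05, 0.9), i.e. screens contain both
classes in realistic proportion. The per-base substitution rate of
emitted reads defaults to 0.001; with it, the fraction of reads within
one mismatch of their source insert follows the binomial
$P(\le 1\ \text{error in } 51) $ closed form, which the tests assert.
Default `cellsPerPeptide` is 200: enough cells that multinomial cell
noise does not dominate, few enough that it is visible, as in real
sorts.

**What the simulator does not model:** PCR amplification bias, FACS
spectral spillover and doublets, plasmid copy-number variation, indels
in reads, and position-specific degron grammar (the ground truth is
composition-only — by construction the thing the predictor can recover
perfectly). Passing recovery tests therefore demonstrates correctness
of the pipeline's inference, not that real degrons are fully described
by composition.

# Counting and the single-mismatch matcher

Reads are trimmed to their candidate 51-nt insert either by a fixed
prefix length or by locating an exact occurrence of the configured
vector anchor; failures (anchor absent, read too short) mark the read
unmatched rather than raising. Matching allows at most one substitution
— indels are deliberately out of scope because substitution errors
dominate short-read platforms, and reads with indels simply fall to
unmatched.

The lookup uses the pigeonhole principle: any 51-mer within Hamming
distance 1 of a library member agrees exactly with one of the member's
two halves, so two half-string hash maps retrieve all candidates in
expected constant time without enumerating the 153 point mutants of
every query. A quadratic brute-force scanner with the same contract is
kept in the package as the independent oracle the matcher is tested
against.

Ambiguity policy: a query with two or more members within distance 1 is
discarded (`"drop"`, default), mirroring unique-alignment filtering;
`"keep-best"` lets an exact hit beat distance-1 neighbors. Identical
inserts from different proteins are collapsed for matching and their
counts replicated into each member row (flagged `shared`), preserving
per-protein profiles. Per-gate unique/ambiguous/unmatched totals are
conserved and reported in `metadata()`. Normalization scales each
non-empty gate to exactly $10^6$; empty gates stay zero with a warning,
and only an entirely empty table is an error.

# Residue projection and smoothing

Two residue tracks are supported. The *central-residue* track places
each tile's PSI at position 9 of its 17-mer; the *coverage-mean* track
(default) assigns each residue the mean over all scored tiles containing
it — with step 5 and length 17 an interior residue is covered by 3 or 4
tiles, fewer where tiles were filtered out. Uncovered residues carry an
explicit `NA`, never zero. Smoothing is a 5-residue (±2) running median;
the window is truncated at protein ends rather than padded (padding
would invent boundary values), missing neighbors are skipped, and
missing positions stay missing. The smoother is validated against a
naive sort-based median at every position.

# The degron model

**Labels.** Peptides with fewer than 50 combined raw reads are removed;
PSI < 2.2 labels unstable (1), PSI > 2.8 stable (0), and the mid-range
is omitted to keep label noise out of training. Values exactly equal to
2.2 or 2.8 are excluded too — the verbal rules ("smaller than", "greater
than", mid-range strictly between) leave the endpoints unclaimed by
either class, so the package excludes them and counts them in an
attribute.

**Features.** Amino-acid composition of the 17-mer, as counts (default)
or frequencies. Composition is the established encoding for this
predictor family; it makes predictions invariant to residue order,
which the tests assert end to end. The ridge strength's meaning depends
on the feature scale, so `featureMode` and `lambda` travel together in
the serialized model.

**Objective and optimizer.** Mean logistic loss plus
$\tfrac{\lambda}{2}\lVert w\rVert^2$ with the intercept unpenalized and
$\lambda = 0.001$ by default. Mean (not sum) loss is stated explicitly
because it fixes $\lambda$'s scale. The optimizer is a full Newton
iteration with step-halving, run to a $10^{-10}$ max-norm gradient —
deterministic, order-invariant, and finite even on separable data
(the ridge term bounds the optimum). The returned optimum is verified in
tests by an independent finite-difference gradient check, and the whole
fit is cross-checked against an independent ridge implementation
(glmnet, $\alpha = 0$) on the same objective.

**Scanning and calling.** Residue $i$ of a protein receives the model
probability of the 17-mer centered on it, defined for
$i \in [9, L-8]$; the eight terminal residues per end are undefined by
construction. Degrons are maximal runs of consecutive defined residues
with probability strictly above the cutoff (default 0.85), optionally
filtered by a minimum length. A cubic smoothing spline over the defined
positions is available for display but off by default — the discrete
track is the canonical output, since any continuous fit is a
presentation choice.

# Structure features

**Hydropathy** is the mean Kyte–Doolittle value over the peptide. The
package reports Spearman correlation between hydropathy and predicted
degron probability; a constant-probability model is flagged degenerate
instead of producing a meaningless coefficient.

**Secondary structure** uses a documented torsion/curvature classifier
rather than a hydrogen-bond (DSSP-style) assignment: helix for
$\varphi \in (-100°, -30°)$, $\psi \in (-80°, -5°)$ in runs of ≥ 4;
sheet for $\varphi \in (-180°, -40°)$ with extended $\psi$ in runs of
≥ 3; remaining residues where the CA-trace direction turns by ≥ 70° over
five residues are `turn` when the span is compact (< 7 Å) and `bend`
otherwise; everything else, including termini without torsions, is
`other`. This keeps the analysis runnable and testable on generated
coordinates (the package includes an internal-coordinate backbone
builder whose torsions round-trip to $10^{-6}$ degrees); externally
computed annotations (e.g. DSSP output) can be supplied as a TSV and
used interchangeably.

**ASA** is Shrake–Rupley: per atom, 960 test points on a fixed
golden-spiral lattice at radius $r + 1.4$ Å are tested against neighbor
spheres; the unoccluded fraction times the sphere area is the atom's
ASA, summed per residue. The lattice lives in the molecule's centered
frame, so results are deterministic and exactly translation-invariant;
exact rotational invariance is deliberately sacrificed for determinism
(the lattice does not rotate with the molecule), with errors bounded by
the lattice resolution. Van der Waals radii default to C 1.70, N 1.55,
O 1.52, S 1.80 Å, overridable. Relative exposure divides residue ASA by
the Tien et al. (2013) theoretical maxima and clips to $[0, 1]$; no
exposed/buried threshold is claimed — it is left to the user.

**Degron report.** Degron residues (probability > cutoff) are compared
to the whole annotated set: secondary-structure class proportions for
both populations (each summing to 1) and a two-sided Mann–Whitney U test
on residue-level ASA — `stats::wilcox.test`, i.e. the normal
approximation with tie correction, exact for small samples. Residue
level (rather than degron-averaged ASA) is used because it is the finer
comparison; this choice is recorded here because the alternative is
defensible.

# Numerical choices and degenerate inputs

* PSI of an all-zero frequency vector is an error, not 0 or NaN.
* Normalization with every gate empty is an error; single empty gates
  warn and stay zero.
* Training with an empty class after filtering raises a diagnostic
  error with the class counts.
* Newton non-convergence raises an error carrying the final gradient
  norm rather than returning a silent partial fit.
* All randomness flows from explicit seeds in the config objects;
  rerunning a pipeline with the same seed is bit-identical on disk.

# Problem sizes used by the test suite

The suite validates geometry and algebra at full specification scale
(100 random CDS lengths for the tiler, $10^5$ frequency vectors for PSI
bounds, $10^4$ queries against a 500-member library for the matcher)
and inference at screen scale: the parameter-recovery run simulates a
~220-protein / ~8,000-tile library at $5 \times 10^5$ reads per gate
through read emission, matching, PSI and training, recovering the
ground-truth weights with Pearson $r > 0.9$ (observed ≈ 0.999). The
PSI-recovery property is asserted on a 10×-spaced read-depth grid in
the read-limited regime (many cells per peptide); at high depth the
error approaches a floor set by finite cell sampling and gating bias,
which read depth cannot remove — a real feature of sort-seq designs,
not an artifact.

# Known limitations

* Composition features ignore residue order; motif- or
  position-dependent degrons are outside the model class, as for any
  composition-based predictor.
* The matcher is Hamming-only; indel-bearing reads are unmatched.
* The secondary-structure classifier is geometric, not H-bond based;
  for publication-grade structure statistics supply DSSP annotations.
* The simulator's noise model (Gaussian gate jitter, multinomial reads)
  omits PCR and sorting artifacts; recovery results bound pipeline
  correctness, not real-screen accuracy.
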