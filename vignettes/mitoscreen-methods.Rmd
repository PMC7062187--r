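---
title: "Statistical methods behind mitoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind mitoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mitoscreen` turns per-well summary tables from 96-well parkin-recruitment
screens into ranked hit lists, and quantifies single-cell puncta dynamics
from two-channel time-lapse stacks. This vignette explains the models, the
parameters that matter, the synthetic data the tests rely on, and the
design decisions taken where the methodology was genuinely open.

## The data model

A screen is plates × replicates of 96-well records. Each well carries a
role (`sample`, `negative_control`, `positive_control`, `empty`), an
optional gene/siRNA identity, and a registered vector of numeric readouts
(84 by default). Non-targeting controls (NTC) define the no-effect
distribution; siPINK1 wells define the strong-effect pole because parkin
recruitment is PINK1-dependent: on a good plate the positive controls sit
far *below* the negatives on every recruitment readout. Two built-in
layouts reflect the two screen stages: `"primary"` with edge-column
controls and `"secondary"` with controls scattered to average out
positional effects. Missing readouts are legal (`NA` in the CSV) and
propagate through all medians and MADs by pairwise deletion, because real
imager exports contain sporadic failed fields.

## Robust primitives

All effect statistics are built from medians and the scaled MAD,
`1.4826 · median(|x − median(x)|)`; the constant (the reciprocal of the
standard-normal upper quartile) makes the MAD estimate the S.D. under
normality, which is what lets MADs and S.D.s share denominators. The
plate-quality score contrasts control medians over the root-sum-square of
their MADs; the per-gene score contrasts a well's replicate median against
the plate's negative controls over
`sqrt(½ s²_well + ½ s₀²)`, where `s₀²` — the median squared
across-replicate S.D. over all wells — regularises a spread estimated from
as few as 3 replicates. S.D.s use the n−1 denominator, matching the
convention the MAD constant targets. Two degenerate cases are defined
explicitly: identical constant inputs give 0/0, which we define as 0 with a
warning; zero spread with differing medians gives a signed-infinity
sentinel. Both arise in synthetic edge cases, not in real data.

## Artifact correction

Dispensing order and edge evaporation produce roughly linear gradients
across a plate. Per plate replicate and per readout we fit
`value ~ intercept + row_slope·row + col_slope·col` by Huber M-estimation
(`MASS::rlm`, 95 %-efficiency tuning, up to 100 IRLS iterations) so that a
handful of genuine phenotypic outliers cannot masquerade as a tilt, and
subtract the *centred* positional part
`row_slope·(row − mean(row)) + col_slope·(col − mean(col))`. Centring is a
deliberate choice: it removes exactly the tilt while leaving the plate
median where it was, so correction and QC commute to good approximation.
Controls are included in the fit — the artifact is positional, not
biological. All 84 readouts are corrected by default (the PLS workflow
consumes all of them); the parameter list is an argument for narrower use.
Rank-deficient designs (all wells in one row) and plates with fewer than 6
finite wells are errors, not silent passes.

## Quality control

`qc_screen()` computes the plate score per plate replicate and removes
those with `SSMD_QC > −2`, the cut-off appropriate for very strong positive
controls. Gating is per plate *replicate* — the conservative reading when
replicates disagree — and the report always lists every plate replicate so
that filtered + failed reconstructs the input. The univariate and PCA
workflows gate on the lead readout (`pct_cells_gt3_puncta`); the PLS
workflow routes its first-model well scores through the same function.

## Hit-selection workflows

**Univariate.** Per-gene SSMDs on the three canonical translocation
readouts (fraction of cells with more than three puncta, puncta area per
cell, puncta intensity per cell), one hit list per readout at strict
|SSMD| > 3. Where a single hit set is needed (recovery metrics, reports)
we take the union of the three lists; with three correlated readouts the
union raises sensitivity while the measured null rate stays well under 1 %.

**PCA.** The three SSMD columns are combined by a one-component SVD
`X = HW' + E`; each entry of `H` (first left singular vector × first
singular value) is the consensus score. The matrix is deliberately *not*
centred or column-scaled: SSMDs already share a dimensionless scale, and
an all-zero gene must map to score 0 for the ±3 semantics to carry over.
The SVD sign ambiguity is fixed by forcing a positive loading on the lead
readout, so suppressed recruitment is always a negative score; without an
anchor, positive and negative modulators would be interchangeable between
runs. Genes with missing SSMDs are dropped and reported, never imputed.

**PLS.** The parameter-agnostic route. Control wells (coded −1 = NTC,
+1 = siPINK1) supervise: (1) Welch t tests per readout with
Benjamini–Hochberg adjustment select features at FDR 0.05 (BH is our
choice; the procedure family was open); (2) Hotelling's T² in the
principal-component subspace holding ≥ 90 % of control variance (capped at
n − 2 components, since 84 readouts exceed typical control counts and the
raw covariance is singular) excludes outlier controls at 99 % confidence;
(3) a NIPALS PLS1 model is fitted with the component count chosen by
stratified 10-fold cross-validation minimising squared label-prediction
error — folds derive from an explicit seed, making the whole fit
bit-reproducible; (4) every well is projected onto the model and the
component-1 score becomes its scalar readout; (5) those scores pass the QC
gate; (6) the model is refitted (same features, fresh outlier removal) on
surviving plates; (7) per-gene SSMDs on the final scores are thresholded
at ±3 (primary) or ±1.3 (secondary).

One convention needed resolving: with the −1/+1 label coding, positive
controls score *high*, which would flip the sign of the plate QC score and
fail every good plate against the −2 rule. We therefore orient the
reported score to recruitment polarity — negative controls high — after
fitting. Any affine recoding of the labels only rescales the final SSMDs,
which are scale-invariant, so nothing but the sign convention is at stake.

## Weighted score and concordance

Measures from different studies and methods are not on one scale, so each
vector is normalized by its own absolute maximum and the per-gene weighted
score is the arithmetic mean of the available normalized measures: genes
behaving oppositely across studies shrink toward zero by construction.
Genes absent from a study are averaged over what they have. The portable
selection rule is the *fraction* (top and bottom 10 %, `ceiling(f·n)` per
tail), not any fixed numeric cut-off, which is data-determined; boundary
ties break deterministically by |score|, then gene id. For non-pooled
secondary screens, concordance per gene counts siRNAs with |SSMD| > 1.3
whose sign matches the primary-screen direction (0–3).

## Expression gate

Pooled log intensities of control samples are bimodal: non-expressed and
expressed genes. `fit_mixture()` fits a two-component unequal-variance
Gaussian mixture by EM (via mclust's deterministic model-based
initialisation) and orders components so component 1 is the lower,
non-expressed one. A fit is degenerate — and gating refuses to proceed —
when a single Gaussian explains the data at least as well by BIC, when a
weight falls below 0.05, or when the means are closer than half the larger
S.D.; this is the honest answer for unimodal input.

`call_expressed()` samples 10,000 points from component 1 and tests each
gene one-sidedly against them, with BH correction and an adjusted-p cut of
0.05. The test statistic deserves a note. A plain two-sample Welch t test
between a gene's ~11 sample values and the 10,000 draws has a standard
error of order `s_g/√11`, so it answers "is this gene's mean above the
component mean?" — and brands a third of the non-expressed component
expressed, because non-expressed gene means legitimately spread around the
component centre. The hypothesis actually at stake is *membership*:
"was this gene's expression level generated from the non-expressed
distribution?" The default statistic therefore keeps the null variance
un-divided, as the variance of a single draw from that distribution:
`t = (x̄_g − x̄₀) / sqrt(s₀²(1 + 1/n₀) + s_g²/n_g)` with
Welch–Satterthwaite degrees of freedom. On labelled synthetic data this
test is both calibrated and accurate (≈ 0.99 against generator labels vs
≈ 0.88 for the plain Welch form, which remains available as
`variant = "welch"`). The alternative is one-sided "greater" because
"expressed" is by definition the higher component; a two-sided test would
call strongly below-null genes expressed.

## Enrichment

`hypergeom_enrichment()` is the exact upper tail
`P(X ≥ k)` for `X ~ Hypergeometric(N, K, n)` via `phyper`, with fold
enrichment `(k/n)/(K/N)`. The universe is the caller's choice and is
recorded in the result; all genes surviving screen QC is the natural
default. Reference genes outside the universe are dropped and counted.
The test suite checks the tail against brute-force enumeration of all
C(20,5) draws.

## Time-lapse puncta quantification

Nuclei are thresholded (Otsu by default) and summarized by fitted-ellipse
moments; the "diameter" used everywhere downstream is the major-axis
length — the generous reading of an ellipse's diameter, chosen so that the
attribution gate errs toward keeping puncta. Frames whose intensity range
is within ten robust S.D.s of the background are declared blank rather
than segmented into noise.

Puncta detection is the extended-maxima transform: greyscale
reconstruction of `frame − h` under `frame` (geodesic dilation to
stability, implemented as repeated directional raster sweeps), whose
residue is `h` on plateaus standing at least `h` proud of their
surroundings. Two practical refinements make the textbook operator robust
on noisy images: candidate regions are the connected pixels with residue
≥ `h/2` (the literal regional-maxima-of-h-maxima definition returns
single pixels once noise breaks a plateau), and a region's peak must also
rise `h` above the frame median, which discards the degenerate whole-frame
plateau of a blank or saturated frame. The area gate is strict on both
sides: `5 < area < 2000` pixels, so a region of exactly 5 px is rejected.
`h` defaults to 0.3 on unit-amplitude spots; detection is invariant to
uniform intensity rescaling when `h` is rescaled with it.

A punctum is attributed to a nucleus iff its centroid lies within that
nucleus's diameter (inclusive); among eligible nuclei the nearest wins;
orphans are reported, never reassigned. Tracking is greedy
nearest-neighbour with a per-frame displacement gate (default: the median
first-frame nucleus diameter); a track that misses a detection terminates
flagged rather than bridging the gap. Each complete track is labelled by
the window — 0–2 h (t ≤ 120 min), 2–4 h (120 < t ≤ 240), 4–6 h
(t > 240) — containing its maximum count; argmax ties take the earliest
frame, so a plateau straddling a boundary belongs to the earlier window.
The fold change reported is peak count over `max(1, first-frame count)`.

## The synthetic generators

`simulate_screen()` draws every readout as
`10 + slope terms + √ρ·Z_block + √(1−ρ)·ε` with per-well latent block
factors (ρ = 0.6, block size 7): real morphology panels come in highly
correlated families, and a shared latent factor per block reproduces that
with one knob. Blocks are assigned round-robin, which places the three
lead readouts in distinct blocks — they measure distinct facets (count,
area, intensity), and under the null this keeps their SSMD noise nearly
independent so the PCA consensus score does not inflate beyond its ±3
SSMD semantics. The first 65 of 84 parameters are "informative": positive
controls drop by 6 noise-S.D. units on them (a very strong control), and
planted modulators shift them by ±4 units (knocking down a positive
modulator suppresses recruitment, so its recorded direction is −1).
Degraded plates shrink the control separation to 20 %, landing them
safely on the failing side of the −2 QC rule. Genes are assigned to
sample wells by a seeded permutation — an arbitrarily plated library —
which matters: contiguous placement would let a block of planted effects
impersonate a positional gradient. Gradients add `row_slope·row +
col_slope·col` to every readout. Everything is bit-reproducible from one
seed.

`simulate_expression()` draws per-gene means from
`(1−f)·N(μ_off, σ_off²) + f·N(μ_on, σ_on²)` and adds per-sample noise
(default S.D. 1, comparable to the component spread — the emulated 11
samples come from heterogeneous platforms and labs). `simulate_timelapse()`
renders elliptical nuclei (semi-axes 11–14 × 8–10 px) on a jittered grid
with a gentle random walk, and unit-amplitude disk puncta (area 8–16 px)
whose per-cell counts follow a strict triangular profile peaking inside
the assigned window; window assignment uses largest-remainder
apportionment, so generated fractions are exact. What the generators do
*not* emulate: optical blur and photobleaching, cell division and
apoptosis, mitotic drift in morphology panels, batch effects across
plates, and probe-level microarray structure. Passing tests therefore
demonstrate that the statistical machinery recovers what it is designed to
recover under its stated noise model — not that segmentation would survive
arbitrary real-world imagery.

## Numerical choices and problem sizes

Greyscale reconstruction iterates directional sweeps to a 1e−9 supremum
tolerance (cap 400 sweeps); the detection mask typically stabilises within
the first 20. NIPALS deflation stops if a weight or score norm falls below
1e−12; EM convergence and initialisation follow mclust's defaults;
Hotelling limits use the exact `k(n−1)/(n−k)·F` form. CSVs are written
with shortest round-trip doubles and parsed with base R's exact float
parser, so `read_screen(write_screen(d))` is bit-identical.

The shipped tests and the acceptance script run: null calibration on a
25-plate × 3-replicate screen (2,000 genes); planted-hit recovery on 13
plates with 100 modulators at 4 S.D. (10 % prevalence); feature-selection
calibration over 20 seeds of 80 × 84 control matrices; mixture recovery at
n = 2,000; and tracking on 20-cell, 25-frame stacks. These sizes were
chosen as the smallest at which the binomial noise of the measured rates
is comfortably below the margins being checked.

## Known limitations

The artifact model is linear by design — bowl-shaped edge effects need a
spatial smoother that is out of scope here. Per-replicate QC can drop a
single replicate of an otherwise good plate, leaving genes with two
replicates (still enough for the SSMD, which requires ≥ 2). The PLS
workflow can only see effects expressed in control-separating readouts;
a modulator acting solely on parameters the controls do not separate is
invisible to it (this is a property of the design, demonstrated by a
dedicated negative-control test, not a bug). Greedy nearest-neighbour
tracking is adequate for the sparse, slowly drifting cells it is specified
for; dense or fast-moving fields would need assignment-based tracking.
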