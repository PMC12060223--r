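---
title: "Estimating upper-limb motor function from task-EEG networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating upper-limb motor function from task-EEG networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokeNet)
```

`strokeNet` estimates upper-limb Fugl-Meyer (UL-FMA) scores of chronic
stroke patients from EEG recorded during a grasp task. This vignette is the
package's account of the science: the model at each stage, the assumptions
behind it, the parameters that matter, the choices we made where the design
was genuinely open, and the limits of what the synthetic validation can show.

## Pipeline and assumptions

The fixed stage order is: band-pass filter and resample → epoch around the
task cue → (optional artifact hook) → common average reference → hemispheric
flipping → window extraction → connectivity → graphs → statistics →
regression. A configuration fingerprint (`pipelineConfig()`) records every
parameter so a run is reproducible from (config, seed, inputs).

**Preprocessing.** Recordings are band-passed 1–80 Hz and resampled to
256 Hz. The original acquisition documentation names only the band and the
target rate, so the filter family is our choice and is config-visible: we
resample first (FIR anti-alias at 80% of the target Nyquist, exact
subsampling for integer ratios, cubic spline otherwise), then apply a
2nd-order Butterworth high-pass at the low edge and a 64-tap windowed-sinc
FIR low-pass at the high edge, both forward–backward. Zero-phase filtering
matters because the epoch timing anchors every later window: a causal filter
would delay the cue relative to the data. Epochs span −2…+5 s around the
cue; trials whose epoch would cross a recording edge are dropped with a
warning rather than padded (padding would fabricate data inside analysis
windows). All windows are half-open `[start, end)`.

**Hemispheric flipping.** To pool subjects whose affected hand differs, the
channel data of left-hand performers are swapped with their left/right
homologs (C3↔C4, FC1↔FC2, …; midline channels are fixed points), so the left
hemisphere is always contralateral to the performing hand. The homolog map
is derived from the 10-10 label grammar (odd↔even digit) and shipped as a
data file for the 64-channel montage; an unmapped lateral channel is an
error, not a silent pass-through.

**Analysis windows.** Pre-task baseline [−1, 0) s and post-task
[0.25, 1.25) s. The 250 ms offset accounts for movement-preparation latency
and stimulus-response components after the cue; both windows are exactly 1 s
so spectral estimates have identical resolution (1 Hz).

## Connectivity: imaginary coherency

Sensor-level EEG mixes every cortical source into every channel
instantaneously (volume conduction), which inflates any connectivity measure
sensitive to zero-lag correlation. We therefore use the imaginary part of
coherency. Per window, each trial's Hann-tapered spectrum X_i(f) (single
1-s segment — the estimator averages over trials, not sub-segments) yields

- cross-spectrum: S_ij(f) = (1/N) Σ_trials X_i(f) X_j*(f),
- coherency: C_ij(f) = S_ij(f) / √(S_ii(f) S_jj(f)),
- band iCOH: the arithmetic mean of ℑ{C_ij(f)} over the bins inside the
  band (alpha 8–13 Hz, beta 13–30 Hz by the usual sensorimotor conventions;
  both overridable since no canonical printed ranges exist).

Instantaneous mixing contributes only real structure to C, so iCOH of a
zero-lag common source is zero in expectation; a coupling with phase lag φ
produces iCOH ∝ |C| sin φ. Descriptions of this estimator do not always
state the auto-spectral normalization explicitly, so the standard (Nolte)
normalization above is used and recorded in the `CoherenceStack` metadata. Note the sign convention: iCOH is antisymmetric
in the channel pair, and with R's forward FFT (e^{−iωt}) a channel *lagging*
the reference by 90° gives a positive imaginary part; only |iCOH| is used
for edge ranking, so downstream results do not depend on this convention.

## Graphs and metrics

iCOH matrices are proportionally thresholded: the top fraction k of channel
pairs ranked by |iCOH| become the edges of a binary graph (exactly
`round(k · n(n−1)/2)` edges; ties broken toward the lower channel-index pair
so runs are reproducible). Binary graphs are the only internally consistent
reading of the metric set: degree centrality DC_i = Σ_j a_ij, clustering
C_i = 2t_i/(k_i(k_i−1)) (0 when k_i < 2), nodal/global efficiency
E_i = Σ_{j≠i} d_ij⁻¹/(n−1), E_glob = mean(E_i), and local efficiency — the
efficiency of the subgraph restricted to a node's neighbors, with the cube
root of the written weighted form acting on the connection-weight product
only, so the binary case reduces exactly to the neighbor-subgraph
efficiency (the K₄-minus-an-edge hub node scores 5/6). Unreachable pairs
contribute 0 to efficiency sums, which makes the edgeless graph 0 and the
complete graph 1. Distances come from per-node breadth-first search; the
test suite proves equivalence against Floyd–Warshall and direct-from-formula
oracles exhaustively on every graph with ≤ 6 nodes.

Thresholding is applied per subject and window (whether to pool edges across
subjects was open; per-subject is the choice that keeps subjects
exchangeable under the null, and it is exposed in the config).

## Task-related statistics

Task-related activity is (post − pre)/pre × 100 for any metric; it is
scale-invariant, and a zero pre-task value is a hard error rather than a
silent drop, because a subject excluded invisibly would bias group
contrasts. ERD is the same contrast on band power from Hann-windowed
short-time spectra (0.5 s frames, 50% overlap — frame length trades 2 Hz
resolution against having ≥ 3 frames per window).

Group contrasts use the two-sided Wilcoxon rank-sum test (exact enumeration
when both groups have ≤ 10 subjects and no ties, normal approximation with
tie correction otherwise — both modes are exposed since the original
analysis does not state which was used). Spearman correlation relates
features to UL-FMA. ANCOVA (`post ~ group + pre`, Type II sums of squares —
the type was unstated, and Type II is the standard choice when the group
effect is tested after the covariate) controls task contrasts for pre-task
baseline differences.

**Threshold scan.** For each fraction from 1% to 90% in 1% steps (the range
is prescribed, the step is ours), each subject's task-related global
efficiency is computed and the groups compared by rank-sum; the selected
threshold is the significant (p < 0.05) fraction with the smallest p, with
no multiple-testing correction across fractions — deliberately mirroring the
published selection rule. This is a caveat, not an endorsement: our null
simulations show the per-fraction test is exactly calibrated, yet the
minimum p over 90 correlated fractions dips below 0.05 in roughly a third
of null cohorts. An uncorrected scan therefore overstates significance, and
its family-wise false-selection rate cannot be pushed below ~10% at
realistic cohort sizes; the package reports the whole p-curve so users can
see how isolated a selection is.

## Regression

Features are the task-related DC, LE and CC plus ERD for the 18 bilateral
motor-area channels (FC1–FC6, C1–C6, CP1–CP6), outcome UL-FMA, stroke
subjects only. Stepwise selection works on a quadratic scope — intercept
plus linear, squared, and all pairwise-product terms — starting from the
intercept-only model, adding (then removing) single terms by partial-F
p-value at α = 0.05 for both entry and removal (one stated significance
level; the two α's are separately configurable). Hierarchy is deliberately
not enforced: the published final models contain squared terms without their
linear parents. A visited-state check stops add/remove cycles.

Leave-one-out prediction refits the *coefficients* per fold while keeping
the term set fixed from selection on the full sample, matching the published
procedure; this carries selection optimism, so a fully nested mode
(selection rerun inside every fold) is available via `nested = TRUE`.
RMSE is reported under both the /n and /(n−1) conventions, because the
printed results are not consistent with a single convention; correlation
between actual and predicted scores is the canonical comparison metric.
"Leave-one-out bootstrapping" for feature stability is read as: hold out one
subject (cycling), resample the remaining n−1 with replacement, rerun
selection, tally term frequencies. Resampling with replacement at n ≈ 10
duplicates rows and makes entry anti-conservative, so null features show
frequencies well above the nominal α; a genuinely driving feature still
separates cleanly (frequency > 0.8 in validation).

## The synthetic cohort generator

Real patient EEG for this design is not publicly available, so the
generator is a first-class module that produces cohorts with the exact
statistical structure the analysis assumes:

- **Protocol defaults** match the study: 64 channels at 256 Hz, 42 trials
  per subject, epochs −2…+5 s, two groups.
- **Couplings.** Each planted edge is one latent band-limited oscillator
  (per-trial random frequency inside the band and random phase) projected
  directly to channel i and with phase delay φ to channel j at the given
  strength — the simplest generative model whose ground-truth iCOH is
  analytically controllable: φ = 0 must give iCOH ≈ 0, φ = π/2 maximal.
- **Volume conduction** is a zero-lag common source mixed into all channels
  (default on, strength 0.5) so the iCOH insensitivity claim is exercised,
  not assumed.
- **ERD effects** scale the post-window amplitude of a baseline oscillation
  by √ratio, so post/pre band power equals the requested ratio.
- **Outcome.** UL-FMA = intercept + Σ coefficient × realized feature
  magnitude + Gaussian noise, clipped to [0, 66]. Per-subject feature
  magnitudes are the stated values times a lognormal factor (σ = 0.15 by
  default) — inter-subject variability of network effects is not reported
  anywhere, so it is an explicit free parameter rather than a hidden
  assumption.
- **Background** is white Gaussian noise per channel, so spectral content
  outside configured bands is flat by construction and band power scales
  quadratically with source amplitude — both are tested properties.
- All draws come from one seeded generator in a fixed order; the same spec
  and seed reproduce a cohort bit-for-bit, and `plantedTruth()` replays the
  subject-level draws without synthesizing signals.

What the generator does *not* emulate: head-model leadfields (mixing is
one-to-one plus a single common source, not a realistic forward model),
muscle/ocular artifacts (the artifact hook is a pass-through), 1/f spectral
background, or nonstationarity within windows. Passing tests therefore show
the *analysis* is correct and calibrated under its own assumptions — they do
not certify performance on real sensor data, where reference choice,
artifact residue and source mixing are harsher. One observed consequence
already appears synthetically: the common average reference spreads a
planted single-channel oscillation into all channels, so channel-level
attribution of a selected feature is not identifiable at small n even when
prediction is nearly perfect.

## Numerical choices and degenerate inputs

- Frequency bins are inclusive `[low, high]` on the 1 Hz grid; 13 Hz
  belongs to both alpha and beta, as with the usual band conventions.
- Coherency magnitudes are clamped at 1 against round-off; band iCOH is
  exactly antisymmetrized and zero-diagonal.
- A single trial, a zero auto-spectrum, an empty band, a single channel for
  re-referencing, a constant sample in correlation, and a singular
  leave-one-out refit are all hard errors naming the culprit.
- Subjects whose pre-window global efficiency is 0 at some scan fraction are
  excluded from that fraction's contrast only.
- Degenerate rank-sum input (all values identical) returns p = 1 with a
  warning instead of erroring, since a scan legitimately hits all-tied
  fractions (e.g. complete graphs pre and post).

## Validation problem sizes

The test suite validates each stage at sizes chosen to finish in minutes on
one CPU while keeping the statistical properties meaningful: exhaustive
graph-oracle equivalence over all 2¹⁵ six-node (and every smaller)
adjacency patterns; 200-trial windows for zero-lag suppression; a
200-cohort Monte-Carlo null for planted-coupling detection; 2000 null
simulations for ANCOVA type-I calibration; 100 null cohorts for the
threshold-scan false-selection rate; 1000 bootstrap runs for stability.
End-to-end pipeline checks use 8-channel, 24-trial, 12-subject cohorts with
epochs −1…+1.5 s; all sizes are visible in the tests and scale up by
changing the cohort specification.

## Known limitations

- The uncorrected threshold scan's selection is anti-conservative by
  design (see above).
- Term selection on the full sample before leave-one-out validation
  carries optimism; use `nested = TRUE` for honest error estimates.
- Binary graphs discard iCOH magnitudes beyond the ranking; the sign of
  iCOH is recorded but unused.
- The generator's linear mixing cannot produce realistic topographies;
  conclusions about specific channels on real data need source-space
  analysis or at least reference-sensitivity checks.
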