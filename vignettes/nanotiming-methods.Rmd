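---
title: "Models and methods behind nanotiming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanotiming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanotiming)
```

`nanotiming` analyses TIMING assays: nanowell grids in which a single
effector (CAR T cell) is confined with one to five tumor cells and at
least one cytokine-capture bead, imaged at 5-minute intervals for 6 hours.
This vignette explains the models the package implements, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the numerical conventions adopted where the underlying procedure is
not fully specified by its field.

## The nanowell simulation model

`simulate_chip()` is a first-class, ground-truthed generator, not a test
fixture. Each well is independent (nanowells confine cells; there is no
division or exit). The moving parts:

* **Motility.** Effectors follow a persistent random walk: each frame the
  step direction is retained with probability `directional_persistence`
  and otherwise redrawn uniformly; step length is
  `migration_speed_um_min × frame interval`, with reflection at the well
  walls. This is the simplest motility model with a tunable "directional"
  phenotype, which is all the migration metrics require. Targets jitter
  with a 0.2 µm/frame Gaussian wobble; beads are static.
* **Conjugation.** A conjugation begins when the effector touches a live
  target (centroid distance ≤ sum of disc-equivalent radii, plus 1 µm
  capture slack), lasts a duration drawn from a gamma distribution
  (shape 2, mean `contact_duration_min`, floored at two frames), during
  which the effector stays on the target surface; contacts may repeat.
* **Killing.** At conjugation onset a Bernoulli draw with
  `kill_prob_per_contact` (capped by `max_kills`) decides whether this
  contact kills. Annexin-V onset occurs `death_latency_min` (gamma, mean
  25 min by default, floored at one frame) after the final detachment, so
  detachment strictly precedes apoptosis — the behavior the kinetic
  analysis is designed to detect. No published distribution exists for
  this latency, so it is an explicit, configurable distribution rather
  than a constant. Kills whose onset would fall beyond the imaging window
  are not ground-truth kills (the target survives the observation, as it
  would in a real assay).
* **Secretion.** Endpoint bead intensity is
  `baseline + secretion_rate × cumulative conjugated minutes + lognormal
  noise` (lognormal because fluorescence is strictly positive). Expected
  intensity is therefore non-decreasing in conjugation time, which the
  suite verifies.

The four bundled behavior profiles (`behavior_presets()`) realize the four
functional classes given conjugation: serial killers (fast, persistent,
repeated short kills, secreting), single killers (one kill, no
secretion), IFN-γ-only secretors (slow, very long conjugations — the
"stays attached" phenotype), and nonfunctional cells (conjugate without
killing or secreting). Speeds (4, 3.5, 1, 0.5 µm/min) and persistence
(0.85–0.2) bracket published T cell motility scales and were chosen once,
as the study conditions, to separate migratory from nonmigratory
phenotypes without making either deterministic.

**What the generator does not emulate**: optics (no point-spread function,
photobleaching or debris), cell division, effector–effector interactions,
partial occlusion beyond simple overwriting, and segmentation artifacts
other than 5% area noise. Consequently, passing tests demonstrate the
correctness and calibration of the analysis rules on data satisfying the
model's assumptions — not robustness to every imaging pathology of real
chips.

## Imaging conventions

Rendered wells are 4-channel tiles (effector dye, target dye, annexin-V,
bead). Segmentation thresholds each dye channel with Otsu (overridable),
fills holes, labels connected components and drops objects below
10 µm². Classification follows two declared rules replacing the trained
CNN used with real chips: beads versus cells by **size exclusion**
(area ≤ 40 µm² ⇒ bead; beads of radius ~2.5 µm are far smaller than cells
of radius 6–7 µm), and effector versus target by dye dominance. A cell
whose area exceeds 1.8× the tile's median cell area is flagged `merged`.

Linking is greedy nearest-neighbor per well and class against a
constant-velocity forecast of each chain (up to `max_step_um = 25`,
bridging gaps of one frame). The forecast term is what preserves identity
when two trajectories cross. Coordinates are in µm, origin at the well's
top-left corner, y increasing downward; the pixel size is mandatory
metadata.

Death calling requires **two consecutive frames** of annexin intensity
above threshold (default 0.5 on the unit intensity scale): at 5-minute
sampling a single positive frame is indistinguishable from noise, and the
two-frame rule makes the call monotone in the threshold. The annexin
positivity threshold and the bead normalization are not published for the
real pipeline; both are configuration with these documented defaults.

Track-table mode and image mode agree exactly on static, non-touching
scenes (verified in the suite). Once cells conjugate they merge under
threshold segmentation, so image-mode tracks differ during contact; the
kinetic analysis is therefore run on identified track tables (simulated
directly, or segmented from scenes where objects remain separable).

## Conjugations, kinetics, functional taxonomy

A **conjugate** is a stable effector–target contact lasting strictly more
than 5 minutes. Contact frames are those where the centroid distance is at
most the sum of disc-equivalent radii plus 2 µm slack (the geometric
definition of "contact" is ours; no published one exists). Runs of contact
frames tolerate one-frame gaps (segmentation flicker), and duration is
counted as `n_contact_frames × frame interval` — so at 5-minute sampling
one frame (5 min) fails the strict filter and two frames (10 min) pass.

Per effector–target pair: `t_Seek` is measured from assay start (whether
it should start at effector settling is not documented; assay start is the
reproducible choice), `t_Death` from first contact to annexin onset, and
`t_Contact` sums conjugated time clipped to the window between first
contact and death, which guarantees `t_Contact ≤ t_Death` for every killer
pair. A death is attributed to the effector when they share a conjugation
interval ending at most 120 minutes before the death (or ongoing at
death); with one effector per well this convention only guards against
spontaneous, unconjugated deaths.

Secretion is called per well against bead-only control wells:
positive when the well's median bead intensity exceeds the control mean
plus `k = 3` control standard deviations (≥ 10 controls required).

Effectors that never conjugate are excluded from the baseline population.
Conjugating effectors are partitioned: ≥ 2 attributed kills ⇒
multifunctional regardless of secretion; 1 kill ⇒ multifunctional if
secreting, otherwise kill-only monofunctional; 0 kills ⇒ IFN-γ-only
monofunctional if secreting, otherwise nonfunctional.

## Directional migration

Directional migration is movement whose direction is maintained for at
least one cell diameter. The package operationalizes "maintained" as a
45° cone: a run is a maximal stretch of consecutive steps each within 45°
of the run's cumulative displacement vector (no angular criterion is
published; 45° separates persistent from diffusive motion at these
sampling rates, and the suite verifies the runs against per-start
exhaustive extension). Near-zero steps count as pauses inside a run. A run
is retained only if its net displacement reaches one cell diameter — the
track-median disc-equivalent diameter, robust to frame-level area noise.
Runs never span a change of contact state; rates are summed run
displacement divided by minutes in the state, reported separately
out-of-contact and in-contact. A continuous rate (µm/min) rather than a
run count is used so group contrasts can use rank tests on a continuous
axis. The rate definition is validated by its invariances (rotation,
coordinate scaling) and by ordering properties between phenotypes, not
against any published distribution.

## Single-cell qPCR

Expression is `Et = max(0, LOD − Ct)` with the detection limit at 40
cycles (the common qPCR convention; configurable). QC flags genes detected
in no-cell/no-RT controls and removes cells expressing fewer than
`min_genes` genes. Differential expression uses the two-sided Mann-Whitney
U test per gene — consistent with the nonparametric group comparisons used
throughout — with Benjamini-Hochberg adjustment across the tested panel
and calls at q < 0.1; the correlogram uses Pearson correlation
("linearly correlated") masked at p < 0.05, with zero-variance genes
masked. Both tests are swappable via arguments. Calibration: under a null
generator the mean number of false calls stays below 0.1 × panel size, and
a 2-fold shift planted in six genes at 48/44 cells is recovered in ≥ 90%
of genes on average across seeds.

## Clinical H score and survival

`h_score = %mild·1 + %moderate·2 + %intense·3`, bounded by 0 (no staining)
and 300 (100% intense). ROC cutoff candidates are midpoints between
consecutive sorted unique scores; the default criterion is Youden's J with
ties broken toward the lower cutoff, and a target-specificity mode returns
the smallest cutoff with specificity at or above the target (the
optimality criterion behind the published cutoff is not stated, so both
modes are provided). Survival uses the Kaplan-Meier product-limit
estimator with the median defined as the first time S(t) ≤ 0.5 (undefined
if never reached) and the two-group log-rank test, two-sided throughout.
The cohort accepts one staining record per patient (how multiple
pathologists' reads are consolidated is unspecified upstream).

At very small cohorts (n ≈ 12) the chi-square reference for the log-rank
statistic deviates from its exact permutation null by up to ~0.05 in p;
the suite's permutation comparisons use a 0.06 tolerance covering that
approximation error plus Monte-Carlo noise.

## Numerical and engineering choices

* Determinism: every generator takes a seed and restores the caller's RNG
  state; identical seeds give identical datasets, and pipeline runs are
  bit-identical per configuration (verified byte-wise in the suite).
* Exact small-sample inference: Mann-Whitney uses the exact U distribution
  when the combined sample is ≤ 12 and tie-free, midranks plus normal
  approximation with continuity correction otherwise.
* Degenerate inputs are flagged, not silently dropped: constant genes
  (p = 1), zero-variance correlations, wells without beads, event-free
  cohorts (log-rank p = 1), degenerate masks (aspect ratio 1).
* Problem sizes in the suite — a 500-well chip for the kinetic,
  annotation and migration guarantees, 10–25 seeds for the DE
  calibrations, 10⁴ permutation shuffles — were chosen as the smallest
  sizes at which the checked contrasts are stable, and they run in about
  two minutes total.

## Known limitations

Threshold segmentation cannot separate touching cells (they are flagged,
not split); kill attribution is a convention, relevant only if multiple
effectors shared a well; the migration statistic is a declared definition
validated by ordering, not a reproduction of any published axis; and the
simulator's phenotypes are idealized mixtures — real infusion products
show continuous variation between these archetypes.
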