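# nanotiming

Dynamic single-cell profiling of CAR T cell–tumor cell interactions in
nanowell grids, as an installable, fully tested R package.

Time-lapse imaging microscopy in nanowell grids (TIMING) confines one
effector T cell with 1–5 tumor cells and cytokine-capture beads in each of
thousands of sub-nanoliter wells, imaged every 5 minutes for 6 hours. From
those movies one can read out, cell by cell, how a CAR T cell seeks,
conjugates, kills (and serially kills), secretes IFN-γ, and migrates — and
then connect those dynamic phenotypes to gene expression and to clinical
outcome. `nanotiming` implements that entire desk-scale workflow:

* **Simulation with ground truth** — `simulate_chip()` generates per-frame
  object tracks for a chip of independent nanowells (persistent-random-walk
  effectors, conjugation, killing with detachment-before-death latency,
  bead-bound secretion), plus the endpoint bead readout and a complete
  event log; `render_frames()` rasterizes wells into 4-channel image
  stacks; `simulate_qpcr_cohort()` and `simulate_clinical_cohort()`
  generate the expression and survival cohorts.
* **Imaging** — `segment_frame()` (Otsu threshold + connected components
  via EBImage), bead/cell discrimination by size exclusion,
  `link_tracks()` (greedy nearest-neighbor with constant-velocity
  forecast), `call_death()` (sustained annexin-V positivity).
* **Kinetics and annotation** — `detect_conjugations()` (stable contacts
  strictly longer than 5 minutes), `compute_kinetics()` with the three
  interaction parameters

  * t_Seek — time from assay start to first conjugation,
  * t_Contact — cumulative conjugation time from first contact to target
    death,
  * t_Death — elapsed time from first contact to apoptosis (annexin-V
    onset),

  and `annotate_function()`, the four-way taxonomy of conjugating
  effectors: **multifunctional** (serial killing, or one kill plus IFN-γ),
  **monofunctional** (kill-only or IFN-γ-only) and **nonfunctional**.
* **Migration** — `directional_runs()` operationalizes directional
  migration (direction maintained over at least one cell diameter) and
  `migration_rates()` splits it into out-of-contact and in-contact rates.
* **Single-cell qPCR** — `ct_to_expression()` (Et = LOD − Ct), QC against
  no-cell/no-RT controls, Mann-Whitney differential expression at FDR
  q < 0.1, and the migration correlogram masked at p < 0.05.
* **Clinical H score** — `h_score()` (H = %mild·1 + %moderate·2 +
  %intense·3, range 0–300), `roc_cutoff()` (Youden or target-specificity),
  Kaplan-Meier (`km_estimate()`), log-rank (`logrank_test()`), and
  `stratified_pfs()` for progression-free survival split at an H-score
  cutoff.
* **Pipeline** — `run_pipeline()` orchestrates all stages with seeds,
  config hashes and provenance headers; `report()` summarizes the group
  contrasts (medians/quartiles, pairwise Mann-Whitney, Kruskal-Wallis).

## Worked example

```r
library(nanotiming)

chip <- simulate_chip(assay_config(wells = 200, control_wells = 20,
                                   rng_seed = 42),
                      behavior_presets(), rep(0.25, 4))
ana <- analyze_chip(chip$tracks, chip$endpoint)
print(ana)
#> timing_analysis: 200 wells of interest, 1003 conjugations, 155 kills
#> monofunctional_ifng monofunctional_kill     multifunctional       nonfunctional
#>                  48                  37                  56                  50
#>                <NA>
#>                   9

kk <- ana$kinetics[ana$kinetics$kill & ana$kinetics$valid, ]
median(kk$t_contact); median(kk$t_death)
#> [1] 45
#> [1] 65
mann_whitney_u(kk$t_contact, kk$t_death)$p_two_sided
#> [1] 3.1e-08
```

All 200 single-effector wells conjugated; the nine `NA` wells formed no
conjugate and are excluded from the baseline population. Among killer
pairs, cumulative conjugation (t_Contact, median 45 min) is significantly
shorter than time-to-death (t_Death, median 65 min): effectors detach
before their targets die.

The clinical arm, on a simulated 40-patient cohort whose below-cutoff
patients carry a 4-fold progression hazard:

```r
coh <- simulate_clinical_cohort(40, hazard_ratio = 4, seed = 1)
s <- stratified_pfs(coh, cutoff = 80)
s$median_high; s$median_low; s$logrank$p_two_sided
#> [1] 30.2
#> [1] 6.7
#> [1] 8.17e-06
```

Patients with H score ≥ 80 have a median PFS of 30.2 months versus 6.7
months below the cutoff.

A full demo run (`run_pipeline(default_run_config(seed = 1))`) writes
tracks, conjugations, kinetics, annotation, migration, qPCR and clinical
tables — each with a provenance header — plus `report.json`, in under a
minute. A thin command-line wrapper is provided in
`inst/scripts/timing-cli.R`.

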