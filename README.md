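# netsweep

Thresholding and scan–rescan consistency analysis for structural brain
networks.

## What this is for

Diffusion-MRI tractography yields weighted connectomes — here `N × N`
symmetric matrices over parcellated brain regions, weighted by number of
streamlines (NOS), fractional anisotropy (FA) and mean diffusivity (MD) —
that are contaminated by false-positive edges: low-weight connections that
appear and disappear between repeated scans of the same person.
Weight-based thresholding removes low-NOS edges to stabilise the network,
but in patient studies it must do so *without* destroying the disease
signal (interindividual variation, decline over time, group differences).

`netsweep` is for researchers who have such scan–rescan connectome
matrices (or want to simulate them) and need to choose a threshold. It
implements, as tested sweeps over threshold grids:

* **MST-anchored fixed-density thresholding** — the maximum spanning tree
  (Kruskal on NOS, density `2/N`) guarantees connectedness; edges are
  added strongest-first until a target density `d ∈ {.02, …, .40}` is
  reached — and **absolute thresholding** (keep `NOS ≥ t`,
  `t ∈ {1, …, 40}`).
* **Consistency statistics** per subject × level: dice similarity of edge
  sets `2|A∩B|/(|A|+|B|)`, and one-way random-effects ICC
  `(MSb − MSw)/(MSb + (k−1)MSw)` of edge weights (over common edges), of
  degree, and of betweenness centrality; plus a paired test of each level
  against unthresholded.
* **Graph metrics**: degree, normalised betweenness centrality, global
  efficiency (mean of inverse shortest path lengths by default), and
  FA/MD-weighted node strength.
* **Sensitivity analysis**: per-level longitudinal z-scores (follow-up
  standardised by baseline mean/SD), cross-threshold Pearson correlation
  matrices for baseline values and change scores, and a 2×2 mixed ANOVA
  (time within, group between via WMH-volume median split) from explicit
  Type III sums of squares, with F on `(1, n−2)` df and Cohen's d per
  effect.
* **A synthetic scan–rescan cohort generator** with recorded ground truth
  (persistent true backbone, session-independent low-weight false
  positives, weight-dependent dropout, subject/session noise, group and
  time effects) for calibration and recovery testing.

See `vignettes/thresholding-methods.Rmd` for the model conventions and
their rationale.

## Worked example

```r
library(netsweep)

cfg <- generator_config(n_subjects = 20, seed = 42)  # 90-node default world
gen <- generate_cohort(cfg)
gen$cohort
#> <cohort> 20 subjects x 2 sessions, 90 nodes

tc <- apply_fixed_density(gen$cohort$subjects[[1]]$baseline, 0.15)
tc
#> <thresholded_connectome> fixed_density @ 0.15: 601 edges (density 0.1501),
#>   90/90 nodes connected

cs <- consistency_sweep(gen$cohort, "fixed_density",
                        levels = round(seq(0.02, 0.30, 0.02), 2),
                        statistics = c("dice", "icc_edge_weight"))
subset(cs$summary, statistic == "dice")[, c("level", "mean", "sd")]
#>  level  mean      sd
#>     NA 0.747 0.00748      <- unthresholded
#>   0.02 0.802 0.02664      <- MST only
#>   ...
#>   0.12 0.944 0.00604      <- maximum: best scan-rescan edge overlap
#>   ...
#>   0.20 0.747 0.00748      <- shortfall region (= unthresholded)
cs$argmax[["dice"]]
#> [1] 0.12
```

The dice curve rises from .747 (unthresholded) to a maximum of .944 at
density .12 — thresholding removes the session-unstable false positives —
then collapses toward the MST floor (.02), where the tree must route
through weak edges. Mean dice at each level up to .18 differs from
unthresholded at `p < 1e-8` (paired t). Levels ≥ .20 exceed this cohort's
unthresholded density, so all edges are kept (`shortfall`) and the curve
is flat.

```r
sw <- sensitivity_sweep(gen$cohort, "mean_strength_FA", "fixed_density",
                        levels = c(0.10, 0.15, 0.20))
subset(sw$anova, effect == "group")
#>  effect    F df1 df2       p cohens_d level critical_F
#>   group 10.7   1  18 0.00419     1.47  0.10       4.41
#>   group 10.8   1  18 0.00405     1.47  0.15       4.41
#>   group 10.7   1  18 0.00423     1.46  0.20       4.41
```

The injected high-vs-low WMH group difference in FA strength stays
detectable (F well above the α = .05 critical value) across the density
band, i.e. these thresholds preserve the disease effect.

The same pipeline runs from the command line against a directory of
delimited matrices plus a `manifest.csv`
(columns: `subject_id, session, group, wmh_volume, followup_months,
nos_path, fa_path, md_path`):

```sh
exec/netsweep synth --out cohort/ --seed 1 --n-subjects 20
exec/netsweep run --cohort cohort/ --method fixed-density --out report/
```

`report/` then contains the per-level consistency summary, node-count
curves, cross-threshold correlation matrices (baseline and change),
per-level ANOVA tables and `run_metadata.json` recording every convention
choice, seed and a config hash.

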