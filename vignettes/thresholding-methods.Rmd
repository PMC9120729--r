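---
title: "Thresholding structural connectomes: methods, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thresholding structural connectomes: methods, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsweep)
```

## The problem

Structural brain networks reconstructed from diffusion MRI tractography
contain false-positive edges (reconstructed connections with no anatomical
counterpart) and false-negative dropouts. False positives are typically
low-weight — few streamlines (NOS) — and unstable between repeated scans,
which degrades the scan–rescan reproducibility of the network's
architecture. Weight-based thresholding removes low-NOS edges in the hope
of discarding mostly noise; the risk is that it also removes disease
signal. `netsweep` implements the two standard weight-based strategies as
full threshold *sweeps* and quantifies, per threshold level, (1) how
consistent the resulting architecture is between two sessions of the same
subject and (2) whether sensitivity to disease effects (interindividual
variation, change over time, group differences) is preserved.

## Thresholding

**Fixed-density thresholding** targets a common network density
$d \in [2/N, 1]$ for all subjects. To guarantee that no node is
disconnected, the maximum spanning tree (MST) of the NOS graph is computed
first — Kruskal's greedy rule, adding edges from strongest to weakest NOS
unless they close a cycle — and edges are then added in decreasing NOS
order until $\mathrm{round}(d \cdot N(N-1)/2)$ edges are kept. The MST of
a connected $N$-node graph has $N-1$ edges and density $2/N$ ($\approx
.02$ for $N = 90$), which is the lower end of the canonical sweep grid
(densities $.02$–$.40$ in steps of $.01$).

**Absolute thresholding** keeps edges with $\mathrm{NOS} \ge t$ for
$t = 1 \dots 40$. It gives no connectivity guarantee; the number of nodes
retaining at least one edge is tracked per level
(`connected_node_count`).

Numerical conventions, chosen once and asserted by tests:

* *Rounding*: the target edge count uses round-half-away-from-zero, which
  is platform-stable (base R `round()` is banker's rounding).
* *Tie-breaking*: edges are totally ordered by (NOS descending, $i$
  ascending, $j$ ascending). This makes the MST, the density filling, and
  therefore the whole pipeline deterministic, and makes kept sets nested
  across density levels even with tied weights.
* *Grid floor*: the canonical grid quotes the MST density rounded to two
  decimals, so targets down to $\mathrm{round}(2/N, 2)$ are accepted and
  clamped to exactly the MST rather than rejected.
* *Shortfall*: subjects whose unthresholded density is below a target keep
  all their edges and carry a `shortfall` flag. The alternative — erroring
  — would make the upper end of the grid unusable, since it is defined as
  a cohort mean that roughly half the subjects sit below.
* *Channels*: thresholding always uses NOS. FA and MD are masked to the
  kept edge set afterwards and only enter through node strength.

## Consistency statistics

Let $A$ and $B$ be the kept edge sets of the two sessions after applying
the *same* threshold spec to each.

* **Dice similarity** $= 2|A \cap B| / (|A| + |B|)$. Undefined (reported
  `NA`) when both sets are empty.
* **ICC** uses the one-way random-effects, single-measurement form
  $\mathrm{ICC} = (MS_b - MS_w) / (MS_b + (k-1) MS_w)$ with $k = 2$
  sessions. The "subjects" of the classical formula are *items within one
  participant*: the common edges (for edge-weight ICC, measured on NOS)
  or all $N$ nodes (for degree and betweenness ICC). Cohort-level curves
  are means of per-participant ICCs — this matches per-subject SD bands
  on consistency curves; pooling items across subjects is a possible
  variant that is deliberately not the default. Negative ICCs are
  reported as computed, never clamped.
* **Comparison against unthresholded** is a paired two-sided t-test on
  per-subject differences by default; the literature rarely names the
  test used for such curves, so the family is configurable (Wilcoxon
  signed-rank as the alternative) and the choice is recorded in run
  metadata. All-zero differences give $p = 1$.

## Graph metrics

Degree and betweenness centrality (binary topology, fractional counting
of tied shortest paths, normalised by $(N-1)(N-2)/2$) feed the hub-score
ICCs. Subject-level outcomes are global efficiency and FA/MD-weighted
node strength (mean channel weight over a node's kept edges; nodes with
no kept edges are *undefined*, excluded from means rather than imputed as
zero — a zero would conflate disconnection with low anisotropy).

Global efficiency is stated in the literature both as "mean of inverse
shortest path lengths" and "inverse of the average shortest path length".
The two only differ on disconnected or irregular graphs. The default here
is the mean-of-inverses form (disconnected pairs contribute 0), which is
robust to fragmentation under absolute thresholding; the
inverse-characteristic-path-length form is selectable
(`convention = "inverse_mean"`) and the choice is recorded in outputs.
Efficiency is computed on the binary kept topology by default; weighted
shortest paths (edge length $1/w$) are available via
`efficiency_weights`.

## Sensitivity analysis

Subject-level metrics at every level are z-scored per level using the
**baseline** mean and sample ($n-1$) SD; follow-up values are standardised
with the same baseline parameters, so follow-up z-scores express change
relative to the baseline distribution, and the change score is baseline
minus follow-up (positive = decline). Pearson correlation matrices
between all level pairs — separately for baseline values and for change
scores — quantify whether interindividual variation survives
thresholding; the per-level baseline–follow-up correlation quantifies
whether subjects keep their relative position over time.

Group comparisons use a $2 \times 2$ mixed ANOVA (time within-subject,
group between-subject), with groups from a median split of WMH volume
(volumes strictly above the median are "high"; the median element itself
goes to "low"; subjects with missing volume are excluded from this stage
only). The F statistics are computed from explicit Type III sums of
squares of the split-plot design — for this design they reduce to
contrasts on subject means (group), change scores (interaction), and the
unweighted mean of group change means (time), each on $(1, n-2)$ degrees
of freedom. This removes any dependence on a stats package's defaults and
admits an independent textbook-SS oracle in the tests. Follow-up-interval
differences are deliberately not adjusted for (they are part of the
interindividual variation under study) but the interval is carried in
outputs.

Cohen's d is reported per effect with explicit conventions — effect sizes
in mixed designs are often quoted without stating the standardiser, which
makes them uninterpretable, so the conventions here are fixed and
recorded: time = mean paired difference /
pooled SD of the two sessions; group = difference of group means of
subject means / pooled between-subject SD; interaction = difference of
group mean changes / pooled SD of change scores. When an effect's sum of
squares is exactly zero, F (and d) are reported as 0 even if the error
term is degenerate — this makes the noise-free identity cohort give
F = 0 rather than 0/0.

## The synthetic cohort generator

Real scan–rescan connectome cohorts of this kind are not publicly
deposited, so the generator states a world with the statistical features
the analysis assumes, with recorded ground truth:

* a **true edge backbone** shared by all subjects and sessions, sampled
  at density 0.15 (within the 0.05–0.30 range typically estimated for
  structural connectomes) and kept connected (rejection sampling; near
  tree density, where rejection cannot succeed, a random spanning tree is
  anchored first);
* **log-normal NOS** on true edges (meanlog 3, sdlog 1: median ≈ 20
  streamlines, heavy upper tail) — order-of-magnitude choices, since the
  real distribution is pipeline-dependent;
* **false positives**: each absent pair appears with probability 0.05 per
  session, *independently across sessions*, with low weights (1–5
  streamlines). This is the mechanism that makes thresholding improve
  dice — removed edges are noisy connections with an unstable, low-weight
  distribution — and the generator warns if the configured weights
  overlap the bulk of true-edge weights;
* **false negatives**: true edges drop out with probability
  $\mathrm{logit}^{-1}(0.5 - 1.5 \log \mathrm{NOS})$, so weak edges drop
  most (≈ 60% at NOS = 1, ≈ 2% at NOS = 20);
* **noise**: per-subject log-normal NOS scaling (sdlog 0.15),
  multiplicative session noise (CV 0.2), and additive
  subject/session/edge noise on FA (0.45 ± 0.06 per edge) and MD
  ((0.80 ± 0.08) × 10⁻³ mm²/s);
* **effects**: standardised group effects (default d = 0.5: FA down, MD
  up, NOS scale down in the high-WMH group) and a longitudinal decline
  (default d = 0.3 per follow-up). WMH volumes are log-normal with the
  high group drawn from the upper half, so the pipeline's median split
  recovers the true groups;
* **reproducibility**: a single master seed drives derived per-subject
  and per-session streams, so any subject's data are identical regardless
  of cohort size.

Defaults were fixed before the acceptance measurements and are not tuned
to test outcomes. Sample sizes mirror the motivating cohort (86 patients,
90 nodes, follow-up 22–35 months).

What a green test on this generator does **not** establish: the generator
has no spatial embedding, no distance-dependent false-positive structure,
no heteroscedasticity between subjects, and its noise is exchangeable
across edges — real tractography errors are none of these. Consistency
curves and power estimates on synthetic cohorts demonstrate that the
*pipeline* behaves as designed, not that any particular threshold is
optimal for a given real dataset.

## Known limitations and open points

* Whether streamline counts should be volume-corrected is left to the
  caller; raw NOS is assumed.
* The density grid endpoint (.40) is a cohort property (mean
  unthresholded density); the grid is configurable, and the generator's
  default world has unthresholded densities around .18, so upper grid
  levels carry shortfall flags there by design.
* The weight channel for shortest paths in global efficiency is not
  standardised in the field; binary is the default and the choice is
  recorded rather than guessed.
* A power analysis note: a between-group effect of d = 0.5 with 43
  subjects per group has ≈ 0.63 power at α = .05 (two-sided); pipelines
  cannot exceed the power of the underlying test, which bounds what any
  threshold level can "preserve".
* The recommended-band rule (within 1 SD of maximum mean dice and no
  fragmented nodes) is an explicit operationalisation of a narrative
  recommendation; both the SD tolerance and the rule itself are
  configurable and recorded in run metadata.
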