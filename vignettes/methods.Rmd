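---
title: "Switching predictability and mutual-information connectivity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Switching predictability and mutual-information connectivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miFCswitch)
```

## The scientific problem

Task switching is costly: responses slow and accuracy drops on trials where
the task rules change. How costly depends on how *predictable* the switches
are — when they occur (sequential predictability), what stimulus category
comes next (perceptual predictability), and where attention must move next
(spatial predictability). A factorial task that crosses these three
dimensions at two levels each (a 2x2x2 space of eight block types) lets one
ask which dimension modulates behaviour, regional activity, and — the focus
of this package — functional connectivity between brain regions, estimated
as the pairwise *mutual information* of regional BOLD timeseries (miFC).

`miFCswitch` implements that full analysis chain as a simulation-validated
pipeline: every stage can be exercised on synthetic data with known ground
truth, so the statistical machinery is testable end-to-end without any
scan data.

## The task generator

`generateDesign()` builds sessions of 3 runs x 8 blocks x 30 trials with
16 s of rest before each block. Each run presents all eight predictability
triplets once, in randomised order. Within a block, one switch falls in
each consecutive group of four trials (7 switches per 30-trial block; the
first trial always presents the initial rules). The predictable levels are
deterministic: switches every fourth trial, stimulus categories cycling
faces, lines, rooms, figures, and the attended row moving one position
down per switch. The unpredictable levels are constrained pseudo-random:
uniform switch position within each later group of four; categories drawn
to avoid both the cycle's next step and a repeat of the current category;
row moves of one position up or down with at most two consecutive moves in
the same direction.

Three choices here were genuinely open and are fixed as follows.
The attended row wraps from row 4 back to row 1, the only closure that
keeps seven predictable downward moves well-defined on four rows. The
direction-frequency constraint on unpredictable spatial moves is read as
"no more than two consecutive moves in the same direction". And the first
trial of every block is counted as a switch trial (it presents rules),
which is what makes the per-block tally 7 with a switch in every group of
four.

Trial timing: a switch trial occupies 6 s (0.5 s attend cue, 4 s flankers,
1.5 s probe) and a stay trial 2 s (cue + probe), giving 88 s blocks and
832 s runs — 416 volumes at TR 2 s.

## The BOLD simulator and its ground truth

`simulateBold()` writes each region's series as HRF-convolved block
regressors (canonical double-gamma: response gamma of shape 6, undershoot
of shape 16, scale 1 s, undershoot ratio 1/6; peak near 5 s) scaled by
per-region betas, plus Gaussian noise. Dependence is injected through the
noise: a coupled pair is drawn bivariate-normal at correlation rho (ground
truth MI = -1/2 log(1 - rho^2) nats) during the volumes of its active
conditions, and independently elsewhere; a *quadratic* pair passes one
region's noise through a unit-variance centred square, which is invisible
to Pearson correlation but carries substantial mutual information. The
default betas are zero so the injected dependence is exact; betas exist to
exercise the GLM stage, not the connectivity stage. A voxel grid, when
requested, broadcasts each region's series to its labelled voxels plus
voxel noise, so region-wise means reproduce the regional series — the
round-trip test for ROI extraction.

What the simulator does *not* emulate: spatial autocorrelation and
physiological noise spectra, scanner drift, slice timing, registration
error, and haemodynamic variability across regions. Passing tests
therefore establish that the statistical machinery is correct and
calibrated under clean dependence structure, not that real scans would
yield the same power.

## Watershed parcellation

`watershedParcellate()` segments a thresholded 3D statistic map by
inverting it (peaks become valley bottoms), ranking the suprathreshold
voxels, and flooding in rank order. Each voxel takes the first applicable
outcome: within 5 voxels (Euclidean, voxel units) of an existing basin
seed, it joins that basin; with no labelled 26-neighbours it seeds a new
basin; with labelled neighbours it goes winner-takes-all to the
neighbouring basin whose seed statistic is highest (ties to the smaller
label). After flooding, any region smaller than 100 voxels that touches
another region is absorbed into its strongest-seed neighbour, smallest
region first, to a fixed point. Plateau ties are broken by voxel
coordinate, so the labelling is deterministic and idempotent.

Open points decided here: adjacency is 26-connected (standard for smoothed
maps); "winner takes all" is resolved by seed statistic; merge order is
smallest-first with sizes re-evaluated after each merge. One behavioural
consequence worth knowing: boundary voxels between two touching basins are
contested and tend to go to the stronger basin, so nominal basin sizes are
approximate near shared faces.

## The miFC estimator

For two z-scored regional series, mutual information is estimated by a
plug-in Gaussian KDE: marginal and joint differential entropies are
computed by leave-one-out resubstitution and combined as
I = H(x) + H(y) - H(x,y). The joint kernel carries the sample covariance
(scaled by h^2), so the estimate adapts to the orientation of the cloud;
the marginals use the same per-dimension width in SD units.

Two numerical choices matter and were made once, against the closed-form
oracle for bivariate Gaussian data (I = -1/2 log(1 - rho^2)):

* **Leave-one-out evaluation.** Including the self-term inflates the joint
  density at sample points more than the marginals (the joint constant is
  O(1/(n h^2)) versus O(1/(n h))), which biases MI upward by about +0.01
  nats at n = 10^4 — an order of magnitude larger than the quantity of
  interest at weak coupling. Leave-one-out removes the self-term from all
  three entropies.
* **Bandwidth** h = 1.5 n^(-1/6) per dimension, the bivariate-rate power
  with a constant calibrated once so the leave-one-out estimator is
  unbiased on the Gaussian oracle to within sampling noise across
  n from block scale (~10^2) to 10^4 and rho from 0 to 0.9. Matching the
  marginal and joint per-dimension widths is what makes the smoothing
  biases cancel in the I = Hx + Hy - Hxy combination.

Raw MI is reported in nats (clipped at zero). The bounded miFC cell is
I / sqrt(H(x) H(y)), clipped to [0, 1]: 0 for independent series, 1 for
perfectly dependent ones (the estimator detects near-singular joint
covariance and saturates). This normalisation is a documented package
choice — a raw KDE MI is unbounded, and any [0, 1] mapping is a
convention; the raw nats are always carried alongside.

Per-condition matrices are computed per run from the volumes of each
condition's block after z-scoring the run and shifting the series forward
10 s (five volumes at TR 2 s) to meet the haemodynamic delay, then
averaged element-wise across runs. Blocks yield roughly 40 usable volumes;
pairs with fewer than 16 volumes are refused rather than estimated.
`sensitivityShift()` repeats the chain at 8 and 12 s shifts to show results
do not hinge on the 10 s choice.

## Reliability screening

ICC(A,k) — two-way model, absolute agreement, mean of k ratings — is
computed from the two-way ANOVA decomposition,
(MS_rows - MS_error) / (MS_rows + (MS_cols - MS_error) / n). The rating
for a region is the mean of its miFC row (diagonal excluded); within-
subject reliability treats regions as targets and runs as raters (one ICC
per subject), across-subject reliability treats subjects as raters (one
ICC per run). Whether "miFC per region" means the row mean or the full row
vector is not determinable from the method's description; the row mean is
the default and the choice is isolated in one helper. Subjects whose ICC
falls more than 2 SD below the group mean are excluded — a principled
numeric form of an exclusion that is otherwise descriptive ("noticeably
less reliable"); zero between-target variance yields ICC 0 with a warning
rather than an error.

## Edgewise factorial inference

For every unordered region pair, the eight per-condition miFC values per
subject enter a fully within-subject 2x2x2 repeated-measures ANOVA. For
two-level within factors each of the seven effects reduces exactly to a
paired contrast: F = n d^2 / var(c_s) with df (1, n-1), where c_s is
subject s's marginal mean difference — the squared paired t. (No
sphericity correction is needed at df 1.) Effect size is
eta^2 = SS_effect / SS_total. The suite cross-checks this machinery
against `aov()` with Error strata to 1e-8.

P values are BH-FDR adjusted across edges *within each effect family*
(whether the correction family should pool effects is not decidable from
the description; per-family is the default and exposed). Under a global
null, BH guarantees at most a 5% chance of any rejection per family — the
calibration the acceptance suite verifies on 100 all-null cohorts for the
sequential family. Direction of an FDR-significant main effect is the sign
of the median paired difference (predictable minus unpredictable) when a
paired Wilcoxon signed-rank test on the marginal means passes p < .05,
and 0 otherwise; zero differences are excluded per the signed-rank
convention.

Behavioural data go through the matching contract: correct-trial RTs are
rank inverse-normal transformed (normal quantiles of mid-rank plotting
positions, ties averaged) and fitted by a linear mixed model with subject
random intercepts; accuracy by a binomial mixed model. The package's own
contribution there is the data assembly and the transform; the solvers are
the standard mixed-model fitters.

## Network graphs

FDR-significant region pairs are grouped by the functional networks of
their endpoints; each distinct pair contributes to exactly one network
edge. The weight of a cross-network edge is, by default, the larger count
of distinct regions contributing on either side ("regions" mode): two
control regions significantly connected to two default-mode regions give
a control-default weight of 2 however the four pairs are arranged. The
alternative "pairs" mode counts distinct significant pairs (4 in that
example). The field's verbal definition ("weighted by the number of
regions") and its worked example disagree with pair counting, so the
example-consistent mode is the default and both are implemented.
Within-network edges are kept in the structure (weighted by pair count)
and only dropped at the display stage; degree is the sum of incident edge
weights with self-loops counted once. `consolidateSubnetworks()` sums edge
weights under a 17-to-macro scheme and, under the display rule, drops
within-macro edges and degree-0 nodes; cross-macro weight is conserved.

## Problem sizes and determinism

The simulated study conditions follow the design: 3 runs x 8 blocks x 30
trials, TR 2 s, DVARS threshold 50 on a median-1000 intensity scale with
exclusion above 20% flagged volumes, watershed threshold z > 3.1 with
5-voxel seed radius and 100-voxel merge, FDR q < .05. Cohort-level test
fixtures use 6-20 subjects and 6-12 regions — large enough to calibrate
type-I error, FDR behaviour and power (the injected rho 0.2 -> 0.7 edge is
detected with power >= 0.8 at 20 subjects) while keeping the suite quick;
the miFC matrix contract is additionally exercised at the full 100-region
scale. Every stochastic stage takes an explicit seed, derived
deterministically from the master seed, and identical configurations
reproduce byte-identical outputs (hashes recorded in a per-run manifest).

## Known limitations

* The watershed is a faithful reconstruction of the described
  invert-rank-flood algorithm, but the original toolbox's exact
  winner-takes-all and flood-rate semantics are not recoverable from its
  description; labellings may differ in contested boundary voxels.
* The [0, 1] normalisation of miFC is a package convention (see above).
* MI here is symmetric and non-directional; nothing causal is implied.
* Group-level GLM inference is desk-scale OLS per voxel/region with BH
  correction — deliberately not a mixed-effects neuroimaging stack with
  random-field cluster inference.
* The behavioural stage validates recovery of injected switch costs and
  accuracy shifts by simulation; it does not reproduce any particular
  cohort's statistics.
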