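# miFCswitch

Mutual-information functional connectivity under switching predictability.

Task switching is costly — responses slow and accuracy drops when task
rules change — and the cost depends on how *predictable* the switches are:
when they occur (sequential), what stimulus category comes next
(perceptual), and where attention moves next (spatial). `miFCswitch` is an
R package for analysing how these three predictability dimensions, crossed
in a fully factorial 2×2×2 block design, shape functional connectivity
between brain regions. Connectivity is measured as the pairwise **mutual
information** of regional BOLD timeseries (miFC),

> I(x;y) = ∬ p(x,y) log [ p(x,y) / (p(x)p(y)) ] dx dy
>        = H(x) + H(y) − H(x,y),

estimated by a leave-one-out Gaussian kernel density plug-in, which
captures nonlinear dependence that Pearson correlation misses. The package
is aimed at cognitive-neuroscience researchers who want this analysis
chain as tested, reusable building blocks, validated end-to-end on
synthetic data with known ground truth.

The pipeline stages, each an exported function family:

* **Task designs** — `generateDesign()`: factorial sessions (3 runs × 8
  blocks × 30 trials, 7 switch trials per block, one block per condition
  triplet per run) with deterministic predictable sequences and
  constrained pseudo-random unpredictable ones.
* **Synthetic BOLD** — `simulateBold()`, `simulateStatMap()`,
  `simulateMotion()`: regional timeseries with condition-dependent linear
  (bivariate normal, analytic MI = −½ log(1−ρ²)) or quadratic
  (Pearson-invisible) coupling, voxel grids, activation maps, motion.
* **Signals** — `extractRoiSeries()`, `zscoreSeries()`, `lagShift()`,
  `dvars()`, `expandMotionConfounds()`, `buildDesignMatrix()`,
  `olsContrast()`: ROI extraction, QC, the 16/8-regressor GLM design
  matrices with the 24-parameter motion expansion, and desk-scale OLS
  contrasts.
* **Parcellation** — `watershedParcellate()`, `labelToTable()`: 3D
  invert–rank–flood watershed (5-voxel seed radius, 100-voxel merge) with
  majority-overlap atlas labelling.
* **miFC** — `mutualInformation()`, `pairwiseMiFC()`,
  `mifcByCondition()`, `conditionAverageMiFC()`: per-condition symmetric
  miFC matrices in [0, 1] with unit diagonal.
* **Reliability** — `iccAk()`, `withinSubjectReliability()`,
  `exclusionScreen()`: ICC(A,k) (two-way, absolute agreement, mean
  ratings) screening.
* **Inference** — `rmAnova2x2x2()`, `edgewiseFactorial()`, `bhFdr()`,
  `rankInverseNormal()`, `behaviouralModels()`: per-edge 2×2×2
  repeated-measures ANOVA with BH-FDR per effect family, Wilcoxon-signed
  direction, η²; mixed-model behavioural stage.
* **Network graphs** — `buildNetworkGraph()`,
  `consolidateSubnetworks()`: significant edges grouped by functional
  network, weighted, with node degrees and macro-network consolidation.
* **Pipeline** — `pipelineConfig()`, `runEndToEnd()`,
  `sensitivityShift()`: the whole chain on a simulated cohort, with
  manifests and byte-reproducible outputs.

See `vignettes/methods.Rmd` for the model assumptions, parameter
defaults, and the design decisions behind the estimator.

## Worked example

```r
library(miFCswitch)

# a factorial session and a run of coupled synthetic BOLD
design <- generateDesign(runs = 3, seed = 1)
table(designTrials(design)$trial_type)
#>   stay switch
#>    552    168           # 720 trials; 7 switch per 30-trial block

coup <- couplingSpec(i = 1, j = 2, form = "linear", strength = 0.8,
                     conditions = "PPP")   # coupled only in the
                                           # all-predictable condition
bold <- simulateBold(design, run = 1, coupling = coup, nRegions = 4,
                     seed = 5)
rts <- roiTimeseries(regionalSeries(bold), tr = 2)

# per-condition miFC (z-score, 10 s lag shift, per-block estimates)
mats <- mifcByCondition(rts, design, run = 1, shiftS = 10)
round(mifcValues(mats[["PPP"]])[1, 2], 2)   # coupled condition
#> [1] 0.19
round(mifcValues(mats[["UUU"]])[1, 2], 2)   # uncoupled condition
#> [1] 0.02
```

The coupled pair shows elevated miFC exactly in the condition where the
coupling is active (single-block estimates use ~40 volumes; averaging
across runs, as the pipeline does, sharpens them). At cohort level, `runEndToEnd(pipelineConfig(...))`
simulates subjects, screens reliability, runs the edgewise factorial
ANOVA with FDR control, and summarises significant edges as network
graphs:

```r
res <- runEndToEnd(pipelineConfig(nSubjects = 12, nRegions = 12, seed = 7))
res$effects
#> EdgeEffectTable: 66 edges x 7 effects, 11 subjects
#>   FDR-significant (q < .05):  seq=3, seq:perc=1
```

The injected sequential-predictability edge (regions 1–2, ρ 0.2 → 0.7) is
recovered with direction +1 (miFC higher under predictable switching).

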